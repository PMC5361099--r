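#' Draw Poisson molecule counts for a layout
#'
#' Grand-canonical loading: the count in partition i is Poisson with mean
#' `concentration * d_i * v_i`, independently across partitions and
#' replicates.
#'
#' @param layout A [assay_layout()].
#' @param concentration True concentration C.
#' @param n Number of replicate assays.
#' @return An `n` x `n_partitions` integer matrix of counts.
#' @export
sample_counts <- function(layout, concentration, n = 1) {
  if (concentration < 0) stop("'concentration' must be >= 0")
  dv <- modulations(layout)
  matrix(rpois_safe(n * length(dv), rep(concentration * dv, each = n)),
         nrow = n)
}

# rpois() overflows the integer range for very large means (the largest
# calibration compartments); a normal approximation is exact to within
# O(1/sqrt(lambda)) there and only the log of these counts ever matters
rpois_safe <- function(n, lambda) {
  big <- lambda > 1e9
  out <- numeric(n)
  if (any(!big)) out[!big] <- stats::rpois(sum(!big), lambda[!big])
  if (any(big))
    out[big] <- round(stats::rnorm(sum(big), lambda[big], sqrt(lambda[big])))
  out
}

#' Simulate threshold cycles from molecule counts
#'
#' Amplicon number grows as `m * q^cycles`, so a partition starting from
#' `m` molecules crosses the fluorescence threshold at
#' `ct = ct_calibration - log_q(m)` cycles, where `ct_calibration` is the
#' crossing cycle of a single starting molecule. Gaussian noise of sd
#' `ct_sd` cycles models threshold-crossing read error. Partitions with
#' fewer than `m_threshold` molecules, or whose crossing falls beyond
#' `max_cycles`, read negative (the latter flagged as censored).
#'
#' @param m Integer vector of starting molecule counts.
#' @param q True per-cycle amplification factor.
#' @param ct_calibration Crossing cycle of a single starting molecule
#'   (default 38).
#' @param ct_sd Gaussian Ct noise, in cycles (default 0.25).
#' @param max_cycles Length of the cycling program (default 45).
#' @param m_threshold Molecule threshold for a positive call.
#' @return List with vectors `signal`, `ct` (NA where negative), `censored`.
#' @export
simulate_ct <- function(m, q = 1.9, ct_calibration = 38, ct_sd = 0.25,
                        max_cycles = 45, m_threshold = 1L) {
  check_q(q)
  if (ct_sd < 0) stop("'ct_sd' must be >= 0")
  n <- length(m)
  signal <- as.integer(m >= m_threshold)
  ct <- rep(NA_real_, n)
  censored <- rep(FALSE, n)
  pos <- which(signal == 1L)
  if (length(pos)) {
    ct0 <- ct_calibration - log(m[pos]) / log(q)
    if (ct_sd > 0) ct0 <- ct0 + stats::rnorm(length(pos), 0, ct_sd)
    # partitions already above threshold when cycling starts read out at
    # the first cycle
    ct0 <- pmax(ct0, 1)
    late <- ct0 > max_cycles
    censored[pos[late]] <- TRUE
    signal[pos[late]] <- 0L
    ct[pos[!late]] <- ct0[!late]
  }
  list(signal = signal, ct = ct, censored = censored)
}

#' Simulate one assay readout
#'
#' Composes Poisson loading ([sample_counts()]) with real-time readout
#' ([simulate_ct()]) into a complete synthetic experiment on a layout.
#'
#' @inheritParams sample_counts
#' @inheritParams simulate_ct
#' @param seed Optional seed for reproducibility.
#' @param counts Optional precomputed count vector (one per partition),
#'   bypassing the Poisson draw.
#' @return A [assay_readout()].
#' @export
simulate_readout <- function(layout, concentration, q = 1.9,
                             ct_calibration = 38, ct_sd = 0.25,
                             max_cycles = 45, m_threshold = 1L,
                             seed = NULL, counts = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(counts)) counts <- drop(sample_counts(layout, concentration, 1))
  sig <- simulate_ct(counts, q = q, ct_calibration = ct_calibration,
                     ct_sd = ct_sd, max_cycles = max_cycles,
                     m_threshold = m_threshold)
  assay_readout(layout, signal = sig$signal, ct = sig$ct,
                censored = sig$censored)
}

# fast readout constructor for simulation loops (inputs already validated);
# builds the wells frame without data.frame()'s checking overhead
new_readout <- function(layout, signal, ct, censored) {
  wells <- structure(
    list(well_id = layout$partitions$well_id, signal = signal, ct = ct,
         censored = censored),
    class = "data.frame", row.names = seq_along(signal))
  structure(list(layout = layout, wells = wells), class = "synpcr_readout")
}

#' Concentrations on the central plateau of a layout
#'
#' Log-spaced concentrations centred on the geometric mean of the layout's
#' characteristic concentrations — the flat middle of its precision
#' profile, away from both sensitivity edges.
#'
#' @param layout A [assay_layout()].
#' @param n Number of points.
#' @param span_decades Total width of the point set in decades (default 2).
#' @return Numeric vector of concentrations.
#' @export
plateau_concentrations <- function(layout, n = 5, span_decades = 2) {
  centre <- exp(mean(log(log(2) / modulations(layout))))
  if (n == 1) return(centre)
  10^seq(log10(centre) - span_decades / 2,
         log10(centre) + span_decades / 2, length.out = n)
}

#' Concentration interval a layout is designed to cover
#'
#' @param layout A [assay_layout()].
#' @param dyn_range Dynamic range Omega = C+/C-; defaults to the layout's
#'   recorded design value.
#' @return Named vector `c(c_minus, c_plus)` centred (in log) on the
#'   layout's characteristic-concentration span.
#' @export
design_range <- function(layout, dyn_range = NULL) {
  if (is.null(dyn_range)) dyn_range <- layout$dyn_range
  if (is.null(dyn_range) || !is.finite(dyn_range))
    stop("no dynamic range recorded in the layout; supply 'dyn_range'")
  if (!is.na(layout$c_minus) && is.finite(layout$c_minus))
    return(c(c_minus = layout$c_minus, c_plus = layout$c_minus * dyn_range))
  centre <- exp(mean(log(log(2) / modulations(layout))))
  c(c_minus = centre / sqrt(dyn_range), c_plus = centre * sqrt(dyn_range))
}

#' Monte-Carlo precision profile of a layout
#'
#' At each concentration of a grid, simulates `replicates` complete
#' readouts and estimates the concentration with the requested readout
#' mode(s); records the precision `sigma(C)` and the relative bias
#' `mean(estimates)/C - 1`. The primary precision measure is the mean,
#' over replicates, of the posterior relative standard deviation
#' `sd(rho)/E(C)` — the width of the distribution that *is* the assay's
#' estimate; the sampling spread of the posterior means across replicates
#' (`sd/mean`) is reported alongside as `sigma_sampling` (it is larger for
#' sparse ladders, whose skewed log-wide posteriors make the posterior
#' mean a long-tailed point estimate). When several modes are given they
#' are applied
#' to the *same* simulated readouts (paired comparison). Boundary readouts
#' (all wells negative or all positive) are estimated too — their posterior
#' is dominated by one tail — and counted in `n_boundary`; a warning is
#' issued if they exceed 5% of replicates at any grid point.
#'
#' @param layout A [assay_layout()].
#' @param concentrations Concentration grid; default is 13 log-spaced
#'   points per decade across the layout's design range (or its plateau
#'   if no range is recorded).
#' @param replicates Simulated readouts per grid point.
#' @param mode Character vector, subset of `c("synergistic", "digital")`.
#' @param q_true True amplification factor used by the simulator.
#' @param fit_q If `TRUE` (default) the synergistic estimator re-estimates
#'   q per readout; otherwise it uses `q_fixed`.
#' @param q_fixed Fixed q for the estimator when `fit_q = FALSE`.
#' @param sigma_max If given, the measured dynamic range (widest contiguous
#'   grid interval with `sigma <= sigma_max`) is attached as attributes.
#' @param seed Seed for the whole profile (deterministic given layout and
#'   settings).
#' @inheritParams simulate_ct
#' @param n_grid Posterior grid size.
#' @param prior A [concentration_prior()].
#' @return A data frame of class `synpcr_profile` with columns
#'   `concentration`, `mode`, `sigma` (mean posterior relative sd),
#'   `sigma_sampling` (sd/mean of the posterior-mean estimates), `bias`,
#'   `n_boundary`, and attributes `replicates`, `seed`, and (if
#'   `sigma_max` given) `c_minus`, `c_plus`, `omega_measured`.
#' @export
precision_profile <- function(layout, concentrations = NULL,
                              replicates = 1000, mode = "synergistic",
                              q_true = 1.9, fit_q = TRUE, q_fixed = 1.9,
                              sigma_max = NULL, seed = NULL,
                              ct_calibration = 38, ct_sd = 0.25,
                              max_cycles = 45, m_threshold = 1L,
                              n_grid = 2000L,
                              prior = concentration_prior()) {
  stopifnot(all(mode %in% c("synergistic", "digital")))
  if (is.null(concentrations)) {
    rng <- tryCatch(design_range(layout), error = function(e) NULL)
    concentrations <- if (is.null(rng)) {
      plateau_concentrations(layout, n = 9, span_decades = 2)
    } else {
      ndec <- log10(rng[["c_plus"]] / rng[["c_minus"]])
      10^seq(log10(rng[["c_minus"]]), log10(rng[["c_plus"]]),
             length.out = max(2, ceiling(13 * ndec)))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_estimator(layout, prior, m_threshold, n_grid)
  dv <- modulations(layout)
  est <- array(NA_real_,
               dim = c(replicates, length(concentrations), length(mode)),
               dimnames = list(NULL, NULL, mode))
  rsd <- est
  nb <- matrix(0L, length(concentrations), length(mode),
               dimnames = list(NULL, mode))
  for (j in seq_along(concentrations)) {
    counts <- sample_counts(layout, concentrations[j], replicates)
    for (r in seq_len(replicates)) {
      sig <- simulate_ct(counts[r, ], q = q_true,
                         ct_calibration = ct_calibration, ct_sd = ct_sd,
                         max_cycles = max_cycles, m_threshold = m_threshold)
      rd <- new_readout(layout, sig$signal, sig$ct, sig$censored)
      for (md in mode) {
        fit <- fit_one_readout(prep, rd, md,
                               q = if (md == "synergistic" && !fit_q) q_fixed else NULL,
                               lean = TRUE)
        est[r, j, md] <- fit$mean
        rsd[r, j, md] <- fit$rsd
        if (fit$boundary != "none") nb[j, md] <- nb[j, md] + 1L
      }
    }
  }
  out <- do.call(rbind, lapply(mode, function(md) {
    e <- matrix(est[, , md], nrow = replicates)
    w <- matrix(rsd[, , md], nrow = replicates)
    mu <- colMeans(e)
    sdv <- apply(e, 2, stats::sd)
    data.frame(concentration = concentrations, mode = md,
               sigma = colMeans(w), sigma_sampling = sdv / mu,
               bias = mu / concentrations - 1,
               n_boundary = nb[, md], stringsAsFactors = FALSE)
  }))
  if (any(out$n_boundary > 0.05 * replicates))
    warning("more than 5% boundary (all-negative or all-positive) readouts ",
            "at some concentrations; sigma there reflects the prior bounds")
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  attr(out, "estimates") <- est
  if (!is.null(sigma_max)) {
    dr <- measured_dynamic_range(out, sigma_max)
    attr(out, "sigma_max") <- sigma_max
    attr(out, "c_minus") <- dr[["c_minus"]]
    attr(out, "c_plus") <- dr[["c_plus"]]
    attr(out, "omega_measured") <- dr[["omega"]]
  }
  class(out) <- c("synpcr_profile", "data.frame")
  out
}

#' Measured dynamic range of a precision profile
#'
#' The widest contiguous run of grid concentrations whose relative
#' standard deviation stays at or below `sigma_max`.
#'
#' @param profile A [precision_profile()] result (single mode, or the mode
#'   is selected with `mode`).
#' @param sigma_max Precision requirement.
#' @param mode Which mode's rows to use when the profile holds several.
#' @return Named vector `c(c_minus, c_plus, omega)`; zeros/NA if no point
#'   meets the requirement.
#' @export
measured_dynamic_range <- function(profile, sigma_max, mode = NULL) {
  p <- profile
  if (!is.null(mode)) p <- p[p$mode == mode, ]
  if (length(unique(p$mode)) > 1)
    stop("profile holds several modes; pick one with 'mode'")
  ok <- p$sigma <= sigma_max
  if (!any(ok)) return(c(c_minus = NA_real_, c_plus = NA_real_, omega = NA_real_))
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  ii <- which(runs$values)
  best <- ii[which.max(runs$lengths[ii])]
  lo <- p$concentration[starts[best]]
  hi <- p$concentration[ends[best]]
  c(c_minus = lo, c_plus = hi, omega = hi / lo)
}

#' @export
print.synpcr_profile <- function(x, ...) {
  cat(sprintf("Precision profile: %d concentrations x %d replicates\n",
              length(unique(x$concentration)), attr(x, "replicates")))
  for (md in unique(x$mode)) {
    s <- x$sigma[x$mode == md]
    cat(sprintf("  %-11s sigma: min %.3f, median %.3f, max %.3f\n",
                md, min(s), stats::median(s), max(s)))
  }
  if (!is.null(attr(x, "omega_measured")))
    cat(sprintf("  dynamic range at sigma <= %.2f: [%.4g, %.4g] (%.3g-fold)\n",
                attr(x, "sigma_max"), attr(x, "c_minus"), attr(x, "c_plus"),
                attr(x, "omega_measured")))
  invisible(x)
}

#' @export
plot.synpcr_profile <- function(x, ...) {
  modes <- unique(x$mode)
  cols <- c(synergistic = "firebrick", digital = "steelblue")
  graphics::plot(NA, xlim = range(x$concentration), ylim = c(0, max(x$sigma)),
                 log = "x", xlab = "concentration C",
                 ylab = "relative standard deviation", ...)
  for (md in modes) {
    p <- x[x$mode == md, ]
    graphics::lines(p$concentration, p$sigma, col = cols[[md]], lwd = 2)
  }
  if (!is.null(attr(x, "sigma_max")))
    graphics::abline(h = attr(x, "sigma_max"), lty = 2)
  graphics::legend("topright", legend = modes, col = cols[modes], lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Write a precision profile as CSV
#'
#' Columns `concentration,mode,sigma,bias,n_boundary` in the same dialect
#' as the well tables.
#'
#' @param profile A `synpcr_profile`.
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
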