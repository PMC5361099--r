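#' Monte-Carlo calibration of the design relations
#'
#' The geometry of an assay is controlled by two quantities: the common
#' ratio x of the modulation ladder, which sets the attainable (saturated)
#' precision `sigma_inf(x)`, and the margin half-width `deltaN_x` at which
#' adding further compartments around the active stripe no longer improves
#' the estimate. Both relations are regenerated here empirically: for each
#' x on a grid, a ladder centred on a reference concentration is simulated
#' with growing margins until the measured relative standard deviation
#' changes by less than `tol` between consecutive margin sizes, at which
#' point `sigma_inf(x)` and `deltaN_x` are recorded. Replicate draws are
#' shared across margin sizes (the smaller ladders are nested subsets of
#' the largest one), so the saturation test compares paired estimates.
#'
#' By the self-similarity of geometric ladders the calibration at one
#' reference concentration transfers to any concentration.
#'
#' @param mode `"synergistic"` or `"digital"` readout.
#' @param x_grid Grid of common ratios to calibrate.
#' @param replicates Monte-Carlo replicates per margin size (>= 1000
#'   recommended for production tables; smaller values give a coarser
#'   table).
#' @param seed Seed; every x uses a seed derived deterministically from it.
#' @param max_delta_n Margin half-width at which the search is cut off; an
#'   x that has not saturated by then is flagged `converged = FALSE`.
#' @param tol Relative change in sigma defining saturation (default 2%).
#' @param delta_n_step Margin increment between tested sizes.
#' @inheritParams precision_profile
#' @return Data frame of class `synpcr_calibration` with columns `x`,
#'   `sigma_inf`, `delta_n`, `converged`, and the Monte-Carlo settings as
#'   attributes.
#' @seealso [common_ratio_for_precision()], [design_assay()]
#' @export
calibrate_design <- function(mode = c("synergistic", "digital"),
                             x_grid = c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8,
                                        0.85, 0.9, 0.925, 0.95),
                             replicates = 1000, seed = 1,
                             max_delta_n = 30, tol = 0.02, delta_n_step = 2,
                             q_true = 1.9, fit_q = TRUE, q_fixed = 1.9,
                             ct_calibration = 38, ct_sd = 0.25,
                             max_cycles = 45, m_threshold = 1L,
                             n_grid = 2000L) {
  mode <- match.arg(mode)
  rows <- vector("list", length(x_grid))
  for (xi in seq_along(x_grid)) {
    x <- x_grid[xi]
    set.seed(seed + xi * 10007L)
    jmax <- max_delta_n
    # ladder centred (C* = 1) on the reference concentration C0 = 1
    dv_full <- log(2) * x^(seq(-jmax, jmax))
    counts <- matrix(rpois_safe(replicates * length(dv_full),
                                rep(dv_full, each = replicates)),
                     nrow = replicates)
    sims <- vector("list", replicates)
    for (r in seq_len(replicates))
      sims[[r]] <- simulate_ct(counts[r, ], q = q_true,
                               ct_calibration = ct_calibration,
                               ct_sd = ct_sd, max_cycles = max_cycles,
                               m_threshold = m_threshold)
    dns <- seq(delta_n_step, max_delta_n, by = delta_n_step)
    sigma_prev <- NA_real_
    sigma_inf <- NA_real_
    dn_sat <- max_delta_n
    converged <- FALSE
    for (dn in dns) {
      idx <- (jmax + 1) + (-dn:dn)
      sub <- assay_layout(dilution = rep(1, length(idx)),
                          volume = dv_full[idx], mode = mode)
      prep <- prepare_estimator(sub, m_threshold = m_threshold,
                                n_grid = n_grid)
      rsd <- numeric(replicates)
      for (r in seq_len(replicates)) {
        rd <- new_readout(sub, sims[[r]]$signal[idx], sims[[r]]$ct[idx],
                          sims[[r]]$censored[idx])
        f <- fit_one_readout(prep, rd, mode,
                             q = if (mode == "synergistic" && !fit_q) q_fixed else NULL,
                             lean = TRUE)
        rsd[r] <- f$rsd
      }
      sigma <- mean(rsd)
      if (is.finite(sigma_prev) &&
          abs(sigma - sigma_prev) < tol * sigma_prev) {
        sigma_inf <- sigma
        dn_sat <- dn
        converged <- TRUE
        break
      }
      sigma_prev <- sigma
      sigma_inf <- sigma
    }
    rows[[xi]] <- data.frame(x = x, sigma_inf = sigma_inf, delta_n = dn_sat,
                             converged = converged)
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  attr(out, "settings") <- list(q_true = q_true, fit_q = fit_q,
                                ct_sd = ct_sd,
                                ct_calibration = ct_calibration,
                                max_cycles = max_cycles,
                                m_threshold = m_threshold, tol = tol,
                                max_delta_n = max_delta_n)
  class(out) <- c("synpcr_calibration", "data.frame")
  out
}

#' @export
print.synpcr_calibration <- function(x, ...) {
  cat(sprintf("Design calibration table (%s mode, %d replicates)\n",
              attr(x, "mode"), attr(x, "replicates")))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write / read a calibration table as JSON
#' @param table A [calibrate_design()] result.
#' @param path File path.
#' @export
write_calibration <- function(table, path) {
  obj <- list(schema = "synpcr-calibration-v1",
              mode = attr(table, "mode"),
              replicates = attr(table, "replicates"),
              seed = attr(table, "seed"),
              settings = attr(table, "settings"),
              rows = as.data.frame(table))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "synpcr-calibration-v1"))
    stop("unknown calibration schema")
  out <- obj$rows
  attr(out, "mode") <- obj$mode
  attr(out, "replicates") <- obj$replicates
  attr(out, "seed") <- obj$seed
  attr(out, "settings") <- obj$settings
  class(out) <- c("synpcr_calibration", "data.frame")
  out
}

# monotone (nonincreasing in x) envelope of the calibrated sigma_inf, used
# for inversion; Monte-Carlo jitter can break strict monotonicity
monotone_sigma <- function(table) {
  o <- order(table$x)
  list(x = table$x[o], sigma = cummin(table$sigma_inf[o]),
       delta_n = table$delta_n[o])
}

#' Common ratio achieving a requested precision
#'
#' Inverts the calibrated `sigma_inf(x)` relation by monotone
#' interpolation: the looser the precision requirement, the smaller the
#' common ratio (the steeper the ladder).
#'
#' @param sigma_max Requested relative standard deviation (fraction).
#' @param table A [calibrate_design()] table for the intended readout mode.
#' @return List: `x`, interpolated `delta_n`, and the `sigma_inf` the table
#'   predicts at that x.
#' @export
common_ratio_for_precision <- function(sigma_max, table) {
  stopifnot(inherits(table, "synpcr_calibration"))
  ms <- monotone_sigma(table)
  if (sigma_max < min(ms$sigma)) {
    k_needed <- ceiling((min(ms$sigma) / sigma_max)^2)
    stop(sprintf(paste0("sigma_max = %.3g is below the single-copy limit ",
                        "%.3g of this table; use library_copies >= %d"),
                 sigma_max, min(ms$sigma), k_needed))
  }
  if (sigma_max >= max(ms$sigma)) {
    i <- which.max(ms$sigma)
    return(list(x = ms$x[i], delta_n = as.integer(ms$delta_n[i]),
                sigma_inf = ms$sigma[i]))
  }
  # sigma decreases with x: interpolate on the reversed axis
  xq <- stats::approx(rev(ms$sigma), rev(ms$x), xout = sigma_max,
                      ties = "ordered")$y
  dnq <- stats::approx(ms$x, ms$delta_n, xout = xq, ties = "ordered")$y
  list(x = xq, delta_n = as.integer(ceiling(dnq)), sigma_inf = sigma_max)
}

core_length <- function(dyn_range, x) {
  if (dyn_range <= 1) return(1L)
  max(1L, as.integer(ceiling(log(dyn_range) / -log(x))))
}

#' Design an assay for requested precision and dynamic range
#'
#' Implements the design recipe: from the requested precision the
#' calibration table gives the common ratio x and margin `deltaN`; the core
#' of the ladder needs `ceiling(log(Omega) / -log(x))` compartments to span
#' the dynamic range `Omega = C+/C-`, and `deltaN` margin compartments are
#' added on each side. The first (largest) compartment is sized so that the
#' largest characteristic concentration sits `deltaN` ladder steps above
#' `C+`. Precision below the single-copy limit of the table is reached with
#' libraries: `k` replicate copies of every modulation, which scales the
#' saturated sigma by about `1/sqrt(k)`. With `library_copies = NULL` the
#' design searches over k for the smallest total well count meeting
#' `sigma_max`.
#'
#' @param sigma_max Requested relative standard deviation (fraction in
#'   (0, 1)).
#' @param dyn_range Requested dynamic range Omega = C+/C- (>= 1).
#' @param table Calibration table for the intended mode
#'   ([calibrate_design()]).
#' @param c_minus Lower end C- of the concentration range (default 1; all
#'   quantities scale with it).
#' @param library_copies Number of copies of each modulation, or `NULL`
#'   (default) to choose the count automatically.
#' @return A `synpcr_layout` carrying the design metadata (`common_ratio`,
#'   `delta_n`, `sigma_max`, `dyn_range`, `c_minus`, `library_copies`).
#' @export
design_assay <- function(sigma_max, dyn_range, table, c_minus = 1,
                         library_copies = NULL) {
  stopifnot(inherits(table, "synpcr_calibration"))
  if (!is.finite(sigma_max) || sigma_max <= 0 || sigma_max >= 1)
    stop("'sigma_max' must be a fraction in (0, 1)")
  if (dyn_range < 1) stop("'dyn_range' must be >= 1")
  ms <- monotone_sigma(table)
  pick <- function(k) {
    target <- sigma_max * sqrt(k)
    if (target < min(ms$sigma)) return(NULL)
    d <- common_ratio_for_precision(min(target, max(ms$sigma)), table)
    n_base <- core_length(dyn_range, d$x) + 2L * d$delta_n
    list(x = d$x, delta_n = d$delta_n, k = k, n_base = n_base,
         n_total = k * n_base, sigma_pred = d$sigma_inf / sqrt(k))
  }
  if (is.null(library_copies)) {
    k_max <- max(8L, 2L * ceiling((min(ms$sigma) / sigma_max)^2))
    cand <- Filter(Negate(is.null), lapply(seq_len(k_max), pick))
    if (!length(cand))
      stop(sprintf("sigma_max = %.3g infeasible even with libraries up to %d copies",
                   sigma_max, k_max))
    best <- cand[[which.min(vapply(cand, `[[`, 0, "n_total"))]]
  } else {
    best <- pick(library_copies)
    if (is.null(best)) {
      k_needed <- ceiling((min(ms$sigma) / sigma_max)^2)
      stop(sprintf(paste0("sigma_max = %.3g is not reachable with ",
                          "library_copies = %d; needs >= %d copies"),
                   sigma_max, library_copies, k_needed))
    }
  }
  build_design_layout(best$x, best$delta_n, best$n_base, best$k,
                      sigma_max, dyn_range, c_minus, attr(table, "mode"))
}

build_design_layout <- function(x, delta_n, n_base, k, sigma_max,
                                dyn_range, c_minus, mode) {
  c_plus <- c_minus * dyn_range
  cstar_last <- c_plus * x^(-delta_n)     # largest C*, deltaN steps above C+
  cstar_first <- cstar_last * x^(n_base - 1)
  d0v0 <- log(2) / cstar_first
  dv <- d0v0 * x^(seq_len(n_base) - 1)
  dv <- rep(dv, each = k)
  lay <- assay_layout(dilution = dv / dv[1], volume = rep(dv[1], length(dv)),
                      common_ratio = x, delta_n = as.integer(delta_n),
                      mode = mode, sigma_max = sigma_max,
                      dyn_range = dyn_range, c_minus = c_minus,
                      library_copies = as.integer(k))
  lay
}

#' Best assay that fits a fixed well budget
#'
#' Searches the calibrated designs for the most precise assay that covers
#' `dyn_range` with at most `n_wells` compartments (library replication
#' allowed), then spends any leftover budget on additional copies of the
#' central modulations.
#'
#' @param n_wells Total well budget (e.g. 96).
#' @inheritParams design_assay
#' @return A `synpcr_layout` with exactly `n_wells` partitions; its
#'   `sigma_max` field records the predicted precision.
#' @export
design_for_wells <- function(n_wells, dyn_range, table, c_minus = 1) {
  stopifnot(inherits(table, "synpcr_calibration"))
  ms <- monotone_sigma(table)
  best <- NULL
  for (k in seq_len(max(1L, n_wells %/% 4L))) {
    n_base <- n_wells %/% k
    for (i in seq_along(ms$x)) {
      need <- core_length(dyn_range, ms$x[i]) + 2L * ms$delta_n[i]
      if (need > n_base) next
      sigma_pred <- ms$sigma[i] / sqrt(k)
      if (is.null(best) || sigma_pred < best$sigma_pred)
        best <- list(x = ms$x[i], delta_n = ms$delta_n[i], k = k,
                     n_base = n_base, sigma_pred = sigma_pred)
    }
  }
  if (is.null(best))
    stop(sprintf("no calibrated design covering a %.3g-fold range fits in %d wells",
                 dyn_range, n_wells))
  # enlarge the margins to spend the per-copy budget
  core <- core_length(dyn_range, best$x)
  dn <- max(best$delta_n, (best$n_base - core) %/% 2L)
  n_base <- core + 2L * dn
  lay <- build_design_layout(best$x, dn, n_base, best$k, best$sigma_pred,
                             dyn_range, c_minus, attr(table, "mode"))
  # pad the remainder with copies of the central modulations
  short <- n_wells - n_partitions(lay)
  if (short > 0) {
    dv <- modulations(lay)
    mid <- order(abs(log(dv) - stats::median(log(dv))))[seq_len(short)]
    dil <- c(lay$partitions$dilution, lay$partitions$dilution[mid])
    vol <- c(lay$partitions$volume, lay$partitions$volume[mid])
    o <- order(-dil * vol)
    lay <- assay_layout(dilution = dil[o], volume = vol[o],
                        common_ratio = best$x, delta_n = as.integer(dn),
                        mode = attr(table, "mode"),
                        sigma_max = best$sigma_pred, dyn_range = dyn_range,
                        c_minus = c_minus, library_copies = best$k)
  }
  lay
}

#' Minimal classic digital assay for a precision over a range
#'
#' For an assay of N identical partitions the relative standard deviation
#' of the most-probable-number estimate at occupancy `lambda = C d v` is
#' `sqrt((exp(lambda) - 1) / N) / lambda` (delta method on the binomial
#' fill fraction). A single partition size must satisfy the precision
#' requirement at both ends of the dynamic range, so the minimal N is the
#' smallest value for which the `sigma <= sigma_max` occupancy interval
#' spans a factor `dyn_range`; it is found at the occupancy placement where
#' both ends are equally hard.
#'
#' @inheritParams design_assay
#' @return List: `n` (minimal compartment count), `lambda_minus` (occupancy
#'   at C-), `lambda_plus`, and `sigma_check`, the analytic sigma at both
#'   ends (equal to `sigma_max` up to the integer ceiling).
#' @export
classic_minimum_wells <- function(sigma_max, dyn_range) {
  if (sigma_max <= 0 || dyn_range < 1) stop("invalid request")
  n_at <- function(lam) (exp(lam) - 1) / (lam^2 * sigma_max^2)
  worst <- function(loglam0) {
    l0 <- exp(loglam0)
    max(n_at(l0), n_at(l0 * dyn_range))
  }
  opt <- stats::optimize(worst, lower = log(1e-14), upper = log(30))
  l0 <- exp(opt$minimum)
  n <- ceiling(opt$objective)
  list(n = n, lambda_minus = l0, lambda_plus = l0 * dyn_range,
       sigma_check = sqrt((exp(c(l0, l0 * dyn_range)) - 1) / n) /
         c(l0, l0 * dyn_range))
}

#' Compare design strategies at a common requirement
#'
#' For each requested mode, designs an assay meeting (`sigma_max`,
#' `dyn_range`), verifies it by a Monte-Carlo precision profile across the
#' range, and reports the total compartment count; a design whose verified
#' plateau misses the requirement is re-issued with one more library copy
#' (at most `max_adjust` times). The classic identical-compartment assay is
#' sized analytically by [classic_minimum_wells()].
#'
#' @param sigma_max,dyn_range The common requirement.
#' @param tables Named list of calibration tables, one per mode to compare
#'   (names among `"synergistic"`, `"digital"`).
#' @param replicates Monte-Carlo replicates per verification point.
#' @param n_check Number of verification concentrations across the range.
#' @param seed Seed for the verification profiles.
#' @param include_classic Include the classic dPCR row.
#' @param max_adjust Maximum library-copy bumps when verification fails.
#' @param slack Multiplicative allowance on `sigma_max` when judging the
#'   verification (Monte-Carlo noise; default 5%).
#' @inheritParams precision_profile
#' @return Data frame with one row per mode: `mode`, `n`, `x`, `delta_n`,
#'   `library_copies`, `sigma_verified`.
#' @export
compare_designs <- function(sigma_max, dyn_range, tables,
                            replicates = 500, n_check = 5, seed = 1,
                            include_classic = TRUE, max_adjust = 2,
                            slack = 1.05, q_true = 1.9, fit_q = TRUE,
                            ct_sd = 0.25) {
  rows <- list()
  for (mode in names(tables)) {
    k <- NULL
    lay <- design_assay(sigma_max, dyn_range, tables[[mode]],
                        library_copies = k)
    for (try in seq_len(max_adjust + 1)) {
      rng <- design_range(lay)
      cc <- 10^seq(log10(rng[["c_minus"]]), log10(rng[["c_plus"]]),
                   length.out = n_check)
      prof <- precision_profile(lay, cc, replicates = replicates,
                                mode = mode, q_true = q_true, fit_q = fit_q,
                                ct_sd = ct_sd, seed = seed + try)
      sig <- mean(prof$sigma)
      if (sig <= sigma_max * slack || try > max_adjust) break
      k <- lay$library_copies + 1L
      lay <- design_assay(sigma_max, dyn_range, tables[[mode]],
                          library_copies = k)
    }
    rows[[mode]] <- data.frame(mode = mode, n = n_partitions(lay),
                               x = lay$common_ratio, delta_n = lay$delta_n,
                               library_copies = lay$library_copies,
                               sigma_verified = sig)
  }
  if (include_classic) {
    cl <- classic_minimum_wells(sigma_max, dyn_range)
    rows$classic <- data.frame(mode = "classic", n = cl$n, x = 1,
                               delta_n = NA_integer_, library_copies = 1L,
                               sigma_verified = max(cl$sigma_check))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
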