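#' Prior over the unknown concentration
#'
#' The default prior is flat in C between 0 and an upper bound `c_inf`
#' (density 1/c_inf), the conventional non-informative choice for digital
#' assays. A flat-in-log alternative (density proportional to 1/C on the
#' grid) is offered because the flat-in-C prior makes estimates weakly
#' dependent on `c_inf` near the upper boundary.
#'
#' @param form `"flat"` (in C, the default) or `"flat-log"`.
#' @param c_inf Upper bound C_inf; `NULL` (default) resolves, per layout, to
#'   1000 times the largest characteristic concentration, which coincides
#'   with the upper end of the posterior grid.
#' @return An object of class `synpcr_prior`.
#' @export
concentration_prior <- function(form = c("flat", "flat-log"), c_inf = NULL) {
  form <- match.arg(form)
  if (!is.null(c_inf) && (!is.finite(c_inf) || c_inf <= 0))
    stop("'c_inf' must be > 0")
  structure(list(form = form, c_inf = c_inf), class = "synpcr_prior")
}

# Precompute everything reusable across readouts of one layout: the
# log-spaced concentration grid spanning [C*_min/1e3, C*_max*1e3],
# trapezoid weights, and per-well log-probability matrices for the plain
# digital signals at threshold m_tr.
prepare_estimator <- function(layout, prior = concentration_prior(),
                              m_threshold = 1L, n_grid = 2000L) {
  check_threshold(m_threshold)
  dv <- modulations(layout)
  cstar <- log(2) / dv
  hi <- max(cstar) * 1e3
  lo <- min(cstar) / 1e3
  c_inf <- if (is.null(prior$c_inf)) hi else prior$c_inf
  hi <- min(hi, c_inf)
  if (hi <= lo) stop("prior upper bound 'c_inf' lies below the grid")
  log_grid <- seq(log(lo), log(hi), length.out = n_grid)
  grid <- exp(log_grid)
  # trapezoid weights on the non-uniform grid
  w <- c(diff(grid) / 2, 0) + c(0, diff(grid) / 2)
  lam <- outer(grid, dv)
  log_p0 <- stats::ppois(m_threshold - 1, lam, lower.tail = TRUE, log.p = TRUE)
  log_p1 <- stats::ppois(m_threshold - 1, lam, lower.tail = FALSE, log.p = TRUE)
  log_prior <- switch(prior$form,
    "flat" = rep(0, n_grid),
    "flat-log" = -log(grid)
  )
  list(layout = layout, dv = dv, grid = grid, log_grid = log_grid, w = w,
       log_p0 = log_p0, log_p1 = log_p1, log_prior = log_prior,
       m_threshold = as.integer(m_threshold), prior = prior, c_inf = c_inf)
}

# Per-well log-likelihood summed on the grid. `k` is the integer molecule
# threshold of each positive well (m_tr for a plain digital positive);
# negatives contribute the lower tail. Positives at the base threshold go
# through the precomputed matrix, so a synergistic readout with all
# delta_ct = 0 follows the digital code path bit for bit.
readout_loglik <- function(prep, signal, k = NULL) {
  pos <- which(signal == 1L)
  ll <- prep$log_prior
  sel <- numeric(length(signal))          # indicator of plain negative wells
  sel[signal == 0L] <- 1
  shifted <- integer(0)
  if (length(pos)) {
    if (is.null(k)) k <- rep(prep$m_threshold, length(pos))
    base <- k == prep$m_threshold
    shifted <- pos[!base]
    sel1 <- numeric(length(signal))
    sel1[pos[base]] <- 1
    if (any(base)) ll <- ll + drop(prep$log_p1 %*% sel1)
    if (length(shifted)) {
      kk <- k[!base]
      for (i in seq_along(shifted)) {
        dv_i <- prep$dv[shifted[i]]
        ll <- ll + log_pois_upper_tail(kk[i], prep$grid * dv_i,
                                       prep$log_grid + log(dv_i))
      }
    }
  }
  if (any(sel > 0)) ll <- ll + drop(prep$log_p0 %*% sel)
  ll
}

# log P(Pois(lambda) >= k) over a lambda vector. ppois (a regularized
# incomplete gamma) is called only inside the sigmoid's transition region
# lambda in (k/2, k + 12 sqrt(k) + 5]. Above it the log-tail is 0 to
# < 1e-30. Below it the tail series Q = pmf(k) * (1 + r1 + r1 r2 + ...)
# with r_j = lambda/(k+j) is summed with three exact terms and a geometric
# remainder, accurate to < 1e-3 in the log for lambda <= k/2 even at
# k = 1; log(pmf) is formed from the precomputed log-lambda.
log_pois_upper_tail <- function(k, lambda, log_lambda = log(lambda)) {
  hi <- k + 12 * sqrt(k) + 5
  lo <- k / 2
  out <- numeric(length(lambda))          # 0 above the window
  mid <- lambda > lo & lambda <= hi
  below <- lambda <= lo
  if (any(mid))
    out[mid] <- stats::ppois(k - 1, lambda[mid], lower.tail = FALSE,
                             log.p = TRUE)
  if (any(below)) {
    lb <- lambda[below]
    r1 <- lb / (k + 1)
    r2 <- lb / (k + 2)
    s <- 1 + r1 + r1 * r2 + r1 * r2 * (lb / (k + 3)) / (1 - lb / (k + 4))
    out[below] <- k * log_lambda[below] - lb - lgamma(k + 1) + log(s)
  }
  out
}

# Normalize a log-posterior on the grid and extract moments and central
# credible intervals by trapezoid quadrature.
posterior_from_loglik <- function(prep, ll) {
  m <- max(ll)
  dens <- exp(ll - m)
  z <- sum(prep$w * dens)
  dens <- dens / z
  mu <- sum(prep$w * dens * prep$grid)
  v <- sum(prep$w * dens * (prep$grid - mu)^2)
  sdv <- sqrt(max(v, 0))
  cdf <- cumsum(prep$w * dens)
  cdf <- cdf / cdf[length(cdf)]
  qs <- stats::approx(cdf, prep$grid, xout = c(0.025, 0.16, 0.5, 0.84, 0.975),
                      ties = "ordered", rule = 2)$y
  list(grid = prep$grid, density = dens, mean = mu, sd = sdv,
       rsd = sdv / mu,
       median = qs[3],
       mode = prep$grid[which.max(dens)],
       ci68 = qs[c(2, 4)],
       ci95 = qs[c(1, 5)])
}

#' Reference well of a synergistic readout
#'
#' Among the positive wells with a usable Ct, the reference well is the one
#' with the largest threshold cycle — the partition that started from the
#' fewest molecules. It anchors the cycle differences
#' `delta_ct_i = ct_ref - ct_i` used to sharpen the positive-well
#' likelihoods. Ties are broken towards the smaller modulation (the more
#' dilute partition).
#'
#' @param readout A [assay_readout()].
#' @return The `well_id` of the reference well.
#' @export
select_reference_well <- function(readout) {
  stopifnot(inherits(readout, "synpcr_readout"))
  w <- readout$wells
  usable <- which(w$signal == 1L & !is.na(w$ct) & !w$censored)
  if (!length(usable))
    stop("no positive well with a Ct value; use the digital estimator")
  dv <- modulations(readout$layout)[usable]
  ct <- w$ct[usable]
  best <- usable[order(-ct, dv)][1]
  w$well_id[best]
}

#' Calibration-free estimation of the amplification factor
#'
#' Estimates the per-cycle amplification factor q from the readout itself,
#' without reference samples. Along a known modulation ladder the expected
#' threshold cycle falls linearly in `log(d_i v_i)` with slope
#' `-1/log(q)`, so an ordinary least-squares fit of `ct_i` on
#' `log(d_i v_i)` yields `q = exp(-1/slope)`. Wells whose implied starting
#' count (relative to the reference well) is below `min_count` molecules
#' are dominated by Poisson loading noise rather than by amplification, so
#' they are dropped and the fit repeated once.
#'
#' @param readout A [assay_readout()] with at least 3 positive Ct wells
#'   spanning at least 2 distinct modulations.
#' @param min_count Starting-count cutoff for the refit (default 5).
#' @param weighted If `TRUE`, weight wells by their implied starting count
#'   in the refit; default is plain OLS.
#' @return List of class `synpcr_q`: `q`, `se` (delta-method standard error
#'   of q), `slope`, `n_used`, `wells_used`.
#' @export
estimate_q <- function(readout, min_count = 5, weighted = FALSE) {
  stopifnot(inherits(readout, "synpcr_readout"))
  w <- readout$wells
  dv <- modulations(readout$layout)
  ok <- which(w$signal == 1L & !is.na(w$ct) & !w$censored)
  if (length(ok) < 3 || length(unique(dv[ok])) < 2)
    stop("q estimation needs >= 3 positive Ct wells over >= 2 distinct ",
         "modulations; supply a fixed q instead (default 1.9)")
  fit1 <- ols_q(log(dv[ok]), w$ct[ok], NULL)
  if (!is.finite(fit1$slope) || fit1$slope >= 0)
    stop("non-negative ct-vs-modulation slope; supply a fixed q instead ",
         "(default 1.9)")
  # implied starting counts relative to the latest-crossing well
  mhat <- fit1$q^(max(w$ct[ok]) - w$ct[ok])
  keep <- mhat >= min_count
  used <- ok
  fit <- fit1
  if (any(!keep) && sum(keep) >= 3 && length(unique(dv[ok][keep])) >= 2) {
    used <- ok[keep]
    wt <- if (weighted) mhat[keep] else NULL
    fit2 <- ols_q(log(dv[used]), w$ct[used], wt)
    if (is.finite(fit2$slope) && fit2$slope < 0) fit <- fit2
    else used <- ok
  }
  structure(list(q = fit$q, se = fit$se, slope = fit$slope,
                 n_used = length(used), wells_used = w$well_id[used]),
            class = "synpcr_q")
}

# closed-form (weighted) least squares of y on x; kept light because the
# profiler runs it once per simulated readout
ols_q <- function(x, y, wt) {
  n <- length(x)
  if (is.null(wt)) wt <- rep(1, n)
  sw <- sum(wt)
  xb <- sum(wt * x) / sw
  yb <- sum(wt * y) / sw
  sxx <- sum(wt * (x - xb)^2)
  b <- sum(wt * (x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  rss <- sum(wt * (y - a - b * x)^2)
  se_b <- if (n > 2) sqrt(rss / (n - 2) / sxx) else NA_real_
  q <- exp(-1 / b)
  list(slope = b, q = q,
       se = if (is.finite(se_b)) se_b * q / b^2 else NA_real_)
}

#' @export
print.synpcr_q <- function(x, ...) {
  cat(sprintf("Amplification factor q = %.4f (se %.4f), fitted on %d wells\n",
              x$q, x$se, x$n_used))
  invisible(x)
}

#' Fit the concentration posterior of an assay readout
#'
#' The central estimator of the package. Each partition contributes a
#' likelihood factor for the unknown concentration C: a negative partition
#' contributes the probability of holding fewer than `m_threshold`
#' molecules, `exp(-C d v)` for the usual threshold of one; a positive
#' partition contributes the upper Poisson tail above its molecule
#' threshold. In `"digital"` mode that threshold is `m_threshold` for every
#' positive. In `"synergistic"` mode the threshold-cycle values are used as
#' well: relative to the reference well (largest Ct), a well that crossed
#' `delta_ct` cycles earlier must have held at least
#' `ceiling(m_threshold * q^delta_ct)` molecules, which sharpens its
#' likelihood and shifts it towards the true concentration. The posterior
#' is the normalized product of all factors with the prior, evaluated on a
#' log-spaced grid.
#'
#' Unless `q` is supplied, the amplification factor is estimated from the
#' readout by [estimate_q()]; if that fails (too few positive Ct wells),
#' `q_fallback` is used and recorded as such.
#'
#' @param readout A [assay_readout()].
#' @param mode `"synergistic"` (digital + Ct information, the default) or
#'   `"digital"` (end-point signals only).
#' @param q Optional fixed per-cycle amplification factor in (1, 2\];
#'   overrides estimation.
#' @param prior A [concentration_prior()].
#' @param m_threshold Molecule threshold defining a positive signal.
#' @param n_grid Number of grid points (default 2000).
#' @param q_fallback Amplification factor used when estimation is
#'   impossible (default 1.9).
#' @return An object of class `synpcr` with `print`, `summary`, `coef`,
#'   `confint`, `plot`, `residuals` and `simulate` methods. Key fields:
#'   `estimate` (posterior mean), `sd`, `rsd` (relative standard
#'   deviation), `ci68`/`ci95` central credible intervals, `posterior`
#'   (grid + density), `evidence` (reference well, per-well delta_ct and
#'   molecule thresholds, q and its provenance), `boundary` flag.
#' @examples
#' lay <- geometric_layout(1, 0.4, 16)
#' rd <- simulate_readout(lay, concentration = 50, seed = 1)
#' fit <- synpcr(rd)
#' coef(fit)
#' confint(fit)
#' @export
synpcr <- function(readout, mode = c("synergistic", "digital"), q = NULL,
                   prior = concentration_prior(), m_threshold = 1L,
                   n_grid = 2000L, q_fallback = 1.9) {
  stopifnot(inherits(readout, "synpcr_readout"))
  mode <- match.arg(mode)
  prep <- prepare_estimator(readout$layout, prior, m_threshold, n_grid)
  fit_one_readout(prep, readout, mode, q, q_fallback, call = match.call())
}

# Shared worker so profiling can reuse one `prep` across many readouts.
fit_one_readout <- function(prep, readout, mode, q = NULL, q_fallback = 1.9,
                            call = NULL, lean = FALSE) {
  w <- readout$wells
  s <- w$signal
  boundary <- if (all(s == 1L)) "all_positive" else
              if (all(s == 0L)) "all_negative" else "none"
  evidence <- NULL
  k <- NULL
  used_mode <- mode
  if (mode == "synergistic") {
    usable <- s == 1L & !is.na(w$ct) & !w$censored
    if (!any(usable)) {
      used_mode <- "digital"
    } else {
      if (is.null(q)) {
        qe <- tryCatch(estimate_q(readout), error = function(e) NULL)
        if (is.null(qe)) {
          qv <- q_fallback; q_se <- NA_real_; q_source <- "fallback"
        } else {
          qv <- qe$q; q_se <- qe$se; q_source <- "estimated"
          # guard: keep q in the physical range
          if (!is.finite(qv) || qv <= 1 || qv > 2) {
            qv <- q_fallback; q_se <- NA_real_; q_source <- "fallback"
          }
        }
      } else {
        check_q(q)
        qv <- q; q_se <- NA_real_; q_source <- "supplied"
      }
      ref <- select_reference_well(readout)
      ct_ref <- w$ct[w$well_id == ref]
      pos <- which(s == 1L)
      delta_ct <- rep(0, length(pos))
      has_ct <- !is.na(w$ct[pos]) & !w$censored[pos]
      delta_ct[has_ct] <- ct_ref - w$ct[pos][has_ct]
      delta_ct[delta_ct < 0] <- 0  # only the reference defines the origin
      k <- ifelse(has_ct,
                  ct_shift_threshold(prep$m_threshold, delta_ct, qv),
                  prep$m_threshold)
      evidence <- list(reference_well = ref, q = qv, q_se = q_se,
                       q_source = q_source,
                       delta_ct = data.frame(well_id = w$well_id[pos],
                                             delta_ct = delta_ct,
                                             k = as.integer(pmin(k, .Machine$integer.max)),
                                             stringsAsFactors = FALSE))
    }
  }
  ll <- readout_loglik(prep, s, k)
  post <- posterior_from_loglik(prep, ll)
  if (lean)
    return(list(mean = post$mean, sd = post$sd, rsd = post$rsd,
                ci95 = post$ci95, boundary = boundary))
  structure(
    list(call = call, readout = readout, layout = readout$layout,
         mode = used_mode, requested_mode = mode,
         prior = prep$prior, m_threshold = prep$m_threshold,
         posterior = list(grid = post$grid, density = post$density),
         estimate = post$mean, sd = post$sd, rsd = post$rsd,
         median = post$median, map = post$mode,
         ci68 = post$ci68, ci95 = post$ci95,
         boundary = boundary, evidence = evidence),
    class = "synpcr"
  )
}

#' @export
print.synpcr <- function(x, ...) {
  cat(sprintf("Synergistic PCR concentration estimate (%s readout)\n", x$mode))
  cat(sprintf("  E(C) = %.6g   sd = %.3g   relative sd = %.1f%%\n",
              x$estimate, x$sd, 100 * x$rsd))
  cat(sprintf("  95%% credible interval: [%.6g, %.6g]\n",
              x$ci95[1], x$ci95[2]))
  if (!is.null(x$evidence))
    cat(sprintf("  q = %.3f (%s), reference well %s\n",
                x$evidence$q, x$evidence$q_source, x$evidence$reference_well))
  if (x$boundary != "none")
    cat(sprintf("  note: %s readout - estimate is a boundary value\n",
                sub("_", "-", x$boundary)))
  invisible(x)
}

#' @export
summary.synpcr <- function(object, ...) {
  out <- list(
    mode = object$mode,
    n_wells = n_partitions(object$layout),
    n_positive = sum(object$readout$wells$signal),
    estimate = object$estimate, sd = object$sd, rsd = object$rsd,
    median = object$median, map = object$map,
    ci68 = object$ci68, ci95 = object$ci95,
    boundary = object$boundary, evidence = object$evidence
  )
  class(out) <- "summary.synpcr"
  out
}

#' @export
print.summary.synpcr <- function(x, ...) {
  cat(sprintf("%s estimate from %d wells (%d positive)\n",
              x$mode, x$n_wells, x$n_positive))
  cat(sprintf("  mean %.6g, median %.6g, mode %.6g\n", x$estimate, x$median, x$map))
  cat(sprintf("  sd %.3g (relative %.1f%%)\n", x$sd, 100 * x$rsd))
  cat(sprintf("  68%% CI [%.6g, %.6g], 95%% CI [%.6g, %.6g]\n",
              x$ci68[1], x$ci68[2], x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
coef.synpcr <- function(object, ...) c(concentration = object$estimate)

#' @export
confint.synpcr <- function(object, parm = "concentration", level = 0.95, ...) {
  ci <- if (isTRUE(all.equal(level, 0.68))) object$ci68
        else if (isTRUE(all.equal(level, 0.95))) object$ci95
        else {
    a <- (1 - level) / 2
    cdfq <- posterior_quantile(object, c(a, 1 - a))
    cdfq
  }
  out <- matrix(ci, nrow = 1,
                dimnames = list("concentration",
                                sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))))
  out
}

posterior_quantile <- function(object, p) {
  g <- object$posterior$grid
  d <- object$posterior$density
  w <- c(diff(g) / 2, 0) + c(0, diff(g) / 2)
  cdf <- cumsum(w * d)
  cdf <- cdf / cdf[length(cdf)]
  stats::approx(cdf, g, xout = p, ties = "ordered", rule = 2)$y
}

#' @export
plot.synpcr <- function(x, ...) {
  g <- x$posterior$grid
  d <- x$posterior$density
  keep <- d > max(d) * 1e-8
  graphics::plot(g[keep], (d * g)[keep], type = "l", log = "x",
                 xlab = "concentration C", ylab = "posterior density (per log C)",
                 main = sprintf("Posterior (%s readout)", x$mode), ...)
  graphics::abline(v = x$estimate, lty = 2)
  graphics::abline(v = x$ci95, lty = 3, col = "grey40")
  invisible(x)
}

#' @export
residuals.synpcr <- function(object, ...) {
  dv <- modulations(object$layout)
  s <- object$readout$wells$signal
  p <- positive_probability(dv, object$estimate, object$m_threshold)
  (s - p) / sqrt(pmax(p * (1 - p), .Machine$double.eps))
}

#' @export
simulate.synpcr <- function(object, nsim = 1, seed = NULL, ...) {
  q <- if (!is.null(object$evidence)) object$evidence$q else 1.9
  if (!is.null(seed)) set.seed(seed)
  extra <- list(...)
  lapply(seq_len(nsim), function(i)
    do.call(simulate_readout,
            c(list(object$layout, object$estimate, q = q), extra)))
}

#' Classic digital PCR estimate (most probable number)
#'
#' The comparator estimator for an assay of identical partitions: invert
#' the fraction of negative partitions through the Poisson zero class,
#' `C = -log(1 - K/N) / dv`, with a delta-method variance.
#'
#' @param n_total Number of partitions N.
#' @param n_positive Number of positive partitions K.
#' @param modulation Shared modulation `d*v` of the partitions.
#' @return List: `concentration`, `sd`, `rsd`, and a `flag`
#'   (`"ok"`, `"all_negative"`, or `"saturated"`; a saturated assay returns
#'   the lower concentration bound implied by K = N - 1/2).
#' @export
classic_dpcr_estimate <- function(n_total, n_positive, modulation) {
  check_modulation(modulation)
  if (n_positive < 0 || n_positive > n_total) stop("need 0 <= n_positive <= n_total")
  if (n_positive == 0)
    return(list(concentration = 0, sd = NA_real_, rsd = NA_real_,
                flag = "all_negative"))
  flag <- "ok"
  f <- n_positive / n_total
  if (n_positive == n_total) {
    f <- (n_total - 0.5) / n_total
    flag <- "saturated"
  }
  conc <- -log(1 - f) / modulation
  sdv <- sqrt(f / ((1 - f) * n_total)) / modulation
  list(concentration = conc, sd = sdv, rsd = sdv / conc, flag = flag)
}
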