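#' Poisson occupancy probability of a partition
#'
#' Probability that a partition with modulation factor `dv` (the product of
#' its dilution factor and volume) contains exactly `m` target molecules when
#' the sample concentration is `concentration`. Molecule loading is Poisson
#' with mean `concentration * dv`.
#'
#' @param dv Modulation factor d*v (dilution times volume), > 0. Sets the
#'   expected molecule count of the partition at unit concentration.
#' @param concentration Target concentration C >= 0, in copies per the volume
#'   unit `dv` is expressed in.
#' @param m Non-negative integer molecule count.
#' @return Probability P(m molecules), a number in \[0, 1\].
#' @examples
#' occupancy_pmf(1, 1, 0)      # exp(-1)
#' occupancy_pmf(0.5, 2, 3)    # Poisson pmf at lambda = 1
#' @export
occupancy_pmf <- function(dv, concentration, m) {
  check_modulation(dv)
  if (any(concentration < 0)) stop("'concentration' must be >= 0")
  if (any(m < 0) || any(m != floor(m))) stop("'m' must be a non-negative integer")
  stats::dpois(m, lambda = concentration * dv)
}

#' Probability of a positive digital signal
#'
#' Probability that a partition yields a positive signal, i.e. contains at
#' least `m_threshold` molecules. This is the upper Poisson tail
#' P(m >= m_tr) at mean `concentration * dv`; for the usual threshold of one
#' molecule it equals `1 - exp(-C * dv)`. As a function of C it is a sigmoid
#' rising from 0 to 1, centred (value 1/2) at the characteristic
#' concentration of the partition.
#'
#' The tail is evaluated through [stats::ppois()] (a regularized
#' incomplete-gamma computation), not by naive summation.
#'
#' @inheritParams occupancy_pmf
#' @param m_threshold Positive integer threshold number of molecules m_tr
#'   that defines a positive signal (default 1).
#' @return Probability in \[0, 1\], nondecreasing in `concentration`.
#' @seealso [negative_probability()], [shifted_positive_probability()],
#'   [characteristic_concentration()]
#' @export
positive_probability <- function(dv, concentration, m_threshold = 1L) {
  check_modulation(dv)
  check_threshold(m_threshold)
  if (any(concentration < 0)) stop("'concentration' must be >= 0")
  stats::ppois(m_threshold - 1, lambda = concentration * dv, lower.tail = FALSE)
}

#' Probability of a negative digital signal
#'
#' Probability that a partition contains no molecule at all,
#' `exp(-C * dv)`. For threshold 1 this is the exact complement of
#' [positive_probability()].
#'
#' @inheritParams occupancy_pmf
#' @return Probability in \[0, 1\], nonincreasing in `concentration`.
#' @export
negative_probability <- function(dv, concentration) {
  check_modulation(dv)
  if (any(concentration < 0)) stop("'concentration' must be >= 0")
  exp(-concentration * dv)
}

#' Ct-shifted positive-signal probability
#'
#' A positive partition read in real time carries more than one bit: if the
#' reference partition (the positive one with the largest threshold cycle)
#' crossed the detection threshold at cycle ct_w, a partition that crossed
#' `delta_ct = ct_w - ct_i` cycles earlier must have started with at least
#' `m_tr * q^delta_ct` molecules, where q is the per-cycle amplification
#' factor. Its likelihood is therefore the upper Poisson tail above the
#' integer threshold `k = max(m_tr, ceiling(m_tr * q^delta_ct))` — a sigmoid
#' in C that is steeper than the plain digital one and shifted towards the
#' true concentration. With `delta_ct = 0` it reduces exactly to
#' [positive_probability()].
#'
#' @inheritParams positive_probability
#' @param delta_ct Nonnegative cycle difference ct_w - ct_i.
#' @param q Per-cycle amplification factor, in (1, 2\].
#' @return Probability in \[0, 1\].
#' @export
shifted_positive_probability <- function(dv, concentration, delta_ct, q,
                                         m_threshold = 1L) {
  check_modulation(dv)
  check_threshold(m_threshold)
  check_q(q)
  if (any(delta_ct < 0)) stop("'delta_ct' must be >= 0 (subtract ct from the reference ct)")
  if (any(concentration < 0)) stop("'concentration' must be >= 0")
  k <- ct_shift_threshold(m_threshold, delta_ct, q)
  stats::ppois(k - 1, lambda = concentration * dv, lower.tail = FALSE)
}

# integer molecule threshold implied by a Ct difference; the small guard
# keeps ceiling() from bumping exact powers up by one ulp
ct_shift_threshold <- function(m_threshold, delta_ct, q) {
  pmax(m_threshold, ceiling(m_threshold * q^delta_ct - 1e-9))
}

#' Characteristic concentration of a partition
#'
#' The concentration C* at which the partition's positive-signal probability
#' is exactly 1/2 — the point of maximal information gain of the binary
#' signal. For threshold 1 it is `log(2) / dv` in closed form; for larger
#' thresholds the monotone tail is inverted numerically.
#'
#' @inheritParams positive_probability
#' @return Concentration C* > 0; scales as 1/`dv`.
#' @export
characteristic_concentration <- function(dv, m_threshold = 1L) {
  check_modulation(dv)
  check_threshold(m_threshold)
  if (m_threshold == 1L) return(log(2) / dv)
  # lambda solving P(Pois(lambda) >= m_tr) = 1/2; bracket around m_tr
  f <- function(lam) stats::ppois(m_threshold - 1, lam, lower.tail = FALSE) - 0.5
  lam <- stats::uniroot(f, lower = 1e-12, upper = m_threshold * 10 + 10,
                        tol = 1e-12)$root
  lam / dv
}

#' Shannon entropy of a binary signal
#'
#' Information content, in bits, of a Bernoulli trial with success
#' probability `p`: `H = -p log2(p) - (1 - p) log2(1 - p)` with
#' `0 * log(0) := 0`. For a partition read digitally, H is maximal (1 bit)
#' at its characteristic concentration, where p = 1/2.
#'
#' @param p Probability in \[0, 1\].
#' @return Entropy in bits, in \[0, 1\].
#' @export
shannon_entropy <- function(p) {
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  term <- function(x) ifelse(x == 0, 0, -x * log2(x))
  term(p) + term(1 - p)
}

# ---- shared argument checks ----

check_modulation <- function(dv) {
  if (any(!is.finite(dv)) || any(dv <= 0)) stop("modulation 'dv' must be finite and > 0")
  invisible(dv)
}

check_threshold <- function(m_threshold) {
  if (length(m_threshold) != 1 || m_threshold < 1 || m_threshold != floor(m_threshold))
    stop("'m_threshold' must be a single integer >= 1")
  invisible(m_threshold)
}

check_q <- function(q) {
  if (length(q) != 1 || !is.finite(q) || q <= 1 || q > 2)
    stop("amplification factor 'q' must lie in (1, 2]")
  invisible(q)
}
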