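#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with the conventional parameters
#' (response peak near 5--6 s, undershoot near 16 s, undershoot ratio 1/6),
#' normalized to unit peak. Returns 0 for `t < 0` and decays to (near) zero
#' by 32 s.
#'
#' @param t time in seconds (vectorized).
#' @param peak_delay,peak_disp shape/dispersion of the positive lobe
#'   (gamma shape = delay/dispersion, rate = 1/dispersion).
#' @param undershoot_delay,undershoot_disp same for the undershoot lobe.
#' @param ratio undershoot amplitude relative to the peak lobe.
#' @return Numeric vector of responses, unit peak.
#' @examples
#' double_gamma_hrf(0)                      # 0
#' which.max(double_gamma_hrf(seq(0, 32, 0.1)))  # peak near 5 s
#' @export
double_gamma_hrf <- function(t, peak_delay = 6, peak_disp = 1,
                             undershoot_delay = 16, undershoot_disp = 1,
                             ratio = 1 / 6) {
  shape1 <- peak_delay / peak_disp
  shape2 <- undershoot_delay / undershoot_disp
  raw <- function(x) {
    out <- numeric(length(x))
    pos <- x >= 0
    out[pos] <- stats::dgamma(x[pos], shape = shape1, rate = 1 / peak_disp) -
      ratio * stats::dgamma(x[pos], shape = shape2, rate = 1 / undershoot_disp)
    out
  }
  fine <- raw(seq(0, 50, by = 0.01))
  raw(t) / max(fine)
}

#' HRF kernel sampled at the TR, normalized to unit sustained response
#'
#' Scaled so that convolving a unit boxcar long enough to reach steady state
#' yields a plateau of exactly 1; a planted percent-signal-change amplitude
#' then equals the plateau PSC of the generated series.
#' @noRd
.hrf_kernel <- function(tr_s, span_s = 32) {
  h <- double_gamma_hrf(seq(0, span_s, by = tr_s))
  h / sum(h)
}

#' Causal convolution of a stimulus vector with the TR-sampled HRF.
#' Uses a one-sided moving sum so that values at time t depend only on
#' stimulus at times <= t (exactly, not just numerically).
#' @noRd
.convolve_hrf <- function(stimulus, tr_s) {
  h <- .hrf_kernel(tr_s)
  padded <- c(rep(0, length(h) - 1), stimulus)
  out <- stats::filter(padded, h, method = "convolution", sides = 1)
  as.numeric(out[length(h) - 1 + seq_along(stimulus)])
}

#' Per-volume condition regressor for a run
#'
#' Boxcar of per-block amplitudes convolved with the canonical HRF, sampled
#' once per TR over the run's full timeline (dummies included, as leading
#' zeros of the stimulus).
#'
#' @param schedule an `nfb_schedule`.
#' @param condition condition whose blocks drive the boxcar.
#' @param amplitudes scalar or one amplitude per block of that condition.
#' @return Numeric vector of length `n_dummy + n_volumes`.
#' @export
condition_regressor <- function(schedule, condition, amplitudes = 1) {
  stopifnot(inherits(schedule, "nfb_schedule"))
  tr <- schedule$tr_s
  total <- schedule$n_dummy + schedule$n_volumes
  idx <- which(schedule$blocks$condition == condition)
  if (length(amplitudes) == 1) amplitudes <- rep(amplitudes, length(idx))
  stopifnot(length(amplitudes) == length(idx))
  stim <- numeric(total)
  for (j in seq_along(idx)) {
    b <- idx[j]
    v0 <- schedule$n_dummy + schedule$blocks$onset_s[b] / tr + 1
    v1 <- v0 + schedule$blocks$duration_s[b] / tr - 1
    stim[v0:v1] <- amplitudes[j]
  }
  .convolve_hrf(stim, tr)
}
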