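# Two-phase batch growth curves: exponential then linear OD increase.

#' Simulate a two-phase optical-density growth curve
#'
#' OD follows `a * exp(r * t)` up to `t_break` and continues linearly with
#' slope `m` thereafter; unless `b` is given, the linear intercept is
#' derived so the curve is continuous at the break. Gaussian noise is
#' added; negative values are clipped at 0 with a warning.
#'
#' @param timepoints Measurement times in hours.
#' @param a Initial OD.
#' @param r Exponential rate (/h).
#' @param m Linear slope (OD/h).
#' @param t_break Time of the exponential-to-linear transition (h); must
#'   lie within the range of `timepoints`.
#' @param b Optional linear intercept; default continuous extension.
#' @param noise_sd SD of additive Gaussian measurement noise.
#' @param seed Integer seed.
#' @return Data frame with columns `time_h`, `od` and `od_true`.
#' @export
simulate_growth_curve <- function(timepoints, a = 0.001, r = 0.0163,
                                  m = 0.00135, t_break = 300, b = NULL,
                                  noise_sd = 0, seed = NULL) {
  stopifnot(noise_sd >= 0, length(timepoints) >= 2)
  if (t_break < min(timepoints) || t_break > max(timepoints))
    stop("t_break must lie within the timepoint range")
  if (is.null(b)) b <- a * exp(r * t_break) - m * t_break
  od_true <- ifelse(timepoints <= t_break,
                    a * exp(r * timepoints),
                    b + m * timepoints)
  with_seed(seed, {
    od <- od_true + if (noise_sd > 0)
      stats::rnorm(length(timepoints), 0, noise_sd) else 0
    if (any(od < 0)) {
      warning("negative OD after noise clipped at 0")
      od[od < 0] <- 0
    }
    data.frame(time_h = timepoints, od = od, od_true = od_true)
  })
}
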