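# Two-phase growth analysis: exponential/linear fits, phase
# segmentation, ancestor comparison, and the rate-vs-fixed-insertions
# regression.

#' Fit the exponential phase (two-parameter model) by log-linear OLS
#'
#' Fits `OD(t) = a * exp(r t)` as `log OD = log a + r t` by ordinary
#' least squares, a deterministic initialization-free estimator for the
#' two-parameter exponential model.
#'
#' @param od_series Data frame with `time_h` and `od`.
#' @param window Optional `c(t_min, t_max)` restricting the fit.
#' @return Object of class `growth_fit` with fields phase, a, r,
#'   se (named vector), r_squared, window, n_points.
#' @export
fit_exponential <- function(od_series, window = NULL) {
  d <- od_series
  if (!is.null(window)) d <- d[d$time_h >= window[1] & d$time_h <=
                                 window[2], , drop = FALSE]
  if (nrow(d) < 4) stop("need at least 4 points in the window")
  if (any(d$od <= 0))
    stop("non-positive OD at t = ",
         paste(d$time_h[d$od <= 0], collapse = ", "),
         "; cannot take logs")
  fit <- stats::lm(log(od) ~ time_h, data = d)
  co <- stats::coef(fit)
  # perfect fits on noiseless curves are legitimate; silence summary.lm
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(phase = "exponential", a = exp(co[[1]]), r = co[[2]],
                 se = c(log_a = se[[1]], r = se[[2]]),
                 r_squared = r2,
                 window = range(d$time_h), n_points = nrow(d)),
            class = "growth_fit")
}

#' Fit the linear phase (two-parameter model) by OLS
#'
#' @inheritParams fit_exponential
#' @return `growth_fit` with fields b (intercept), m (slope OD/h).
#' @export
fit_linear <- function(od_series, window = NULL) {
  d <- od_series
  if (!is.null(window)) d <- d[d$time_h >= window[1] & d$time_h <=
                                 window[2], , drop = FALSE]
  if (nrow(d) < 4) stop("need at least 4 points in the window")
  if (stats::var(d$time_h) == 0) stop("degenerate time variance")
  fit <- stats::lm(od ~ time_h, data = d)
  co <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(phase = "linear", b = co[[1]], m = co[[2]],
                 se = c(b = se[[1]], m = se[[2]]),
                 r_squared = r2,
                 window = range(d$time_h), n_points = nrow(d)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  if (x$phase == "exponential")
    cat(sprintf("Exponential fit: a = %.4g, r = %.4g /h (SE %.2g), R2 = %.4f, n = %d\n",
                x$a, x$r, x$se[["r"]], x$r_squared, x$n_points))
  else
    cat(sprintf("Linear fit: b = %.4g, m = %.4g OD/h (SE %.2g), R2 = %.4f, n = %d\n",
                x$b, x$m, x$se[["m"]], x$r_squared, x$n_points))
  invisible(x)
}

#' Segment a growth curve into exponential and linear phases
#'
#' Searches the observed timepoints for the breakpoint t* minimizing
#' SSE(exponential fit on t <= t*) + SSE(linear fit on t >= t*), with at
#' least 4 points on each side; ties resolve to the earliest t*. SSE of
#' the exponential segment is computed on the OD scale so the two
#' segments are comparable.
#'
#' @param od_series Data frame with `time_h`, `od` (>= 8 timepoints;
#'   OD must be positive where logs are taken).
#' @return List (t_break, sse, exponential, linear, degenerate):
#'   the two `growth_fit`s on their windows; `degenerate` is `TRUE` when
#'   the exponential segment explains essentially nothing beyond the
#'   linear trend (purely linear data).
#' @export
segment_phases <- function(od_series) {
  d <- od_series[order(od_series$time_h), , drop = FALSE]
  tp <- unique(d$time_h)
  if (length(tp) < 8) stop("need at least 8 timepoints")
  if (any(d$od <= 0)) stop("non-positive OD in series")
  best <- NULL
  for (tb in tp[seq(4, length(tp) - 3)]) {
    left <- d[d$time_h <= tb, , drop = FALSE]
    right <- d[d$time_h >= tb, , drop = FALSE]
    if (nrow(left) < 4 || nrow(right) < 4) next
    fe <- fit_exponential(left)
    fl <- fit_linear(right)
    sse <- sum((left$od - fe$a * exp(fe$r * left$time_h))^2) +
      sum((right$od - (fl$b + fl$m * right$time_h))^2)
    if (is.null(best) || sse < best$sse - 1e-15)
      best <- list(t_break = tb, sse = sse, exponential = fe, linear = fl)
  }
  # degenerate exponential phase: the whole curve is as linear as the
  # right segment (slope ratio of phases ~ 1)
  full_lin <- fit_linear(d)
  best$degenerate <- best$t_break == tp[4] &&
    full_lin$r_squared > 0.999
  best
}

#' One-tailed comparison of evolved growth rates to the ancestor
#'
#' Default mode: one-sample t test of the per-population evolved rate
#' means against the ancestor's point estimate, alternative
#' "evolved > ancestor". A two-sample Welch mode against ancestor
#' replicate values is also provided.
#'
#' @param evolved Numeric vector of per-population rate estimates.
#' @param ancestor Single ancestor rate (one-sample mode) or replicate
#'   values (Welch mode).
#' @param mode `"one-sample"` or `"welch"`.
#' @return List (t, p, df, mode, alternative).
#' @export
compare_to_ancestor <- function(evolved, ancestor,
                                mode = c("one-sample", "welch")) {
  mode <- match.arg(mode)
  stopifnot(length(evolved) >= 2)
  if (stats::var(evolved) == 0) stop("zero variance in evolved values")
  tt <- if (mode == "one-sample") {
    stopifnot(length(ancestor) == 1)
    stats::t.test(evolved, mu = ancestor, alternative = "greater")
  } else {
    stopifnot(length(ancestor) >= 2)
    stats::t.test(evolved, ancestor, alternative = "greater",
                  var.equal = FALSE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mode = mode, alternative = "greater")
}

#' Regression of linear growth rate on fixed insertion count
#'
#' Pearson correlation R with `F = R^2 (n-2) / (1 - R^2)` on (1, n-2)
#' degrees of freedom and the upper-tail p value.
#'
#' @param rates Per-population linear growth rates.
#' @param fixed_counts Per-population fixed insertion counts
#'   (non-negative integers).
#' @return Object of class `rate_regression`: R, F, df, p, slope,
#'   slope_se, n.
#' @export
regress_rate_on_fixed <- function(rates, fixed_counts) {
  n <- length(rates)
  stopifnot(n >= 3, length(fixed_counts) == n, all(fixed_counts >= 0))
  if (stats::var(rates) == 0 || stats::var(fixed_counts) == 0)
    stop("zero variance in rates or counts")
  R <- stats::cor(fixed_counts, rates)
  Fstat <- R^2 * (n - 2) / (1 - R^2)
  fit <- stats::lm(rates ~ fixed_counts)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[[2]])
  structure(list(R = R, F = Fstat, df = c(1, n - 2),
                 p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
                 slope = stats::coef(fit)[[2]], slope_se = se, n = n),
            class = "rate_regression")
}

#' @export
print.rate_regression <- function(x, ...) {
  cat(sprintf("R = %.3f; N = %d; F[%d,%d] = %.3f, P = %.4f\n",
              x$R, x$n, x$df[1], x$df[2], x$F, x$p))
  invisible(x)
}
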