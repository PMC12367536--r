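#' Fit the one-parameter hyperbolic response coefficient
#'
#' The yield response Out = c * In / (c + In) links N output to N input
#' through a single coefficient c, the asymptotic maximum achievable N
#' output under the prevailing technological and management practices
#' (TMPs). Given window-mean input and output the coefficient has the
#' closed form c = In * Out / (In - Out), which reproduces the window mean
#' exactly. Alternatively (`method = "annual"`), c can be fitted by least
#' squares to the annual (In, Out) points of the window.
#'
#' @param mean_in,mean_out window means of N input and output
#'   (kgN ha^-1 yr^-1), with `0 < mean_out < mean_in`.
#' @param annual_in,annual_out optional annual values for
#'   `method = "annual"`.
#' @param method `"window_mean"` (closed form, default) or `"annual"`.
#' @return the coefficient c (kgN ha^-1 yr^-1).
#' @export
#' @examples
#' fit_c(100, 50)   # 100
#' fit_c(100, 80)   # 400
#' predict_output(fit_c(100, 80), 100)  # 80: exact round trip
fit_c <- function(mean_in, mean_out, annual_in = NULL, annual_out = NULL,
                  method = c("window_mean", "annual")) {
  method <- match.arg(method)
  if (method == "annual") {
    if (is.null(annual_in) || is.null(annual_out))
      stop_ns("method = 'annual' needs annual_in and annual_out")
    if (any(annual_out <= 0) || any(annual_out >= annual_in))
      stop_ns("response undefined: need 0 < Out < In for every year")
    start <- fit_c(mean(annual_in), mean(annual_out))
    obj <- function(cc) sum((annual_out - cc * annual_in / (cc + annual_in))^2)
    stats::optimize(obj, interval = c(start / 10, start * 10))$minimum
  } else {
    if (mean_out <= 0) stop_ns("response undefined: mean N output must be > 0")
    if (mean_out >= mean_in)
      stop_ns("response undefined: mean N output (%.3g) >= mean N input (%.3g)",
              mean_out, mean_in)
    mean_in * mean_out / (mean_in - mean_out)
  }
}

#' Predict N output from the hyperbolic response
#'
#' @param c_coef response coefficient (> 0, kgN ha^-1 yr^-1).
#' @param in_level N input level (>= 0).
#' @return predicted N output, strictly below `min(c_coef, in_level)` for
#'   positive inputs and saturating at `c_coef` for large inputs.
#' @export
predict_output <- function(c_coef, in_level) {
  if (any(c_coef <= 0)) stop_ns("response coefficient must be positive")
  if (any(in_level < 0)) stop_ns("N input must be non-negative")
  c_coef * in_level / (c_coef + in_level)
}

#' Default trend windows for the response coefficient
#'
#' Seven 5-year intervals and the final 4-year interval spanning the
#' sustainable intensification phase: 1981-1985, 1986-1990, ...,
#' 2011-2015, 2016-2019.
#'
#' @return a list of `c(start, end)` pairs.
#' @export
trend_windows <- function() {
  w <- lapply(seq(1981, 2011, 5), function(s) c(s, s + 4))
  w[[8]] <- c(2016, 2019)
  w
}

#' Fit the linear technology trend of the response coefficient
#'
#' Ordinary least squares of the eight window-wise coefficients c on the
#' window midpoint year, extrapolated to a horizon year (2030). The 95%
#' interval is the confidence interval of the mean response of the linear
#' fit at the horizon (t distribution, 6 degrees of freedom for 8 support
#' points). The relative technology gain is
#' `delta_tmp = c_2030 / c_baseline - 1`, with c_baseline supplied
#' separately (fitted on the 2015-2019 baseline window).
#'
#' @param c_values the eight window coefficients, ordered in time.
#' @param midpoints window midpoint years; default the midpoints of
#'   [trend_windows()] (1983, 1988, ..., 2017.5).
#' @param c_baseline baseline coefficient (2015-2019 window fit).
#' @param horizon projection year (default 2030).
#' @param level interval coverage (default 0.95).
#' @return object of class `ns_trend`: list with `slope`, `intercept`,
#'   `c_horizon`, `c_low`, `c_high`, `delta_tmp` (and `delta_low`,
#'   `delta_high`), `midpoints`, `c_values`, `horizon`, `c_baseline`.
#' @export
fit_c_trend <- function(c_values,
                        midpoints = vapply(trend_windows(), mean, numeric(1)),
                        c_baseline, horizon = 2030, level = 0.95) {
  if (length(c_values) != 8)
    stop_ns("the technology trend is fitted on exactly 8 window estimates (got %d)",
            length(c_values))
  if (length(midpoints) != 8 || any(diff(midpoints) <= 0))
    stop_ns("midpoints must be 8 strictly increasing years")
  if (missing(c_baseline) || c_baseline <= 0)
    stop_ns("a positive baseline coefficient is required")
  fit <- lm(c_values ~ midpoints)
  pr <- predict(fit, newdata = data.frame(midpoints = horizon),
                interval = "confidence", level = level)
  out <- list(
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    c_horizon = unname(pr[1, "fit"]),
    c_low = unname(pr[1, "lwr"]), c_high = unname(pr[1, "upr"]),
    c_baseline = c_baseline,
    delta_tmp = unname(pr[1, "fit"]) / c_baseline - 1,
    delta_low = unname(pr[1, "lwr"]) / c_baseline - 1,
    delta_high = unname(pr[1, "upr"]) / c_baseline - 1,
    midpoints = midpoints, c_values = c_values,
    horizon = horizon, level = level
  )
  class(out) <- "ns_trend"
  out
}

#' @export
print.ns_trend <- function(x, ...) {
  cat(sprintf(
    "response-coefficient trend: slope %.3f /yr; c(%d) = %.1f [%.1f, %.1f]\n",
    x$slope, x$horizon, x$c_horizon, x$c_low, x$c_high))
  cat(sprintf("technology gain vs baseline c = %.1f: %+.1f%% [%+.1f%%, %+.1f%%]\n",
              x$c_baseline, 100 * x$delta_tmp, 100 * x$delta_low,
              100 * x$delta_high))
  invisible(x)
}

#' Resolve the 2030 response coefficient under a TMP mode
#'
#' Under same TMPs the response stays at the baseline coefficient. Under
#' improved TMPs the baseline coefficient is scaled by the extrapolated
#' technology gain, `c_baseline * (1 + delta_tmp)`, at the requested bound
#' of the 95% interval.
#'
#' @param c_baseline baseline coefficient (2015-2019).
#' @param trend an `ns_trend` (required for `mode = "improved"`).
#' @param mode `"same"` or `"improved"`.
#' @param bound `"point"`, `"low"` or `"high"` interval bound (improved
#'   mode only).
#' @return the coefficient to use for 2030 projections.
#' @export
apply_tmp_mode <- function(c_baseline, trend = NULL,
                           mode = c("same", "improved"),
                           bound = c("point", "low", "high")) {
  mode <- match.arg(mode)
  bound <- match.arg(bound)
  if (mode == "same") return(c_baseline)
  if (is.null(trend)) stop_ns("improved TMP mode requires a fitted trend")
  delta <- switch(bound, point = trend$delta_tmp, low = trend$delta_low,
                  high = trend$delta_high)
  out <- c_baseline * (1 + delta)
  if (out <= 0)
    stop_ns("technology trend drives the response coefficient non-positive (%.3g)",
            out)
  out
}

#' N input level producing a target surplus
#'
#' Under the hyperbolic response the surplus at input level In is
#' S = In - c In / (c + In) = In^2 / (c + In). Solving for In gives the
#' positive root In = (S + sqrt(S^2 + 4 c S)) / 2. Used to cross-check the
#' bottom-up reduction grid's 50% contour analytically.
#'
#' @param c_coef response coefficient (> 0).
#' @param target_surplus desired surplus S (> 0, kgN ha^-1 yr^-1).
#' @return the input level In.
#' @export
#' @examples
#' required_input_for_surplus(100, 50)  # 100: 100^2 / 200 = 50
required_input_for_surplus <- function(c_coef, target_surplus) {
  if (any(c_coef <= 0)) stop_ns("response coefficient must be positive")
  if (any(target_surplus <= 0)) stop_ns("target surplus must be positive")
  (target_surplus + sqrt(target_surplus^2 + 4 * c_coef * target_surplus)) / 2
}
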