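#' Attrition-bias slope
#'
#' Selection-by-survival in the wait zone: trials that remain longer tend to
#' have started with a higher initial willingness to wait. Each accepted
#' trial contributes its `W0` once for every second it is in the wait zone
#' (accepted, not yet quit, not yet earned: seconds `0 .. e-1`, where `e` is
#' the quit time or the full offer). The measure is the OLS slope of this
#' pooled (time-spent, `W0`) scatter — computed from the actual sample
#' points, not a binned histogram.
#'
#' The slope is evaluated in closed form from per-trial sufficient
#' statistics (a trial with endpoint `e` contributes `e` points with
#' time-spent sums `e(e-1)/2` and `(e-1)e(2e-1)/6`), which is numerically
#' identical to expanding the scatter and fitting `lm(w0 ~ s)`.
#'
#' @param trials A [session_set()] with `w0` recorded (simulation-origin
#'   data).
#' @return Slope in seconds of `W0` per second of time spent; `NA` with a
#'   message when `w0` is absent (not applicable to data without it).
#' @export
attrition_slope <- function(trials) {
  acc <- trials[trials$accepted %in% TRUE, ]
  if (nrow(acc) == 0 || all(is.na(acc$w0))) {
    message("attrition slope not applicable: no w0 recorded")
    return(NA_real_)
  }
  acc <- acc[!is.na(acc$w0), ]
  e <- as.numeric(acc$time_spent_s)
  w <- acc$w0
  n <- sum(e)
  sx <- sum(e * (e - 1) / 2)
  sxx <- sum((e - 1) * e * (2 * e - 1) / 6)
  sy <- sum(w * e)
  sxy <- sum(w * e * (e - 1) / 2)
  denom <- n * sxx - sx^2
  if (denom <= 0) return(NA_real_)  # all points at a single time-spent
  (n * sxy - sx * sy) / denom
}
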