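#' Grid maximum-likelihood threshold
#'
#' Subjects on these foraging tasks reveal a per-site delay threshold:
#' offers below it are typically accepted, above it skipped. The threshold
#' is estimated by maximising the Bernoulli likelihood of the accept/skip
#' choices over an integer grid of candidate thresholds 0..30 s, under a
#' step psychometric with a fixed lapse rate (accept probability `1 - lapse`
#' at or below the candidate, `lapse` above it). Ties are broken toward the
#' midpoint of the maximising set.
#'
#' @param trials A [session_set()].
#' @param site Site identifier; `NULL` pools all sites.
#' @param lapse Fixed lapse rate in (0, 0.5). Default 0.05. The likelihood
#'   ordering over candidates does not depend on its exact value.
#' @param grid Candidate thresholds; default `0:30`.
#' @return Threshold in seconds (possibly half-integer from tie-breaking),
#'   with attribute `degenerate = TRUE` when the data are all-accept or
#'   all-skip and the estimate sits on the grid boundary.
#' @export
estimate_threshold <- function(trials, site = NULL, lapse = 0.05,
                               grid = 0:30) {
  stopifnot(lapse > 0, lapse < 0.5)
  d <- trials[!is.na(trials$accepted), ]
  if (!is.null(site)) d <- d[d$site_id == site, ]
  if (nrow(d) == 0) stop("no offer-zone decisions at this site", call. = FALSE)
  acc <- as.numeric(d$accepted)
  ll <- vapply(grid, function(T) {
    p <- ifelse(d$offer_s <= T, 1 - lapse, lapse)
    sum(acc * log(p) + (1 - acc) * log1p(-p))
  }, numeric(1))
  best <- grid[ll >= max(ll) - 1e-9]
  est <- (min(best) + max(best)) / 2
  degenerate <- all(acc == 1) || all(acc == 0)
  structure(est, degenerate = degenerate)
}

#' Economic value of an offer
#'
#' `value = threshold - offer`: offers shorter than the site threshold have
#' positive value (good deals), longer ones negative value (bad deals).
#'
#' @param threshold Site threshold (s).
#' @param offer Offered (or remaining) delay (s).
#' @return Value in seconds.
#' @export
offer_value <- function(threshold, offer) threshold - offer

#' Probit fit of the accept/skip psychometric
#'
#' Two-parameter maximum-likelihood probit of the accept (1) / skip (0)
#' decision on the offered delay. Reports the midpoint (the delay at which
#' accepting is 50% likely — the revealed threshold) and the tangent of the
#' fitted curve at that midpoint, `|dP/d offer| at P = 0.5 = |beta| * phi(0)`.
#' For data generated by the change-of-mind agent the accept probability is
#' exactly `Phi((W_T - offer) / sigma_W)`, so the tangent estimates
#' `phi(0) / sigma_W` — the hook used by [estimate_sigma_w()].
#'
#' @param trials A [session_set()].
#' @param site Site identifier; `NULL` pools all sites.
#' @return List: `midpoint` (s), `tangent` (probability per second),
#'   `separated` (logical; `TRUE` with `tangent = Inf` when accepts and
#'   skips are perfectly separated in delay and the slope is unbounded).
#' @export
probit_accept_fit <- function(trials, site = NULL) {
  d <- trials[!is.na(trials$accepted), ]
  if (!is.null(site)) d <- d[d$site_id == site, ]
  if (!any(d$accepted) || all(d$accepted)) {
    stop("probit fit needs both accepts and skips", call. = FALSE)
  }
  hi_acc <- max(d$offer_s[d$accepted])
  lo_skip <- min(d$offer_s[!d$accepted])
  if (hi_acc < lo_skip) {
    return(list(midpoint = (hi_acc + lo_skip) / 2, tangent = Inf,
                separated = TRUE))
  }
  # aggregate to per-offer counts: identical likelihood, much faster
  k <- tapply(as.numeric(d$accepted), d$offer_s, sum)
  m <- tapply(d$accepted, d$offer_s, length)
  o <- as.numeric(names(k))
  fit <- suppressWarnings(
    stats::glm(cbind(k, m - k) ~ o, family = stats::binomial("probit")))
  beta <- stats::coef(fit)
  list(midpoint = unname(-beta[1] / beta[2]),
       tangent = unname(abs(beta[2]) * stats::dnorm(0)),
       separated = FALSE)
}

#' Hyperbolic calibration fit (a + b/x)
#'
#' Least-squares fit of `y = a + b / x`, linear in `1/x`. Used to calibrate
#' the map from the probit tangent at threshold to the generating `sigma_W`;
#' the ideal closed form is `a = 0`, `b = phi(0) ~ 0.3989`.
#'
#' @param x Tangents (must be positive and finite).
#' @param y Generating `sigma_W` values.
#' @return A `calibration_fit`: list with `a`, `b`, `adj_r2`, `n`.
#' @export
fit_hyperbolic <- function(x, y) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(x > 0))
  fit <- stats::lm(y ~ I(1 / x))
  structure(list(a = unname(stats::coef(fit)[1]),
                 b = unname(stats::coef(fit)[2]),
                 adj_r2 = summary(fit)$adj.r.squared,
                 n = length(x)),
            class = "calibration_fit")
}

#' Ideal tangent-to-sigma_W calibration
#'
#' The closed-form calibration `sigma_W = phi(0) / tangent` (a = 0,
#' b = dnorm(0)), exact in the large-sample limit of the probit fit.
#'
#' @return A `calibration_fit`.
#' @export
ideal_calibration <- function() {
  structure(list(a = 0, b = stats::dnorm(0), adj_r2 = 1, n = Inf),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> sigma_W = %.4f + %.4f / tangent (adj R^2 = %.5f, n = %s)\n",
              x$a, x$b, x$adj_r2, format(x$n)))
  invisible(x)
}

#' Estimate sigma_W from a probit tangent
#'
#' Applies a hyperbolic calibration (see [fit_hyperbolic()]) to a measured
#' tangent: `sigma_W_hat = a + b / tangent`. This is the behaviorally
#' accessible estimate of the initial willingness-to-wait spread — the
#' flatter the accept/skip psychometric, the larger `sigma_W`.
#'
#' @param tangent Probit tangent at threshold (must be > 0).
#' @param fit A `calibration_fit`; default the ideal closed form.
#' @return Estimated `sigma_W` in seconds.
#' @export
estimate_sigma_w <- function(tangent, fit = ideal_calibration()) {
  if (any(!is.finite(tangent) | tangent <= 0)) {
    stop("tangent must be positive and finite", call. = FALSE)
  }
  fit$a + fit$b / tangent
}
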