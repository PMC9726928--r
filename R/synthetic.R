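#' Hazard-model session generator configuration
#'
#' Generates behavioral sessions from a statistical model deliberately
#' outside the drift-diffusion family, so the measurement chain can be
#' validated against known ground truth that shares no machinery with the
#' simulator under test. The generative structure mirrors what the analysis
#' assumes of real sessions: a per-site accept threshold with a probit
#' psychometric (plus lapses), and a per-second quit hazard in the wait
#' zone,
#' `h(t) = logistic(logit(base) + c_r * (offer - t) + c_s * t)`,
#' where `c_r` scales the time remaining and `c_s` the time already spent.
#' A negative `c_s` makes quitting harder the longer the subject has waited
#' — escalating commitment, which the sunk-cost bubble must recover with a
#' positive sign; `c_s = 0` builds in no sunk-cost structure and the bubble
#' must come out at zero.
#'
#' @param site_thresholds Named numeric of per-site accept thresholds (s).
#'   Default four sites at 12, 16, 20, 24 s — heterogeneous preferences in
#'   the style of four differently ranked reward flavors/galleries.
#' @param accept_noise Probit SD (s) of the accept rule.
#' @param lapse Symmetric lapse rate of the accept psychometric.
#' @param quit_hazard_base Baseline per-second quit hazard (on the
#'   probability scale, at zero remaining and zero spent).
#' @param hazard_coef_remaining Log-odds of quitting per second remaining.
#' @param hazard_coef_spent Log-odds of quitting per second already spent
#'   (negative = sunk-cost escalation).
#' @param n_trials Number of trials.
#' @param offer_support Integer offer support (uniform).
#' @param seed Integer seed.
#' @return A list of class `"behavior_gen_config"`.
#' @export
behavior_gen_config <- function(site_thresholds = c(site1 = 12, site2 = 16,
                                                    site3 = 20, site4 = 24),
                                accept_noise = 4, lapse = 0.02,
                                quit_hazard_base = 0.05,
                                hazard_coef_remaining = 0.10,
                                hazard_coef_spent = -0.08,
                                n_trials = 10000L, offer_support = 1:30,
                                seed = 1L) {
  stopifnot(accept_noise > 0, lapse >= 0, lapse < 0.5,
            quit_hazard_base > 0, quit_hazard_base < 1, n_trials >= 1)
  if (is.null(names(site_thresholds))) {
    names(site_thresholds) <- paste0("site", seq_along(site_thresholds))
  }
  structure(list(site_thresholds = site_thresholds,
                 accept_noise = accept_noise, lapse = lapse,
                 quit_hazard_base = quit_hazard_base,
                 hazard_coef_remaining = hazard_coef_remaining,
                 hazard_coef_spent = hazard_coef_spent,
                 n_trials = as.integer(n_trials),
                 offer_support = as.integer(offer_support),
                 seed = as.integer(seed)),
            class = "behavior_gen_config")
}

quit_hazard <- function(t, offer, config) {
  stats::plogis(stats::qlogis(config$quit_hazard_base) +
                  config$hazard_coef_remaining * (offer - t) +
                  config$hazard_coef_spent * t)
}

#' Generate synthetic behavioral sessions
#'
#' Offers are uniform over the support and sites uniform over the
#' configured sites. The accept probability is the lapse-mixed probit
#' `lapse/2 + (1 - lapse) * Phi((threshold_site - offer) / accept_noise)`;
#' accepted trials then face the per-second quit hazard at
#' `t = 1 .. offer - 1` (see [behavior_gen_config()]). Deterministic given
#' the seed.
#'
#' @param config A [behavior_gen_config()].
#' @param subject_id,session_id Identifiers for the emitted log.
#' @return A [session_set()] (no `w0`; this generator has no latent
#'   willingness variable).
#' @export
generate_sessions <- function(config, subject_id = "synth",
                              session_id = sprintf("synth%08d", config$seed)) {
  set.seed(config$seed)
  n <- config$n_trials
  support <- config$offer_support
  sites <- names(config$site_thresholds)
  offers <- support[sample.int(length(support), n, replace = TRUE)]
  site <- sites[sample.int(length(sites), n, replace = TRUE)]
  thr <- config$site_thresholds[site]
  p_acc <- config$lapse / 2 +
    (1 - config$lapse) * stats::pnorm((thr - offers) / config$accept_noise)
  accepted <- stats::runif(n) < p_acc
  quit_t <- rep(NA_integer_, n)
  active <- accepted
  for (t in seq_len(max(support) - 1L)) {
    li <- which(active & offers > t)
    if (!length(li)) break
    h <- quit_hazard(t, offers[li], config)
    q <- stats::runif(length(li)) < h
    quit_t[li[q]] <- t
    active[li[q]] <- FALSE
  }
  time_spent <- integer(n)
  outcome <- rep("skip", n)
  acc_i <- which(accepted)
  time_spent[acc_i] <- ifelse(is.na(quit_t[acc_i]), offers[acc_i],
                              quit_t[acc_i])
  outcome[acc_i] <- ifelse(is.na(quit_t[acc_i]), "earn", "quit")
  trials <- tibble::tibble(
    subject_id = subject_id, session_id = session_id, site_id = site,
    offer_s = as.integer(offers), accepted = accepted,
    time_spent_s = as.integer(time_spent), outcome = outcome, w0 = NA_real_
  )
  session_set(trials,
              meta = list(generator = "hazard_model",
                          config = unclass(config), seed = config$seed,
                          offer_support = support),
              validate = FALSE)
}

#' Closed-form p(Earn) for the hazard generator
#'
#' Analytic earning probability for a trial of the hazard model observed in
#' state (time-spent `spent`, offer `offer`): the survival product over the
#' remaining quit opportunities,
#' `prod_{t = spent+1}^{offer-1} (1 - h(t))`. This is an exact oracle for
#' the entire measurement chain: [build_pearn_matrix()] applied to
#' generated sessions must converge on it cell by cell.
#'
#' @param config A [behavior_gen_config()].
#' @param offer Offer delay (s).
#' @param spent Seconds already waited (0 .. offer-1).
#' @return Earning probability.
#' @export
pearn_survival_oracle <- function(config, offer, spent = 0L) {
  stopifnot(spent >= 0, spent <= offer - 1)
  tt <- seq_len(offer - 1L)
  tt <- tt[tt > spent]
  if (!length(tt)) return(1)
  prod(1 - quit_hazard(tt, offer, config))
}
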