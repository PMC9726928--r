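#' Simulation configuration for the change-of-mind agent
#'
#' The agent makes two decisions per trial. In the offer zone it draws an
#' initial willingness to wait `W0 = w_threshold + N(0, sigma_w)` and accepts
#' the offered delay iff `W0 >= offer` (or always, under the accept-all
#' policy). In the wait zone `W` drifts once per second,
#' `W(t) = W(t-1) + N(0, sigma_n)`, and the agent quits the countdown at the
#' first second `t` (checked at `t = 1 .. offer-1`) where `W(t)` falls below
#' the quit threshold `T_WZ(t)`; surviving every check earns the reward at
#' `t = offer`.
#'
#' The quit threshold variants (see [quit_threshold_at()]):
#' * `twz_init = "offer"`, `twz_slope = -1` — the original expanding bound:
#'   `T_WZ` starts at the offer on entry and falls 1 s per second, reaching 0
#'   when the countdown ends.
#' * `twz_slope = 0` — a flat bound at the offer; `twz_init = "zero"` pins it
#'   at 0 (the agent must drift below zero to quit); `twz_slope = +1` is the
#'   anti-sunk-cost collapsing bound.
#' * `twz_init = "offer_at_dt_end"` — the bound sits at the offer until the
#'   imposed decision time ends and only then starts moving (reset model 1);
#'   reset model 2 is `twz_init = "offer"` with `decision_time_s > 0`.
#'
#' During an imposed decision time (`decision_time_s` > 0, modelling a covert
#' offer-zone-like deliberation) quitting is not permitted and `W` holds at
#' `W0` until the decision time ends; offers no longer than the decision time
#' are earned automatically. With `upper_bound = "non_increasing"` any drift
#' draw that would raise `W` is clipped to `W(t-1)`.
#'
#' @param w_threshold Offer-zone threshold `W_T` in seconds; also the mean of
#'   the `W0` distribution. Default 18.
#' @param sigma_w Standard deviation (s) of the initial willingness to wait.
#' @param sigma_n Per-second drift standard deviation (s).
#' @param accept_policy `"threshold"` (accept iff `W0 >= offer`) or
#'   `"accept_all"`.
#' @param twz_init `"offer"`, `"zero"`, or `"offer_at_dt_end"`.
#' @param twz_slope Quit-threshold slope in s per second: -1 (original
#'   expanding bound), 0 (flat), +1 (anti-sunk collapsing bound).
#' @param upper_bound `"none"` or `"non_increasing"`.
#' @param decision_time_s Imposed decision time (s) during which quitting is
#'   blocked; 0 disables it.
#' @param n_trials Number of independent trials.
#' @param offer_support Integer support of the uniform offer distribution.
#' @param seed Integer seed; the whole experiment is a deterministic function
#'   of `(config, seed)`.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(w_threshold = 18, sigma_w = 5, sigma_n = 3,
                       accept_policy = c("threshold", "accept_all"),
                       twz_init = c("offer", "zero", "offer_at_dt_end"),
                       twz_slope = -1, upper_bound = c("none", "non_increasing"),
                       decision_time_s = 0L, n_trials = 100000L,
                       offer_support = 1:30, seed = 1L) {
  accept_policy <- match.arg(accept_policy)
  twz_init <- match.arg(twz_init)
  upper_bound <- match.arg(upper_bound)
  stopifnot(sigma_w >= 0, sigma_n >= 0, decision_time_s >= 0, n_trials >= 1,
            length(offer_support) >= 1, all(offer_support >= 1),
            all(offer_support %% 1 == 0))
  structure(list(
    w_threshold = w_threshold, sigma_w = sigma_w, sigma_n = sigma_n,
    accept_policy = accept_policy, twz_init = twz_init,
    twz_slope = twz_slope, upper_bound = upper_bound,
    decision_time_s = as.integer(decision_time_s),
    n_trials = as.integer(n_trials),
    offer_support = as.integer(offer_support), seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>",
      sprintf("W_T = %g s, sigma_W = %g, sigma_N = %g", x$w_threshold,
              x$sigma_w, x$sigma_n),
      sprintf("policy = %s, T_WZ init = %s, slope = %+g/s, upper bound = %s",
              x$accept_policy, x$twz_init, x$twz_slope, x$upper_bound),
      sprintf("decision time = %d s, trials = %d, offers %d..%d, seed = %d",
              x$decision_time_s, x$n_trials, min(x$offer_support),
              max(x$offer_support), x$seed),
      sep = "\n")
  invisible(x)
}

#' Quit threshold T_WZ at a given second
#'
#' Value of the wait-zone quit threshold `t` seconds after wait-zone entry
#' for the configured variant. For `twz_init = "offer"` this is
#' `offer + twz_slope * t` (so with slope -1 it reaches 0 exactly when the
#' countdown ends); `"zero"` is identically 0; `"offer_at_dt_end"` holds at
#' the offer through the decision time and then moves:
#' `offer + twz_slope * max(0, t - decision_time_s)`. The threshold is not
#' floored at zero for variant slopes.
#'
#' @param t Seconds since wait-zone entry (vectorised).
#' @param offer Offer delay in seconds (vectorised).
#' @param config A [sim_config()].
#' @return Numeric threshold value(s) in seconds.
#' @export
quit_threshold_at <- function(t, offer, config) {
  stopifnot(all(t >= 0))
  switch(config$twz_init,
    offer = offer + config$twz_slope * t,
    zero = rep_len(0, max(length(t), length(offer))),
    offer_at_dt_end = offer +
      config$twz_slope * pmax(0, t - config$decision_time_s)
  )
}

#' Simulate a single trial
#'
#' Step-by-step simulation of one offer encounter, drawing from R's current
#' random stream (seed it with `set.seed()` for reproducibility). This is the
#' readable scalar reference path; [run_experiment()] runs the same process
#' vectorised over trials.
#'
#' @param offer Offer delay (integer seconds, within the configured support).
#' @param config A [sim_config()].
#' @return A list with `offer_s`, `w0`, `accepted`, `quit_time_s` (`NA` when
#'   no quit occurred) and `earned`.
#' @export
simulate_trial <- function(offer, config) {
  stopifnot(offer %in% config$offer_support)
  w0 <- config$w_threshold + stats::rnorm(1, 0, config$sigma_w)
  accepted <- config$accept_policy == "accept_all" || w0 >= offer
  quit_time <- NA_integer_
  if (accepted && offer > 1L) {
    w <- w0
    for (t in seq_len(offer - 1L)) {
      if (t <= config$decision_time_s) next  # no quitting; W holds at W0
      dw <- stats::rnorm(1, 0, config$sigma_n)
      if (config$upper_bound == "non_increasing" && dw > 0) dw <- 0
      w <- w + dw
      if (w < quit_threshold_at(t, offer, config)) {
        quit_time <- t
        break
      }
    }
  }
  list(offer_s = as.integer(offer), w0 = w0, accepted = accepted,
       quit_time_s = quit_time, earned = accepted && is.na(quit_time))
}

#' Run a simulated experiment
#'
#' Runs `config$n_trials` independent trials with offers drawn i.i.d.
#' uniformly from the offer support, vectorised over trials. Deterministic
#' given `(config, seed)`: the random stream is consumed in a fixed order —
#' offers, then all `W0` draws, then one block of drift draws per second over
#' the trials still in the wait zone, in trial order.
#'
#' @param config A [sim_config()].
#' @param subject_id,session_id,site_id Identifiers stamped on the emitted
#'   trial log.
#' @return A [session_set()] with one row per trial; `w0` is recorded and
#'   `time_spent_s` holds the quit time for quits and the full offer for
#'   earns. Metadata records the generator, configuration and seed.
#' @export
run_experiment <- function(config, subject_id = "agent",
                           session_id = sprintf("sim%08d", config$seed),
                           site_id = "site1") {
  set.seed(config$seed)
  n <- config$n_trials
  support <- config$offer_support
  offers <- support[sample.int(length(support), n, replace = TRUE)]
  w0 <- config$w_threshold + stats::rnorm(n, 0, config$sigma_w)
  accepted <- if (config$accept_policy == "accept_all") rep(TRUE, n)
              else w0 >= offers
  idx <- which(accepted)
  off <- offers[idx]
  W <- w0[idx]
  quit_t <- rep(NA_integer_, length(idx))
  active <- rep(TRUE, length(idx))
  dt <- config$decision_time_s
  if (length(idx)) {
    for (t in seq_len(max(off) - 1L)) {
      if (t <= dt) next  # quitting blocked; W holds at W0 until DT ends
      li <- which(active & off > t)
      if (!length(li)) next
      dW <- stats::rnorm(length(li), 0, config$sigma_n)
      if (config$upper_bound == "non_increasing") dW <- pmin(dW, 0)
      Wn <- W[li] + dW
      W[li] <- Wn
      thr <- quit_threshold_at(t, off[li], config)
      q <- Wn < thr
      if (any(q)) {
        quit_t[li[q]] <- t
        active[li[q]] <- FALSE
      }
    }
  }
  time_spent <- integer(n)
  outcome <- rep("skip", n)
  spent_acc <- ifelse(is.na(quit_t), off, quit_t)
  time_spent[idx] <- spent_acc
  outcome[idx] <- ifelse(is.na(quit_t), "earn", "quit")
  trials <- tibble::tibble(
    subject_id = subject_id, session_id = session_id, site_id = site_id,
    offer_s = as.integer(offers), accepted = accepted,
    time_spent_s = as.integer(time_spent), outcome = outcome, w0 = w0
  )
  session_set(trials,
              meta = list(generator = "ddm_change_of_mind",
                          config = unclass(config), seed = config$seed,
                          offer_support = support),
              validate = FALSE)
}
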