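# Independent oracles, deliberately sharing no code with the package paths
# they check.

# Step-by-step scalar simulation of one trial of the change-of-mind agent.
# Written directly from the process description, with its own control flow.
oracle_trial <- function(offer, w_threshold = 18, sigma_w = 5, sigma_n = 3,
                         accept_all = FALSE, twz_start = "offer",
                         slope = -1, dt = 0) {
  w0 <- rnorm(1, w_threshold, sigma_w)
  if (!accept_all && w0 < offer) {
    return(list(accepted = FALSE, earned = FALSE, quit_time = NA))
  }
  w <- w0
  t <- 1
  while (t <= offer - 1) {
    if (t > dt) {
      w <- w + rnorm(1, 0, sigma_n)
      thr <- if (twz_start == "offer") offer + slope * t else 0
      if (w < thr) {
        return(list(accepted = TRUE, earned = FALSE, quit_time = t))
      }
    }
    t <- t + 1
  }
  list(accepted = TRUE, earned = TRUE, quit_time = NA)
}

# Brute-force p(Earn) counting: walks every accepted trial second by second
# and tallies each visited (spent, remaining) state individually.
oracle_pearn_counts <- function(trials, dmax = 30) {
  n_pass <- matrix(0L, dmax, dmax)
  n_earn <- matrix(0L, dmax, dmax)
  for (i in seq_len(nrow(trials))) {
    if (!isTRUE(trials$accepted[i])) next
    D <- trials$offer_s[i]
    earned <- trials$outcome[i] == "earn"
    last_s <- if (earned) D - 1L else trials$time_spent_s[i] - 1L
    for (s in 0:last_s) {
      n_pass[s + 1L, D - s] <- n_pass[s + 1L, D - s] + 1L
      if (earned) n_earn[s + 1L, D - s] <- n_earn[s + 1L, D - s] + 1L
    }
  }
  list(n_pass = n_pass, n_earn = n_earn)
}

# Exact two-sided permutation p-value of the rank-sum statistic, by full
# enumeration of group assignments (feasible for <= 8 per group).
oracle_ranksum_perm_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  nx <- length(x)
  obs <- sum(r[seq_len(nx)])
  idx <- utils::combn(length(pooled), nx)
  stats <- apply(idx, 2, function(j) sum(r[j]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-9)
}

# Expected accept rate of the threshold policy under offers uniform on
# 1..30: mean over offers of P(N(W_T, sigma_w) >= offer).
oracle_accept_rate <- function(w_threshold = 18, sigma_w = 5) {
  mean(pnorm((w_threshold - (1:30)) / sigma_w))
}

baseline_cfg <- function(n, seed, ...) {
  sim_config(n_trials = n, seed = seed, ...)
}
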