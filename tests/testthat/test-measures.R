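session_from <- function(offer, outcome, spent, site = "a", w0 = NA_real_) {
  session_set(tibble::tibble(
    subject_id = "x", session_id = "s", site_id = site,
    offer_s = offer, accepted = outcome != "skip",
    time_spent_s = spent, outcome = outcome, w0 = w0))
}

test_that("p(Earn) matrix matches the worked state-counting examples", {
  # a 5 s offer quit at 3 passes (0,5),(1,4),(2,3) as not-earn; no state at s=3
  ses <- session_from(5L, "quit", 3L)
  m <- build_pearn_matrix(ses)
  expect_equal(m$n_pass[cbind(1:3, 5:3)], rep(1L, 3))
  expect_equal(m$n_earn[cbind(1:3, 5:3)], rep(0L, 3))
  expect_equal(sum(m$n_pass), 3)
  expect_equal(m$n_pass[4, 2], 0L)

  # a 3 s offer earned passes (0,3),(1,2),(2,1) all as earns
  m2 <- build_pearn_matrix(session_from(3L, "earn", 3L))
  expect_equal(m2$p_earn[cbind(1:3, 3:1)], rep(1, 3))
  expect_equal(sum(m2$n_pass), 3)
})

test_that("p(Earn) matrix equals brute-force per-trial enumeration", {
  set.seed(77)
  n <- 200
  offers <- sample.int(30, n, replace = TRUE)
  outcome <- ifelse(runif(n) < 0.25, "skip",
                    ifelse(runif(n) < 0.4 & offers > 1, "quit", "earn"))
  spent <- ifelse(outcome == "skip", 0L,
                  ifelse(outcome == "earn", offers,
                         pmax(1L, floor(runif(n) * (offers - 1)) + 1L)))
  ses <- session_from(as.integer(offers), outcome, as.integer(spent))
  m <- build_pearn_matrix(ses)
  oracle <- oracle_pearn_counts(ses)
  expect_identical(unname(m$n_pass), oracle$n_pass)
  expect_identical(unname(m$n_earn), oracle$n_earn)
})

test_that("bubble sums hand-computed probability differences", {
  n_pass <- matrix(0L, 2, 5)
  n_earn <- matrix(0L, 2, 5)
  n_pass[1, 4:5] <- 10L; n_earn[1, 4:5] <- 5L          # p(0,.) = 0.5, 0.5
  n_pass[2, 4:5] <- 10L; n_earn[2, 4] <- 6L; n_earn[2, 5] <- 7L  # 0.6, 0.7
  m <- pearn_matrix(n_pass, n_earn)
  bub <- sunk_cost_bubble(m)
  expect_equal(unname(bub$bubble_by_spent[1]), 0.3)
  expect_equal(bub$bubble_total, 0.3)

  # identical probabilities across time spent: null bubble
  n_earn[2, 4:5] <- 5L
  bub0 <- sunk_cost_bubble(pearn_matrix(n_pass, n_earn))
  expect_equal(bub0$bubble_total, 0)

  # no overlapping defined cells: undefined with diagnostic
  n_pass2 <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  expect_warning(b2 <- sunk_cost_bubble(pearn_matrix(n_pass2, n_pass2 * 0L)),
                 "undefined")
  expect_true(is.na(b2$bubble_total))
})

test_that("baseline slope is the exact OLS slope of the zero-invested row", {
  r <- 1:20
  n_pass <- matrix(0L, 2, 20)
  n_pass[1, ] <- 1000L
  n_earn <- n_pass
  n_earn[1, ] <- as.integer(round(1000 * (1 - 0.02 * r)))
  m <- pearn_matrix(n_pass, n_earn)
  expect_equal(baseline_slope(m), -0.02, tolerance = 1e-4)

  # constant row: slope 0; single cell: undefined
  n_earn[1, ] <- 500L
  expect_equal(baseline_slope(pearn_matrix(n_pass, n_earn)), 0)
  n_pass[1, -1] <- 0L; n_earn[1, -1] <- 0L
  expect_warning(s <- baseline_slope(pearn_matrix(n_pass, n_earn)), "undefined")
  expect_true(is.na(s))
})

test_that("attrition slope matches an expanded lm and its degenerate cases", {
  ses <- run_experiment(sim_config(n_trials = 2000, seed = 21))
  acc <- ses[ses$accepted, ]
  pts <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
    data.frame(s = 0:(acc$time_spent_s[i] - 1L), w0 = acc$w0[i])
  }))
  expect_equal(attrition_slope(ses),
               unname(coef(lm(w0 ~ s, pts))[2]), tolerance = 1e-10)

  # all W0 equal: slope exactly 0
  flat <- session_from(rep(10L, 5), rep("earn", 5), rep(10L, 5), w0 = rep(3, 5))
  expect_equal(attrition_slope(flat), 0)

  # no w0: not-applicable signal
  g <- generate_sessions(behavior_gen_config(n_trials = 200, seed = 1))
  expect_message(a <- attrition_slope(g), "not applicable")
  expect_true(is.na(a))
})

test_that("attrition is near zero without selection and positive with it", {
  # accept-all with the zero-pinned quit threshold: essentially no quits, so
  # time in the wait zone is the offer alone, independent of W0
  ses0 <- run_experiment(sim_config(accept_policy = "accept_all",
                                    twz_init = "zero", twz_slope = 0,
                                    sigma_n = 0, n_trials = 5e4, seed = 22))
  expect_lt(abs(attrition_slope(ses0)), 0.02)
  # baseline threshold policy: selection by acceptance and survival
  ses1 <- run_experiment(sim_config(n_trials = 5e4, seed = 23))
  expect_gt(attrition_slope(ses1), 0.1)
})

test_that("measures are invariant to trial order", {
  ses <- run_experiment(sim_config(n_trials = 5000, seed = 24))
  perm <- session_set(as.data.frame(ses)[sample(nrow(ses)), ],
                      meta = session_meta(ses))
  expect_equal(sunk_cost_bubble(build_pearn_matrix(perm))$bubble_total,
               sunk_cost_bubble(build_pearn_matrix(ses))$bubble_total)
  expect_equal(attrition_slope(perm), attrition_slope(ses))
  expect_equal(baseline_slope(build_pearn_matrix(perm)),
               baseline_slope(build_pearn_matrix(ses)))
})

test_that("threshold MLE separates, recovers, and stays on its grid", {
  # perfectly separable: accepts exactly offers <= 12
  offers <- rep(1:30, each = 4)
  acc <- offers <= 12
  ses <- session_from(as.integer(offers),
                      ifelse(acc, "earn", "skip"),
                      as.integer(ifelse(acc, offers, 0L)))
  expect_equal(as.numeric(estimate_threshold(ses)), 12)

  # probit-generated choices recover the generating threshold
  set.seed(31)
  n <- 10000
  offers <- sample.int(30, n, replace = TRUE)
  acc <- runif(n) < pnorm((18 - offers) / 5)
  ses <- session_from(as.integer(offers), ifelse(acc, "earn", "skip"),
                      as.integer(ifelse(acc, offers, 0L)))
  expect_lt(abs(as.numeric(estimate_threshold(ses)) - 18), 1 + 1e-9)

  # all-accept data: boundary estimate with degeneracy flag
  ses_all <- session_from(rep(5L, 20), rep("earn", 20), rep(5L, 20))
  t_all <- estimate_threshold(ses_all)
  expect_true(attr(t_all, "degenerate"))
  expect_true(as.numeric(t_all) >= 0 && as.numeric(t_all) <= 30)
})

test_that("offer value is threshold minus offer", {
  expect_equal(offer_value(18, 10), 8)
  expect_equal(offer_value(18, 20), -2)
  expect_equal(offer_value(7.5, 7.5), 0)
})

test_that("probit tangent recovers the generating psychometric slope", {
  gen <- function(sigma, n = 20000, seed = 41) {
    set.seed(seed)
    offers <- sample.int(30, n, replace = TRUE)
    acc <- runif(n) < pnorm((18 - offers) / sigma)
    session_from(as.integer(offers), ifelse(acc, "earn", "skip"),
                 as.integer(ifelse(acc, offers, 0L)))
  }
  f5 <- probit_accept_fit(gen(5))
  expect_equal(f5$tangent, dnorm(0) / 5, tolerance = 0.08)
  expect_equal(f5$midpoint, 18, tolerance = 0.5)
  expect_false(f5$separated)
  # doubling sigma_W halves the tangent
  f10 <- probit_accept_fit(gen(10, seed = 42))
  expect_equal(f5$tangent / f10$tangent, 2, tolerance = 0.15)
  # perfect separation: unbounded slope flagged
  sep <- session_from(as.integer(rep(1:30, 3)),
                      ifelse(rep(1:30, 3) <= 15, "earn", "skip"),
                      as.integer(ifelse(rep(1:30, 3) <= 15, rep(1:30, 3), 0L)))
  fs <- probit_accept_fit(sep)
  expect_true(fs$separated)
  expect_identical(fs$tangent, Inf)
})

test_that("sigma_W estimation applies and inverts the calibration", {
  fit <- structure(list(a = -0.13, b = 0.40, adj_r2 = 1, n = 80),
                   class = "calibration_fit")
  expect_equal(estimate_sigma_w(0.08, fit), 4.87)
  # ideal calibration is the exact inverse of the ideal tangent
  for (sw in c(1, 3, 5, 8)) {
    expect_equal(estimate_sigma_w(dnorm(0) / sw), sw)
  }
  expect_error(estimate_sigma_w(0), "positive")
})

test_that("hyperbolic fit recovers exact coefficients on ideal points", {
  sig <- c(0.25, 0.5, 1, 3, 5, 8, 10, 20)
  fit <- fit_hyperbolic(dnorm(0) / sig, sig)
  expect_equal(fit$a, 0, tolerance = 1e-10)
  expect_equal(fit$b, dnorm(0), tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-10)
})

test_that("value-conditioned deltas localise the bubble and match exact tests", {
  # hand-built matrix: positive deltas only where value < 0 (remaining > thr)
  n_pass <- matrix(0L, 3, 12)
  n_pass[, 2:12] <- 100L
  n_earn <- n_pass
  n_earn[1, 2:12] <- 50L
  n_earn[2:3, 2:12] <- 50L
  n_earn[2:3, 9:12] <- 70L   # remaining 9..12 > threshold 8 -> value < 0
  v <- value_conditioned_deltas(pearn_matrix(n_pass, n_earn), threshold = 8)
  expect_gt(v$median_neg, v$median_pos)
  neg <- v$table$delta_p[v$table$value < 0]
  pos <- v$table$delta_p[v$table$value > 0]
  expect_equal(unique(neg), 0.2)
  expect_equal(unique(pos), 0)

  # all-zero deltas: no effect, non-significant
  v0 <- value_conditioned_deltas(pearn_matrix(n_pass, n_pass %/% 2L),
                                 threshold = 8)
  expect_equal(v0$p_value, 1)
  expect_equal(v0$median_neg, 0)

  # rank-sum p equals exhaustive permutation enumeration (no ties, <= 8/group)
  x <- c(0.21, 0.33, 0.41, 0.18)
  y <- c(0.02, -0.05, 0.11, 0.07, 0.01)
  expect_equal(wilcox.test(x, y, exact = TRUE)$p.value,
               oracle_ranksum_perm_p(x, y), tolerance = 1e-12)
})

test_that("baseline simulation shows larger deltas at negative value", {
  ses <- run_experiment(sim_config(n_trials = 1e5, seed = 51))
  m <- build_pearn_matrix(ses)
  thr <- as.numeric(estimate_threshold(ses))
  v <- value_conditioned_deltas(m, thr)
  expect_gt(v$median_neg, v$median_pos)
  expect_lt(v$p_value, 0.01)
})

test_that("latency to accrual applies the detection and outlier rules", {
  b <- c(5, 6, 7, 8)                      # large from the first second
  expect_equal(as.integer(latency_to_accrual(b)), 1L)

  b2 <- c(0, 0.01, 0.02, 2, 3, 4, 5)      # grows from s = 4
  expect_equal(as.integer(latency_to_accrual(b2)), 4L)
  expect_false(attr(latency_to_accrual(b2), "outlier"))

  b3 <- c(rep(0, 28), 5, 6)               # crossing at s = 29: outlier
  lat3 <- latency_to_accrual(b3)
  expect_equal(as.integer(lat3), 29L)
  expect_true(attr(lat3, "outlier"))

  expect_true(is.na(latency_to_accrual(c(-1, -2, 0))))  # never grows
  # single noisy bin is not persistent accrual
  expect_equal(as.integer(latency_to_accrual(c(0, 9, 0, 5, 5, 5))), 4L)
})

test_that("interaction model recovers exact surfaces and the OLS solution", {
  n_pass <- matrix(1000L, 10, 15)
  r <- rep(1:15, each = 10); s <- rep(0:9, times = 15)
  p <- 0.2 + 0.01 * r + 0.02 * s
  n_earn <- matrix(as.integer(round(1000 * p)), 10, 15)
  m <- pearn_matrix(n_pass, n_earn)
  im <- interaction_model(m)
  co <- im$coefficients
  expect_equal(co$estimate[co$term == "remaining:spent"], 0, tolerance = 1e-3)
  expect_gt(im$adj_r2, 0.999)

  # constant surface: all slope terms zero
  mc <- pearn_matrix(n_pass, matrix(400L, 10, 15))
  imc <- interaction_model(mc)
  expect_equal(imc$coefficients$estimate[-1], rep(0, 3))

  # coefficients match the normal-equations solution on a random 20-cell table
  set.seed(61)
  cells <- pearn_cells(m)[sample(150, 20), ]
  n_pass2 <- matrix(0L, 10, 15); n_earn2 <- matrix(0L, 10, 15)
  idx <- cbind(cells$spent + 1L, cells$remaining)
  n_pass2[idx] <- 1000L
  n_earn2[idx] <- as.integer(round(1000 * runif(20)))
  m2 <- pearn_matrix(n_pass2, n_earn2)
  im2 <- interaction_model(m2)
  c2 <- pearn_cells(m2)
  X <- cbind(1, c2$remaining, c2$spent, c2$remaining * c2$spent)
  beta <- solve(t(X) %*% X, t(X) %*% c2$p_earn)
  expect_equal(im2$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
})

test_that("linear/quadratic comparison identifies curvature exactly", {
  x <- -2:2
  fq <- linquad_convexity_fit(x, x^2)
  expect_equal(fq$quad_adj_r2, 1)
  expect_equal(fq$curvature, "convex")
  expect_gt(fq$quad_coef, 0)

  fl <- linquad_convexity_fit(x, 3 - 2 * x)
  expect_equal(fl$quad_coef, 0, tolerance = 1e-10)
  expect_equal(fl$linear_adj_r2, 1)

  fc <- linquad_convexity_fit(x, -(x^2) + x)
  expect_equal(fc$curvature, "concave")

  expect_error(linquad_convexity_fit(1:3, 1:3), "4 points")
})
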