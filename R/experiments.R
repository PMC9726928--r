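#' Standard measure set for one session
#'
#' Computes the per-session scalar measures used throughout the simulation
#' campaigns: total sunk-cost bubble, baseline slope, attrition slope,
#' probit tangent (with `sigma_w_hat` through a calibration) and, when the
#' bubble crosses its detection level, the latency to accrual.
#'
#' @param trials A [session_set()].
#' @param min_count Cell threshold for the p(Earn) matrix.
#' @param calibration A `calibration_fit` mapping tangent to `sigma_w_hat`;
#'   default the ideal closed form.
#' @param kappa_frac Latency detection fraction (see [latency_to_accrual()]).
#' @return A one-row tibble: `bubble_total`, `baseline_slope`,
#'   `attrition_slope`, `probit_tangent`, `sigma_w_hat`,
#'   `latency_to_accrual_s`.
#' @export
session_measures <- function(trials, min_count = 1L,
                             calibration = ideal_calibration(),
                             kappa_frac = 0.10) {
  m <- build_pearn_matrix(trials, min_count = min_count)
  bub <- sunk_cost_bubble(m)
  tangent <- NA_real_
  if (any(trials$accepted) && !all(trials$accepted)) {
    pf <- probit_accept_fit(trials)
    tangent <- pf$tangent
  }
  sigma_w_hat <- if (is.finite(tangent) && tangent > 0) {
    estimate_sigma_w(tangent, calibration)
  } else NA_real_
  lat <- latency_to_accrual(bub$bubble_by_spent, kappa_frac)
  tibble::tibble(
    bubble_total = bub$bubble_total,
    baseline_slope = suppressWarnings(baseline_slope(m)),
    attrition_slope = attrition_slope(trials),
    probit_tangent = tangent,
    sigma_w_hat = sigma_w_hat,
    latency_to_accrual_s = as.integer(lat)
  )
}

# deterministic per-run seed from (base seed, cell, replicate); kept < 2^31
derive_seed <- function(base_seed, cell, replicate) {
  as.integer((as.numeric(base_seed) + 7919 * cell + 104729 * replicate) %%
               .Machine$integer.max)
}

#' Parameter sweep over (sigma_W, sigma_N)
#'
#' Runs a full simulated experiment for every grid cell and replicate and
#' measures each run (bubble, baseline slope, attrition slope, probit
#' tangent / `sigma_w_hat`). Seeds are derived deterministically from the
#' base seed, cell index and replicate, so the sweep is reproducible and
#' individual cells can be re-run in isolation.
#'
#' @param base A [sim_config()] providing everything except the swept
#'   parameters.
#' @param grid Data frame with columns `sigma_w` and `sigma_n`; default the
#'   9 x 4 campaign grid `{0, 0.25, 0.5, 1, 3, 5, 8, 10, 20} x {0, 2, 3, 5}`.
#' @param replicates Replicate experiments per cell.
#' @param trials_per_run Trials per experiment.
#' @param calibration Calibration used for `sigma_w_hat`.
#' @return A `sweep_result`: `grid`, `replicates`, `measures` (one row per
#'   cell x replicate) and `mesh` (per-cell means of the measures).
#' @export
run_parameter_sweep <- function(base,
                                grid = expand.grid(
                                  sigma_w = c(0, 0.25, 0.5, 1, 3, 5, 8, 10, 20),
                                  sigma_n = c(0, 2, 3, 5)),
                                replicates = 1L,
                                trials_per_run = base$n_trials,
                                calibration = ideal_calibration()) {
  stopifnot(nrow(grid) >= 1, all(c("sigma_w", "sigma_n") %in% names(grid)))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(replicates)) {
      cfg <- base
      cfg$sigma_w <- grid$sigma_w[i]
      cfg$sigma_n <- grid$sigma_n[i]
      cfg$n_trials <- as.integer(trials_per_run)
      cfg$seed <- derive_seed(base$seed, i, r)
      ses <- run_experiment(cfg)
      meas <- session_measures(ses, calibration = calibration)
      rows[[length(rows) + 1]] <- cbind(
        tibble::tibble(cell = i, sigma_w = grid$sigma_w[i],
                       sigma_n = grid$sigma_n[i], replicate = r,
                       seed = cfg$seed),
        meas)
    }
  }
  measures <- tibble::as_tibble(do.call(rbind, rows))
  mesh <- stats::aggregate(
    measures[c("bubble_total", "baseline_slope", "attrition_slope",
               "probit_tangent", "sigma_w_hat")],
    by = measures[c("cell", "sigma_w", "sigma_n")],
    FUN = function(v) mean(v))
  mesh <- tibble::as_tibble(mesh[order(mesh$cell), ])
  structure(list(grid = tibble::as_tibble(grid), replicates = replicates,
                 trials_per_run = trials_per_run,
                 measures = measures, mesh = mesh),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells x %d replicate(s), %s trials/run\n",
              nrow(x$grid), x$replicates,
              format(x$trials_per_run, big.mark = ",")))
  invisible(x)
}

# per-predictor F (1 df) = squared t of the coefficient, identical to the
# drop-one partial F; model F is the usual F versus the constant model
lm_f_table <- function(formula, data, label) {
  fit <- stats::lm(formula, data)
  s <- summary(fit)
  fstat <- s$fstatistic
  terms <- rownames(s$coefficients)[-1]
  tibble::tibble(
    model = label,
    term = c(terms, "(model)"),
    f = c(unname(s$coefficients[-1, "t value"]^2), unname(fstat[1])),
    p = c(unname(s$coefficients[-1, "Pr(>|t|)"]),
          unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))),
    adj_r2 = s$adj.r.squared,
    df = fit$df.residual
  )
}

#' Regressions over the sweep mesh
#'
#' Four OLS models over the per-cell mean measures: attrition, baseline
#' slope and bubble each on `sigma_w + sigma_n`, and bubble on attrition.
#' Per-predictor F statistics are the squared coefficient t values
#' (1-numerator-df partial F); the model row reports F against the
#' constant-only model. Cells with missing measures are excluded with a
#' note and the degrees of freedom adjust accordingly.
#'
#' @param sweep A `sweep_result`.
#' @return Tibble of model/term rows with `f`, `p`, `adj_r2`, `df`.
#' @export
sweep_regressions <- function(sweep) {
  mesh <- sweep$mesh
  out <- list()
  for (spec in list(
    list(f = attrition_slope ~ sigma_w + sigma_n, label = "attrition"),
    list(f = baseline_slope ~ sigma_w + sigma_n, label = "baseline"),
    list(f = bubble_total ~ sigma_w + sigma_n, label = "bubble"),
    list(f = bubble_total ~ attrition_slope, label = "bubble_vs_attrition"))) {
    vars <- all.vars(spec$f)
    ok <- stats::complete.cases(mesh[vars])
    if (any(!ok)) {
      message(spec$label, ": ", sum(!ok), " cell(s) with missing measures excluded")
    }
    out[[spec$label]] <- lm_f_table(spec$f, mesh[ok, ], spec$label)
  }
  tibble::as_tibble(do.call(rbind, out))
}

#' Calibrate the tangent-to-sigma_W relation
#'
#' Runs replicate experiments across a grid of generating `sigma_W` values
#' (baseline `sigma_N`, threshold accept policy), fits the accept/skip
#' probit of each run, takes the tangent at the 50% point, and fits the
#' hyperbolic relation `sigma_W = a + b / tangent` over all (tangent,
#' sigma_W) points. Perfectly separated runs (unbounded probit slope) are
#' dropped with a warning. The large-sample closed form is `a = 0`,
#' `b = phi(0)`.
#'
#' @param base A [sim_config()].
#' @param sigma_w_values Generating `sigma_W` grid; must exclude 0 (its
#'   tangent is unbounded). Default `c(0.25, 0.5, 1, 3, 5, 8, 10, 20)`.
#' @param replicates Replicates per value (default 10).
#' @param trials_per_run Trials per experiment.
#' @return List: `fit` (a `calibration_fit`) and `points` (tibble of
#'   `sigma_w`, `replicate`, `tangent`).
#' @export
calibrate_sigma_w_relation <- function(base,
                                       sigma_w_values = c(0.25, 0.5, 1, 3, 5,
                                                          8, 10, 20),
                                       replicates = 10L,
                                       trials_per_run = base$n_trials) {
  stopifnot(all(sigma_w_values > 0))
  pts <- list()
  dropped <- 0L
  for (i in seq_along(sigma_w_values)) {
    for (r in seq_len(replicates)) {
      cfg <- base
      cfg$sigma_w <- sigma_w_values[i]
      cfg$accept_policy <- "threshold"
      cfg$n_trials <- as.integer(trials_per_run)
      cfg$seed <- derive_seed(base$seed, 1000L + i, r)
      ses <- run_experiment(cfg)
      pf <- probit_accept_fit(ses)
      if (pf$separated) {
        dropped <- dropped + 1L
        next
      }
      pts[[length(pts) + 1]] <- tibble::tibble(
        sigma_w = sigma_w_values[i], replicate = r, tangent = pf$tangent)
    }
  }
  if (dropped) {
    warning(dropped, " perfectly separated run(s) dropped from calibration",
            call. = FALSE)
  }
  points <- tibble::as_tibble(do.call(rbind, pts))
  list(fit = fit_hyperbolic(points$tangent, points$sigma_w), points = points)
}

#' Reset-hypothesis experiment
#'
#' Models task variants without a usable offer zone: agents accept every
#' offer but cannot quit for an imposed decision time (DT), after which `W`
#' is reset to `W0`. Two hypotheses about the quit threshold:
#' * model 1 — `T_WZ` sits at the offer until DT ends and only then starts
#'   decreasing 1 s/s (the escalation of commitment excludes the decision
#'   time);
#' * model 2 — `T_WZ` starts decreasing at wait-zone entry, through the
#'   decision time (the escalation includes it).
#'
#' For each decision time on the grid, runs an experiment and sums the
#' total sunk-cost bubble; then compares linear and quadratic fits of total
#' sensitivity against decision time ([linquad_convexity_fit()]). The two
#' models produce distinct shapes: model 1 stays close to linear while
#' model 2 bends strongly (positive quadratic coefficient, flattening at
#' long DT).
#'
#' @param base A [sim_config()].
#' @param model `"model1"` or `"model2"`.
#' @param decision_times Integer DT grid; default 0..10 s.
#' @param trials_per_dt Trials per decision time.
#' @return List: `per_dt` (tibble of `decision_time_s`, `bubble_total`,
#'   `seed`), `fit` (the lin/quad comparison), `model`.
#' @export
run_reset_experiment <- function(base, model = c("model1", "model2"),
                                 decision_times = 0:10,
                                 trials_per_dt = base$n_trials) {
  model <- match.arg(model)
  rows <- list()
  for (i in seq_along(decision_times)) {
    cfg <- base
    cfg$accept_policy <- "accept_all"
    cfg$twz_init <- if (model == "model1") "offer_at_dt_end" else "offer"
    cfg$twz_slope <- -1
    cfg$decision_time_s <- as.integer(decision_times[i])
    cfg$n_trials <- as.integer(trials_per_dt)
    cfg$seed <- derive_seed(base$seed, 2000L + i, 1L)
    ses <- run_experiment(cfg)
    bub <- sunk_cost_bubble(build_pearn_matrix(ses))
    rows[[i]] <- tibble::tibble(decision_time_s = decision_times[i],
                                bubble_total = bub$bubble_total,
                                seed = cfg$seed)
  }
  per_dt <- tibble::as_tibble(do.call(rbind, rows))
  list(per_dt = per_dt,
       fit = linquad_convexity_fit(per_dt$decision_time_s,
                                   per_dt$bubble_total),
       model = model)
}

#' Compare subjects to the simulation mesh
#'
#' Places each subject — summarised by (baseline slope, total bubble, fitted
#' `sigma_W`) — against the sweep's per-cell mean mesh. Candidate cells are
#' those whose generating `sigma_W` is nearest the subject's `sigma_w_hat`;
#' among candidates the cell minimising Euclidean distance in z-scored
#' (baseline slope, bubble) space is chosen (axes standardised by the mesh
#' means and SDs, so the two measures weigh equally). Signed differences
#' (subject minus mesh) are tested against zero with one-sample Wilcoxon
#' signed-rank tests: if the model family captured the subjects, both
#' difference distributions should centre at 0.
#'
#' @param subjects Data frame with columns `baseline_slope`, `bubble_total`,
#'   `sigma_w_hat`.
#' @param sweep A `sweep_result`.
#' @return A `mesh_comparison` list: `per_subject` (chosen cell and signed
#'   deltas), `p_baseline`, `p_bubble`, `low_power` (fewer than 6 subjects),
#'   `rule` (a record of the nearest-point convention).
#' @export
mesh_comparison <- function(subjects, sweep) {
  stopifnot(all(c("baseline_slope", "bubble_total", "sigma_w_hat") %in%
                  names(subjects)))
  mesh <- sweep$mesh
  mu_b <- mean(mesh$baseline_slope, na.rm = TRUE)
  sd_b <- stats::sd(mesh$baseline_slope, na.rm = TRUE)
  mu_u <- mean(mesh$bubble_total, na.rm = TRUE)
  sd_u <- stats::sd(mesh$bubble_total, na.rm = TRUE)
  if (!isTRUE(sd_b > 0)) sd_b <- 1
  if (!isTRUE(sd_u > 0)) sd_u <- 1
  per <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    d_sw <- abs(mesh$sigma_w - s$sigma_w_hat)
    cand <- which(d_sw <= min(d_sw) + 1e-12)
    dist <- sqrt(((mesh$baseline_slope[cand] - s$baseline_slope) / sd_b)^2 +
                   ((mesh$bubble_total[cand] - s$bubble_total) / sd_u)^2)
    j <- cand[which.min(dist)]
    tibble::tibble(
      subject = i, cell = mesh$cell[j],
      mesh_sigma_w = mesh$sigma_w[j], mesh_sigma_n = mesh$sigma_n[j],
      delta_baseline = s$baseline_slope - mesh$baseline_slope[j],
      delta_bubble = s$bubble_total - mesh$bubble_total[j])
  })
  per <- tibble::as_tibble(do.call(rbind, per))
  signed_rank_p <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    if (all(x == 0)) return(structure(NA_real_, degenerate = TRUE))
    suppressWarnings(stats::wilcox.test(x, mu = 0)$p.value)
  }
  structure(list(
    per_subject = per,
    p_baseline = signed_rank_p(per$delta_baseline),
    p_bubble = signed_rank_p(per$delta_bubble),
    low_power = nrow(subjects) < 6,
    rule = paste("nearest sigma_W first, then Euclidean distance on",
                 "z-scored (baseline slope, bubble) axes;",
                 "one-sample Wilcoxon signed-rank vs 0")
  ), class = "mesh_comparison")
}
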