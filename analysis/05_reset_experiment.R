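#!/usr/bin/env Rscript
# Reset-hypothesis experiment: agents accept every offer and cannot quit for
# an imposed decision time DT. Model 1 starts the quit-threshold countdown
# after DT; model 2 lets it run from wait-zone entry. The shape of total
# sunk-cost sensitivity against DT discriminates the two.

suppressMessages(library(sunkddm))
started <- Sys.time()
dir.create("results", showWarnings = FALSE)
n <- 2e5
seed <- 20260928

tabs <- list()
for (model in c("model1", "model2")) {
  res <- run_reset_experiment(sim_config(seed = seed), model,
                              decision_times = 0:10, trials_per_dt = n)
  cat(sprintf("%s: bubbles %s\n", model,
              paste(sprintf("%.0f", res$per_dt$bubble_total), collapse = " ")))
  cat(sprintf("  linear adj R^2 %.4f, quadratic adj R^2 %.4f, quad coef %+.3f (%s)\n",
              res$fit$linear_adj_r2, res$fit$quad_adj_r2, res$fit$quad_coef,
              res$fit$curvature))
  tabs[[model]] <- cbind(model = model, res$per_dt)
}

cat("\nlatency to accrual under model 1, DT = 5 s:\n")
cfg <- sim_config(accept_policy = "accept_all", twz_init = "offer_at_dt_end",
                  decision_time_s = 5, n_trials = n, seed = seed)
bub <- sunk_cost_bubble(build_pearn_matrix(run_experiment(cfg)))
lat <- latency_to_accrual(bub$bubble_by_spent)
cat(sprintf("  latency %d s (accrual starts after the decision time)\n",
            as.integer(lat)))

cat("\nReading: model 2 bends strongly (mid-range DT less sensitive than the\n")
cat("linear trend) while model 1 declines near-linearly; the quadratic term\n")
cat("separates the two reset hypotheses.\n")

out <- "results/05_reset_per_dt.tsv"
write.table(do.call(rbind, tabs), out, sep = "\t", row.names = FALSE,
            quote = FALSE)
write_run_manifest("results/05_reset_manifest.json", "reset_experiment",
                   list(trials_per_dt = n, decision_times = 0:10), seed, out,
                   started)
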