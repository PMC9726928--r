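#!/usr/bin/env Rscript
# Baseline change-of-mind agent (W_T = 18, sigma_W = 5, sigma_N = 3):
# simulates the original threshold-accept model and the accept-all variant,
# measures sunk-cost sensitivity, and asks where in value space it lives.

suppressMessages(library(sunkddm))
started <- Sys.time()
dir.create("results", showWarnings = FALSE)
n <- 5e5
seed <- 20260928

cat("== Baseline model ==\n")
cfg <- sim_config(n_trials = n, seed = seed)
ses <- run_experiment(cfg)
cat(sprintf("accept rate %.3f (closed form %.3f); P(earn | accepted) %.3f\n",
            mean(ses$accepted), mean(pnorm((18 - 1:30) / 5)),
            mean(ses$outcome[ses$accepted] == "earn")))
ms <- session_measures(ses)
cat(sprintf("bubble %.1f, baseline slope %.4f/s, attrition %.3f s/s, sigma_W_hat %.2f\n",
            ms$bubble_total, ms$baseline_slope, ms$attrition_slope,
            ms$sigma_w_hat))

thr <- as.numeric(estimate_threshold(ses))
v <- value_conditioned_deltas(build_pearn_matrix(ses), thr)
cat(sprintf("threshold %.1f s; delta-p medians: value<0 %.3f vs value>0 %.3f (p = %.2g)\n",
            thr, v$median_neg, v$median_pos, v$p_value))
cat("-> sunk-cost sensitivity concentrates on economically bad states\n\n")

cat("== Accept-all variant ==\n")
ses_all <- run_experiment(sim_config(accept_policy = "accept_all",
                                     n_trials = n, seed = seed))
ms_all <- session_measures(ses_all)
cat(sprintf("bubble %.1f (vs %.1f), attrition %.3f (vs %.3f)\n",
            ms_all$bubble_total, ms$bubble_total,
            ms_all$attrition_slope, ms$attrition_slope))
cat("-> removing offer-zone selection shrinks the attrition bias but the\n")
cat("   bubble, if anything, grows: attrition does not cause the sensitivity\n")

out <- "results/01_baseline_measures.tsv"
tab <- rbind(cbind(policy = "threshold", ms), cbind(policy = "accept_all", ms_all))
write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
write_run_manifest("results/01_baseline_manifest.json", "baseline_model",
                   list(n_trials = n), seed, out, started)
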