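#!/usr/bin/env Rscript
# Where does the model's sunk-cost sensitivity come from? Knock out each
# decision-process component: the expanding quit threshold (slope -1/s), the
# unbounded upward drift of W, or both, plus the anti-sunk collapsing bound.

suppressMessages(library(sunkddm))
started <- Sys.time()
dir.create("results", showWarnings = FALSE)
n <- 5e5
seed <- 20260928

variants <- list(
  original        = sim_config(n_trials = n, seed = seed),
  flat_at_offer   = sim_config(twz_slope = 0, n_trials = n, seed = seed),
  pinned_at_zero  = sim_config(twz_init = "zero", twz_slope = 0,
                               n_trials = n, seed = seed),
  anti_sunk       = sim_config(twz_slope = 1, n_trials = n, seed = seed),
  noninc_drift    = sim_config(upper_bound = "non_increasing",
                               n_trials = n, seed = seed),
  flat_and_noninc = sim_config(twz_slope = 0, upper_bound = "non_increasing",
                               n_trials = n, seed = seed)
)

rows <- lapply(names(variants), function(nm) {
  ses <- run_experiment(variants[[nm]])
  acc <- ses[ses$accepted, ]
  bub <- sunk_cost_bubble(build_pearn_matrix(ses))
  cat(sprintf("%-16s quit rate %.4f  bubble %8.2f\n", nm,
              mean(acc$outcome == "quit"), bub$bubble_total))
  data.frame(variant = nm, quit_rate = mean(acc$outcome == "quit"),
             bubble_total = bub$bubble_total)
})
tab <- do.call(rbind, rows)

cat("\nReadings:\n")
cat("- flattening the bound reduces the bubble; pinning it at 0 all but\n")
cat("  eliminates quitting; the collapsing (+1/s) bound inverts the bubble\n")
cat("- clipping the drift to non-increasing adds a downward trend in W and\n")
cat("  pushes the bubble negative rather than to zero: with a flat bound at\n")
cat("  the offer the accepted initial margin W0 - offer shrinks with the\n")
cat("  offer, so the quit hazard rises with time spent regardless\n")

out <- "results/02_bound_variants.tsv"
write.table(tab, out, sep = "\t", row.names = FALSE, quote = FALSE)
write_run_manifest("results/02_bound_variants_manifest.json", "bound_variants",
                   list(n_trials = n), seed, out, started)
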