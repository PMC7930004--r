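#!/usr/bin/env Rscript
# Step 3 — coarse hyperparameter screening.
#
# First-pass grid search on a 75/25 split of the all-signal, level-1 feature
# matrix: every combination of the wide stage-1 grid is scored on the
# validation split and, per classifier, candidate values within 2 accuracy
# points of the best are retained. This reproduces the two-stage narrowing
# that precedes the cross-validated evaluation of step 4.
#
# Outputs: results/grid_screening.csv, results/grid_reduced.json

suppressPackageStartupMessages(library(physiowork))

fm <- read.csv("results/features_EDA-ECG-RESP_L1.csv", check.names = FALSE)
x <- as.matrix(fm[, setdiff(names(fm), c("subject_id", "window", "condition"))])
y <- factor(fm$condition, levels = c("control", "task"))

# the long-iteration wide-net MLP corners dominate screening runtime; the
# demo trims them and FULL_GRID=1 restores the complete stage-1 ranges
g1 <- grid_stage1()
if (!nzchar(Sys.getenv("FULL_GRID"))) {
  g1$MLP$hidden <- c(32, 64, 128)
  g1$MLP$max_iter <- 500
}

t0 <- Sys.time()
red <- coarse_grid_search(x, y, fm$subject_id, grid = g1,
                          margin = 0.02, seed = 7)
cat(sprintf("screened %d combinations in %.1f min\n",
            nrow(attr(red, "screening")),
            as.numeric(Sys.time() - t0, units = "mins")))

write.csv(attr(red, "screening"), "results/grid_screening.csv",
          row.names = FALSE)
jsonlite::write_json(red, "results/grid_reduced.json", auto_unbox = TRUE,
                     null = "null", digits = NA)

scr <- attr(red, "screening")
for (cl in unique(scr$classifier)) {
  s <- scr[scr$classifier == cl, ]
  cat(sprintf("%s: best validation accuracy %.2f (%d combos, %d retained)\n",
              cl, max(s$accuracy), nrow(s),
              sum(s$accuracy >= max(s$accuracy) - 0.02)))
}
cat("retained grids written to results/grid_reduced.json\n")
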