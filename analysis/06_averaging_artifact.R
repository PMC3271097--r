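#!/usr/bin/env Rscript
# Demonstrates why averaging fixation locations across opposed start
# positions is misleading: the average regresses toward the face center,
# a location where few fixations actually land, and hides the reversal of
# the spatial bias between the first and second fixation.

suppressMessages(library(fixmapr))

out_dir <- "results/averaging"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(n_participants = 20, trials_per_cell = 8,
                        kappa = 0.8, delta = 1.2, seed = 99)
demo <- averaging_demo(cfg, starts = c("upper", "lower"), ordinals = 1:2)
data.table::fwrite(demo, file.path(out_dir, "averaging_demo.csv"))

ctr <- attr(demo, "face_center")
cat(sprintf("face center (half-nose midpoint): y = %+.2f deg\n", ctr[["y"]]))
for (o in 1:2) {
  d <- demo[demo$ordinal == o, ]
  cat(sprintf("fixation %d mean vertical location (deg, y down):\n", o))
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-8s y = %+.2f\n", d$start_position[i], d$y_mean[i]))
}
cat("\nThe per-start means flip sides between fixations 1 and 2 while the\n")
cat("across-start average stays near the face center on both - the\n")
cat("averaged location describes almost no actual fixation.\n")
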