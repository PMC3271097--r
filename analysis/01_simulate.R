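#!/usr/bin/env Rscript
# Simulate a full start-position face-viewing experiment and write the raw
# artifacts: fixation report, per-face AOI rectangles, derived start
# positions, and the old/new behavioral table.
#
# The synthetic observer reproduces the structure the downstream analyses
# assume: first fixations near the face center with a slight toward-start
# bias, fixations 2-5 biased toward the opposite side of the face, shorter
# first fixations, and slower first saccades from the central start.

suppressMessages(library(fixmapr))

out_dir <- "results/simulated"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cfg <- generator_config(seed = 20120202)
print(cfg)

ds <- generate_dataset(cfg)

write_fixation_report(ds$fixations, file.path(out_dir, "fixation_report.tsv"))
write_aoi_file(ds$faces, file.path(out_dir, "aois.tsv"))
write_start_positions(ds$faces, file.path(out_dir, "start_positions.csv"))
data.table::fwrite(ds$behavior, file.path(out_dir, "behavior.csv"))

cat(sprintf("simulated %d fixations over %d trials from %d participants\n",
            nrow(ds$fixations), length(unique(ds$fixations$trial_id)),
            cfg$n_participants))
cat(sprintf("faces: %d; study trials per orientation x start cell: %d\n",
            cfg$n_faces, cfg$trials_per_cell))
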