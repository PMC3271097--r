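#!/usr/bin/env Rscript
# Ingest the simulated fixation report, apply the study's filters (first
# five fixations per trial, out-of-image clamping), and write the
# descriptive summaries: AOI relative frequencies, latency to first
# saccade, per-ordinal fixation durations, and per-participant d-prime.
#
# Expects results/simulated/ from analysis/01_simulate.R.

suppressMessages(library(fixmapr))

in_dir <- "results/simulated"
out_dir <- "results/preprocessed"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

fx <- read_fixation_report(file.path(in_dir, "fixation_report.tsv"))
faces <- read_aoi_file(file.path(in_dir, "aois.tsv"),
                       image_bounds = canonical_face()$image_bounds)
beh <- data.table::fread(file.path(in_dir, "behavior.csv"),
                         data.table = FALSE)

fx5 <- select_first_k(fx, k = 5)
cat(sprintf("dropped %d fixations beyond the fifth; %d trials had < 5\n",
            attr(fx5, "n_removed"), attr(fx5, "n_short_trials")))

clamped <- clamp_to_image(fx5, canonical_face())
cat(sprintf("clamped %.2f%% of fixations to the image edge\n",
            100 * attr(clamped, "clamped_fraction")))

upright_study <- clamped[clamped$phase == "study" &
                           clamped$orientation == "upright", ]
freq <- relative_frequencies(upright_study, faces)
data.table::fwrite(freq, file.path(out_dir, "aoi_frequencies.csv"))

eye_rows <- freq$aoi %in% c("left_eye", "mid_eye", "right_eye")
mouth_rows <- freq$aoi %in% c("left_mouth", "right_mouth")
cat(sprintf("mean relative frequency: eye region %.3f vs mouth %.3f\n",
            mean(freq$rel_freq[eye_rows]), mean(freq$rel_freq[mouth_rows])))

prof <- duration_profile(clamped)
data.table::fwrite(prof$latency, file.path(out_dir, "latency_summary.csv"))
data.table::fwrite(prof$durations, file.path(out_dir, "duration_summary.csv"))

lat <- prof$latency
cat(sprintf("latency to first saccade: center %.0f ms vs peripheral %.0f ms\n",
            mean(lat$latency_mean_ms[lat$start_position == "center"]),
            mean(lat$latency_mean_ms[lat$start_position != "center"])))
dur <- prof$durations
cat(sprintf("fixation duration: ordinal 1 %.0f ms vs ordinals 2-5 %.0f ms\n",
            mean(dur$duration_mean_ms[dur$ordinal == 1]),
            mean(dur$duration_mean_ms[dur$ordinal %in% 2:5])))

dp <- dprime_table(beh)
data.table::fwrite(dp, file.path(out_dir, "dprime_table.csv"))
cat(sprintf("mean d-prime %.2f (true generator value %.2f)\n",
            mean(dp$dprime), generator_config()$dprime_true))
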