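#!/usr/bin/env Rscript
# Stage 1: simulate the cohort.
#
# Generates ground-truth-known recordings for a scaled-down cohort of six
# subjects with 200 cue-go trials each (160 directional, 40 non-directional;
# the full design uses 400, halved here to keep the whole analysis chain
# runnable in minutes). Recording parameters follow the study design:
# 64 channels, 1000 Hz, 2000 ms cue-go interval, RT-coupled CNV.
#
# Writes per subject under results/sim/: the raw container, events.tsv and
# the ground-truth table.

library(erpcnv)

n_subjects <- 6L
seed <- 7L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# between-subject structure: each subject's mean CNV slope is drawn from the
# same N(-4, 1.5^2) uV/s population used by the subject-level cohort model,
# so the median split and the CNV-RT correlation act on real differences
set.seed(seed)
subject_slope_mean <- rnorm(n_subjects, -4, 1.5)

for (s in seq_len(n_subjects)) {
  cfg <- sim_config(n_trials = 200,
                    cnv_slope_mean_uv_per_s = subject_slope_mean[s],
                    seed = seed * 100L + s)
  sub <- simulate_subject(cfg)
  id <- sprintf("sub%02d", s)
  write_raw(sub$recording, file.path(out, paste0(id, ".raw")))
  write_events(sub$events, file.path(out, paste0(id, "_events.tsv")))
  utils::write.table(sub$truth, file.path(out, paste0(id, "_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: %d trials, %d channels, %.0f s | mean RT %.0f ms, mean CNV slope %.2f uV/s",
    id, nrow(sub$truth), nrow(sub$recording$data),
    recording_duration(sub$recording), mean(sub$truth$rt_ms),
    mean(sub$truth$cnv_slope)))
}
message("cohort written to ", out)
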