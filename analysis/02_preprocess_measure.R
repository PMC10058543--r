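#!/usr/bin/env Rscript
# Stage 2: preprocess every subject and measure components, CNV and RTs.
#
# For each simulated recording: resample to 512 Hz, band-pass 0.2-30 Hz
# (zero-phase FIR), epoch (5 s cue epochs for the CNV; 1100 ms cue- and
# go-locked segments for the components), reject epochs exceeding 100 uV
# peak to peak, baseline-correct, then measure P100/P150/N200/P300/P400
# per condition and lock, the within-subject fast/slow trial contrast, and
# the Cz CNV (mean value and slope).
#
# The 60-epoch-per-condition guard is lowered to 25 for this half-size
# cohort (40 non-directional trials per subject).
#
# Writes results/measures/: measures.tsv, cnv.tsv, rt.tsv, cnv waveforms.

library(erpcnv)

sim_dir <- "results/sim"
out <- "results/measures"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- pipeline_config(overrides = list(
  preprocess = list(min_per_condition = 25)
))

subjects <- sub("\\.raw$", "", list.files(sim_dir, pattern = "\\.raw$"))
all_measures <- list()
all_cnv <- list()
all_rt <- list()
wave_rows <- list()

for (id in subjects) {
  rec <- read_raw(file.path(sim_dir, paste0(id, ".raw")))
  ev <- read_events(file.path(sim_dir, paste0(id, "_events.tsv")))
  res <- analyze_subject(rec, ev, cfg, subject = id)
  rm(rec)
  invisible(gc())
  all_measures[[id]] <- res$measures
  all_cnv[[id]] <- res$cnv
  all_rt[[id]] <- res$rt
  for (cond in names(res$cnv_waveforms)) {
    cm <- res$cnv_waveforms[[cond]]
    wave_rows[[paste(id, cond)]] <- data.frame(
      subject = id, condition = cond, time_s = cm$times,
      amplitude_uv = cm$waveform)
  }
  message(sprintf(
    "%s: epochs cue/go %d/%d | DS mean RT %.0f ms | CNV slope (all) %.2f uV/s%s",
    id, res$n_epochs$cue_seg, res$n_epochs$go_seg,
    res$rt$mean_rt_ms[res$rt$condition == "DS"],
    res$cnv$slope_uv_per_s[res$cnv$condition == "all"],
    if (length(res$warnings)) paste0(" | ", length(res$warnings), " warning(s)")
    else ""))
}

tsv <- function(x, f) utils::write.table(do.call(rbind, x), file.path(out, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
tsv(all_measures, "measures.tsv")
tsv(all_cnv, "cnv.tsv")
tsv(all_rt, "rt.tsv")
tsv(wave_rows, "cnv_waveforms.tsv")
message("measures written to ", out)
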