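#!/usr/bin/env Rscript
# Stage 4: fast (F) vs slow (S) subjects.
#
# Median split of per-subject mean RTs (separately for the DS and nDS
# conditions; subjects exactly at the median are excluded), then unpaired
# equal-variance t-tests per electrode on the go-locked component
# amplitudes between the groups, BH-FDR corrected per component, plus the
# F vs S grand-average CNV curves.
#
# Writes results/analysis/: subject splits (JSON), stats_fs_subjects_*.tsv,
# CNV figure.

library(erpcnv)

meas <- utils::read.delim("results/measures/measures.tsv", check.names = FALSE)
rt <- utils::read.delim("results/measures/rt.tsv")
waves <- utils::read.delim("results/measures/cnv_waveforms.tsv")
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mon <- standard_montage()
comps <- names(component_definitions())

for (cond in c("DS", "nDS")) {
  mr <- rt$mean_rt_ms[rt$condition == cond]
  names(mr) <- rt$subject[rt$condition == cond]
  sp <- subject_median_split(mr)
  write_split(sp, file.path(out, sprintf("subject_split_%s.json", cond)))
  f <- names(sp$membership)[sp$membership == "F"]
  s <- names(sp$membership)[sp$membership == "S"]
  message(sprintf("%s split: F = {%s}, S = {%s}, median %.0f ms", cond,
                  toString(f), toString(s), sp$threshold_ms))
  if (length(f) < 2 || length(s) < 2) {
    message("groups too small for electrode-wise tests; skipping")
    next
  }
  maps <- list()
  for (cp in comps) {
    rows <- meas[meas$lock == "go" & meas$condition == cond &
                   meas$component == cp, ]
    g <- as.matrix(rows[, mon$name])
    rownames(g) <- rows$subject
    maps[[cp]] <- unpaired_t_map(g[f, , drop = FALSE], g[s, , drop = FALSE],
                                 contrast = sprintf("go %s F-S %s", cond, cp))
    message(sprintf("  %s: %d electrodes significant", cp,
                    sum(maps[[cp]]$mask)))
  }
  stat_table(maps, file.path(out, sprintf("stats_fs_subjects_%s.tsv", cond)))

  # F vs S grand CNV (condition-specific curves)
  gw <- function(ids) {
    w <- waves[waves$condition == cond & waves$subject %in% ids, ]
    ag <- stats::aggregate(amplitude_uv ~ time_s, data = w, FUN = mean)
    structure(list(waveform = ag$amplitude_uv, times = ag$time_s,
                   condition = cond, n_trials = length(ids), channel = "Cz"),
              class = "cnv_measure")
  }
  fw <- gw(f)
  sw <- gw(s)
  plot_cnv(list(F = fw, S = sw),
           path = file.path(out, sprintf("cnv_fs_subjects_%s.png", cond)))
  message(sprintf("  grand CNV slope: F %.2f, S %.2f uV/s",
                  cnv_slope(fw), cnv_slope(sw)))
}
message("fast/slow subject analysis written to ", out)
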