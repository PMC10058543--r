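#!/usr/bin/env Rscript
# Stage 5: fast vs slow trials within subjects.
#
# Stage 2 classified each subject's directional go trials as fast (RT below
# mean - SD/2) or slow (RT above mean + SD/2) and measured the component
# maps of the two trial groups. Here: paired t-tests per electrode between
# the per-subject trialF and trialS maps (BH-FDR per component), and the
# latency comparison (one-way ANOVA per component across trial groups).
#
# Writes results/analysis/: stats_fs_trials.tsv, trial latency table.

library(erpcnv)

meas <- utils::read.delim("results/measures/measures.tsv", check.names = FALSE)
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mon <- standard_montage()
comps <- names(component_definitions())

maps <- list()
lat_rows <- list()
for (cp in comps) {
  fr <- meas[meas$condition == "trialF" & meas$component == cp, ]
  sr <- meas[meas$condition == "trialS" & meas$component == cp, ]
  shared <- intersect(fr$subject, sr$subject)
  fr <- fr[match(shared, fr$subject), ]
  sr <- sr[match(shared, sr$subject), ]
  if (length(shared) < 2) next
  maps[[cp]] <- paired_t_map(as.matrix(fr[, mon$name]),
                             as.matrix(sr[, mon$name]),
                             contrast = sprintf("go trialF-S %s", cp))
  an <- latency_anova(list(fr$latency_ms, sr$latency_ms))
  lat_rows[[cp]] <- data.frame(component = cp, n_subjects = length(shared),
                               mean_lat_f = mean(fr$latency_ms),
                               mean_lat_s = mean(sr$latency_ms),
                               F = an$F, p = an$p)
  message(sprintf("%s: %d electrodes significant; latency F vs S %.1f vs %.1f ms (p = %.3f)",
                  cp, sum(maps[[cp]]$mask), mean(fr$latency_ms),
                  mean(sr$latency_ms), an$p))
}
stat_table(maps, file.path(out, "stats_fs_trials.tsv"))
utils::write.table(do.call(rbind, lat_rows),
                   file.path(out, "latency_fs_trials.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("fast/slow trial analysis written to ", out)
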