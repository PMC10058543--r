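#!/usr/bin/env Rscript
# Stage 3: directional vs non-directional cues.
#
# Paired two-tailed t-tests per electrode between the DS and nDS
# per-subject amplitude maps for every component, at both the cue and go
# locks, with the Benjamini-Hochberg threshold recomputed per component;
# latency homogeneity checks; grand-average CNV curves per condition.
#
# Writes results/analysis/: stats_ds_nds_{cue,go}.tsv, latency table,
# topography and CNV figures.

library(erpcnv)

meas <- utils::read.delim("results/measures/measures.tsv", check.names = FALSE)
waves <- utils::read.delim("results/measures/cnv_waveforms.tsv")
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mon <- standard_montage()
comps <- names(component_definitions())
emat <- function(lock, cond, comp)
  as.matrix(meas[meas$lock == lock & meas$condition == cond &
                   meas$component == comp, mon$name])

lat_rows <- list()
for (lk in c("cue", "go")) {
  maps <- list()
  for (cp in comps) {
    a <- emat(lk, "DS", cp)
    b <- emat(lk, "nDS", cp)
    maps[[cp]] <- paired_t_map(a, b, contrast = sprintf("%s DS-nDS %s", lk, cp))
    la <- meas$latency_ms[meas$lock == lk & meas$condition == "DS" &
                            meas$component == cp]
    lb <- meas$latency_ms[meas$lock == lk & meas$condition == "nDS" &
                            meas$component == cp]
    hom <- latency_homogeneity(la, lb)
    lat_rows[[paste(lk, cp)]] <- data.frame(
      lock = lk, component = cp, mean_lat_ds = mean(la),
      mean_lat_nds = mean(lb), t = hom$t, p = hom$p, flag = hom$flag)
    thr <- maps[[cp]]$fdr_threshold
    message(sprintf(
      "%s %s: %d/%d electrodes significant (FDR threshold %s)",
      lk, cp, sum(maps[[cp]]$mask), nrow(mon),
      if (is.na(thr)) "none" else sprintf("p < %.4f", thr)))
  }
  stat_table(maps, file.path(out, sprintf("stats_ds_nds_%s.tsv", lk)))
  # topography of the N200 mean DS-nDS amplitude difference
  d <- colMeans(emat(lk, "DS", "N200")) - colMeans(emat(lk, "nDS", "N200"))
  grid <- interpolate_topography(d, mon)
  plot_topography(grid, mon, main = sprintf("N200 DS-nDS (%s)", lk),
                  path = file.path(out, sprintf("topo_n200_ds_nds_%s.png", lk)))
}
utils::write.table(do.call(rbind, lat_rows),
                   file.path(out, "latency_homogeneity_ds_nds.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# grand-average CNV per condition
grand <- function(cond) {
  w <- waves[waves$condition == cond, ]
  ag <- stats::aggregate(amplitude_uv ~ time_s, data = w, FUN = mean)
  structure(list(waveform = ag$amplitude_uv, times = ag$time_s,
                 condition = cond, n_trials = length(unique(w$subject)),
                 channel = "Cz"), class = "cnv_measure")
}
ds <- grand("DS")
nds <- grand("nDS")
plot_cnv(list(DS = ds, nDS = nds), path = file.path(out, "cnv_ds_vs_nds.png"))
message(sprintf("grand CNV slope 1200-2000 ms: DS %.2f uV/s, nDS %.2f uV/s",
                cnv_slope(ds), cnv_slope(nds)))
message("DS vs nDS analysis written to ", out)
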