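#!/usr/bin/env Rscript
# Stage 6: correlation between mean CNV value and reaction time.
#
# Pools all subjects: each contributes its mean CNV value (Cz, 1500-2000 ms
# post-cue, all conditions) and its mean RT. Pearson's r with the two-tailed
# p from the t transform. The expected direction is positive: subjects with
# a larger (more negative) CNV build-up respond faster.
#
# Writes results/analysis/correlation.json and a scatter figure.

library(erpcnv)

cnv <- utils::read.delim("results/measures/cnv.tsv")
rt <- utils::read.delim("results/measures/rt.tsv")
out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cnv_all <- cnv[cnv$condition == "all", ]
rt_all <- rt[rt$condition == "all", ]
stopifnot(all(cnv_all$subject == rt_all$subject))

res <- pearson_corr(cnv_all$mean_uv, rt_all$mean_rt_ms)
message(sprintf("CNV-RT correlation over %d subjects: r = %.3f (p = %.3f)",
                res$n, res$r, res$p))
jsonlite::write_json(res, file.path(out, "correlation.json"),
                     auto_unbox = TRUE, digits = NA)

grDevices::png(file.path(out, "cnv_rt_scatter.png"), width = 600, height = 500)
plot(cnv_all$mean_uv, rt_all$mean_rt_ms, pch = 19,
     xlab = "mean CNV value (uV)", ylab = "mean RT (ms)",
     main = sprintf("r = %.3f, p = %.3f (n = %d)", res$r, res$p, res$n))
abline(stats::lm(rt_all$mean_rt_ms ~ cnv_all$mean_uv), lty = 2)
grDevices::dev.off()
message("correlation analysis written to ", out)
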