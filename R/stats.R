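#' Electrode-wise statistics and FDR threshold recomputation
#'
#' Electrode-by-electrode paired or unpaired two-tailed t-tests produce a
#' statistical map; the per-map family of p-values is then corrected with
#' the Benjamini-Hochberg step-up procedure, which returns a *new, data-
#' dependent threshold* (the largest rejected raw p-value) in place of the
#' nominal alpha — electrodes with p at or below that threshold form the
#' significance mask. Electrodes with no variance yield p = 1 by convention
#' rather than NaN, so degenerate synthetic inputs give stable maps.
#'
#' @name stats_maps
NULL

.safe_t <- function(x, y, paired, var_equal = TRUE) {
  if (paired) {
    d <- x - y
    if (stats::sd(d) == 0) return(c(t = 0, p = 1))
    r <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(c(t = 0, p = 1))
    r <- stats::t.test(x, y, var.equal = var_equal)
  }
  c(t = unname(r$statistic), p = r$p.value)
}

.statmap <- function(electrodes, tval, pval, test, contrast, alpha) {
  fdr <- fdr_threshold(pval, alpha)
  thr <- fdr$adjusted_threshold
  structure(
    list(electrodes = electrodes, statistic = tval, p = pval,
         test = test, contrast = contrast, alpha = alpha,
         fdr_threshold = thr,
         mask = if (is.na(thr)) rep(FALSE, length(pval)) else pval <= thr),
    class = "stat_map"
  )
}

#' Paired t-test map
#'
#' Per electrode, a two-tailed paired t-test between two within-subject
#' amplitude matrices (subjects x electrodes, same subjects and electrode
#' order), FDR-corrected as one family.
#'
#' @param a,b subjects x electrodes numeric matrices.
#' @param electrodes electrode names (default taken from `colnames(a)`).
#' @param contrast free-text description stored in the map.
#' @param alpha nominal significance level before FDR (default 0.05).
#' @return a `stat_map`.
#' @export
paired_t_map <- function(a, b, electrodes = colnames(a),
                         contrast = "paired", alpha = 0.05) {
  if (!all(dim(a) == dim(b)))
    stop("paired maps need matrices of identical dimension")
  if (nrow(a) < 2L) stop("paired t-test needs at least two subjects")
  res <- vapply(seq_len(ncol(a)),
                function(j) .safe_t(a[, j], b[, j], paired = TRUE),
                numeric(2))
  .statmap(electrodes, res[1, ], res[2, ], "paired_t", contrast, alpha)
}

#' Unpaired (two-sample) t-test map
#'
#' Equal-variance (pooled) two-sample t by default, per electrode, between
#' two disjoint subject groups.
#'
#' @param group_f,group_s subjects x electrodes matrices (e.g. fast and
#'   slow groups).
#' @param var_equal pooled-variance t (TRUE, default) or Welch.
#' @inheritParams paired_t_map
#' @return a `stat_map`.
#' @export
unpaired_t_map <- function(group_f, group_s, electrodes = colnames(group_f),
                           contrast = "unpaired", alpha = 0.05,
                           var_equal = TRUE) {
  if (ncol(group_f) != ncol(group_s))
    stop("groups must share the electrode set")
  if (nrow(group_f) < 2L || nrow(group_s) < 2L)
    stop("each group needs at least two subjects")
  res <- vapply(seq_len(ncol(group_f)),
                function(j) .safe_t(group_f[, j], group_s[, j],
                                    paired = FALSE, var_equal = var_equal),
                numeric(2))
  .statmap(electrodes, res[1, ], res[2, ], "unpaired_t", contrast, alpha)
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s (%s), %d electrodes, FDR threshold %s, %d significant\n",
              x$contrast, x$test, length(x$p),
              if (is.na(x$fdr_threshold)) "none"
              else format(x$fdr_threshold, digits = 3),
              sum(x$mask)))
  invisible(x)
}

#' Benjamini-Hochberg FDR threshold
#'
#' Step-up procedure: sort the m p-values ascending, find the largest k
#' with p_(k) <= k * alpha / m; the adjusted threshold is p_(k) and every
#' p-value at or below it is rejected. When no k qualifies the threshold is
#' reported as `NA` and nothing is rejected.
#'
#' @param pvals p-values in [0, 1].
#' @param alpha starting threshold (default 0.05).
#' @return list of class `fdr_result`: `alpha`, `adjusted_threshold`
#'   (`NA` if none), `rejected` (indices into `pvals`), `n_rejected`.
#' @export
fdr_threshold <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvals)
  ps <- sort(pvals)
  ok <- which(ps <= seq_len(m) * alpha / m)
  if (!length(ok)) {
    thr <- NA_real_
    rej <- integer(0)
  } else {
    thr <- ps[max(ok)]
    rej <- which(pvals <= thr)
  }
  structure(list(alpha = alpha, adjusted_threshold = thr, rejected = rej,
                 n_rejected = length(rej)),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("<fdr_result> alpha = %g, new threshold = %s, %d rejected\n",
              x$alpha,
              if (is.na(x$adjusted_threshold)) "none"
              else format(x$adjusted_threshold, digits = 3),
              x$n_rejected))
  invisible(x)
}

#' One-way ANOVA on component latencies
#'
#' @param groups list of numeric latency samples, one per group.
#' @return list with `F`, `p`, `df`.
#' @export
latency_anova <- function(groups) {
  if (length(groups) < 2L) stop("ANOVA needs at least two groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("each group needs at least two observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (stats::sd(y) == 0) return(list(F = 0, p = 1,
                                     df = c(length(groups) - 1L,
                                            length(y) - length(groups))))
  a <- stats::anova(stats::lm(y ~ g))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df)
}

#' Latency homogeneity check
#'
#' Two-tailed t-test on component latencies between two conditions; when
#' p falls below `flag_level` the returned `flag` is set, marking that
#' downstream amplitude comparisons are made at different latencies.
#'
#' @param lat_a,lat_b latency samples, ms.
#' @param flag_level caution level (default 0.05).
#' @return list with `t`, `p`, `flag`.
#' @export
latency_homogeneity <- function(lat_a, lat_b, flag_level = 0.05) {
  if (length(lat_a) < 2L || length(lat_b) < 2L)
    stop("need at least two latencies per condition")
  r <- .safe_t(lat_a, lat_b, paired = FALSE)
  list(t = unname(r["t"]), p = unname(r["p"]),
       flag = unname(r["p"]) < flag_level)
}

#' Pearson correlation with two-tailed p
#'
#' r with the p-value from the t transform t = r sqrt((n-2)/(1-r^2)) on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least three observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in x or y: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Interpolate a per-electrode quantity onto a scalp grid
#'
#' Inverse-distance weighting (power 2 by default) of electrode values onto
#' a regular grid over the unit disc; nodes outside the disc are `NA` and
#' nodes coinciding with an electrode take its value exactly.
#'
#' @param values named per-electrode values (or a vector ordered as
#'   `montage`).
#' @param montage an `eeg_montage` with 2D positions.
#' @param grid_n grid resolution per axis (default 67).
#' @param power IDW exponent.
#' @return list with `x`, `y` (grid axes) and `z` (grid_n x grid_n matrix).
#' @export
interpolate_topography <- function(values, montage, grid_n = 67, power = 2) {
  if (nrow(montage) < 3L) stop("need at least three electrodes")
  pos <- cbind(montage$x, montage$y)
  if (anyDuplicated(round(pos, 10)))
    stop("coincident electrode positions")
  if (!is.null(names(values)))
    values <- values[montage$name]
  if (anyNA(values)) stop("missing electrode value(s)")
  ax <- seq(-1, 1, length.out = grid_n)
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) {
    for (j in seq_len(grid_n)) {
      if (ax[i]^2 + ax[j]^2 > 1 + 1e-9) next
      d2 <- (pos[, 1] - ax[i])^2 + (pos[, 2] - ax[j])^2
      hit <- which(d2 < 1e-12)
      if (length(hit)) {
        z[j, i] <- values[hit[1]]
      } else {
        w <- 1 / d2^(power / 2)
        z[j, i] <- sum(w * values) / sum(w)
      }
    }
  }
  list(x = ax, y = ax, z = z)
}

#' Export stat maps as a table with electrode rows
#'
#' One row per electrode, one column per map; significant electrodes show
#' their raw p-value (4 decimals), others `"-"` — the layout used for
#' published per-component significance tables.
#'
#' @param maps named list of `stat_map`s sharing an electrode set.
#' @param path optional TSV output path.
#' @return the data frame, invisibly if written.
#' @export
stat_table <- function(maps, path = NULL) {
  el <- maps[[1]]$electrodes
  df <- data.frame(electrode = el, stringsAsFactors = FALSE)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    df[[nm]] <- ifelse(m$mask, sprintf("%.4f", m$p), "-")
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
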