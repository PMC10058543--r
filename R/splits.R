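#' Fast/slow performance splits
#'
#' Two procedures classify performance from reaction times: a between-
#' subject median split of per-subject mean RTs (strictly below the median
#' -> F, strictly above -> S, exactly at the median -> excluded), and a
#' within-subject trial split at mean +/- half the sample standard
#' deviation (below the lower threshold -> F trials, above the upper -> S
#' trials, in between -> excluded).
#'
#' @name performance_split
NULL

#' Mean reaction time
#'
#' Arithmetic mean ignoring missing responses, with the missing count
#' reported.
#'
#' @param rts RTs in ms (`NA` = no response).
#' @param conditions optional per-trial condition labels; with `selector`
#'   restricts the mean to matching trials.
#' @param selector condition selector (default `"all"`).
#' @return list with `mean_ms`, `n`, `n_missing`.
#' @export
mean_rt <- function(rts, conditions = NULL, selector = "all") {
  if (!is.null(conditions)) {
    keep <- conditions %in% expand_conditions(selector)
    rts <- rts[keep]
  }
  n_missing <- sum(is.na(rts))
  ok <- rts[!is.na(rts)]
  if (!length(ok)) stop("no finite reaction times to average")
  list(mean_ms = mean(ok), n = length(ok), n_missing = n_missing)
}

#' Subject-level median split
#'
#' The median of the per-subject mean RTs is computed; subjects strictly
#' below it form the fast (F) group, strictly above the slow (S) group, and
#' subjects exactly at the median are excluded (with an odd number of
#' distinct means this excludes exactly one subject).
#'
#' @param mean_rts named numeric vector of per-subject mean RTs, ms.
#' @return list of class `split_result`: `level = "subject"`, `membership`
#'   (named "F"/"S"/"excluded"), `threshold_ms` (the median), counts.
#' @export
subject_median_split <- function(mean_rts) {
  if (length(mean_rts) < 2L) stop("need at least two subjects to split")
  if (is.null(names(mean_rts)))
    names(mean_rts) <- paste0("sub", seq_along(mean_rts))
  med <- stats::median(mean_rts)
  memb <- ifelse(mean_rts < med, "F", ifelse(mean_rts > med, "S", "excluded"))
  if (!any(memb == "F") && !any(memb == "S"))
    stop("all subject means are identical; the median split is empty")
  structure(
    list(level = "subject", membership = memb, threshold_ms = med,
         n_fast = sum(memb == "F"), n_slow = sum(memb == "S"),
         n_excluded = sum(memb == "excluded")),
    class = "split_result"
  )
}

#' Within-subject trial split at mean +/- SD/2
#'
#' Thresholds are the subject's mean RT minus/plus half the sample standard
#' deviation (n-1 denominator), computed on trials matching the condition
#' selector (directional trials by default; the non-directional condition
#' rarely has enough trials for a within split).
#'
#' @param rts per-trial RTs in ms for one subject.
#' @param conditions optional per-trial condition labels.
#' @param selector condition selector (default `"DS"` when `conditions` is
#'   given, otherwise all trials are used).
#' @param sd_mult multiple of the SD defining the thresholds (default 0.5).
#' @param min_group warn when either group ends up smaller than this.
#' @return `split_result` with `level = "trial"`, `membership` indexed by
#'   trial, and `threshold_ms = c(lower, upper)`.
#' @export
trial_sd_split <- function(rts, conditions = NULL, selector = "DS",
                           sd_mult = 0.5, min_group = 10) {
  idx <- seq_along(rts)
  if (!is.null(conditions)) {
    keep <- conditions %in% expand_conditions(selector)
    idx <- idx[keep]
  }
  idx <- idx[!is.na(rts[idx])]
  if (length(idx) < 2L) stop("need at least two finite RTs to split trials")
  x <- rts[idx]
  s <- stats::sd(x)
  if (s == 0) stop("zero RT variance: the split thresholds collapse")
  lo <- mean(x) - sd_mult * s
  hi <- mean(x) + sd_mult * s
  memb <- rep("excluded", length(rts))
  memb[idx[x < lo]] <- "F"
  memb[idx[x > hi]] <- "S"
  names(memb) <- seq_along(rts)
  nf <- sum(memb == "F"); ns <- sum(memb == "S")
  if (min(nf, ns) < min_group)
    warning("trial split leaves a small group (F = ", nf, ", S = ", ns, ")")
  structure(
    list(level = "trial", membership = memb, threshold_ms = c(lo, hi),
         mean_ms = mean(x), sd_ms = s, n_fast = nf, n_slow = ns,
         n_excluded = sum(memb == "excluded"), n_used = length(idx)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %s level: F = %d, S = %d, excluded = %d\n",
              x$level, x$n_fast, x$n_slow, x$n_excluded))
  cat("  threshold(s) ms:", paste(round(x$threshold_ms, 2), collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialise a split result to JSON
#' @param split a `split_result`.
#' @param path output path.
#' @export
write_split <- function(split, path) {
  x <- unclass(split)
  x$membership <- as.list(x$membership)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
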