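#' Electrode montages
#'
#' A montage is a data frame with one row per electrode: its 10-20/10-10
#' label, a 2D position projected onto the unit disc (x = right, y = anterior)
#' used for scalp-map interpolation, and a 3D position on the unit sphere.
#' Positions are derived from the systematic angular grid of the extended
#' 10-20 scheme: anterior-posterior rows (Fp, AF, F, FC/FT, C/T, CP/TP, P,
#' PO, O) and lateral columns (z, 1/2, ..., 9/10) each advance by 18 degrees
#' (10% of the nasion-inion respectively ear-to-ear arc).
#'
#' @name montage
NULL

.row_angle <- c(Fp = 4, AF = 3, F = 2, FC = 1, FT = 1, C = 0, T = 0,
                CP = -1, TP = -1, P = -2, PO = -3, O = -4)

#' Parse an extended 10-20 electrode label
#'
#' @param label electrode label such as "Cz", "P7", "TP9".
#' @return list with `row` (letters), `num` (0 for z-line, else 1..10),
#'   `side` (-1 left / odd, +1 right / even, 0 midline).
#' @keywords internal
parse_1020_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+?)(z|[0-9]{1,2})$", label))[[1]]
  if (length(m) != 3L)
    stop("cannot parse electrode label: ", label)
  row <- m[2]
  # normalise case quirks such as "FPZ", "fp1"
  row <- paste0(toupper(substr(row, 1, 1)), tolower(substring(row, 2)))
  if (row == "Af") row <- "AF"
  if (row %in% c("Fc", "Ft")) row <- toupper(row)
  if (row %in% c("Cp", "Tp", "Po")) row <- toupper(row)
  if (row == "Po") row <- "PO"
  if (!row %in% names(.row_angle))
    stop("unknown electrode row in label: ", label)
  if (tolower(m[3]) == "z")
    return(list(row = row, num = 0L, side = 0L))
  num <- as.integer(m[3])
  if (num < 1L || num > 10L)
    stop("electrode number out of range in label: ", label)
  list(row = row, num = num, side = if (num %% 2L == 1L) -1L else 1L)
}

#' Mirror an electrode label across the midline
#'
#' @param label electrode label.
#' @return the contralateral label (midline labels map to themselves).
#' @export
#' @examples mirror_electrode("P7")  # "P8"
mirror_electrode <- function(label) {
  p <- parse_1020_label(label)
  if (p$side == 0L) return(label)
  num <- p$num - p$side  # odd (left) -> +1 even partner; even (right) -> -1
  sub("(z|[0-9]+)$", num, label)
}

#' Build a montage from electrode labels
#'
#' Positions come from the angular grid described in \link{montage}: polar
#' angle from the vertex theta = 18 * sqrt(m^2 + l^2) degrees (m = row index,
#' l = lateral index) and azimuth atan2(side * l, m) measured from the
#' anterior midline. 2D positions scale theta onto the unit disc.
#'
#' @param labels character vector of unique extended 10-20 labels.
#' @return data frame of class `eeg_montage` with columns
#'   `name, x, y, x3, y3, z3`.
#' @export
make_montage <- function(labels) {
  if (anyDuplicated(labels))
    stop("duplicate electrode labels in montage")
  rows <- lapply(labels, parse_1020_label)
  m <- .row_angle[vapply(rows, `[[`, character(1), "row")]
  num <- vapply(rows, `[[`, integer(1), "num")
  l <- ifelse(num == 0L, 0, ceiling(num / 2))
  side <- vapply(rows, `[[`, integer(1), "side")
  theta <- 18 * sqrt(m^2 + l^2) * pi / 180
  az <- atan2(side * l, m)
  r2 <- (theta * 180 / pi) / 92  # outermost ring (TP9/10, FT9/10) just inside the disc
  out <- data.frame(
    name = as.character(labels),
    x = r2 * sin(az),
    y = r2 * cos(az),
    x3 = sin(theta) * sin(az),
    y3 = sin(theta) * cos(az),
    z3 = cos(theta),
    stringsAsFactors = FALSE
  )
  class(out) <- c("eeg_montage", "data.frame")
  out
}

#' Default 64-channel montage
#'
#' The standard 64-electrode 10-10 set of BrainAmp-style caps. It contains
#' every scalp label used in the component and CNV channel groups
#' (Fp1...Oz, including TP9/TP10) plus AFz, FT9 and FT10.
#'
#' @return an `eeg_montage` with 64 rows.
#' @export
standard_montage <- function() {
  make_montage(c(
    "Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T7", "T8", "P7", "P8", "Fz", "Cz", "Pz", "Oz",
    "FC1", "FC2", "CP1", "CP2", "FC5", "FC6", "CP5", "CP6", "TP9", "TP10",
    "F1", "F2", "C1", "C2", "P1", "P2", "AF3", "AF4", "FC3", "FC4",
    "CP3", "CP4", "PO3", "PO4", "F5", "F6", "C5", "C6", "P5", "P6",
    "AF7", "AF8", "FT7", "FT8", "TP7", "TP8", "PO7", "PO8",
    "Fpz", "CPz", "POz", "AFz", "FT9", "FT10"
  ))
}

#' Read / write a montage as TSV
#'
#' Columns: `name`, `x`, `y` and optionally `x3, y3, z3`.
#'
#' @param path file path.
#' @param montage an `eeg_montage`.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(as.data.frame(montage), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("montage file is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$name)) stop("duplicate electrode labels in montage")
  class(df) <- c("eeg_montage", "data.frame")
  df
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", nrow(x), " electrodes: ",
      paste(utils::head(x$name, 8), collapse = ", "),
      if (nrow(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}
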