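#' File input/output
#'
#' Three interchange surfaces: the package raw container (a JSON header plus
#' little-endian float32 channel-major binary, round-trip exact to float32
#' precision), BIDS-style `events.tsv`, and minimal 16-bit EDF for
#' interoperability with other EEG software.
#'
#' @name io
NULL

.RAW_MAGIC <- charToRaw("ERPCNVR1")

#' Write / read the package raw container
#'
#' Layout: an 8-byte magic string, a little-endian uint32 header length, a
#' JSON header (`names`, `sfreq`, `start`, `dtype`, `layout`, `n_samples`),
#' then the voltages as little-endian 32-bit floats, channel-major (all
#' samples of channel 1, then channel 2, ...). Montage positions ride along
#' in the header so that a round trip preserves them.
#'
#' @param recording a `continuous_recording`.
#' @param path output file path.
#' @return `read_raw` returns a `continuous_recording`; voltages match the
#'   written ones to float32 precision, sfreq and channel order exactly.
#' @export
write_raw <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  hdr <- list(
    names = recording$montage$name,
    sfreq = recording$sfreq,
    start = recording$start,
    dtype = "float32",
    layout = "channel-major",
    n_samples = ncol(recording$data),
    montage = as.data.frame(recording$montage)
  )
  hjson <- charToRaw(jsonlite::toJSON(hdr, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.RAW_MAGIC, con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  writeBin(as.numeric(t(recording$data)), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 8L)
  if (!identical(magic, .RAW_MAGIC))
    stop("not a recognised raw container (bad magic): ", path)
  hlen <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  hdr <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = hlen)))
  nch <- length(hdr$names)
  n <- hdr$n_samples
  vals <- readBin(con, "numeric", n = nch * n, size = 4L, endian = "little")
  if (length(vals) != nch * n)
    stop("corrupt raw container: expected ", nch * n, " samples, got ",
         length(vals), " (", path, ")")
  mon <- hdr$montage
  class(mon) <- c("eeg_montage", "data.frame")
  continuous_recording(matrix(vals, nrow = nch, byrow = TRUE),
                       sfreq = as.numeric(hdr$sfreq), montage = mon,
                       start = if (is.null(hdr$start)) 0
                               else as.numeric(hdr$start))
}

#' Write / read a BIDS-style events.tsv
#'
#' Columns `onset` (s), `duration` (s), `trial_type` and `response_time`
#' (ms); missing values are written as `n/a`.
#'
#' @param events an `eeg_events` table.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  df <- as.data.frame(events)
  df$response_time <- ifelse(is.na(df$response_time), "n/a",
                             format(df$response_time, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("n/a", "NA", ""))
  need <- c("onset", "duration", "trial_type", "response_time")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("events file is missing required column(s): ",
         paste(miss, collapse = ", "))
  event_table(df$onset, df$trial_type, df$duration,
              suppressWarnings(as.numeric(df$response_time)))
}

# ---- EDF ------------------------------------------------------------------

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording as EDF
#'
#' Minimal EDF: one-second data records, 16-bit samples, a shared physical
#' range per signal spanning the data. Requires an integer sampling rate;
#' the final partial record, if any, is zero padded.
#'
#' @param recording a `continuous_recording`.
#' @param path output path.
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "continuous_recording"))
  sf <- recording$sfreq
  if (abs(sf - round(sf)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  sf <- as.integer(round(sf))
  nch <- nrow(recording$data)
  n <- ncol(recording$data)
  nrec <- ceiling(n / sf)
  pmax_ <- max(1, ceiling(max(abs(recording$data))))
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste(.edf_pad(x, width), collapse = ""),
                                     con, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256L * (1L + nch), 8); wr("", 44); wr(nrec, 8); wr("1", 8); wr(nch, 4)
  wr(recording$montage$name, 16)
  wr(rep("", nch), 80)                      # transducer
  wr(rep("uV", nch), 8)
  wr(rep(-pmax_, nch), 8); wr(rep(pmax_, nch), 8)
  wr(rep(-32768L, nch), 8); wr(rep(32767L, nch), 8)
  wr(rep("", nch), 80)                      # prefiltering
  wr(rep(sf, nch), 8); wr(rep("", nch), 32)
  scale <- 32767 / pmax_
  padded <- cbind(recording$data,
                  matrix(0, nch, nrec * sf - n))
  for (r in seq_len(nrec)) {
    block <- padded[, (r - 1L) * sf + seq_len(sf), drop = FALSE]
    dig <- round(pmin(pmax(block, -pmax_), pmax_) * scale)
    # transpose first: each record stores signal 1's samples, then signal 2's
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Supports the plain (non +D/+C annotated) EDF layout with a common
#' samples-per-record across signals. Signal labels that parse as 10-20
#' names receive montage positions; otherwise positions are `NA`.
#'
#' @param path EDF file path.
#' @return a `continuous_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width, n = 1L)
    trimws(vapply(seq_len(n),
                  function(i) suppressWarnings(
                    readChar(con, width, useBytes = TRUE)),
                  character(1)))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hbytes <- suppressWarnings(as.integer(rd(8))); rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  recdur <- suppressWarnings(as.numeric(rd(8)))
  nch <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(hbytes, nrec, recdur, nch)) || nch <= 0L || nrec < 0L)
    stop("not a valid EDF file (unparseable header): ", path)
  labels <- rd(16, nch); rd(80, nch); rd(8, nch)
  pmin_ <- as.numeric(rd(8, nch)); pmax_ <- as.numeric(rd(8, nch))
  dmin_ <- as.numeric(rd(8, nch)); dmax_ <- as.numeric(rd(8, nch))
  rd(80, nch)
  spr <- as.integer(rd(8, nch)); rd(32, nch)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  sf <- spr[1] / recdur
  raw_n <- nrec * sum(spr)
  dig <- readBin(con, "integer", n = raw_n, size = 2L, signed = TRUE,
                 endian = "little")
  if (length(dig) != raw_n)
    stop("corrupt EDF: expected ", raw_n, " samples, got ", length(dig))
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  off <- pmin_ - gain * dmin_
  dat <- matrix(0, nch, nrec * spr[1])
  dim(dig) <- c(spr[1], nch, nrec)
  for (ch in seq_len(nch))
    dat[ch, ] <- as.vector(dig[, ch, ]) * gain[ch] + off[ch]
  mon <- tryCatch(make_montage(labels), error = function(e) {
    df <- data.frame(name = labels, x = NA_real_, y = NA_real_,
                     stringsAsFactors = FALSE)
    class(df) <- c("eeg_montage", "data.frame")
    df
  })
  continuous_recording(dat, sfreq = sf, montage = mon)
}
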