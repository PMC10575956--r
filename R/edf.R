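# Minimal European Data Format (EDF) I/O for uniform-rate, 16-bit recordings.
# Covers the subset the pipeline needs: one record duration, identical sample
# rate across channels, no annotation channel.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) stop("EDF header field too long: ", x)
  formatC(x, width = width, flag = "-")
}

edf_num_field <- function(raw, what) {
  txt <- trimws(rawToChar(raw))
  val <- suppressWarnings(as.numeric(txt))
  if (length(val) != 1 || is.na(val)) {
    stop(sprintf("EDF format error: header field '%s' is not numeric ('%s')",
                 what, txt))
  }
  val
}

#' Write a recording to an EDF file
#'
#' Signals are scaled to 16-bit integers over each channel's observed physical
#' range. The epoch start clock time, when present, is stored in the EDF
#' start-time header field (whole seconds).
#'
#' @param rec an \code{ieeg_recording}; the sample count must be a whole
#'   number of seconds.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n <- n_samples(rec)
  if (n %% fs != 0) stop("EDF writer requires a whole number of 1-s records")
  n_rec <- n %/% fs
  ns <- nrow(rec$data)

  start_time <- "00.00.00"
  if (!is.na(rec$epoch_start)) {
    secs <- round(rec$epoch_start * 3600) %% 86400
    start_time <- sprintf("%02d.%02d.%02d", secs %/% 3600,
                          (secs %% 3600) %/% 60, secs %% 60)
  }

  phys_min <- apply(rec$data, 1, min)
  phys_max <- apply(rec$data, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768
  dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$subject_id, 80),
    edf_pad("ieegatlas", 80),
    edf_pad("01.01.00", 8),
    edf_pad(start_time, 8),
    edf_pad(256 + ns * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(1, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, nchars = nchar(hdr), eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(rec$channel_ids, 16)
  field(rep("", ns), 80)
  field(rep("uV", ns), 8)
  field(formatC(phys_min, digits = 6, format = "g"), 8)
  field(formatC(phys_max, digits = 6, format = "g"), 8)
  field(rep(dig_min, ns), 8)
  field(rep(dig_max, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- vapply(seq_len(ns), function(ch) {
      as.integer(round((rec$data[ch, idx] - phys_min[ch]) / scale[ch]) + dig_min)
    }, integer(fs))
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param channels optional character vector selecting and ordering channels.
#' @return an \code{ieeg_recording}; channel order as stored unless
#'   \code{channels} reorders it.
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readBin(con, "raw", 256)
  if (length(fixed) < 256) stop("EDF format error: fixed header truncated")
  take <- function(raw, from, len) raw[from:(from + len - 1)]
  subject_id <- trimws(rawToChar(take(fixed, 9, 80)))
  start_time <- trimws(rawToChar(take(fixed, 177, 8)))
  n_rec <- edf_num_field(take(fixed, 237, 8), "number of data records")
  rec_dur <- edf_num_field(take(fixed, 245, 8), "record duration")
  ns <- edf_num_field(take(fixed, 253, 4), "number of signals")
  if (ns < 1) stop("EDF format error: number of signals < 1")
  ns <- as.integer(ns)

  sig_hdr <- readBin(con, "raw", ns * 256)
  if (length(sig_hdr) < ns * 256) stop("EDF format error: signal header truncated")
  slice <- function(offset, width, i) {
    from <- offset * ns + (i - 1) * width + 1
    sig_hdr[from:(from + width - 1)]
  }
  labels <- vapply(seq_len(ns), function(i) trimws(rawToChar(slice(0, 16, i))), "")
  phys_min <- vapply(seq_len(ns), function(i)
    edf_num_field(slice(16 + 80 + 8, 8, i), "physical minimum"), 0)
  phys_max <- vapply(seq_len(ns), function(i)
    edf_num_field(slice(16 + 80 + 8 + 8, 8, i), "physical maximum"), 0)
  dig_min <- vapply(seq_len(ns), function(i)
    edf_num_field(slice(16 + 80 + 8 + 16, 8, i), "digital minimum"), 0)
  dig_max <- vapply(seq_len(ns), function(i)
    edf_num_field(slice(16 + 80 + 8 + 24, 8, i), "digital maximum"), 0)
  spr <- vapply(seq_len(ns), function(i)
    edf_num_field(slice(16 + 80 + 8 + 32 + 80, 8, i), "samples per record"), 0)
  if (length(unique(spr)) != 1) {
    stop("EDF format error: samples per record differ across signals")
  }
  if (rec_dur <= 0) stop("EDF format error: record duration (fs) missing or zero")
  fs <- spr[1] / rec_dur

  n_vals <- as.integer(n_rec) * as.integer(spr[1]) * ns
  raw_vals <- readBin(con, "integer", n_vals, size = 2, endian = "little")
  if (length(raw_vals) < n_vals) {
    stop("EDF format error: data section truncated (expected ", n_vals,
         " samples, found ", length(raw_vals), ")")
  }
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  data <- matrix(0, nrow = ns, ncol = as.integer(n_rec) * spr[1])
  k <- spr[1]
  for (r in seq_len(as.integer(n_rec))) {
    base <- (r - 1) * k * ns
    for (ch in seq_len(ns)) {
      v <- raw_vals[(base + (ch - 1) * k + 1):(base + ch * k)]
      data[ch, ((r - 1) * k + 1):(r * k)] <- (v - dig_min[ch]) * scale[ch] + phys_min[ch]
    }
  }

  epoch_start <- NA_real_
  if (grepl("^\\d{2}\\.\\d{2}\\.\\d{2}$", start_time)) {
    p <- as.numeric(strsplit(start_time, ".", fixed = TRUE)[[1]])
    epoch_start <- p[1] + p[2] / 60 + p[3] / 3600
  }
  rec <- recording(data, fs = fs, channel_ids = labels,
                   subject_id = if (nzchar(subject_id)) subject_id else "unknown",
                   epoch_start = epoch_start)
  if (!is.null(channels)) {
    i <- match(channels, rec$channel_ids)
    if (anyNA(i)) stop("unknown channel(s): ",
                       paste(channels[is.na(i)], collapse = ", "))
    rec$data <- rec$data[i, , drop = FALSE]
    rec$channel_ids <- channels
  }
  rec
}

#' Read a recording from EDF or a BIDS-like directory
#'
#' \code{format = "bids_like"} expects a directory holding exactly one
#' \code{*_ieeg.edf} file; a sibling \code{*_channels.tsv} with a \code{name}
#' column, when present, selects and orders the channels.
#'
#' @param path file (edf) or directory (bids_like).
#' @param format \code{"edf"} or \code{"bids_like"}.
#' @param channels optional channel selection, overriding any channels.tsv.
#' @return an \code{ieeg_recording}.
#' @export
read_recording <- function(path, format = c("edf", "bids_like"),
                           channels = NULL) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path, channels = channels))
  if (!dir.exists(path)) stop("bids_like path must be a directory: ", path)
  edfs <- list.files(path, pattern = "_ieeg\\.edf$", full.names = TRUE)
  if (length(edfs) != 1) {
    stop("bids_like directory must contain exactly one *_ieeg.edf file, found ",
         length(edfs))
  }
  if (is.null(channels)) {
    chtsv <- list.files(path, pattern = "_channels\\.tsv$", full.names = TRUE)
    if (length(chtsv) == 1) {
      tab <- utils::read.delim(chtsv, sep = "\t", stringsAsFactors = FALSE)
      if (!"name" %in% names(tab)) stop("channels.tsv lacks a 'name' column")
      channels <- tab$name
    }
  }
  read_edf(edfs[1], channels = channels)
}
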