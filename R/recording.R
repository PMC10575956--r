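#' Multichannel iEEG recording
#'
#' Lightweight container for a block of equally sampled signals: a channels x
#' samples matrix in microvolts plus sampling rate and channel identifiers.
#' Study-equivalent analyses assume \code{fs = 1000} Hz; the container itself
#' only requires a positive rate.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in samples/second.
#' @param channel_ids character vector, one id per row of \code{data}.
#' @param subject_id subject identifier.
#' @param epoch_start optional epoch onset clock time as decimal hours in
#'   \code{[0, 24)}; used by the sleep-onset circular test.
#' @return An object of class \code{ieeg_recording}: a list with fields
#'   \code{subject_id}, \code{channel_ids}, \code{fs}, \code{data},
#'   \code{epoch_start}.
#' @examples
#' rec <- recording(matrix(rnorm(2000), nrow = 2), fs = 1000)
#' n_samples(rec)
#' @export
recording <- function(data, fs, channel_ids = NULL, subject_id = "S01",
                      epoch_start = NA_real_) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("fs must be a single positive number")
  }
  if (anyNA(data)) stop("recording data must not contain missing samples")
  if (is.null(channel_ids)) {
    channel_ids <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  if (length(channel_ids) != nrow(data)) {
    stop("channel_ids length must equal the number of channels")
  }
  if (!is.na(epoch_start) && (epoch_start < 0 || epoch_start >= 24)) {
    stop("epoch_start must be a decimal hour in [0, 24)")
  }
  structure(
    list(subject_id = subject_id, channel_ids = as.character(channel_ids),
         fs = fs, data = data, epoch_start = epoch_start),
    class = "ieeg_recording")
}

#' @rdname recording
#' @param rec an \code{ieeg_recording}.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname recording
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$fs

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("ieeg_recording: %d channel(s) x %d samples @ %g Hz (%.1f s), subject %s\n",
              nrow(x$data), ncol(x$data), x$fs, duration_s(x), x$subject_id))
  invisible(x)
}

# Pull one channel as a numeric vector (by id or index).
channel_vector <- function(rec, channel) {
  if (is.character(channel)) {
    i <- match(channel, rec$channel_ids)
    if (is.na(i)) stop("unknown channel: ", channel)
  } else {
    i <- as.integer(channel)
  }
  rec$data[i, ]
}
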