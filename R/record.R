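#' Construct a heart-sound record
#'
#' A `heart_sound_record` holds one mono phonocardiogram: the sampled
#' amplitude sequence, its sampling rate in Hz, an identifier, and an
#' optional class label (`"normal"` or `"abnormal"`).
#'
#' @param samples Numeric vector of amplitudes; must be non-empty and finite.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param record_id Character identifier for the record.
#' @param label Optional class label, `"normal"`, `"abnormal"` or `NULL`.
#' @return An object of class `heart_sound_record`.
#' @export
#' @examples
#' r <- heart_sound_record(sin(2 * pi * 50 * seq(0, 1, by = 5e-4)), 2000, "demo")
heart_sound_record <- function(samples, sampling_rate, record_id = "record",
                               label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("`samples` must be non-empty", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("`samples` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)", call. = FALSE)
  }
  label <- check_label(label)
  structure(
    list(
      record_id = as.character(record_id)[1L],
      samples = samples,
      sampling_rate = sampling_rate,
      label = label
    ),
    class = "heart_sound_record"
  )
}

check_label <- function(label) {
  if (is.null(label) || (length(label) == 1L && is.na(label))) return(NULL)
  label <- match.arg(as.character(label), c("normal", "abnormal"))
  label
}

#' @export
print.heart_sound_record <- function(x, ...) {
  cat(sprintf(
    "<heart_sound_record> %s: %d samples @ %g Hz (%.2f s)%s\n",
    x$record_id, length(x$samples), x$sampling_rate,
    length(x$samples) / x$sampling_rate,
    if (is.null(x$label)) "" else paste0(", label=", x$label)
  ))
  invisible(x)
}

#' Window a record to a fixed number of samples
#'
#' Takes the first `n` samples of the record; shorter records are zero-padded
#' on the right to length `n`. The label and sampling rate are preserved.
#' The default of 10000 samples at 2000 Hz corresponds to a 5 s analysis
#' window.
#'
#' @param record A [heart_sound_record()].
#' @param n Target length in samples (positive integer).
#' @return A `heart_sound_record` of exactly `n` samples.
#' @export
window_record <- function(record, n = 10000L) {
  stopifnot(inherits(record, "heart_sound_record"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0 ||
      n != round(n)) {
    stop("`n` must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  x <- record$samples
  out <- if (length(x) >= n) x[seq_len(n)] else c(x, numeric(n - length(x)))
  heart_sound_record(out, record$sampling_rate, record$record_id, record$label)
}
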