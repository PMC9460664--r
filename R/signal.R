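#' Construct a single-channel signal
#'
#' A lightweight container for a finite real-valued sample sequence together
#' with its sampling rate. All decomposition and metric functions in the
#' package operate on this type.
#'
#' @param samples Numeric vector of amplitudes (arbitrary units, e.g. uV).
#'   Must have length >= 2 and contain only finite values.
#' @param fs Sampling rate in Hz (single positive number).
#' @return An object of class `eeg_signal`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' s <- eeg_signal(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' print(s)
#' @export
eeg_signal <- function(samples, fs) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("signal must contain at least 2 samples", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("signal contains non-finite samples", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs)),
            class = "eeg_signal")
}

#' Coerce to an `eeg_signal`
#'
#' @param x A numeric vector or an `eeg_signal`.
#' @param fs Sampling rate in Hz; required when `x` is a bare vector.
#' @return An `eeg_signal`.
#' @export
as_eeg_signal <- function(x, fs = NULL) {
  if (inherits(x, "eeg_signal")) return(x)
  if (is.null(fs)) stop("fs is required to build a signal from a vector",
                        call. = FALSE)
  eeg_signal(x, fs)
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf("<eeg_signal> %d samples @ %g Hz (%.3f s), sd = %.4g\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              stats::sd(x$samples)))
  invisible(x)
}

#' @export
length.eeg_signal <- function(x) length(x$samples)

#' Read a single-column sample file
#'
#' Reads one sample per line (plain text or CSV, optional header) and pairs
#' it with a sampling rate supplied by the caller.
#'
#' @param path Path to a text/CSV file with one numeric sample per line.
#' @param fs Sampling rate in Hz.
#' @return An `eeg_signal`.
#' @export
read_signal_csv <- function(path, fs) {
  first <- readLines(path, n = 1L)
  header <- is.na(suppressWarnings(as.numeric(first)))
  x <- utils::read.csv(path, header = header)[[1L]]
  eeg_signal(x, fs)
}

#' Write a signal to a single-column CSV
#'
#' @param signal An `eeg_signal`.
#' @param path Output path.
#' @param header Column name written as a header row.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path, header = "sample") {
  signal <- as_eeg_signal(signal)
  df <- stats::setNames(data.frame(signal$samples), header)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
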