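#' Judgment accuracy of a center frequency across mode counts
#'
#' The ratio of the a-th (ascending) center frequency obtained with K modes
#' to the a-th center frequency obtained with K + 1 modes. A ratio far from
#' 1 means the extra mode reshuffled that band, i.e. the K-mode
#' decomposition was not stable at that order.
#'
#' @param freq_k Center frequency (order a) of the K-mode decomposition;
#'   strictly positive.
#' @param freq_k_plus_1 Center frequency (order a) of the (K+1)-mode
#'   decomposition; strictly positive.
#' @return The ratio `freq_k / freq_k_plus_1`.
#' @export
judgment_accuracy <- function(freq_k, freq_k_plus_1) {
  if (!is.finite(freq_k) || freq_k <= 0 ||
      !is.finite(freq_k_plus_1) || freq_k_plus_1 <= 0) {
    stop("center frequencies must be strictly positive", call. = FALSE)
  }
  freq_k / freq_k_plus_1
}

#' Is a judgment accuracy an invalid center frequency?
#'
#' Inclusive on both thresholds: an accuracy `>= theta2` or `<= theta1` is
#' invalid.
#'
#' @param accuracy Positive judgment accuracy (vectorized).
#' @param theta1 Lower threshold (default 1.0).
#' @param theta2 Upper threshold (default 1.2).
#' @return Logical vector.
#' @export
is_invalid_accuracy <- function(accuracy, theta1 = 1.0, theta2 = 1.2) {
  accuracy >= theta2 | accuracy <= theta1
}

#' Select K from a precomputed judgment-accuracy table
#'
#' Applies the invalid-center-frequency rule to a ragged accuracy table:
#' the selected K is the smallest whose row contains any invalid entry
#' (first-K-wins; the within-row position of the trigger is irrelevant).
#'
#' @param accuracy_table Named list: element `"K"` holds the K accuracies of
#'   row K. Row names (or a parallel `k_values` vector) give the K of each
#'   row.
#' @param k_values Integer K value of each row; defaults to
#'   `as.integer(names(accuracy_table))`.
#' @param theta1,theta2 Invalidity thresholds, see [is_invalid_accuracy()].
#' @return List with `selected_k` (integer, or `NA` if no row triggers),
#'   `fallback_k` (advisory `max(k_values)` reported only when nothing
#'   triggers), and `invalid_flags` (list of logical vectors parallel to
#'   the table).
#' @export
select_k_from_accuracy <- function(accuracy_table, k_values = NULL,
                                   theta1 = 1.0, theta2 = 1.2) {
  if (is.null(k_values)) k_values <- as.integer(names(accuracy_table))
  if (anyNA(k_values)) stop("row K values are required", call. = FALSE)
  flags <- lapply(accuracy_table, function(row) {
    f <- is_invalid_accuracy(row, theta1, theta2)
    f[!is.finite(row)] <- TRUE           # unratioable entries count as invalid
    f
  })
  hit <- vapply(flags, any, logical(1))
  selected <- if (any(hit)) k_values[which(hit)[1L]] else NA_integer_
  list(selected_k = selected,
       fallback_k = if (is.na(selected)) max(k_values) else NA_integer_,
       invalid_flags = stats::setNames(flags, k_values))
}

#' Automatic selection of the VMD mode count
#'
#' Decomposes the signal once for every K in `k_range` (plus `max + 1`, so
#' the last row has a comparison point), forms the judgment-accuracy table
#' `accuracy[K][a] = center_freq[K][a] / center_freq[K+1][a]` over matching
#' ascending-frequency orders `a`, flags invalid entries with
#' [is_invalid_accuracy()], and selects the smallest K whose row contains an
#' invalid entry. A non-positive center frequency in a ratio marks that
#' entry invalid directly (the ratio is undefined; an idle mode parked at
#' DC is itself evidence of over-decomposition).
#'
#' @param signal An `eeg_signal`.
#' @param base_cfg A [vmd_config()] providing `alpha`, `gamma`, `epsilon`,
#'   `init` scheme (`"zeros"` or `"random"`; a fixed list cannot apply
#'   across K), `max_iters` and `mirror`; its `K` is ignored.
#' @param k_range Inclusive integer interval of candidate K, default
#'   `c(2, 10)`.
#' @param theta1,theta2 Invalidity thresholds.
#' @return A `k_selection_trace`: list with `k_range`, `center_freq_table`
#'   (per-K ascending normalized center frequencies, including the
#'   `max + 1` helper row), `accuracy_table`, `invalid_flags`,
#'   `selected_k` (`NA` when no row triggers) and `fallback_k` (advisory
#'   `max(k_range)` in that case).
#' @export
select_k <- function(signal, base_cfg = vmd_config(alpha = 2000),
                     k_range = c(2L, 10L), theta1 = 1.0, theta2 = 1.2) {
  signal <- as_eeg_signal(signal)
  if (is.numeric(base_cfg$init)) {
    stop("select_k needs a K-independent init scheme (zeros or random)",
         call. = FALSE)
  }
  k_range <- as.integer(k_range)
  if (length(k_range) != 2L || k_range[1L] < 2L ||
      k_range[2L] < k_range[1L]) {
    stop("k_range must be an interval c(lo, hi) with lo >= 2", call. = FALSE)
  }
  ks <- seq.int(k_range[1L], k_range[2L] + 1L)
  cf <- lapply(ks, function(k) {
    cfg <- vmd_config(K = k, alpha = base_cfg$alpha, gamma = base_cfg$gamma,
                      epsilon = base_cfg$epsilon, init = base_cfg$init,
                      seed = base_cfg$seed, max_iters = base_cfg$max_iters,
                      mirror = base_cfg$mirror)
    vmd_decompose(signal, cfg)$center_freqs
  })
  names(cf) <- ks
  rows <- as.character(seq.int(k_range[1L], k_range[2L]))
  acc <- lapply(rows, function(kchr) {
    k <- as.integer(kchr)
    a <- seq_len(k)
    num <- cf[[kchr]][a]
    den <- cf[[as.character(k + 1L)]][a]
    ratio <- ifelse(num > 0 & den > 0, num / den, NA_real_)
    ratio
  })
  names(acc) <- rows
  sel <- select_k_from_accuracy(acc, theta1 = theta1, theta2 = theta2)
  structure(list(k_range = k_range, center_freq_table = cf,
                 accuracy_table = acc, invalid_flags = sel$invalid_flags,
                 selected_k = sel$selected_k, fallback_k = sel$fallback_k),
            class = "k_selection_trace")
}

#' @export
print.k_selection_trace <- function(x, ...) {
  cat(sprintf("<k_selection_trace> K in [%d, %d]\n",
              x$k_range[1L], x$k_range[2L]))
  for (k in names(x$accuracy_table)) {
    flags <- x$invalid_flags[[k]]
    cat(sprintf("  K=%s: %s\n", k,
                paste(sprintf("%.4f%s", x$accuracy_table[[k]],
                              ifelse(flags, "*", "")), collapse = "  ")))
  }
  if (is.na(x$selected_k)) {
    cat(sprintf("  no invalid entry; advisory fallback K = %d\n",
                x$fallback_k))
  } else {
    cat(sprintf("  selected K = %d (first row with an invalid entry)\n",
                x$selected_k))
  }
  invisible(x)
}

#' Worked example of the K-selection procedure
#'
#' Center-frequency and judgment-accuracy tables from a published worked
#' example of the invalid-center-frequency rule on a semi-simulated EEG
#' recording (250 Hz, EOG + EMG contamination), shipped as package data.
#' Feeding the accuracy table to [select_k_from_accuracy()] selects K = 3.
#'
#' @return List with `center_freqs` and `accuracy`, each a named list of
#'   per-K numeric rows (row K has K entries).
#' @export
kselect_example <- function() {
  read_ragged <- function(file) {
    path <- system.file("extdata", file, package = "eegscrub",
                        mustWork = TRUE)
    df <- utils::read.csv(path)
    out <- lapply(seq_len(nrow(df)), function(i) {
      v <- as.numeric(df[i, -1L])
      v[!is.na(v)]
    })
    names(out) <- df[[1L]]
    out
  }
  list(center_freqs = read_ragged("kselect_example_center_freqs.csv"),
       accuracy = read_ragged("kselect_example_accuracy.csv"))
}
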