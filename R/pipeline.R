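#' Apply a labeling policy to fuzzy-entropy scores
#'
#' Under the `"extremes"` policy (the default, intended for the canonical
#' three-component separation) the minimum-entropy component is labeled EOG
#' (slow, highly regular), the maximum-entropy component EMG (broadband,
#' irregular), and the rest EEG. Ties for an artifact role go to the
#' higher-index component so the lower index keeps its EEG label, with a
#' warning. A `"threshold"` policy labels scores below `low` as EOG and
#' above `high` as EMG, for separations with other component counts.
#'
#' @param fe_scores Numeric vector of non-negative fuzzy-entropy scores.
#' @param policy `"extremes"` or `"threshold"`.
#' @param low,high Bounds for the threshold policy.
#' @return An `artifact_labeling`: list with `fe_scores`, `labels`
#'   (character, in `EEG`/`EOG`/`EMG`), and `removal_mask` (logical,
#'   `TRUE` = component is zeroed). At least one component is always
#'   labeled EEG.
#' @export
apply_label_policy <- function(fe_scores, policy = c("extremes",
                                                     "threshold"),
                               low = NULL, high = NULL) {
  policy <- match.arg(policy)
  ncomp <- length(fe_scores)
  if (ncomp < 2L) stop("at least 2 components are required", call. = FALSE)
  labels <- rep("EEG", ncomp)
  if (policy == "extremes") {
    if (ncomp < 3L) {
      stop("the extremes policy needs >= 3 components; use the threshold policy",
           call. = FALSE)
    }
    if (anyDuplicated(fe_scores)) {
      warning("tied fuzzy-entropy scores; lower-index component keeps EEG")
    }
    # on ties pick the larger index so the lower index stays EEG
    i_eog <- max(which(fe_scores == min(fe_scores)))
    i_emg <- max(which(fe_scores == max(fe_scores) &
                         seq_len(ncomp) != i_eog))
    labels[i_eog] <- "EOG"
    labels[i_emg] <- "EMG"
  } else {
    if (is.null(low) || is.null(high) || low >= high) {
      stop("threshold policy requires bounds low < high", call. = FALSE)
    }
    labels[fe_scores < low] <- "EOG"
    labels[fe_scores > high] <- "EMG"
    if (!any(labels == "EEG")) {
      stop("threshold policy labeled every component an artifact",
           call. = FALSE)
    }
  }
  structure(list(fe_scores = fe_scores, labels = labels,
                 removal_mask = labels != "EEG"),
            class = "artifact_labeling")
}

#' @export
print.artifact_labeling <- function(x, ...) {
  df <- data.frame(component = seq_along(x$labels),
                   fe = signif(x$fe_scores, 4), label = x$labels,
                   removed = x$removal_mask)
  print(df, row.names = FALSE)
  invisible(x)
}

# Fraction of spectral power of x inside [lo, hi] Hz.
band_power_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  tot <- sum(p)
  if (tot == 0) return(0)
  tol <- fs * 1e-9        # guard band-edge bins against rounding
  sum(p[freq >= lo - tol & freq <= hi + tol]) / tot
}

#' Label separated components as EEG / EOG / EMG
#'
#' Computes the fuzzy entropy of each separated component and applies a
#' labeling policy ([apply_label_policy()]). By default a spectral sanity
#' check can veto an artifact label: an EOG candidate must carry most of
#' its power below 5 Hz and an EMG candidate most of its power above
#' 45 Hz; a vetoed component reverts to EEG with a warning.
#'
#' @param sources Components-by-samples matrix (e.g. `sobi_result$sources`).
#' @param fs Sampling rate in Hz (needed for the spectral check).
#' @param fe_cfg An [fe_config()].
#' @param policy,low,high Passed to [apply_label_policy()].
#' @param spectral_check Logical, default `TRUE`.
#' @return An `artifact_labeling`.
#' @export
label_components <- function(sources, fs, fe_cfg = fe_config(),
                             policy = "extremes", low = NULL, high = NULL,
                             spectral_check = TRUE) {
  sources <- as.matrix(sources)
  if (nrow(sources) < 2L) stop("at least 2 components are required",
                               call. = FALSE)
  scores <- apply(sources, 1L, fuzzy_entropy, cfg = fe_cfg)
  lab <- apply_label_policy(scores, policy = policy, low = low, high = high)
  if (spectral_check) {
    for (i in which(lab$labels == "EOG")) {
      if (band_power_fraction(sources[i, ], fs, 0, 5) <= 0.5) {
        warning(sprintf(
          "component %d: EOG label vetoed by spectral check (power not below 5 Hz)",
          i))
        lab$labels[i] <- "EEG"
      }
    }
    for (i in which(lab$labels == "EMG")) {
      if (band_power_fraction(sources[i, ], fs, 45, fs / 2) <= 0.5) {
        warning(sprintf(
          "component %d: EMG label vetoed by spectral check (power not above 45 Hz)",
          i))
        lab$labels[i] <- "EEG"
      }
    }
    lab$removal_mask <- lab$labels != "EEG"
  }
  lab
}

#' Zero artifact components and reconstruct the cleaned signal
#'
#' Masked sources are zeroed together with their share of the channel
#' means, the remainder is back-projected through the estimated mixing
#' matrix to cleaned mode channels, and the channels are summed into one
#' signal. With an empty mask this reproduces `reconstruct(modes)` exactly
#' (the back-projection inverts the separation).
#'
#' @param modes The `mode_set` that fed the separation.
#' @param sobi The `sobi_result` for those modes.
#' @param labeling An `artifact_labeling` whose mask selects components to
#'   drop. Masking every component is refused.
#' @return The cleaned `eeg_signal`.
#' @export
remove_and_reconstruct <- function(modes, sobi, labeling) {
  y <- sobi$sources
  mask <- labeling$removal_mask
  if (length(mask) != nrow(y)) stop("mask length must match components",
                                    call. = FALSE)
  if (all(mask)) stop("refusing to remove every component", call. = FALSE)
  # channel means expressed in source coordinates travel with each component
  mu_s <- as.vector(t(sobi$rotation) %*% sobi$whitening %*% sobi$means)
  y[mask, ] <- 0
  mu_s[mask] <- 0
  clean_channels <- sobi$mixing %*% (y + mu_s)
  eeg_signal(colSums(clean_channels), modes$fs)
}

#' Signal-quality metrics between a reference and an estimate
#'
#' SNR in dB, `10 * log10(sum(x^2) / sum((Y - x)^2))`; relative
#' root-mean-square error, `sqrt(sum((Y - x)^2) / sum(x^2))`; and the
#' Pearson correlation coefficient. Identical signals give `rrmse = 0`,
#' `cc = 1` and `snr_db = Inf` (sentinel).
#'
#' @param reference The ground-truth `eeg_signal` (or vector).
#' @param estimate The estimate, equal length.
#' @return A list with `snr_db`, `rrmse`, `cc`.
#' @export
compute_metrics <- function(reference, estimate) {
  x <- if (inherits(reference, "eeg_signal")) reference$samples else
    as.numeric(reference)
  y <- if (inherits(estimate, "eeg_signal")) estimate$samples else
    as.numeric(estimate)
  if (length(x) != length(y)) stop("signals must have equal length",
                                   call. = FALSE)
  ex <- sum(x^2)
  if (ex == 0) stop("reference has zero energy; metrics undefined",
                    call. = FALSE)
  err <- sum((y - x)^2)
  list(snr_db = if (err == 0) Inf else 10 * log10(ex / err),
       rrmse = sqrt(err / ex),
       cc = if (err == 0) 1 else stats::cor(x, y))
}

#' End-to-end single-channel artifact removal
#'
#' Runs the full chain: VMD decomposition into K narrow-band modes, SOBI
#' separation of the mode matrix, fuzzy-entropy labeling of the separated
#' components, zeroing of the artifact components, back-projection, and
#' mode summation into the cleaned signal. Deterministic given the seeds
#' in the configurations.
#'
#' @param signal The contaminated `eeg_signal`.
#' @param vmd_cfg A [vmd_config()]; defaults to [vmd_default_config()] at
#'   the signal's sampling rate.
#' @param sobi_cfg A [sobi_config()].
#' @param fe_cfg An [fe_config()].
#' @param policy,low,high,spectral_check Passed to [label_components()].
#' @param k `"fixed"` (default) uses `vmd_cfg$K`; `"auto"` first runs
#'   [select_k()] with `k_select_cfg` and substitutes the selected K
#'   (advisory fallback when nothing triggers).
#' @param k_select_cfg Base [vmd_config()] for `k = "auto"`.
#' @return A `pipeline_result`: list with `cleaned` (`eeg_signal`),
#'   `labeling`, `modes`, `sobi`, `k_trace` (when `k = "auto"`), and the
#'   resolved `vmd_cfg`.
#' @examples
#' \donttest{
#' rec <- simulate_recording(sim_config(seed = 7, snr_db = -1))
#' res <- run_pipeline(rec$mixture)
#' compute_metrics(rec$eeg, res$cleaned)$cc
#' }
#' @export
run_pipeline <- function(signal, vmd_cfg = NULL, sobi_cfg = sobi_config(),
                         fe_cfg = fe_config(), policy = "extremes",
                         low = NULL, high = NULL, spectral_check = TRUE,
                         k = c("fixed", "auto"),
                         k_select_cfg = vmd_config(alpha = 2000)) {
  signal <- as_eeg_signal(signal)
  k <- match.arg(k)
  if (is.null(vmd_cfg)) vmd_cfg <- vmd_default_config(signal$fs)
  k_trace <- NULL
  if (k == "auto") {
    k_trace <- select_k(signal, base_cfg = k_select_cfg)
    k_sel <- if (is.na(k_trace$selected_k)) k_trace$fallback_k else
      k_trace$selected_k
    init <- vmd_cfg$init
    if (is.numeric(init) && length(init) != k_sel) init <- "zeros"
    vmd_cfg <- vmd_config(K = k_sel, alpha = vmd_cfg$alpha,
                          gamma = vmd_cfg$gamma, epsilon = vmd_cfg$epsilon,
                          init = init, seed = vmd_cfg$seed,
                          max_iters = vmd_cfg$max_iters,
                          mirror = vmd_cfg$mirror)
  }
  modes <- vmd_decompose(signal, vmd_cfg)
  sep <- sobi_separate(modes, sobi_cfg)
  lab <- label_components(sep$sources, fs = signal$fs, fe_cfg = fe_cfg,
                          policy = policy, low = low, high = high,
                          spectral_check = spectral_check)
  cleaned <- remove_and_reconstruct(modes, sep, lab)
  structure(list(cleaned = cleaned, labeling = lab, modes = modes,
                 sobi = sep, k_trace = k_trace, vmd_cfg = vmd_cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  K = %d modes, center frequencies: %s\n",
              ncol(x$modes$modes),
              paste(signif(x$modes$center_freqs, 4), collapse = ", ")))
  print(x$labeling)
  invisible(x)
}
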