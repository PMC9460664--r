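#' Semi-simulation configuration
#'
#' Describes a contaminated single-channel recording built as
#' `X(t) = X_EEG(t) + theta * X_artifact(t)`, with band-limited noise
#' surrogates standing in for real recordings: a slow ocular (EOG) band at
#' 0-5 Hz, a cortical (EEG) band at 10-50 Hz, and a muscular (EMG) band
#' from 80 Hz up to Nyquist. `theta` is solved so the EEG-to-artifact power
#' ratio hits `snr_db`.
#'
#' @param fs Sampling rate in Hz (default 250).
#' @param duration_s Recording length in seconds (default 8;
#'   `fs * duration_s` must be >= 512).
#' @param seed Integer seed; the whole fixture is a pure function of this
#'   configuration.
#' @param snr_db Target signal-to-artifact ratio in dB (default -1).
#' @param bands Named list of frequency intervals in Hz for the `eog`,
#'   `eeg` and `emg` surrogates. The EMG upper edge is clamped to Nyquist.
#' @param include_eog,include_emg Logical switches for each artifact.
#' @return A `sim_config` list.
#' @export
sim_config <- function(fs = 250, duration_s = 8, seed = 1L, snr_db = -1,
                       bands = list(eog = c(0, 5), eeg = c(10, 50),
                                    emg = c(80, fs / 2)),
                       include_eog = TRUE, include_emg = TRUE) {
  if (fs <= 0) stop("fs must be positive", call. = FALSE)
  if (round(fs * duration_s) < 512) {
    stop("fs * duration_s must be at least 512 samples", call. = FALSE)
  }
  bands$emg[2L] <- min(bands$emg[2L], fs / 2)
  for (b in bands) {
    if (b[2L] > fs / 2 + 1e-9) {
      stop("band upper edges must not exceed fs/2", call. = FALSE)
    }
  }
  if (!include_eog && !include_emg) {
    stop("at least one artifact must be included", call. = FALSE)
  }
  structure(list(fs = fs, duration_s = duration_s, seed = as.integer(seed),
                 snr_db = snr_db, bands = bands, include_eog = include_eog,
                 include_emg = include_emg),
            class = "sim_config")
}

#' Band-limited stochastic surrogate component
#'
#' White Gaussian noise restricted to a frequency band by zeroing FFT bins
#' outside it, then standardized to zero mean and unit variance. Because
#' the band restriction is exact in the discrete spectrum, out-of-band
#' power is numerically zero. The `"eog"` kind additionally superimposes
#' slow blink-like bumps (Gaussian pulses, ~0.25 s wide, ~0.3 per second)
#' before band-limiting, giving the characteristic spiky ocular waveform.
#'
#' @param band Length-2 Hz interval within `[0, fs/2]`, strictly increasing.
#' @param fs Sampling rate in Hz.
#' @param duration_s Length in seconds.
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param kind `"noise"` (default) or `"eog"`.
#' @return An `eeg_signal`.
#' @export
make_component <- function(band, fs, duration_s, seed,
                           kind = c("noise", "eog")) {
  kind <- match.arg(kind)
  if (length(band) != 2L || band[2L] <= band[1L]) {
    stop("band must be an increasing interval", call. = FALSE)
  }
  if (band[1L] < 0 || band[2L] > fs / 2 + 1e-9) {
    stop("band must lie within [0, fs/2]", call. = FALSE)
  }
  n <- round(fs * duration_s)
  x <- withr_seed(seed, {
    base <- stats::rnorm(n)
    if (kind == "eog") {
      tt <- seq_len(n) / fs
      n_blinks <- max(1L, stats::rpois(1L, 0.3 * duration_s))
      centers <- stats::runif(n_blinks, 0.3, duration_s - 0.3)
      amps <- stats::runif(n_blinks, 3, 6)
      bumps <- rowSums(vapply(seq_len(n_blinks), function(b) {
        amps[b] * exp(-((tt - centers[b])^2) / (2 * 0.08^2))
      }, numeric(n)))
      base <- 0.3 * base + bumps
    }
    base
  })
  # exact band restriction in the discrete spectrum
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)          # two-sided bin frequency
  keep <- freq >= band[1L] & freq <= band[2L]
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y <- y - mean(y)
  if (stats::sd(y) == 0) stop("band contains no spectral bins", call. = FALSE)
  eeg_signal(y / stats::sd(y), fs)
}

#' Mix clean EEG with artifacts at a target SNR
#'
#' Solves the scale `theta` so that
#' `10 * log10(power(eeg) / power(theta * sum(artifacts))) = snr_db` and
#' returns the contaminated mixture `eeg + theta * sum(artifacts)`.
#'
#' @param eeg Clean `eeg_signal`.
#' @param artifacts List of `eeg_signal`s (or a single one), equal length.
#' @param snr_db Target SNR in dB.
#' @return List with `mixture` (`eeg_signal`) and `theta`.
#' @export
mix_at_snr <- function(eeg, artifacts, snr_db) {
  eeg <- as_eeg_signal(eeg)
  if (inherits(artifacts, "eeg_signal")) artifacts <- list(artifacts)
  art <- lapply(artifacts, as_eeg_signal)
  if (any(vapply(art, length, integer(1)) != length(eeg$samples))) {
    stop("eeg and artifacts must have equal length", call. = FALSE)
  }
  asum <- Reduce(`+`, lapply(art, `[[`, "samples"))
  p_art <- mean(asum^2)
  if (p_art == 0) stop("artifact power is zero", call. = FALSE)
  p_eeg <- mean(eeg$samples^2)
  theta <- sqrt(p_eeg / p_art) * 10^(-snr_db / 20)
  list(mixture = eeg_signal(eeg$samples + theta * asum, eeg$fs),
       theta = theta)
}

#' Generate a full semi-simulated recording
#'
#' Builds the pure EEG-band component and the requested artifact
#' surrogates from sub-seeds derived from `cfg$seed`, mixes them at
#' `cfg$snr_db`, and returns every piece so tests can compare the cleaned
#' output against the known truth.
#'
#' @param cfg A [sim_config()].
#' @return List with `mixture`, `eeg`, `artifacts` (named list of
#'   `eeg_signal`s), `theta`, and `cfg`.
#' @export
simulate_recording <- function(cfg = sim_config()) {
  if (!inherits(cfg, "sim_config")) stop("cfg must be a sim_config",
                                         call. = FALSE)
  eeg <- make_component(cfg$bands$eeg, cfg$fs, cfg$duration_s,
                        seed = cfg$seed * 13L + 1L)
  artifacts <- list()
  if (cfg$include_eog) {
    artifacts$eog <- make_component(cfg$bands$eog, cfg$fs, cfg$duration_s,
                                    seed = cfg$seed * 13L + 2L, kind = "eog")
  }
  if (cfg$include_emg) {
    artifacts$emg <- make_component(cfg$bands$emg, cfg$fs, cfg$duration_s,
                                    seed = cfg$seed * 13L + 3L)
  }
  mixed <- mix_at_snr(eeg, artifacts, cfg$snr_db)
  list(mixture = mixed$mixture, eeg = eeg, artifacts = artifacts,
       theta = mixed$theta, cfg = cfg)
}

#' Generate a sweep of semi-simulated recordings over SNR
#'
#' One call that produces the whole evaluation grid: a recording per SNR
#' value, all deriving from one seed (the default grid spans -1.5 to
#' 1.5 dB in 0.5 dB steps; a wider -12 to 8 dB grid suits convergence
#' studies).
#'
#' @param snrs_db Numeric vector of target SNRs in dB.
#' @param seed Base seed; recording i uses `seed + i`.
#' @param ... Further arguments to [sim_config()].
#' @return Named list of [simulate_recording()] outputs, one per SNR.
#' @export
snr_sweep <- function(snrs_db = seq(-1.5, 1.5, by = 0.5), seed = 1L, ...) {
  out <- lapply(seq_along(snrs_db), function(i) {
    simulate_recording(sim_config(seed = seed + i, snr_db = snrs_db[i], ...))
  })
  names(out) <- sprintf("%g", snrs_db)
  out
}
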