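#' VMD configuration
#'
#' Parameters of the variational mode decomposition. The defaults follow the
#' settings that work well for 250 Hz EEG: a moderate penalty factor, no
#' noise-tolerance residual (`gamma = 0`), and a tight relative-change
#' convergence threshold.
#'
#' @param K Number of modes to extract (integer >= 1).
#' @param alpha Quadratic penalty factor controlling mode bandwidth; larger
#'   values give narrower modes. Positive.
#' @param gamma Noise tolerance in `[0, 1]` weighting the Lagrange-multiplier
#'   update. `gamma = 0` drops the exact-reconstruction residual (robust for
#'   noisy signals); `gamma = 1` enforces high fidelity.
#' @param epsilon Convergence threshold on the summed relative squared change
#'   of the mode spectra between iterations. Positive.
#' @param init Center-frequency initialization: `"zeros"` (all start at 0),
#'   `"random"` (K draws uniform in (0, 0.5), needs `seed`), or a numeric
#'   vector of K normalized frequencies in `[0, 0.5)`.
#' @param seed Integer seed used only by `init = "random"`.
#' @param max_iters Iteration cap (positive integer).
#' @param mirror Logical; extend the signal by even mirror reflection of half
#'   its length at each end before the FFT and crop after reconstruction.
#'   Reduces boundary leakage; on by default.
#' @return A `vmd_config` list.
#' @seealso [vmd_default_config()] for the EEG preset, [vmd_decompose()].
#' @export
vmd_config <- function(K = 3L, alpha = 1500, gamma = 0, epsilon = 1e-5,
                       init = "zeros", seed = NULL, max_iters = 500L,
                       mirror = TRUE) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be an integer >= 1", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0) stop("alpha must be positive",
                                             call. = FALSE)
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    stop("gamma must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop("epsilon must be positive",
                                                 call. = FALSE)
  if (is.numeric(init)) {
    if (length(init) != K) {
      stop("fixed init must supply exactly K center frequencies",
           call. = FALSE)
    }
    if (any(init < 0 | init >= 0.5)) {
      stop("fixed init frequencies must lie in [0, 0.5) (cycles/sample)",
           call. = FALSE)
    }
  } else if (!(is.character(init) && length(init) == 1L &&
               init %in% c("zeros", "random"))) {
    stop('init must be "zeros", "random", or a numeric vector of length K',
         call. = FALSE)
  }
  max_iters <- as.integer(max_iters)
  if (is.na(max_iters) || max_iters < 1L) {
    stop("max_iters must be a positive integer", call. = FALSE)
  }
  structure(list(K = K, alpha = alpha, gamma = gamma, epsilon = epsilon,
                 init = init, seed = seed, max_iters = max_iters,
                 mirror = isTRUE(mirror)),
            class = "vmd_config")
}

#' Convert Hz initial center frequencies to normalized cycles/sample
#'
#' Frequencies at or above Nyquist are clamped just below 0.5 so that a
#' preset written in Hz (e.g. `c(5, 30, 150)`) remains usable at any
#' sampling rate; a 150 Hz seed at fs = 250 simply starts the search at the
#' top of the analyzable band.
#'
#' @param hz Numeric vector of frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @return Normalized frequencies in `[0, 0.5)`.
#' @export
vmd_init_hz <- function(hz, fs) {
  if (any(hz < 0)) stop("frequencies must be non-negative", call. = FALSE)
  pmin(hz / fs, 0.5 - 1e-4)
}

#' Default VMD configuration for EEG at a given sampling rate
#'
#' K = 3 modes (slow ocular, cortical, muscular bands), fixed initial center
#' frequencies at 5, 30 and 150 Hz (clamped to Nyquist), `alpha = 1500`,
#' `gamma = 0`, `epsilon = 1e-5`, at most 500 iterations.
#'
#' @param fs Sampling rate in Hz.
#' @return A `vmd_config`.
#' @export
vmd_default_config <- function(fs) {
  vmd_config(K = 3L, alpha = 1500, gamma = 0, epsilon = 1e-5,
             init = vmd_init_hz(c(5, 30, 150), fs), max_iters = 500L)
}

# Even mirror extension of half the signal length at each end.
mirror_extend <- function(x) {
  h <- floor(length(x) / 2)
  c(rev(x[seq_len(h)]), x, rev(x[seq.int(length(x) - h + 1L, length(x))]))
}

#' Variational mode decomposition of a single-channel signal
#'
#' Decomposes a signal into `K` narrow-band amplitude/frequency-modulated
#' modes by the frequency-domain alternating-direction scheme: each mode is
#' refreshed by a Wiener-filter update around its current center frequency,
#' each center frequency by the power-weighted mean frequency of its mode
#' spectrum, and (when `gamma > 0`) a Lagrange multiplier accumulates the
#' reconstruction residual. Iteration stops when the summed relative squared
#' change of the mode spectra drops below `epsilon`, or at `max_iters`.
#'
#' All spectral updates act on the non-negative half-spectrum; time-domain
#' modes are recovered by conjugate-symmetric inverse FFT. Center
#' frequencies are reported normalized (cycles/sample, in `[0, 0.5)`);
#' multiply by `fs` for Hz. Modes are returned in ascending center-frequency
#' order. A mode whose spectrum has zero energy keeps its previous center
#' frequency (0 at a zeros initialization).
#'
#' @param signal An `eeg_signal` (or numeric vector with `fs`).
#' @param cfg A [vmd_config()].
#' @param fs Sampling rate, used when `signal` is a bare vector.
#' @return A `mode_set`: list with `modes` (length-N x K matrix, one column
#'   per mode), `center_freqs` (normalized, ascending), `n_iters`,
#'   `converged`, and `fs`. Hitting `max_iters` without meeting the
#'   threshold sets `converged = FALSE` but is not an error.
#' @examples
#' t <- seq_len(1024)
#' s <- eeg_signal(cos(2 * pi * 0.1 * t), fs = 250)
#' m <- vmd_decompose(s, vmd_config(K = 1, alpha = 2000))
#' m$center_freqs  # close to 0.1
#' @export
vmd_decompose <- function(signal, cfg = vmd_config(), fs = NULL) {
  signal <- as_eeg_signal(signal, fs)
  if (!inherits(cfg, "vmd_config")) stop("cfg must be a vmd_config",
                                         call. = FALSE)
  x <- signal$samples
  n0 <- length(x)
  if (cfg$K > n0 / 2) {
    stop("K exceeds half the signal length", call. = FALSE)
  }
  if (cfg$mirror) {
    h <- floor(n0 / 2)
    x <- mirror_extend(x)
  } else {
    h <- 0L
  }
  n <- length(x)
  nh <- floor(n / 2) + 1L                 # half-spectrum bins
  omega <- (seq_len(nh) - 1) / n          # cycles/sample, [0, 0.5]
  fhat <- stats::fft(x)[seq_len(nh)]

  K <- cfg$K
  w <- if (is.numeric(cfg$init)) {
    sort(as.numeric(cfg$init))
  } else if (identical(cfg$init, "random")) {
    if (is.null(cfg$seed)) stop('init = "random" requires a seed',
                                call. = FALSE)
    sort(withr_seed(cfg$seed, stats::runif(K, 0, 0.5)))
  } else {
    rep(0, K)
  }

  u <- matrix(0 + 0i, nrow = K, ncol = nh)
  lam <- rep(0 + 0i, nh)
  sum_u <- rep(0 + 0i, nh)
  iter <- 0L
  converged <- FALSE
  tiny <- .Machine$double.eps

  while (iter < cfg$max_iters) {
    iter <- iter + 1L
    u_prev <- u
    for (k in seq_len(K)) {
      s_k <- sum_u - u[k, ]
      u_new <- (fhat - s_k + lam / 2) / (1 + 2 * cfg$alpha * (omega - w[k])^2)
      pw <- Mod(u_new)^2
      tot <- sum(pw)
      if (tot > 0) w[k] <- sum(omega * pw) / tot
      sum_u <- s_k + u_new
      u[k, ] <- u_new
    }
    lam <- lam + cfg$gamma * (fhat - sum_u)
    diffstat <- sum(vapply(seq_len(K), function(k) {
      sum(Mod(u[k, ] - u_prev[k, ])^2) / (sum(Mod(u_prev[k, ])^2) + tiny)
    }, numeric(1)))
    if (is.finite(diffstat) && diffstat < cfg$epsilon) {
      converged <- TRUE
      break
    }
  }

  ord <- order(w, seq_len(K))
  w <- w[ord]
  u <- u[ord, , drop = FALSE]

  modes <- matrix(0, nrow = n0, ncol = K)
  keep <- seq.int(h + 1L, h + n0)
  for (k in seq_len(K)) {
    full <- rep(0 + 0i, n)
    full[seq_len(nh)] <- u[k, ]
    if (nh > 1L) {
      idx <- seq.int(2L, nh)
      full[n - idx + 2L] <- Conj(u[k, idx])   # Hermitian completion
    }
    mt <- Re(stats::fft(full, inverse = TRUE)) / n
    modes[, k] <- mt[keep]
  }
  colnames(modes) <- paste0("imf", seq_len(K))

  mode_set(modes, center_freqs = w, fs = signal$fs,
           n_iters = iter, converged = converged)
}

# Evaluate expr under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Construct a mode set
#'
#' Container for the output of [vmd_decompose()]: K equal-length mode
#' channels and their normalized center frequencies.
#'
#' @param modes Numeric matrix with one column per mode, or a list of
#'   equal-length numeric vectors.
#' @param center_freqs Normalized center frequencies in `[0, 0.5)`, one per
#'   mode.
#' @param fs Sampling rate in Hz.
#' @param n_iters Iterations used by the decomposition.
#' @param converged Logical convergence flag.
#' @return A `mode_set`.
#' @export
mode_set <- function(modes, center_freqs, fs, n_iters = NA_integer_,
                     converged = NA) {
  if (is.list(modes) && !is.data.frame(modes)) {
    lens <- lengths(modes)
    if (length(unique(lens)) != 1L) {
      stop("modes must all have the same length", call. = FALSE)
    }
    modes <- do.call(cbind, modes)
  }
  modes <- as.matrix(modes)
  if (ncol(modes) < 1L) stop("mode set must be non-empty", call. = FALSE)
  if (length(center_freqs) != ncol(modes)) {
    stop("one center frequency per mode is required", call. = FALSE)
  }
  if (any(center_freqs < 0 | center_freqs >= 0.5)) {
    stop("center frequencies must lie in [0, 0.5)", call. = FALSE)
  }
  if (is.null(colnames(modes))) colnames(modes) <- paste0("imf",
                                                          seq_len(ncol(modes)))
  structure(list(modes = modes, center_freqs = as.numeric(center_freqs),
                 fs = fs, n_iters = n_iters, converged = converged),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("<mode_set> %d modes x %d samples @ %g Hz\n",
              ncol(x$modes), nrow(x$modes), x$fs))
  cat("  center frequencies (cycles/sample):",
      paste(signif(x$center_freqs, 4), collapse = ", "), "\n")
  cat(sprintf("  iterations: %s, converged: %s\n", x$n_iters, x$converged))
  invisible(x)
}

#' Sum a mode set back into a signal
#'
#' The decomposition is constrained so that the modes sum to the input (up
#' to the residual discarded when `gamma = 0`); this applies that sum.
#'
#' @param modes A `mode_set`.
#' @return An `eeg_signal` with the source sampling rate.
#' @export
reconstruct <- function(modes) {
  if (!inherits(modes, "mode_set")) stop("expected a mode_set", call. = FALSE)
  eeg_signal(rowSums(modes$modes), modes$fs)
}

#' Write a mode set as multi-column CSV plus a JSON sidecar
#'
#' @param modes A `mode_set`.
#' @param path CSV output path (columns `imf1..imfK`). A sidecar
#'   `<path>.json` records center frequencies, sampling rate, iteration
#'   count and convergence flag.
#' @return `path`, invisibly.
#' @export
write_modeset_csv <- function(modes, path) {
  utils::write.csv(as.data.frame(modes$modes), path, row.names = FALSE)
  meta <- list(center_freqs = modes$center_freqs, fs = modes$fs,
               n_iters = modes$n_iters, converged = modes$converged)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a mode set written by [write_modeset_csv()]
#'
#' @param path CSV path; `<path>.json` must exist alongside it.
#' @return A `mode_set`.
#' @export
read_modeset_csv <- function(path) {
  m <- as.matrix(utils::read.csv(path))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  mode_set(m, center_freqs = meta$center_freqs, fs = meta$fs,
           n_iters = meta$n_iters, converged = meta$converged)
}
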