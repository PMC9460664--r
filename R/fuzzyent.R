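#' Fuzzy entropy configuration
#'
#' @param m Embedding dimension (integer >= 1). Default 2, the customary
#'   choice for short physiological series.
#' @param n_grad Gradient of the exponential membership boundary (positive).
#'   Default 2.
#' @param r Similarity tolerance. With `r_mode = "sd"` (default) it is a
#'   multiple of the sequence standard deviation (default 0.2), which makes
#'   the entropy scale-invariant; with `r_mode = "absolute"` it is used
#'   directly.
#' @param r_mode `"sd"` or `"absolute"`.
#' @return An `fe_config` list.
#' @export
fe_config <- function(m = 2L, n_grad = 2, r = 0.2, r_mode = c("sd",
                                                              "absolute")) {
  m <- as.integer(m)
  r_mode <- match.arg(r_mode)
  if (is.na(m) || m < 1L) stop("m must be an integer >= 1", call. = FALSE)
  if (n_grad <= 0) stop("n_grad must be positive", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  structure(list(m = m, n_grad = n_grad, r = r, r_mode = r_mode),
            class = "fe_config")
}

#' Fuzzy entropy of a sequence
#'
#' Measures the irregularity of a time series as
#' `ln(Phi_m) - ln(Phi_{m+1})`, where `Phi_m` is the mean pairwise
#' similarity of baseline-removed m-length embedding vectors under the
#' exponential membership function `exp(-(d/r)^n)` with `d` the Chebyshev
#' distance. Each embedding vector has its own mean subtracted; self-pairs
#' are excluded from the average; both embedding dimensions use the same
#' `N - m` vectors so the two averages are comparable. More complex signals
#' score higher: broadband muscle noise scores above cortical rhythms, which
#' score above slow ocular drifts.
#'
#' @param x Numeric vector (or `eeg_signal`) of length >= `m + 2`.
#' @param cfg An [fe_config()].
#' @return A single non-negative number. A zero-variance sequence returns 0
#'   (all similarities are 1 at every dimension).
#' @examples
#' fuzzy_entropy(rnorm(500))          # high: white noise
#' fuzzy_entropy(sin(seq_len(500) / 5)) # low: regular oscillation
#' @export
fuzzy_entropy <- function(x, cfg = fe_config()) {
  if (inherits(x, "eeg_signal")) x <- x$samples
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("sequence contains non-finite values",
                               call. = FALSE)
  n <- length(x)
  if (n < cfg$m + 2L) stop("sequence too short for the embedding dimension",
                           call. = FALSE)
  if (stats::sd(x) == 0) return(0)
  r <- if (cfg$r_mode == "sd") cfg$r * stats::sd(x) else cfg$r

  phi <- function(mm) {
    nv <- n - cfg$m - 1L + 1L            # same vector count for m and m+1
    X <- vapply(seq_len(mm), function(j) x[seq_len(nv) + j - 1L],
                numeric(nv))
    X <- X - rowMeans(X)
    D <- matrix(0, nv, nv)
    for (j in seq_len(mm)) {
      D <- pmax(D, abs(outer(X[, j], X[, j], "-")))
    }
    S <- exp(-(D / r)^cfg$n_grad)
    (sum(S) - nv) / (nv * (nv - 1L))     # off-self average
  }

  log(phi(cfg$m)) - log(phi(cfg$m + 1L))
}
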