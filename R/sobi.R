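#' SOBI configuration
#'
#' @param lags Positive integer delays (in samples) whose covariance
#'   matrices are jointly diagonalized. `NULL` selects the default
#'   `1:min(100, floor(T/4))` at run time.
#' @param jd_tolerance Convergence threshold for the Givens-rotation sweeps:
#'   the sweep stops when the largest rotation sine falls below it.
#' @param max_sweeps Cap on diagonalization sweeps.
#' @param ridge Non-negative ridge added to the channel covariance before
#'   whitening; 0 (default) errors on a rank-deficient covariance instead of
#'   regularizing.
#' @return A `sobi_config` list.
#' @export
sobi_config <- function(lags = NULL, jd_tolerance = 1e-8, max_sweeps = 100L,
                        ridge = 0) {
  if (!is.null(lags)) {
    lags <- as.integer(lags)
    if (length(lags) == 0L || any(lags < 1L)) {
      stop("lags must be positive integers", call. = FALSE)
    }
  }
  if (jd_tolerance <= 0) stop("jd_tolerance must be positive", call. = FALSE)
  if (ridge < 0) stop("ridge must be non-negative", call. = FALSE)
  structure(list(lags = lags, jd_tolerance = jd_tolerance,
                 max_sweeps = as.integer(max_sweeps), ridge = ridge),
            class = "sobi_config")
}

as_channel_matrix <- function(x) {
  if (inherits(x, "mode_set")) x <- t(x$modes)
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 channels are required", call. = FALSE)
  if (ncol(x) <= nrow(x)) stop("more samples than channels are required",
                               call. = FALSE)
  if (!all(is.finite(x))) stop("channels contain non-finite values",
                               call. = FALSE)
  x
}

#' Whiten a multichannel matrix
#'
#' Removes channel means and applies `Q = D^{-1/2} E^T` from the
#' eigendecomposition of the sample channel covariance, so the output has
#' zero mean and identity covariance.
#'
#' @param x Channels-by-samples numeric matrix (rows = channels), or a
#'   `mode_set` whose modes become the channels.
#' @param ridge Non-negative ridge added to the covariance diagonal; with
#'   the default 0 a rank-deficient covariance is an error.
#' @return List with `Q` (whitening matrix), `z` (whitened channels),
#'   `means` (removed channel means).
#' @export
whiten <- function(x, ridge = 0) {
  x <- as_channel_matrix(x)
  m <- nrow(x)
  mu <- rowMeans(x)
  xc <- x - mu
  # divisor T keeps the lag-0 covariance of the output exactly identity
  C <- tcrossprod(xc) / ncol(xc)
  if (ridge > 0) C <- C + diag(ridge, m)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < max(e$values) * 1e-10 || max(e$values) <= 0) {
    stop("channel covariance is rank-deficient; enable ridge regularization",
         call. = FALSE)
  }
  Q <- diag(1 / sqrt(e$values), m) %*% t(e$vectors)
  list(Q = Q, z = Q %*% xc, means = mu)
}

#' Time-lagged covariance matrices
#'
#' `R(tau) = (1/(T - tau)) * Z[, (1+tau):T] %*% t(Z[, 1:(T-tau)])`,
#' symmetrized as `(R + t(R))/2` because sample lagged covariances are not
#' exactly symmetric.
#'
#' @param z Channels-by-samples matrix (typically whitened).
#' @param lags Non-negative integer delays in samples, all `< ncol(z)`.
#' @return List of symmetric matrices, one per lag.
#' @export
lagged_covariances <- function(z, lags) {
  z <- as.matrix(z)
  T_ <- ncol(z)
  lags <- as.integer(lags)
  if (any(lags >= T_)) stop("every lag must be smaller than the sample count",
                            call. = FALSE)
  if (any(lags < 0L)) stop("lags must be non-negative", call. = FALSE)
  lapply(lags, function(tau) {
    a <- z[, seq.int(1L + tau, T_), drop = FALSE]
    b <- z[, seq.int(1L, T_ - tau), drop = FALSE]
    R <- tcrossprod(a, b) / (T_ - tau)
    (R + t(R)) / 2
  })
}

#' Joint approximate diagonalization by Givens rotations
#'
#' Finds one orthogonal matrix `V` that makes every matrix in the set as
#' diagonal as possible, by cyclic sweeps of two-dimensional rotations, each
#' chosen to maximize the diagonal mass of the target pair across all
#' matrices. The summed squared off-diagonal mass is non-increasing over
#' sweeps.
#'
#' @param mats List of square symmetric matrices of equal size.
#' @param tol Sweep convergence threshold on the largest rotation sine.
#' @param max_sweeps Sweep cap.
#' @return Orthogonal matrix `V` with attributes `sweeps` (number used) and
#'   `off_trace` (off-diagonal mass after each sweep).
#' @export
joint_diagonalize <- function(mats, tol = 1e-8, max_sweeps = 100L) {
  if (!is.list(mats)) mats <- list(mats)
  if (length(mats) == 0L) stop("at least one matrix is required",
                               call. = FALSE)
  m <- nrow(mats[[1L]])
  ok <- vapply(mats, function(A) is.matrix(A) && nrow(A) == m &&
                 ncol(A) == m, logical(1))
  if (!all(ok)) stop("matrices must be square and of equal size",
                     call. = FALSE)
  A <- array(unlist(mats), dim = c(m, m, length(mats)))
  V <- diag(m)
  off_mass <- function() sum(vapply(seq_len(dim(A)[3]), function(j) {
    M <- A[, , j]
    sum(M^2) - sum(diag(M)^2)
  }, numeric(1)))
  off_trace <- numeric(0)
  sweeps <- 0L
  if (m > 1L) {
    repeat {
      sweeps <- sweeps + 1L
      max_s <- 0
      for (p in seq_len(m - 1L)) {
        for (q in seq.int(p + 1L, m)) {
          ton <- A[p, p, ] - A[q, q, ]
          toff <- A[p, q, ] + A[q, p, ]
          g11 <- sum(ton * ton); g22 <- sum(toff * toff)
          g12 <- sum(ton * toff)
          theta <- 0.5 * atan2(2 * g12, g11 - g22 +
                                 sqrt((g11 - g22)^2 + 4 * g12^2))
          cs <- cos(theta); sn <- sin(theta)
          if (abs(sn) > max_s) max_s <- abs(sn)
          if (abs(sn) > .Machine$double.eps) {
            Ap <- cs * A[p, , ] + sn * A[q, , ]
            Aq <- -sn * A[p, , ] + cs * A[q, , ]
            A[p, , ] <- Ap; A[q, , ] <- Aq
            Ap <- cs * A[, p, ] + sn * A[, q, ]
            Aq <- -sn * A[, p, ] + cs * A[, q, ]
            A[, p, ] <- Ap; A[, q, ] <- Aq
            vp <- cs * V[, p] + sn * V[, q]
            vq <- -sn * V[, p] + cs * V[, q]
            V[, p] <- vp; V[, q] <- vq
          }
        }
      }
      off_trace <- c(off_trace, off_mass())
      if (max_s < tol || sweeps >= max_sweeps) break
    }
  }
  attr(V, "sweeps") <- sweeps
  attr(V, "off_trace") <- off_trace
  V
}

#' Second-order blind identification
#'
#' Separates a channels-by-samples matrix into statistically independent
#' components using only second-order statistics: the channels are whitened,
#' covariance matrices at a set of time lags are computed, one orthogonal
#' rotation `V` jointly diagonalizes them, and the sources are
#' `y = t(V) %*% Q %*% (x - means)` with mixing matrix `A = solve(Q) %*% V`.
#'
#' @param x Channels-by-samples matrix or a `mode_set`.
#' @param cfg A [sobi_config()].
#' @param fs Sampling rate carried through to the result (taken from a
#'   `mode_set` input when omitted).
#' @return A `sobi_result`: list with `whitening` (Q), `rotation` (V),
#'   `mixing` (A), `sources` (m x T matrix), `means`, `lags`, `fs`.
#' @examples
#' s <- rbind(stats::arima.sim(list(ar = 0.9), 1000),
#'            stats::arima.sim(list(ar = -0.5), 1000))
#' mixed <- matrix(c(1, 0.5, 0.3, 1), 2) %*% s
#' res <- sobi_separate(mixed, fs = 250)
#' @export
sobi_separate <- function(x, cfg = sobi_config(), fs = NULL) {
  if (inherits(x, "mode_set") && is.null(fs)) fs <- x$fs
  x <- as_channel_matrix(x)
  T_ <- ncol(x)
  lags <- cfg$lags
  if (is.null(lags)) lags <- seq_len(min(100L, floor(T_ / 4)))
  w <- whiten(x, ridge = cfg$ridge)
  Rs <- lagged_covariances(w$z, lags)
  V <- joint_diagonalize(Rs, tol = cfg$jd_tolerance,
                         max_sweeps = cfg$max_sweeps)
  A <- solve(w$Q) %*% V
  y <- t(V) %*% w$z
  structure(list(whitening = w$Q, rotation = V, mixing = A, sources = y,
                 means = w$means, lags = lags, fs = fs),
            class = "sobi_result")
}

#' @export
print.sobi_result <- function(x, ...) {
  cat(sprintf("<sobi_result> %d sources x %d samples, %d lags\n",
              nrow(x$sources), ncol(x$sources), length(x$lags)))
  invisible(x)
}

#' Write separated sources as multi-column CSV plus matrices as JSON
#'
#' @param res A `sobi_result`.
#' @param path CSV output path (columns `ic1..icm`); `<path>.json` stores
#'   the whitening and mixing matrices.
#' @return `path`, invisibly.
#' @export
write_sources_csv <- function(res, path) {
  df <- as.data.frame(t(res$sources))
  names(df) <- paste0("ic", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(whitening = res$whitening, mixing = res$mixing,
                            means = res$means, lags = res$lags),
                       paste0(path, ".json"), digits = NA, matrix = "rowmajor")
  invisible(path)
}
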