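test_that("whitening yields identity covariance", {
  set.seed(3)
  x <- matrix(rnorm(3 * 2000), 3) * c(1, 5, 0.2) + c(10, -2, 0)
  w <- whiten(x)
  cov_z <- tcrossprod(w$z) / ncol(x)
  expect_lt(max(abs(cov_z - diag(3))), 1e-8)
  expect_lt(max(abs(rowMeans(w$z))), 1e-12)
})

test_that("already-white input gives an orthogonal whitener", {
  set.seed(4)
  x <- matrix(rnorm(3 * 5000), 3)
  w <- whiten(x)
  z <- w$z
  w2 <- whiten(z)
  # idempotence up to an orthogonal factor
  expect_lt(max(abs(crossprod(w2$Q) - diag(3))), 1e-8)
})

test_that("rank-deficient covariance errors without ridge, passes with it", {
  set.seed(5)
  a <- rnorm(1000)
  x <- rbind(a, 2 * a, rnorm(1000))
  expect_error(whiten(x), "rank-deficient")
  expect_silent(whiten(x, ridge = 1e-6))
})

test_that("lagged covariances match closed forms", {
  set.seed(6)
  # white noise: entries vanish as 1/sqrt(T)
  T_ <- 4000
  z <- matrix(rnorm(3 * T_), 3)
  for (R in lagged_covariances(z, c(1, 5, 20))) {
    expect_lt(max(abs(R)), 5 / sqrt(T_))
    expect_equal(R, t(R))
  }
  # lag 0 on whitened input is the identity
  w <- whiten(matrix(rnorm(3 * T_), 3))
  expect_lt(max(abs(lagged_covariances(w$z, 0)[[1]] - diag(3))), 1e-8)
  # sinusoid pair: diagonal entries are cos(2 pi f tau) times channel power
  f <- 0.05
  t <- seq_len(T_)
  zs <- rbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  tau <- 7
  R <- lagged_covariances(zs, tau)[[1]]
  expect_equal(diag(R), rep(0.5 * cos(2 * pi * f * tau), 2),
               tolerance = 0.01, ignore_attr = TRUE)
  expect_error(lagged_covariances(z, T_), "smaller than the sample count")
})

test_that("joint diagonalization recovers a planted rotation", {
  # single diagonal matrix: V is the identity up to sign/permutation
  V <- joint_diagonalize(list(diag(c(3, 1, 2))))
  expect_true(is_signed_permutation(V))

  set.seed(7)
  th <- runif(3, 0, pi)
  R1 <- diag(3); R1[1:2, 1:2] <- matrix(c(cos(th[1]), sin(th[1]),
                                          -sin(th[1]), cos(th[1])), 2)
  R2 <- diag(3); R2[2:3, 2:3] <- matrix(c(cos(th[2]), sin(th[2]),
                                          -sin(th[2]), cos(th[2])), 2)
  P <- R1 %*% R2
  mats <- lapply(1:5, function(i) {
    d <- diag(runif(3, 0.5, 3) * i)
    P %*% d %*% t(P)
  })
  V <- joint_diagonalize(mats)
  expect_true(is_signed_permutation(t(V) %*% P))
  # orthogonality and monotone off-diagonal objective
  expect_lt(max(abs(crossprod(V) - diag(3))), 1e-10)
  trace <- attr(V, "off_trace")
  expect_true(all(diff(trace) <= 1e-10))

  # commuting matrices with shared eigenvectors diagonalize to machine zero
  D1 <- diag(c(1, 2, 3)); D2 <- diag(c(5, 1, 4))
  M1 <- P %*% D1 %*% t(P); M2 <- P %*% D2 %*% t(P)
  V2 <- joint_diagonalize(list(M1, M2))
  off <- function(M) sum(M^2) - sum(diag(M)^2)
  expect_lt(off(t(V2) %*% M1 %*% V2) + off(t(V2) %*% M2 %*% V2), 1e-10)

  expect_error(joint_diagonalize(list(matrix(1:6, 2))), "square")
})

test_that("SOBI recovers AR sources up to permutation and sign", {
  fix <- make_ar_mixture(T_ = 5000, seed = 1)
  res <- sobi_separate(fix$x, fs = 250)
  C <- abs(stats::cor(t(res$sources), t(fix$sources)))
  expect_true(all(apply(C, 1, max) > 0.95))
  expect_true(all(colSums(C > 0.95) == 1) && all(rowSums(C > 0.95) == 1))
  # algebraic identity: mixing %*% sources reproduces the centered input
  xc <- fix$x - rowMeans(fix$x)
  expect_lt(max(abs(res$mixing %*% res$sources - xc)) /
              max(abs(xc)), 1e-6)
  # rotation is orthogonal
  expect_lt(max(abs(crossprod(res$rotation) - diag(3))), 1e-8)
})

test_that("identity mixing of white, spectrally distinct sources is preserved", {
  fix <- make_ar_mixture(T_ = 5000, seed = 2)
  # feed the sources directly (identity mixing)
  res <- sobi_separate(fix$sources, fs = 250)
  C <- abs(stats::cor(t(res$sources), t(fix$sources)))
  expect_true(all(apply(C, 1, max) > 0.95))
})

test_that("sources CSV export writes ic headers and matrices JSON", {
  fix <- make_ar_mixture(T_ = 600, seed = 3)
  res <- sobi_separate(fix$x, fs = 100)
  path <- file.path(tempdir(), "sources.csv")
  write_sources_csv(res, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("ic1", "ic2", "ic3"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(dim(meta$mixing), c(3, 3))
})
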