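# Oracle for the channel covariance: explicit double loop over channel
# pairs, independent of the matrix-algebra implementation.
brute_covariance <- function(map) {
  C <- map$c
  hw <- map$h * map$w
  rows <- lapply(seq_len(C), function(i) as.vector(t(map$values[i, , ])))
  S <- matrix(0, C, C)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    xi <- rows[[i]] - mean(rows[[i]])
    xj <- rows[[j]] - mean(rows[[j]])
    S[i, j] <- sum(xi * xj) / (hw - 1)
  }
  S
}

test_that("channel flattening is row-major, mean-tracked and invertible", {
  vals <- array(0, c(2, 2, 2))
  vals[1, , ] <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  vals[2, , ] <- matrix(c(5, 6, 7, 8), 2, 2, byrow = TRUE)
  cm <- flatten_channels(feature_map(vals))
  expect_equal(cm$X[1, ], c(1, 2, 3, 4))
  expect_equal(cm$means, c(2.5, 6.5))
  # constant map flags zero-variance rows
  const <- flatten_channels(feature_map(array(3, c(2, 3, 3))))
  expect_true(all(const$zero_var))
  # round trip is the identity
  set.seed(21)
  for (i in 1:5) {
    m <- random_map(sample(2:6, 1), sample(2:5, 1), sample(2:5, 1))
    expect_equal(unflatten_channels(flatten_channels(m))$values, m$values)
  }
})

test_that("channel covariance matches the brute-force double loop", {
  set.seed(22)
  for (i in 1:10) {
    m <- random_map(sample(2:5, 1), sample(2:4, 1), sample(2:4, 1))
    S <- channel_covariance(flatten_channels(m))
    expect_equal(S, brute_covariance(m), tolerance = 1e-10)
    expect_equal(S, t(S))
    expect_true(min(eigen(S, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-8)
  }
  # identical channels: all four covariance entries equal
  v <- matrix(rnorm(9), 3, 3)
  dup <- array(0, c(2, 3, 3)); dup[1, , ] <- v; dup[2, , ] <- v
  S2 <- channel_covariance(flatten_channels(feature_map(dup)))
  expect_equal(max(abs(S2 - S2[1, 1])), 0, tolerance = 1e-10)
  # orthogonal (after centering) channels: zero off-diagonal
  o <- array(0, c(2, 1, 4))
  o[1, 1, ] <- c(1, 1, -1, -1); o[2, 1, ] <- c(1, -1, 1, -1)
  S3 <- channel_covariance(flatten_channels(feature_map(o)))
  expect_equal(S3[1, 2], 0, tolerance = 1e-12)
  expect_error(channel_covariance(flatten_channels(
    feature_map(array(1:3, c(3, 1, 1))))), "H\\*W = 1")
})

test_that("principal subspace resolves k and enforces conventions", {
  ps <- principal_subspace(diag(c(3, 1)), cpca_config(k_mode = "fixed",
                                                      k_value = 1))
  expect_equal(ps$values, c(3, 1))
  expect_equal(abs(ps$Vk[, 1]), c(1, 0))
  expect_identical(ps$k, 1L)
  # variance_fraction = 1 keeps every component
  set.seed(23)
  m <- random_map(4, 3, 3)
  S <- channel_covariance(flatten_channels(m))
  ps2 <- principal_subspace(S, cpca_config(k_value = 1.0))
  expect_identical(ps2$k, 4L)
  expect_equal(crossprod(ps2$vectors), diag(4), tolerance = 1e-6)
  # rank-1 structure: one component carries the full variance
  pat <- matrix(rnorm(12), 3, 4)
  r1 <- array(0, c(3, 3, 4))
  for (i in 1:3) r1[i, , ] <- i * pat
  S1 <- channel_covariance(flatten_channels(feature_map(r1)))
  ps1 <- principal_subspace(S1, cpca_config(k_value = 0.999999))
  expect_identical(ps1$k, 1L)
  expect_equal(ps1$values[1] / sum(ps1$values), 1, tolerance = 1e-6)
  expect_error(principal_subspace(matrix(c(1, 2, 0, 1), 2, 2)), "symmetric")
})

test_that("rank-k reconstruction is exact when nothing is discarded", {
  set.seed(24)
  m <- random_map(5, 4, 4)
  out <- cpca_apply(m, cpca_config(k_mode = "fixed", k_value = 5))
  expect_equal(out$values, m$values, tolerance = 1e-5)
  # rank-1 map reconstructed exactly with k = 1
  pat <- matrix(rnorm(16), 4, 4)
  r1 <- array(0, c(3, 4, 4))
  for (i in 1:3) r1[i, , ] <- (i - 2) * pat   # includes a negative scaling
  out1 <- cpca_apply(feature_map(r1), cpca_config(k_mode = "fixed",
                                                  k_value = 1))
  expect_equal(out1$values, r1, tolerance = 1e-5)
})

test_that("reconstruction error equals the discarded eigenvalue mass", {
  set.seed(25)
  for (rep in 1:5) {
    m <- random_map(6, 5, 5)
    S <- channel_covariance(flatten_channels(m))
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    errs <- numeric(6)
    for (k in 1:6) {
      out <- cpca_apply(m, cpca_config(k_mode = "fixed", k_value = k))
      errs[k] <- sum((out$values - m$values)^2) / (m$h * m$w - 1)
      expect_equal(errs[k], sum(ev[seq_len(6) > k]), tolerance = 1e-5)
    }
    # monotone: error non-increasing in k
    expect_true(all(diff(errs) <= 1e-10))
  }
})

test_that("rank-1 projection matches a full-matrix PCA oracle", {
  # independent oracle: svd of the centred channel matrix
  set.seed(26)
  m <- random_map(4, 3, 4)
  cm <- flatten_channels(m)
  Xc <- cm$X - rowMeans(cm$X)
  sv <- svd(Xc)
  k <- 1
  oracle <- sv$u[, 1, drop = FALSE] %*% (t(sv$u[, 1, drop = FALSE]) %*% Xc) +
    rowMeans(cm$X)
  out <- cpca_apply(m, cpca_config(k_mode = "fixed", k_value = 1))
  expect_equal(out$values, unflatten_channels(cm, oracle)$values,
               tolerance = 1e-6)
})

test_that("compression mode returns k score maps", {
  set.seed(27)
  m <- random_map(6, 4, 4)
  out <- cpca_apply(m, cpca_config(k_mode = "fixed", k_value = 2,
                                   output_mode = "compress_k"))
  expect_identical(dim(out$values), c(2L, 4L, 4L))
  expect_identical(attr(out, "k"), 2L)
})

test_that("degenerate all-constant maps pass through with a warning", {
  const <- feature_map(array(2, c(3, 4, 4)))
  expect_warning(out <- cpca_apply(const), "unchanged")
  expect_equal(out$values, const$values)
  expect_true(attr(out, "degenerate"))
})

test_that("reconstruction is idempotent at fixed k", {
  set.seed(28)
  m <- random_map(5, 4, 4)
  cfg <- cpca_config(k_mode = "fixed", k_value = 2)
  once <- cpca_apply(m, cfg)
  twice <- cpca_apply(once, cfg)
  expect_equal(twice$values, once$values, tolerance = 1e-5)
})

test_that("CPCA insertion adds zero parameters to a host model", {
  set.seed(29)
  with_cpca <- build_cgenet(4, variant_spec("A_cgenet", use_cpca = TRUE))
  set.seed(29)
  without <- build_cgenet(4, variant_spec("A_cgenet", use_cpca = FALSE))
  expect_identical(count_params(with_cpca)$params_exact,
                   count_params(without)$params_exact)
})
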