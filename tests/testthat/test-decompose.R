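make_stack_pair <- function(V = 5, n = 3, seed = 1) {
  set.seed(seed)
  g <- make_lattice_geometry(V, 1) # V x 1 lattice: V vertices
  list(stack_from_matrix(matrix(rnorm(n * V), n, V), g, "a"),
       stack_from_matrix(matrix(rnorm(n * V), n, V), g, "b"))
}

test_that("per-individual centering zeroes each block's column means", {
  st <- make_stack_pair()
  cm <- concatenate_and_center(st, "per_individual")
  expect_equal(dim(cm$X), c(6L, 5L))
  for (i in 1:2) {
    r <- cm$blocks$start[i]:cm$blocks$end[i]
    expect_lt(max(abs(colMeans(cm$X[r, ]))), 1e-10)
  }
})

test_that("global centering equals per-individual centering for one stack", {
  st <- make_stack_pair()[1]
  a <- concatenate_and_center(st, "global")
  b <- concatenate_and_center(st, "per_individual")
  expect_equal(a$X, b$X, tolerance = 1e-12)
})

test_that("concatenation validates geometry and ids", {
  st <- make_stack_pair()
  st[[2]]$geometry <- make_lattice_geometry(6, 1)
  expect_error(concatenate_and_center(st), "geometry")
  st2 <- make_stack_pair()
  st2[[2]]$individual_id <- "a"
  expect_error(concatenate_and_center(st2), "duplicate")
})

test_that("rank-one data yields a single component with unit cosine", {
  g <- make_lattice_geometry(10, 1)
  set.seed(2)
  a <- rnorm(6); a <- a - mean(a)
  s <- rnorm(10); s <- s / sqrt(sum(s^2))
  X <- outer(a, s)
  fit <- stp_decompose(concatenate_and_center(
    list(stack_from_matrix(X, g, "a")), "global"))
  expect_equal(fit$variance_fraction[1], 1, tolerance = 1e-10)
  expect_equal(abs(sum(fit$spatial[, 1] * s)), 1, tolerance = 1e-10)
})

test_that("two orthogonal components with 2:1 loading norms give f = 0.8/0.2", {
  g <- make_lattice_geometry(12, 1)
  set.seed(3)
  S <- qr.Q(qr(matrix(rnorm(24), 12, 2)))
  a1 <- standardize(rnorm(8)); a2 <- standardize(residuals(lm(rnorm(8) ~ a1)))
  X <- outer(2 * a1, S[, 1]) + outer(a2, S[, 2])
  cm <- concatenate_and_center(list(stack_from_matrix(X, g, "a")), "global")
  fit <- stp_decompose(cm)
  expect_equal(fit$variance_fraction[1:2], c(0.8, 0.2), tolerance = 1e-10)
  # brute-force Gram eigendecomposition oracle
  ev <- eigen(crossprod(cm$X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(fit$d^2, ev[seq_along(fit$d)], tolerance = 1e-8)
})

test_that("SVD identities hold on random matrices", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(4:20, 1); V <- sample((n + 1):50, 1)
    g <- make_lattice_geometry(V, 1)
    X <- matrix(rnorm(n * V), n, V)
    cm <- concatenate_and_center(list(stack_from_matrix(X, g, "a")), "global")
    fit <- stp_decompose(cm)
    K <- length(fit$d)
    # orthonormality
    expect_equal(crossprod(fit$spatial), diag(K), tolerance = 1e-8)
    expect_equal(crossprod(fit$temporal), diag(K), tolerance = 1e-8)
    # variance fractions sum to one
    expect_lt(abs(sum(fit$variance_fraction) - 1), 1e-10)
    # reconstruction
    R <- fit$temporal %*% diag(fit$d, K) %*% t(fit$spatial)
    expect_lt(norm(R - cm$X, "F") / norm(cm$X, "F"), 1e-8)
    # sigma^2 against the Gram eigensolver oracle
    ev <- eigen(crossprod(cm$X), symmetric = TRUE, only.values = TRUE)$values
    expect_equal(fit$d^2, ev[1:K], tolerance = 1e-8)
    # sign convention
    for (k in 1:K) expect_gt(fit$spatial[which.max(abs(fit$spatial[, k])), k], 0)
  }
})

test_that("permuting stack order permutes blocks but not spatial patterns", {
  st <- make_stack_pair(V = 8, n = 5, seed = 5)
  f1 <- stp_decompose(concatenate_and_center(st))
  f2 <- stp_decompose(concatenate_and_center(rev(st)))
  K <- min(4, length(f1$d))
  for (k in 1:K) {
    expect_lt(min(max(abs(f1$spatial[, k] - f2$spatial[, k])),
                  max(abs(f1$spatial[, k] + f2$spatial[, k]))), 1e-8)
  }
  expect_equal(f2$blocks$individual_id, c("b", "a"))
})

fake_fit <- function(vf) {
  K <- length(vf)
  structure(list(spatial = matrix(rnorm(10 * K), 10, K),
                 temporal = matrix(rnorm(6 * K), 6, K),
                 temporal_std = matrix(rnorm(6 * K), 6, K),
                 d = sqrt(vf), variance_fraction = vf,
                 blocks = data.frame(individual_id = "a", start = 1L, end = 6L),
                 sessions = data.frame(individual_id = rep("a", 6), day = 1:6),
                 geometry = NULL, retained = rep(TRUE, K)),
            class = "stp_decomposition")
}

test_that("retention keeps components down to 9.5% of variance", {
  expect_length(select_components(fake_fit(c(0.477, 0.204, 0.097, 0.04)))$d, 3)
  expect_length(select_components(fake_fit(c(0.95, 0.05)))$d, 1)
  expect_length(select_components(fake_fit(c(0.095, 0.905 * c(0.09, 0.01))))$d, 1)
  expect_warning(out <- select_components(fake_fit(c(0.09, rep(0.091, 10)))),
                 "retaining")
  expect_length(out$d, 1)
})

test_that("display thresholding zeroes small weights and clips large ones", {
  v <- c(0.005, -0.05, 0.15, -0.2, 0.01, 0.1)
  out <- threshold_spatial(v)
  expect_equal(out, c(0, -0.05, 0.1, -0.1, 0.01, 0.1))
  expect_error(threshold_spatial(v, low = 0.2, high = 0.1), "smaller")
})

test_that("temporal standardization is per block", {
  blocks <- data.frame(individual_id = c("a", "b"), start = c(1L, 4L),
                       end = c(3L, 8L))
  u <- c(1, 2, 3, rnorm(5))
  z <- standardize_temporal(u, blocks)
  expect_equal(z[1:3], c(-1, 0, 1))
  expect_lt(abs(mean(z[4:8])), 1e-12)
  expect_equal(sd(z[4:8]), 1)
  expect_error(standardize_temporal(c(1, 1, 1, rnorm(5)), blocks), "constant")
})
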