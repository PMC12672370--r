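test_that("TFCE of a zero map is zero and respects the t = 0 support", {
  g <- tiny_geometry()
  V <- length(g$mask_idx)
  expect_equal(tfce_enhance(numeric(V), g)$pos, numeric(V))
  set.seed(24)
  stat <- rnorm(V) * rbinom(V, 1, 0.5)
  enh <- tfce_enhance(stat, g)
  expect_true(all(enh$pos[stat == 0] == 0))
  expect_true(all(enh$neg[stat == 0] == 0))
  expect_true(all(enh$pos[stat < 0] == 0))
})

test_that("an isolated plateau matches the closed-form TFCE integral", {
  g <- make_phantom_mask(c(12, 12, 12), 2)
  V <- length(g$mask_idx)
  ar <- arrayInd(g$mask_idx, g$shape)
  plateau <- which(ar[, 1] %in% 6:7 & ar[, 2] %in% 6:7 & ar[, 3] %in% 6:7)
  h0 <- 3
  stat <- numeric(V)
  stat[plateau] <- h0
  e <- length(plateau)
  enh <- tfce_enhance(stat, g, n_steps = 100)
  closed <- sqrt(e) * h0^3 / 3
  expect_lt(max(abs(enh$pos[plateau] - closed)) / closed, 0.02)
  # 10,000-step Riemann refinement converges onto the closed form
  fine <- tfce_enhance(stat, g, n_steps = 10000)
  expect_lt(max(abs(fine$pos[plateau] - closed)) / closed, 1e-3)
})

test_that("TFCE values converge in the step count on smooth random maps", {
  g <- make_phantom_mask(c(10, 10, 10), 2)
  set.seed(25)
  stat <- smooth_volume(array(rnorm(prod(g$shape)), g$shape), g, 8)[g$mask_idx]
  stat <- stat / max(abs(stat)) * 4
  e100 <- tfce_enhance(stat, g, n_steps = 100)
  e200 <- tfce_enhance(stat, g, n_steps = 200)
  e10k <- tfce_enhance(stat, g, n_steps = 10000)
  expect_lt(max(abs(e200$pos - e100$pos)) / max(e10k$pos), 0.01)
  expect_lt(max(abs(e100$pos - e10k$pos)) / max(e10k$pos), 0.01)
})

test_that("single-threshold H=0, E=1 TFCE equals cluster size x dh", {
  # volumes, 26-connectivity
  set.seed(26)
  for (i in 1:3) {
    g <- tiny_geometry()
    V <- length(g$mask_idx)
    stat <- ifelse(runif(V) < 0.4, runif(V, 0.5, 1), 0)
    enh <- tfce_enhance(stat, g, E = 1, H = 0, n_steps = 1)
    dh <- max(stat)
    nb <- cyclebrain:::geometry_neighbors(g)
    lab <- oracle_flood_fill(stat >= dh, nb$ptr, nb$idx)
    sz <- tabulate(lab)
    want <- ifelse(stat >= dh, sz[pmax(lab, 1)] * dh, 0)
    expect_equal(enh$pos, want)
  }
  # vertex graphs
  set.seed(27)
  gs <- make_lattice_geometry(10, 10)
  stat <- ifelse(runif(100) < 0.5, runif(100, 0.5, 1), 0)
  enh <- tfce_enhance(stat, gs, E = 1, H = 0, n_steps = 1)
  nb <- cyclebrain:::geometry_neighbors(gs)
  dh <- max(stat)
  lab <- oracle_flood_fill(stat >= dh, nb$ptr, nb$idx)
  sz <- tabulate(lab)
  expect_equal(enh$pos, ifelse(stat >= dh, sz[pmax(lab, 1)] * dh, 0))
})

test_that("TFCE is monotone under amplification of the statistic map", {
  g <- tiny_geometry()
  set.seed(28)
  stat <- rnorm(length(g$mask_idx))
  a <- tfce_enhance(stat, g)
  b <- tfce_enhance(1.7 * stat, g)
  expect_true(all(b$pos >= a$pos - 1e-10))
  expect_true(all(b$neg >= a$neg - 1e-10))
})

test_that("mass-univariate t maps match a per-voxel lm oracle", {
  g <- tiny_geometry()
  V <- length(g$mask_idx)
  d <- default_study_design(seed = 41, geometry = g)
  glm <- fit_masswise_glm(d$stacks, d$hormones, "progesterone",
                          scope = "pooled")
  x <- unlist(lapply(d$stacks, function(s)
    sqrt(d$hormones[[s$individual_id]]$progesterone_nmol_l)))
  blk <- factor(rep(seq_along(d$stacks),
                    vapply(d$stacks, function(s) nrow(s$X), 1L)))
  Y <- do.call(rbind, lapply(d$stacks, function(s) s$X))
  set.seed(29)
  for (j in sample(V, 5)) {
    fit <- summary(lm(Y[, j] ~ blk + x))
    expect_equal(glm$t[j], fit$coefficients["x", "t value"], tolerance = 1e-8)
  }
})

test_that("a planted voxel carries the largest absolute t statistic", {
  g <- tiny_geometry()
  V <- length(g$mask_idx)
  h <- simulate_cycle(hormone_profile("typical", seed = 2), 1:25)
  set.seed(30)
  X <- matrix(rnorm(25 * V), 25, V)
  X[, 101] <- 2 * sqrt(h$progesterone_nmol_l) + rnorm(25, 0, 0.05)
  st <- stack_from_matrix(X, g, "typical", h$day)
  glm <- fit_masswise_glm(list(st), list(typical = h), "progesterone")
  expect_equal(which.max(abs(glm$t)), 101L)
  # orthogonalized response has t = 0
  xc <- sqrt(h$progesterone_nmol_l) - mean(sqrt(h$progesterone_nmol_l))
  X[, 50] <- rnorm(25)
  X[, 50] <- X[, 50] - xc * sum(X[, 50] * xc) / sum(xc^2)
  st2 <- stack_from_matrix(X, g, "typical", h$day)
  glm2 <- fit_masswise_glm(list(st2), list(typical = h), "progesterone")
  expect_lt(abs(glm2$t[50]), 1e-10)
})

test_that("the gray-matter absolute threshold keeps means >= 0.1", {
  g <- tiny_geometry()
  V <- length(g$mask_idx)
  X <- matrix(0.5, 4, V)
  X[, 1] <- 0.05
  X[, 2] <- 0.1
  st <- stack_from_matrix(X, g, "a")
  keep <- apply_absolute_threshold(list(st))
  expect_false(1L %in% keep)
  expect_true(2L %in% keep)
  st0 <- stack_from_matrix(matrix(0.01, 4, V), g, "a")
  expect_error(apply_absolute_threshold(list(st0)), "every location")
})

test_that("permutation FWE is deterministic and bounded below", {
  g <- make_phantom_mask(c(10, 10, 10), 2)
  h <- simulate_cycle(hormone_profile("typical", seed = 3),
                      cyclebrain:::weekday_days(25))
  st <- noise_stack(g, h$day, "typical", seed = 31)
  r1 <- permutation_fwe(list(st), list(typical = h), g, n_perm = 120, seed = 5)
  r2 <- permutation_fwe(list(st), list(typical = h), g, n_perm = 120, seed = 5)
  expect_identical(r1$fwe_p_pos, r2$fwe_p_pos)
  expect_identical(r1$null_max_neg, r2$null_max_neg)
  expect_true(all(r1$fwe_p_pos >= 1 / 121))
  expect_true(all(r1$fwe_p_pos <= 1))
  # fwe p monotone nonincreasing in the observed TFCE value
  o <- order(r1$tfce_pos)
  expect_true(all(diff(r1$fwe_p_pos[o]) <= 1e-12))
  expect_error(permutation_fwe(list(st), list(typical = h), g, n_perm = 50),
               "at least 100")
})
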