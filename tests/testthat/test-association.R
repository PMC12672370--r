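test_that("time-series regression matches hand-computed least squares", {
  ex <- time_series_regression(2 + 3 * (1:6), 1:6)
  expect_equal(ex$beta1, 3, tolerance = 1e-12)
  expect_equal(ex$beta0, 2, tolerance = 1e-12)
  expect_lt(max(abs(ex$residuals)), 1e-12)
  # Sxy = 3.0, Sxx = 5.0 -> slope 0.6 (padded to the minimum length of 5)
  h <- time_series_regression(c(2, 1, 4, 3, 2.5), c(1, 2, 3, 4, 2.5))
  lmfit <- lm(y ~ x, data.frame(x = c(1, 2, 3, 4, 2.5), y = c(2, 1, 4, 3, 2.5)))
  expect_equal(h$beta1, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(h$p, summary(lmfit)$coefficients[2, 4], tolerance = 1e-12)
  expect_error(time_series_regression(rnorm(6), rep(1, 6)), "constant")
  expect_error(time_series_regression(rnorm(6), rnorm(5)), "mismatch")
})

test_that("slope of y = 2 + 0.6 x construction is exact", {
  # four-point case with Sxy = 3, Sxx = 5
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  r <- time_series_regression(y, x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  expect_equal(r$beta1, sxy / sxx, tolerance = 1e-14)
})

test_that("Spearman is +/-1 on monotone pairs", {
  x <- sort(rnorm(8))
  expect_equal(spearman(x, exp(x))$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  expect_error(spearman(rep(1, 6), rnorm(6)), "constant")
  expect_error(spearman(1:3, 1:3), "at least 4")
})

test_that("exact Spearman p equals exhaustive enumeration for n <= 7", {
  set.seed(14)
  for (i in 1:20) {
    n <- sample(4:7, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 3 == 0) x[1:2] <- x[2:1] * 0 + x[1] # inject ties
    s <- spearman(x, y)
    o <- oracle_spearman_exact(x, y)
    expect_equal(s$rho, o$rho, tolerance = 1e-12)
    expect_equal(s$p, o$p, tolerance = 1e-12)
    expect_identical(s$method, "exact")
  }
})

test_that("large-n Spearman p uses the t approximation", {
  set.seed(15)
  x <- rnorm(20); y <- rnorm(20)
  s <- spearman(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(s$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(s$p, ct$p.value, tolerance = 1e-10)
  expect_identical(s$method, "t")
})

test_that("a perfectly coupled component is flagged with tiny FDR p", {
  d <- default_study_design(seed = 31,
                            geometry = make_phantom_mask(c(16, 16, 16), 2))
  fit <- select_components(stp_decompose(concatenate_and_center(d$stacks)))
  # replace component-1 scores by the exact coupling target
  for (i in seq_len(nrow(fit$blocks))) {
    r <- fit$blocks$start[i]:fit$blocks$end[i]
    h <- d$hormones[[fit$blocks$individual_id[i]]]
    fit$temporal_std[r, 1] <- standardize(sqrt(h$progesterone_nmol_l))
  }
  a <- associate_all(fit, d$hormones)
  sel <- a$component == 1 & a$predictor == "progesterone"
  expect_true(all(a$p_beta_fdr[sel] < 0.001))
  expect_true(all(a$beta1[sel] > 0))
  expect_true(all(a$rho[sel] > 0))
})

test_that("misaligned hormone days abort with the individual named", {
  d <- default_study_design(seed = 32,
                            geometry = make_phantom_mask(c(12, 12, 12), 2))
  fit <- select_components(stp_decompose(concatenate_and_center(d$stacks)))
  h <- d$hormones
  h$oc <- h$oc[-3, ]
  expect_error(associate_all(fit, h), "oc")
})

test_that("hormone rescaling leaves rho unchanged and rescales beta exactly", {
  set.seed(16)
  n <- 25
  h <- rlnorm(n, 2, 0.5)
  y <- standardize(sqrt(h)) * 0.8 + rnorm(n, 0, 0.3)
  c0 <- 4.7
  r1 <- time_series_regression(y, sqrt(h))
  r2 <- time_series_regression(y, sqrt(c0 * h))
  expect_equal(r2$beta1, r1$beta1 / sqrt(c0), tolerance = 1e-12)
  expect_equal(r2$p, r1$p, tolerance = 1e-12)
  expect_equal(spearman(sqrt(h), y)$rho, spearman(sqrt(c0 * h), y)$rho,
               tolerance = 1e-12)
})

test_that("regression and Spearman agree in sign on monotone couplings", {
  set.seed(17)
  for (i in 1:10) {
    n <- 24
    h <- rlnorm(n, 2, 0.6)
    sgn <- sample(c(-1, 1), 1)
    y <- sgn * standardize(sqrt(h)) + rnorm(n, 0, 0.25)
    r <- time_series_regression(y, sqrt(h))
    s <- spearman(sqrt(h), y)
    if (abs(s$rho) > 0.2) expect_equal(sign(s$rho), sign(r$beta1))
  }
})

test_that("FDR families are per individual and per statistic", {
  d <- default_study_design(seed = 33,
                            geometry = make_phantom_mask(c(12, 12, 12), 2))
  fit <- select_components(stp_decompose(concatenate_and_center(d$stacks)))
  a <- associate_all(fit, d$hormones)
  for (id in unique(a$individual_id)) {
    sel <- a$individual_id == id
    expect_equal(a$p_beta_fdr[sel], fdr_adjust(a$p_beta[sel]))
    expect_equal(a$p_rho_fdr[sel], fdr_adjust(a$p_rho[sel]))
  }
  expect_true(all(a$p_beta_fdr >= a$p_beta - 1e-15))
})
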