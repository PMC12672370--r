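test_that("typical templates show the expected cycle phenomenology", {
  for (tpl in c("typical", "typical_28andme")) {
    cfg <- hormone_profile(tpl, seed = 2)
    days <- seq_len(cfg$cycle_length_days)
    h <- simulate_cycle(cfg, days)
    expect_true(all(h$estradiol_pmol_l > 0))
    expect_true(all(h$progesterone_nmol_l > 0))
    # luteal progesterone rise
    expect_gt(mean(h$progesterone_nmol_l[h$phase == "luteal"]),
              mean(h$progesterone_nmol_l[h$phase == "follicular"]))
    # menses precede ovulation
    expect_lt(max(h$day[h$phase == "menses"]), h$day[h$phase == "ovulation"])
    # ovulatory by the progesterone criterion
    expect_true(classify_ovulatory(h))
  }
})

test_that("noiseless typical estradiol has a pre-ovulatory and a luteal peak", {
  cfg <- hormone_profile("typical", noise_cv = 0, seed = 1)
  h <- simulate_cycle(cfg, 1:28)
  e <- h$estradiol_pmol_l
  maxima <- which(diff(sign(diff(e))) == -2) + 1
  expect_length(maxima, 2)
  expect_lt(maxima[1], cfg$ovulation_day)   # pre-ovulatory peak
  expect_gt(maxima[2], cfg$ovulation_day)   # secondary luteal peak
  expect_gt(max(h$progesterone_nmol_l), 15.9)
})

test_that("oral contraceptive template has flat suppressed progesterone", {
  h <- simulate_cycle(hormone_profile("oc", seed = 1), 1:25)
  expect_true(all(h$progesterone_nmol_l < 4))
  expect_false(classify_ovulatory(h))
  expect_true("inactive_pill" %in% h$phase)
})

test_that("male template stays in the low calibration band for any seed", {
  for (s in c(1, 17, 123456)) {
    h <- simulate_cycle(hormone_profile("male", seed = s), 1:25)
    expect_true(all(h$estradiol_pmol_l >= 98.0))
    expect_true(all(h$estradiol_pmol_l <= 161.0))
    expect_true(all(h$progesterone_nmol_l <= 3.5))
    expect_false(classify_ovulatory(h))
  }
})

test_that("estradiol-dominant templates have lower luteal P/E ratio", {
  lut_ratio <- function(tpl, s) {
    cfg <- hormone_profile(tpl, seed = s)
    n <- if (tpl == "male") 25 else cfg$cycle_length_days
    h <- simulate_cycle(cfg, seq_len(n))
    mean(h$ratio[h$phase == "luteal"])
  }
  for (s in 1:5) {
    typ <- lut_ratio("typical", s)
    expect_lt(lut_ratio("endometriosis", s), typ)
    expect_lt(lut_ratio("oc", s), typ)
  }
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- hormone_profile("typical", seed = 11)
  h1 <- simulate_cycle(cfg, 1:28)
  h2 <- simulate_cycle(cfg, 1:28)
  expect_identical(h1, h2)
  h3 <- simulate_cycle(hormone_profile("typical", seed = 12), 1:28)
  expect_false(identical(h1$estradiol_pmol_l, h3$estradiol_pmol_l))
})

test_that("ovulation classification uses a strict 15.9 nmol/l threshold", {
  base <- simulate_cycle(hormone_profile("typical", seed = 1), 1:10)
  at <- base
  at$progesterone_nmol_l <- seq(1, 15.9, length.out = 10)
  expect_false(classify_ovulatory(at))
  above <- base
  above$progesterone_nmol_l <- seq(1, 16.0, length.out = 10)
  expect_true(classify_ovulatory(above))
  expect_error(classify_ovulatory(base[0, ]), "nonempty")
})

test_that("ratio follows the pmol-per-pmol convention with an nmol switch", {
  h <- simulate_cycle(hormone_profile("typical", seed = 3), 1:28)
  expect_equal(h$ratio,
               1000 * h$progesterone_nmol_l / h$estradiol_pmol_l)
  hn <- simulate_cycle(hormone_profile("typical", seed = 3,
                                       ratio_units = "nmol_per_pmol"), 1:28)
  expect_equal(hn$ratio, hn$progesterone_nmol_l / hn$estradiol_pmol_l)
})

test_that("simulate_cycle validates its inputs", {
  cfg <- hormone_profile("typical")
  expect_error(simulate_cycle(cfg, integer(0)), "empty")
  expect_error(simulate_cycle(cfg, c(3, 2, 5)), "increasing")
  expect_error(hormone_profile("typical", baseline_estradiol = -5), "positive")
  expect_error(hormone_profile("typical", cycle_length_days = 40), "20, 35")
})

test_that("sqrt transform and standardization behave analytically", {
  expect_equal(sqrt_transform(c(4, 9, 16)), c(2, 3, 4))
  expect_equal(sqrt_transform(0), 0)
  expect_error(sqrt_transform(c(1, -1)), "index 2")
  expect_equal(standardize(c(2, 3, 4)), c(-1, 0, 1))
  expect_error(standardize(c(5, 5, 5)), "constant")
  set.seed(8)
  for (i in 1:5) {
    v <- rnorm(sample(3:30, 1))
    expect_lt(abs(mean(standardize(v))), 1e-12)
    expect_equal(sd(standardize(v)), 1)
  }
})

test_that("hormone tables round-trip through TSV and recompute a missing ratio", {
  h <- simulate_cycle(hormone_profile("endometriosis", seed = 5), 1:24)
  f <- tempfile(fileext = ".tsv")
  write_hormone_table(h, f)
  h2 <- read_hormone_table(f)
  expect_equal(h2$estradiol_pmol_l, h$estradiol_pmol_l, tolerance = 1e-12)
  expect_equal(h2$ratio, h$ratio, tolerance = 1e-12)
  # drop the ratio column: recomputed on load
  write.table(h[, setdiff(names(h), "ratio")], f, sep = "\t",
              quote = FALSE, row.names = FALSE)
  h3 <- read_hormone_table(f)
  expect_equal(h3$ratio, 1000 * h$progesterone_nmol_l / h$estradiol_pmol_l,
               tolerance = 1e-12)
  unlink(f)
})
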