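# Synthetic endocrine profiles.
#
# Daily estradiol/progesterone trajectories are built from Gaussian bumps over
# a baseline (a pre-ovulatory estradiol peak, and luteal estradiol and
# progesterone bumps), multiplied by mean-one lognormal noise with a given
# coefficient of variation. The templates reproduce the phenomenology of a
# typical ovulatory cycle, a short estradiol-dominant endometriosis cycle, an
# oral-contraceptive cycle with selectively suppressed progesterone, and a
# male profile with low, weakly fluctuating levels.

PROG_OVULATION_THRESHOLD <- 15.9 # nmol/l; max P above this marks an ovulatory cycle

#' Hormone profile configuration
#'
#' Builds the parameter set for one individual's synthetic hormone series.
#' Concentrations are serum estradiol in pmol/l and progesterone in nmol/l.
#' Peak parameters are the deterministic curve maxima (not increments over
#' baseline). The `oc` template forces the progesterone luteal peak down to
#' baseline (suppressed); the `male` template has no ovulation day and uses a
#' bounded noise model so its estradiol stays inside the low male range.
#'
#' @param template One of `"typical"`, `"typical_28andme"`, `"endometriosis"`,
#'   `"oc"`, `"male"`.
#' @param cycle_length_days Cycle length in days (20--35). Ignored for `male`.
#' @param ovulation_day Cycle day of ovulation; `NA` for `oc` and `male`.
#' @param estradiol_peak Pre-ovulatory estradiol maximum, pmol/l.
#' @param estradiol_luteal_peak Mid-luteal (secondary) estradiol maximum, pmol/l.
#' @param progesterone_luteal_peak Mid-luteal progesterone maximum, nmol/l.
#' @param baseline_estradiol,baseline_progesterone Baseline levels.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   day-to-day noise.
#' @param ratio_units `"pmol_per_pmol"` computes the progesterone-to-estradiol
#'   ratio with both hormones in pmol/l (1000 * P[nmol/l] / E[pmol/l]);
#'   `"nmol_per_pmol"` is the naive unconverted ratio.
#' @param seed Integer seed making the series reproducible.
#' @return A list of class `"hormone_profile"`.
#' @export
hormone_profile <- function(template = c("typical", "typical_28andme",
                                         "endometriosis", "oc", "male"),
                            cycle_length_days = NULL,
                            ovulation_day = NULL,
                            estradiol_peak = NULL,
                            estradiol_luteal_peak = NULL,
                            progesterone_luteal_peak = NULL,
                            baseline_estradiol = NULL,
                            baseline_progesterone = NULL,
                            noise_cv = NULL,
                            ratio_units = c("pmol_per_pmol", "nmol_per_pmol"),
                            seed = 1L) {
  template <- match.arg(template)
  ratio_units <- match.arg(ratio_units)
  def <- switch(template,
    typical = list(cycle_length_days = 28L, ovulation_day = 14L,
                   estradiol_peak = 750, estradiol_luteal_peak = 500,
                   progesterone_luteal_peak = 33,
                   baseline_estradiol = 150, baseline_progesterone = 1.5,
                   noise_cv = 0.10),
    typical_28andme = list(cycle_length_days = 30L, ovulation_day = 14L,
                   estradiol_peak = 700, estradiol_luteal_peak = 480,
                   progesterone_luteal_peak = 30,
                   baseline_estradiol = 140, baseline_progesterone = 1.2,
                   noise_cv = 0.10),
    endometriosis = list(cycle_length_days = 24L, ovulation_day = 16L,
                   estradiol_peak = 950, estradiol_luteal_peak = 700,
                   progesterone_luteal_peak = 20,
                   baseline_estradiol = 260, baseline_progesterone = 1.2,
                   noise_cv = 0.10),
    oc = list(cycle_length_days = 28L, ovulation_day = NA_integer_,
                   estradiol_peak = 600, estradiol_luteal_peak = 450,
                   progesterone_luteal_peak = 1.0,
                   baseline_estradiol = 150, baseline_progesterone = 1.0,
                   noise_cv = 0.10),
    male = list(cycle_length_days = NA_integer_, ovulation_day = NA_integer_,
                   estradiol_peak = NA_real_, estradiol_luteal_peak = NA_real_,
                   progesterone_luteal_peak = NA_real_,
                   baseline_estradiol = 128.7, baseline_progesterone = 0.89,
                   noise_cv = 0.045)
  )
  cfg <- list(template = template,
              cycle_length_days = cycle_length_days %||% def$cycle_length_days,
              ovulation_day = ovulation_day %||% def$ovulation_day,
              estradiol_peak = estradiol_peak %||% def$estradiol_peak,
              estradiol_luteal_peak =
                estradiol_luteal_peak %||% def$estradiol_luteal_peak,
              progesterone_luteal_peak =
                progesterone_luteal_peak %||% def$progesterone_luteal_peak,
              baseline_estradiol =
                baseline_estradiol %||% def$baseline_estradiol,
              baseline_progesterone =
                baseline_progesterone %||% def$baseline_progesterone,
              noise_cv = noise_cv %||% def$noise_cv,
              ratio_units = ratio_units,
              seed = seed)
  if (template == "oc") {
    # suppressed progesterone: the luteal "peak" never exceeds baseline
    cfg$progesterone_luteal_peak <-
      min(cfg$progesterone_luteal_peak, cfg$baseline_progesterone)
    cfg$ovulation_day <- NA_integer_
  }
  if (template == "male") cfg$ovulation_day <- NA_integer_
  if (template != "male") {
    if (cfg$cycle_length_days < 20 || cfg$cycle_length_days > 35) {
      stop("cycle_length_days must be in [20, 35]")
    }
  }
  conc <- c(cfg$baseline_estradiol, cfg$baseline_progesterone)
  if (template != "male") {
    conc <- c(conc, cfg$estradiol_peak, cfg$estradiol_luteal_peak,
              cfg$progesterone_luteal_peak)
  }
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("configured concentrations must be positive")
  }
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0")
  class(cfg) <- "hormone_profile"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic template curves on cycle positions (1-based, recycled mod cycle)
hormone_template_curves <- function(cfg, session_days) {
  if (cfg$template == "male") {
    e <- cfg$baseline_estradiol * (1 + 0.13 * sin(2 * pi * session_days / 10))
    p <- rep(cfg$baseline_progesterone, length(session_days))
    return(list(estradiol = e, progesterone = p,
                pos = rep(NA_integer_, length(session_days))))
  }
  len <- cfg$cycle_length_days
  pos <- ((session_days - 1L) %% len) + 1L
  ovu <- if (is.na(cfg$ovulation_day)) round(len / 2) else cfg$ovulation_day
  luteal_mid <- ovu + (len - ovu) / 2
  bump <- function(center, width) exp(-((pos - center)^2) / (2 * width^2))
  e <- cfg$baseline_estradiol +
    (cfg$estradiol_peak - cfg$baseline_estradiol) * bump(ovu - 2, 2.0) +
    (cfg$estradiol_luteal_peak - cfg$baseline_estradiol) * bump(luteal_mid, 3.2)
  p <- cfg$baseline_progesterone +
    (cfg$progesterone_luteal_peak - cfg$baseline_progesterone) *
      bump(luteal_mid, 3.2)
  list(estradiol = e, progesterone = p, pos = pos)
}

hormone_phases <- function(cfg, pos) {
  n <- length(pos)
  if (cfg$template == "male") return(rep(NA_character_, n))
  if (cfg$template == "oc") {
    # no ovulation under oral contraceptives; the menses slot at the start of
    # the nominal pill cycle is the inactive-pill (withdrawal) window, and the
    # post-midcycle days are labelled by nominal cycle position so that
    # phase-wise ratio comparisons against natural cycles remain defined
    ph <- rep("follicular", n)
    ph[pos <= 5L] <- "inactive_pill"
    ph[pos > round(cfg$cycle_length_days / 2)] <- "luteal"
    return(ph)
  }
  ovu <- cfg$ovulation_day
  ph <- rep("follicular", n)
  ph[pos <= 5L] <- "menses"
  ph[pos == ovu] <- "ovulation"
  ph[pos > ovu] <- "luteal"
  ph
}

hormone_ratio <- function(progesterone_nmol_l, estradiol_pmol_l,
                          ratio_units = "pmol_per_pmol") {
  if (ratio_units == "pmol_per_pmol") {
    1000 * progesterone_nmol_l / estradiol_pmol_l
  } else {
    progesterone_nmol_l / estradiol_pmol_l
  }
}

#' Simulate one individual's hormone series
#'
#' Evaluates the template curve at the requested test days and applies
#' multiplicative lognormal noise (mean one, coefficient of variation
#' `noise_cv`). The male template uses noise truncated at 2.2 standard normal
#' deviations so that its estradiol remains inside the low male calibration
#' range and its progesterone never approaches the ovulation threshold.
#'
#' @param config A [hormone_profile()].
#' @param session_days Strictly increasing integer vector of test days
#'   (1-based; gaps allowed).
#' @param individual_id Label stored with the series.
#' @return A `data.frame` of class `"hormone_series"` with columns
#'   `individual_id`, `day`, `estradiol_pmol_l`, `progesterone_nmol_l`,
#'   `ratio`, `phase`.
#' @export
simulate_cycle <- function(config, session_days,
                           individual_id = config$template) {
  if (!inherits(config, "hormone_profile")) {
    stop("'config' must be a hormone_profile")
  }
  if (length(session_days) == 0L) stop("'session_days' is empty")
  if (any(diff(session_days) <= 0)) {
    stop("'session_days' must be strictly increasing")
  }
  n <- length(session_days)
  cur <- hormone_template_curves(config, session_days)
  with_seed(config$seed, {
    if (config$template == "male") {
      sdlog_e <- sqrt(log(1 + config$noise_cv^2))
      sdlog_p <- sqrt(log(1 + 0.55^2))
      ze <- pmin(pmax(rnorm(n), -2.2), 2.2)
      zp <- pmin(pmax(rnorm(n), -2.2), 2.2)
      e <- cur$estradiol * exp(ze * sdlog_e - sdlog_e^2 / 2)
      p <- cur$progesterone * exp(zp * sdlog_p - sdlog_p^2 / 2)
    } else {
      sdlog <- sqrt(log(1 + config$noise_cv^2))
      e <- cur$estradiol * exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
      p <- cur$progesterone * exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)
    }
    out <- data.frame(
      individual_id = individual_id,
      day = as.integer(session_days),
      estradiol_pmol_l = e,
      progesterone_nmol_l = p,
      ratio = hormone_ratio(p, e, config$ratio_units),
      phase = hormone_phases(config, cur$pos),
      stringsAsFactors = FALSE
    )
    class(out) <- c("hormone_series", "data.frame")
    out
  })
}

#' Classify a cycle as ovulatory
#'
#' A series is called ovulatory when its maximum progesterone concentration
#' strictly exceeds 15.9 nmol/l.
#'
#' @param series A `"hormone_series"` data frame.
#' @return Logical scalar.
#' @export
classify_ovulatory <- function(series) {
  if (!is.data.frame(series) || nrow(series) == 0L) {
    stop("'series' must be a nonempty hormone series")
  }
  max(series$progesterone_nmol_l) > PROG_OVULATION_THRESHOLD
}

#' Write / read a hormone table
#'
#' Tab-separated, UTF-8, dot decimal, with header `individual_id`, `day`,
#' `estradiol_pmol_l`, `progesterone_nmol_l`, `ratio`, `phase`. A missing
#' ratio column is recomputed on load with the pmol-per-pmol convention.
#'
#' @param series A hormone series (or several rbound together).
#' @param path File path.
#' @return `read_hormone_table` returns a `"hormone_series"` data frame.
#' @export
write_hormone_table <- function(series, path) {
  write.table(series, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hormone_table
#' @export
read_hormone_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "day", "estradiol_pmol_l", "progesterone_nmol_l")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("hormone table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(tab$ratio) || anyNA(tab$ratio)) {
    tab$ratio <- hormone_ratio(tab$progesterone_nmol_l, tab$estradiol_pmol_l)
  }
  if (is.null(tab$phase)) tab$phase <- NA_character_
  class(tab) <- c("hormone_series", "data.frame")
  tab
}

#' @export
print.hormone_series <- function(x, ...) {
  ids <- unique(x$individual_id)
  cat(sprintf("Hormone series: %d sessions, %d individual(s) [%s]\n",
              nrow(x), length(ids), paste(ids, collapse = ", ")))
  cat(sprintf("  estradiol %0.1f-%0.1f pmol/l, progesterone %0.2f-%0.2f nmol/l\n",
              min(x$estradiol_pmol_l), max(x$estradiol_pmol_l),
              min(x$progesterone_nmol_l), max(x$progesterone_nmol_l)))
  NextMethod()
}
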