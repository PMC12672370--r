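# Brain-hormone association statistics.
#
# For each individual, each retained component's standardized temporal scores
# are related to square-root transformed hormone levels by (i) ordinary
# least-squares time-series regression with a two-sided t test on the slope,
# and (ii) Spearman rank correlation with an exact permutation p-value for
# n <= 7 and the t approximation otherwise. Benjamini-Hochberg FDR is applied
# within each individual's family of tests, separately for the regression and
# the Spearman p-values.

#' Time-series regression of scores on a hormone predictor
#'
#' Ordinary least squares of `scores` on `x` (contemporaneous values, no lag
#' or autocorrelation terms), with a two-sided t test on the slope using
#' n - 2 degrees of freedom.
#'
#' @param scores Response vector.
#' @param x Predictor vector (typically square-root hormone levels).
#' @return List: `beta0`, `beta1`, `t`, `p`, `n`, `residuals`.
#' @export
time_series_regression <- function(scores, x) {
  n <- length(scores)
  if (length(x) != n) stop("length mismatch between scores and predictor")
  if (n < 5L) stop("need at least 5 sessions")
  if (sd(x) == 0) stop("constant predictor")
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (scores - mean(scores)))
  beta1 <- sxy / sxx
  beta0 <- mean(scores) - beta1 * mean(x)
  res <- scores - beta0 - beta1 * x
  rss <- sum(res^2)
  se <- sqrt(rss / (n - 2) / sxx)
  tval <- if (se > 0) beta1 / se else sign(beta1) * Inf
  p <- 2 * pt(abs(tval), n - 2, lower.tail = FALSE)
  list(beta0 = beta0, beta1 = beta1, t = tval, p = p, n = n, residuals = res)
}

spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  if (den == 0) stop("constant input: Spearman correlation undefined")
  num / den
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                         drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- blk
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes rho as the Pearson correlation of mid-ranks (average ranks for
#' ties). The two-sided p-value is exact for n <= 7 -- the proportion of all
#' n! permutations of one variable whose |rho| is at least the observed |rho|
#' (within numerical tolerance) -- and uses the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` on n - 2 df otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List: `rho`, `p`, `n`, `method` (`"exact"` or `"t"`).
#' @export
spearman <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("length mismatch")
  if (n < 4L) stop("need at least 4 observations")
  rho <- spearman_rho(x, y)
  if (n <= 7L) {
    rx <- rank(x)
    perms <- all_perms(n)
    ry <- rank(y)
    ryc <- ry - mean(ry)
    den <- sqrt(sum((rx - mean(rx))^2) * sum(ryc^2))
    rhos <- as.vector((perms_to_ranks(perms, rx) %*% ryc) / den)
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, n = n, method = "exact")
  } else {
    tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(abs(tval), n - 2, lower.tail = FALSE))
    list(rho = rho, p = p, n = n, method = "t")
  }
}

# rows of rank vectors: permutations applied to the observed mid-ranks of x,
# centered; ties in x are preserved under permutation of positions
perms_to_ranks <- function(perms, rx) {
  m <- matrix(rx[perms], nrow(perms), ncol(perms))
  m - rowMeans(m)
}

#' Associate retained components with hormone predictors
#'
#' Runs [time_series_regression()] and [spearman()] for every combination of
#' individual, retained component and predictor (square-root estradiol,
#' square-root progesterone, square-root ratio). Hormone days must align
#' exactly with the component score days of each individual. FDR adjustment
#' is applied within each individual (3 predictors x retained components),
#' separately for the regression and the Spearman p-values.
#'
#' @param fit A component-selected `"stp_decomposition"`.
#' @param hormones Named list of hormone series (names = individual ids), or a
#'   single combined hormone table with an `individual_id` column.
#' @param predictors Subset of `c("estradiol", "progesterone", "ratio")`.
#' @param sqrt_predictors Apply the square-root transform (default TRUE).
#' @return Data frame of class `"assoc_result"`: individual_id, component,
#'   predictor, beta0, beta1, p_beta, p_beta_fdr, rho, p_rho, p_rho_fdr, n.
#' @export
associate_all <- function(fit, hormones,
                          predictors = c("estradiol", "progesterone", "ratio"),
                          sqrt_predictors = TRUE) {
  stopifnot(inherits(fit, "stp_decomposition"))
  predictors <- match.arg(predictors, several.ok = TRUE)
  if (is.data.frame(hormones)) {
    hormones <- split(hormones, hormones$individual_id)
  }
  K <- ncol(fit$temporal_std)
  rows <- list()
  for (i in seq_len(nrow(fit$blocks))) {
    id <- fit$blocks$individual_id[i]
    r <- fit$blocks$start[i]:fit$blocks$end[i]
    days <- fit$sessions$day[r]
    h <- hormones[[id]]
    if (is.null(h)) stop(sprintf("no hormone series for individual '%s'", id))
    if (!identical(as.integer(h$day), as.integer(days))) {
      stop(sprintf(
        "hormone days do not align with session days for '%s' (hormones: %s; sessions: %s)",
        id, paste(h$day, collapse = ","), paste(days, collapse = ",")))
    }
    for (pred in predictors) {
      hv <- switch(pred, estradiol = h$estradiol_pmol_l,
                   progesterone = h$progesterone_nmol_l, ratio = h$ratio)
      xv <- if (sqrt_predictors) sqrt_transform(hv) else hv
      for (k in seq_len(K)) {
        sc <- fit$temporal_std[r, k]
        reg <- time_series_regression(sc, xv)
        sp <- spearman(xv, sc)
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = id, component = k, predictor = pred,
          beta0 = reg$beta0, beta1 = reg$beta1, p_beta = reg$p,
          rho = sp$rho, p_rho = sp$p, n = reg$n, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_beta_fdr <- NA_real_
  out$p_rho_fdr <- NA_real_
  for (id in unique(out$individual_id)) {
    sel <- out$individual_id == id
    out$p_beta_fdr[sel] <- fdr_adjust(out$p_beta[sel])
    out$p_rho_fdr[sel] <- fdr_adjust(out$p_rho[sel])
  }
  out <- out[, c("individual_id", "component", "predictor", "beta0", "beta1",
                 "p_beta", "p_beta_fdr", "rho", "p_rho", "p_rho_fdr", "n")]
  class(out) <- c("assoc_result", "data.frame")
  out
}
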