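# Endocrine profile comparison across individuals.
#
# Sessions are treated as independent observations, exactly as in the
# originating analysis design: a one-way MANOVA on (estradiol, progesterone,
# ratio) with the individual as the factor, followed by post hoc one-way
# ANOVAs per variable and Bonferroni-corrected pairwise two-tailed t-tests
# with the pooled within-group variance as denominator (the SPSS post hoc
# convention).

#' One-way MANOVA with Pillai's trace and Roy's largest root
#'
#' Computes the between-group (H) and within-group (E) SSCP matrices, the
#' eigenvalues of `solve(E) %*% H`, and the two test statistics with their
#' standard F approximations: for Pillai's trace `V`, with
#' `s = min(p, g - 1)`, `m = (|p - g + 1| - 1)/2`, `n' = (N - g - p - 1)/2`,
#' `df1 = s(2m + s + 1)`, `df2 = s(2n' + s + 1)` and
#' `F = (df2/df1) V/(s - V)`; for Roy's largest root `theta` (an upper bound),
#' `df1 = max(p, g - 1)`, `df2 = N - df1 - 1` and `F = theta df2/df1`.
#' Partial eta squared is `V/s` for Pillai and `theta/(1 + theta)` for Roy.
#'
#' @param Y Numeric matrix (N x p) of response vectors.
#' @param groups Factor (length N) of group labels, g >= 2 levels.
#' @return Object of class `"cycle_manova"`.
#' @export
one_way_manova <- function(Y, groups) {
  Y <- as.matrix(Y)
  groups <- droplevels(as.factor(groups))
  p <- ncol(Y)
  g <- nlevels(groups)
  N <- nrow(Y)
  if (g < 2L) stop("need at least 2 groups")
  ncounts <- table(groups)
  if (any(ncounts < p + 1)) stop("each group needs at least p + 1 observations")
  grand <- colMeans(Y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lv in levels(groups)) {
    Yi <- Y[groups == lv, , drop = FALSE]
    mi <- colMeans(Yi)
    H <- H + nrow(Yi) * tcrossprod(mi - grand)
    E <- E + crossprod(sweep(Yi, 2, mi))
  }
  if (rcond(E) < 1e-14) stop("singular within-group SSCP matrix")
  lam <- Re(eigen(solve(E, H), only.values = TRUE)$values)
  lam <- sort(pmax(lam, 0), decreasing = TRUE)
  s <- min(p, g - 1)
  V <- sum(lam / (1 + lam))
  theta <- lam[1]
  m <- (abs(p - g + 1) - 1) / 2
  nprime <- (N - g - p - 1) / 2
  df1_p <- s * (2 * m + s + 1)
  df2_p <- s * (2 * nprime + s + 1)
  F_pillai <- (df2_p / df1_p) * (V / (s - V))
  p_pillai <- pf(F_pillai, df1_p, df2_p, lower.tail = FALSE)
  df1_r <- max(p, g - 1)
  df2_r <- N - df1_r - 1
  F_roy <- theta * df2_r / df1_r
  p_roy <- pf(F_roy, df1_r, df2_r, lower.tail = FALSE)
  structure(list(groups = g, variables = p, N = N, H = H, E = E,
                 eigenvalues = lam,
                 pillai = V, F_pillai = F_pillai,
                 df_pillai = c(df1_p, df2_p), p_pillai = p_pillai,
                 eta2_pillai = V / s,
                 roy = theta, F_roy = F_roy, df_roy = c(df1_r, df2_r),
                 p_roy = p_roy, eta2_roy = theta / (1 + theta)),
            class = "cycle_manova")
}

#' @export
print.cycle_manova <- function(x, ...) {
  cat(sprintf("One-way MANOVA: %d groups, %d variables, N = %d\n",
              x$groups, x$variables, x$N))
  cat(sprintf("  Pillai's trace    V = %.3f, F(%g, %g) = %.2f, p = %.3g, partial eta2 = %.2f\n",
              x$pillai, x$df_pillai[1], x$df_pillai[2], x$F_pillai,
              x$p_pillai, x$eta2_pillai))
  cat(sprintf("  Roy's largest root theta = %.3f, F(%g, %g) = %.2f, p = %.3g, partial eta2 = %.2f\n",
              x$roy, x$df_roy[1], x$df_roy[2], x$F_roy, x$p_roy, x$eta2_roy))
  invisible(x)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition via `lm`, with
#' `eta2 = SSB / SST`.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @return List: `F`, `df1`, `df2`, `p`, `eta2`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  a <- anova(lm(values ~ groups))
  ssb <- a[["Sum Sq"]][1]
  ssw <- a[["Sum Sq"]][2]
  list(F = a[["F value"]][1], df1 = a[["Df"]][1], df2 = a[["Df"]][2],
       p = a[["Pr(>F)"]][1], eta2 = ssb / (ssb + ssw))
}

#' Pairwise two-tailed t-tests with Bonferroni correction
#'
#' All g(g-1)/2 pairs. By default the t denominator uses the pooled
#' within-group variance from the one-way ANOVA (mean square within, with
#' N - g degrees of freedom); `pooled = FALSE` uses ordinary two-sample
#' pooled-pair t-tests instead. Adjusted p-values are
#' `min(1, p_raw * number of pairs)`.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @param pooled Use the pooled ANOVA mean square within (default TRUE).
#' @return Data frame: group1, group2, t, df, p_raw, p_adj.
#' @export
pairwise_t_bonferroni <- function(values, groups, pooled = TRUE) {
  groups <- droplevels(as.factor(groups))
  g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  lv <- levels(groups)
  N <- length(values)
  msw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / (N - g)
  pairs <- combn(lv, 2)
  npair <- ncol(pairs)
  rows <- lapply(seq_len(npair), function(j) {
    a <- values[groups == pairs[1, j]]
    b <- values[groups == pairs[2, j]]
    if (pooled) {
      se <- sqrt(msw * (1 / length(a) + 1 / length(b)))
      df <- N - g
    } else {
      sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      se <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      df <- length(a) + length(b) - 2
    }
    tval <- (mean(a) - mean(b)) / se
    p <- 2 * pt(abs(tval), df, lower.tail = FALSE)
    data.frame(group1 = pairs[1, j], group2 = pairs[2, j], t = tval, df = df,
               p_raw = p, p_adj = min(1, p * npair), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare endocrine profiles across individuals
#'
#' Runs the one-way MANOVA on (estradiol, progesterone, ratio), post hoc
#' one-way ANOVAs per variable, and Bonferroni-corrected pairwise t-tests.
#' Hormone values enter untransformed. The ratio column is recomputed with
#' the pmol-per-pmol convention unless `use_ratio_column = TRUE`.
#'
#' @param hormone_table Combined hormone table (several individuals).
#' @param use_ratio_column Trust the table's `ratio` column instead of
#'   recomputing it.
#' @return List: `manova` (`"cycle_manova"`), `anova` (data frame per
#'   variable), `posthoc` (named list of pairwise tables).
#' @export
endocrine_compare <- function(hormone_table, use_ratio_column = FALSE) {
  ratio <- if (use_ratio_column) hormone_table$ratio else {
    hormone_ratio(hormone_table$progesterone_nmol_l,
                  hormone_table$estradiol_pmol_l)
  }
  Y <- cbind(estradiol = hormone_table$estradiol_pmol_l,
             progesterone = hormone_table$progesterone_nmol_l,
             ratio = ratio)
  grp <- hormone_table$individual_id
  man <- one_way_manova(Y, grp)
  av <- do.call(rbind, lapply(colnames(Y), function(v) {
    a <- one_way_anova(Y[, v], grp)
    data.frame(variable = v, F = a$F, df1 = a$df1, df2 = a$df2, p = a$p,
               eta2 = a$eta2, stringsAsFactors = FALSE)
  }))
  ph <- lapply(colnames(Y), function(v) pairwise_t_bonferroni(Y[, v], grp))
  names(ph) <- colnames(Y)
  list(manova = man, anova = av, posthoc = ph)
}
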