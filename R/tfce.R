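# Mass-univariate GLM with threshold-free cluster enhancement and
# permutation family-wise error control.
#
# Per location, the map value is regressed on the square-root hormone level
# (with one intercept per individual in pooled designs); the slope t map is
# enhanced by TFCE (E = 0.5, H = 2, 26-connectivity for volumes, graph
# adjacency for vertices) separately for positive and negative effects, and
# compared against the permutation distribution of the map-wide maximum TFCE
# statistic obtained by permuting hormone values across sessions (within
# individual for pooled designs).

# adjacency of the analysis locations as 0-based CSR lists
geometry_neighbors <- function(geometry, loc_idx = NULL) {
  if (geometry$type == "volume") {
    idx <- if (is.null(loc_idx)) geometry$mask_idx else loc_idx
    sh <- geometry$shape
    V <- length(idx)
    pos <- integer(prod(sh))
    pos[idx] <- seq_len(V)
    ar <- arrayInd(idx, sh)
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    off <- off[rowSums(abs(off)) > 0, , drop = FALSE] # 26-connectivity
    from <- integer(0); to <- integer(0)
    for (r in seq_len(nrow(off))) {
      nb <- sweep(ar, 2, off[r, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] & nb[, 2] >= 1 & nb[, 2] <= sh[2] &
        nb[, 3] >= 1 & nb[, 3] <= sh[3]
      lin <- nb[ok, 1] + (nb[ok, 2] - 1L) * sh[1] +
        (nb[ok, 3] - 1L) * sh[1] * sh[2]
      hit <- pos[lin] > 0L
      from <- c(from, which(ok)[hit])
      to <- c(to, pos[lin[hit]])
    }
    edges <- cbind(from, to)
  } else {
    e <- geometry$edges
    if (!is.null(loc_idx)) {
      V <- length(loc_idx)
      pos <- integer(geometry$n_vertices)
      pos[loc_idx] <- seq_len(V)
      keep <- pos[e[, 1]] > 0L & pos[e[, 2]] > 0L
      e <- cbind(pos[e[keep, 1]], pos[e[keep, 2]])
    } else {
      V <- geometry$n_vertices
    }
    edges <- rbind(e, e[, 2:1])
  }
  o <- order(edges[, 1])
  edges <- edges[o, , drop = FALSE]
  ptr <- c(0L, cumsum(tabulate(edges[, 1], nbins = V)))
  list(ptr = as.integer(ptr), idx = as.integer(edges[, 2] - 1L), V = V)
}

#' Gray-matter absolute threshold
#'
#' Restricts volumetric analyses to locations whose mean map value across all
#' sessions (all individuals) is at least `cutoff`, focusing the tests on
#' gray matter.
#'
#' @param stacks List of `"session_stack"` objects.
#' @param cutoff Mean-value cutoff (default 0.1); locations with mean below
#'   the cutoff are excluded, the boundary value is retained.
#' @return Integer vector of retained column indices (into the stack columns).
#' @export
apply_absolute_threshold <- function(stacks, cutoff = 0.1) {
  if (inherits(stacks, "session_stack")) stacks <- list(stacks)
  X <- do.call(rbind, lapply(stacks, function(s) s$X))
  keep <- which(colMeans(X) >= cutoff)
  if (length(keep) == 0L) stop("absolute threshold removed every location")
  keep
}

#' Mass-univariate GLM t maps
#'
#' Per analysis location, ordinary least squares of the map value on the
#' square-root hormone level. `scope = "pooled"` fits one common hormone slope
#' with a separate intercept per individual (values and predictor centered
#' within individual); `scope = "per_individual"` returns one t map per
#' individual. For a single covariate the slope t statistic is symmetric in
#' response and predictor, so regressing maps on hormones matches the
#' hormone-as-dependent formulation.
#'
#' @param stacks List of session stacks (or one stack).
#' @param hormones Named list of hormone series or combined table.
#' @param predictor `"estradiol"`, `"progesterone"` or `"ratio"`.
#' @param scope `"pooled"` or `"per_individual"`.
#' @param loc_idx Columns to analyze (e.g. from [apply_absolute_threshold()]).
#' @param sqrt_predictor Square-root transform the hormone (default TRUE).
#' @return List: `t` (t map over `loc_idx`, or list of maps), `df`, `Yc`,
#'   `xc`, `block` -- the centered pieces reused by [permutation_fwe()].
#' @export
fit_masswise_glm <- function(stacks, hormones,
                             predictor = c("progesterone", "estradiol", "ratio"),
                             scope = c("pooled", "per_individual"),
                             loc_idx = NULL, sqrt_predictor = TRUE) {
  predictor <- match.arg(predictor)
  scope <- match.arg(scope)
  if (inherits(stacks, "session_stack")) stacks <- list(stacks)
  if (is.data.frame(hormones)) hormones <- split(hormones, hormones$individual_id)
  ids <- vapply(stacks, function(s) s$individual_id, "")
  ns <- vapply(stacks, function(s) nrow(s$X), 1L)
  if (any(ns < 5L)) stop("fewer than 5 sessions for an individual")
  X <- do.call(rbind, lapply(stacks, function(s) s$X))
  if (is.null(loc_idx)) loc_idx <- seq_len(ncol(X))
  Y <- X[, loc_idx, drop = FALSE]
  block <- rep(seq_along(stacks), ns)
  x <- unlist(lapply(seq_along(stacks), function(i) {
    h <- hormones[[ids[i]]]
    if (is.null(h)) stop(sprintf("no hormone series for '%s'", ids[i]))
    if (!identical(as.integer(h$day), as.integer(stacks[[i]]$days))) {
      stop(sprintf("hormone days misaligned for '%s'", ids[i]))
    }
    hv <- switch(predictor, estradiol = h$estradiol_pmol_l,
                 progesterone = h$progesterone_nmol_l, ratio = h$ratio)
    if (sqrt_predictor) sqrt_transform(hv) else hv
  }))
  t_of <- function(Yc, xc, df) {
    sxx <- sum(xc^2)
    if (sxx == 0) stop("constant predictor")
    cp <- drop(crossprod(Yc, xc))
    yss <- colSums(Yc^2)
    rss <- pmax(yss - cp^2 / sxx, 1e-300)
    (cp / sqrt(sxx)) / sqrt(rss / df)
  }
  if (scope == "pooled") {
    Yc <- Y
    xc <- x
    for (b in unique(block)) {
      r <- block == b
      Yc[r, ] <- sweep(Y[r, , drop = FALSE], 2, colMeans(Y[r, , drop = FALSE]))
      xc[r] <- x[r] - mean(x[r])
    }
    df <- nrow(Y) - length(stacks) - 1L
    list(t = t_of(Yc, xc, df), df = df, Yc = Yc, xc = xc, block = block,
         loc_idx = loc_idx, scope = scope)
  } else {
    per <- lapply(unique(block), function(b) {
      r <- block == b
      Yc <- sweep(Y[r, , drop = FALSE], 2, colMeans(Y[r, , drop = FALSE]))
      xc <- x[r] - mean(x[r])
      df <- sum(r) - 2L
      list(t = t_of(Yc, xc, df), df = df, Yc = Yc, xc = xc,
           individual_id = ids[b])
    })
    names(per) <- ids
    list(t = lapply(per, `[[`, "t"), per = per, block = block,
         loc_idx = loc_idx, scope = scope)
  }
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(x) = sum_{h = dh, 2dh, ..., t(x)} e(h, x)^E h^H dh` with
#' `dh = max|t| / n_steps`, where `e(h, x)` is the size of the connected
#' component of the suprathreshold set `{t >= h}` containing `x`
#' (26-connectivity on volumes, supplied adjacency on vertex graphs).
#' Positive and negated maps are enhanced separately.
#'
#' @param stat_map Per-location statistic (signed).
#' @param geometry A `"brain_geometry"`, or a neighbor structure from
#'   `geometry_neighbors`.
#' @param loc_idx Analysis locations when `stat_map` covers a subset.
#' @param E,H TFCE extent and height exponents (defaults 0.5 and 2).
#' @param n_steps Number of integration steps (default 100).
#' @return List with `pos` and `neg` enhanced maps (both non-negative).
#' @export
tfce_enhance <- function(stat_map, geometry, loc_idx = NULL, E = 0.5, H = 2,
                         n_steps = 100L) {
  if (n_steps < 1L) stop("n_steps must be positive")
  if (any(!is.finite(stat_map))) stop("stat_map must be finite")
  nb <- if (inherits(geometry, "brain_geometry")) {
    geometry_neighbors(geometry, loc_idx)
  } else geometry
  if (nb$V != length(stat_map)) stop("stat_map does not match the adjacency")
  list(pos = .tfce_cpp(pmax(stat_map, 0), nb$ptr, nb$idx, E, H,
                       as.integer(n_steps), 0),
       neg = .tfce_cpp(pmax(-stat_map, 0), nb$ptr, nb$idx, E, H,
                       as.integer(n_steps), 0))
}

#' Permutation family-wise error control for TFCE maps
#'
#' Builds the null distribution of the map-wide maximum TFCE statistic by
#' permuting hormone values across sessions (within individual for pooled
#' designs), and assigns each location
#' `fwe_p(x) = (1 + #{perm max >= TFCE(x)}) / (n_perm + 1)`, separately for
#' positive and negative associations.
#'
#' @param stacks,hormones,predictor,scope,loc_idx As in [fit_masswise_glm()]
#'   (`scope = "pooled"` or a single individual).
#' @param geometry The shared `"brain_geometry"`.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level (default 0.01).
#' @param E,H,n_steps TFCE parameters.
#' @param seed Integer seed for the permutations.
#' @return Object of class `"tfce_result"`: `t_map`, `tfce_pos`, `tfce_neg`,
#'   `fwe_p_pos`, `fwe_p_neg`, `null_max_pos`, `null_max_neg`, `alpha`,
#'   `n_perm`, `loc_idx`, `params`.
#' @export
permutation_fwe <- function(stacks, hormones, geometry,
                            predictor = c("progesterone", "estradiol", "ratio"),
                            scope = "pooled", loc_idx = NULL,
                            n_perm = 1000L, alpha = 0.01,
                            E = 0.5, H = 2, n_steps = 100L, seed = 1L) {
  predictor <- match.arg(predictor)
  if (n_perm < 100L) stop("n_perm must be at least 100")
  glm <- fit_masswise_glm(stacks, hormones, predictor, scope = "pooled",
                          loc_idx = loc_idx)
  nb <- geometry_neighbors(geometry, glm$loc_idx)
  enh <- list(pos = .tfce_cpp(pmax(glm$t, 0), nb$ptr, nb$idx, E, H,
                              as.integer(n_steps), 0),
              neg = .tfce_cpp(pmax(-glm$t, 0), nb$ptr, nb$idx, E, H,
                              as.integer(n_steps), 0))
  n <- length(glm$xc)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- seq_len(n)
      for (b in unique(glm$block)) {
        r <- which(glm$block == b)
        idx[r] <- r[sample.int(length(r))]
      }
      idx - 1L
    }, integer(n))
  })
  nul <- .perm_tfce_null_cpp(glm$Yc, glm$xc, perms, nb$ptr, nb$idx,
                             E, H, as.integer(n_steps), glm$df)
  fwe <- function(obs, null_max) {
    vapply(obs, function(v) (1 + sum(null_max >= v)) / (n_perm + 1), 1)
  }
  structure(list(t_map = glm$t, tfce_pos = enh$pos, tfce_neg = enh$neg,
                 fwe_p_pos = fwe(enh$pos, nul$max_pos),
                 fwe_p_neg = fwe(enh$neg, nul$max_neg),
                 null_max_pos = nul$max_pos, null_max_neg = nul$max_neg,
                 alpha = alpha, n_perm = n_perm, loc_idx = glm$loc_idx,
                 params = list(E = E, H = H, n_steps = n_steps,
                               predictor = predictor, seed = seed)),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat(sprintf("TFCE permutation inference: %d locations, %d permutations\n",
              length(x$t_map), x$n_perm))
  cat(sprintf("  significant at FWE p < %.2g: %d positive, %d negative\n",
              x$alpha, sum(x$fwe_p_pos < x$alpha), sum(x$fwe_p_neg < x$alpha)))
  invisible(x)
}

#' @export
summary.tfce_result <- function(object, ...) {
  data.frame(direction = c("pos", "neg"),
             n_significant = c(sum(object$fwe_p_pos < object$alpha),
                               sum(object$fwe_p_neg < object$alpha)),
             max_tfce = c(max(object$tfce_pos), max(object$tfce_neg)),
             null_max_q99 = c(quantile(object$null_max_pos, 0.99),
                              quantile(object$null_max_neg, 0.99)))
}
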