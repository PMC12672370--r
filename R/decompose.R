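# SVD spatiotemporal decomposition.
#
# Per-session maps from several individuals are stacked into one
# sessions x locations matrix, column-centered within each individual's block
# (so static anatomy drops out and shared spatial patterns reflect
# within-cycle change), and decomposed by thin SVD. Each component pairs a
# unit-norm spatial weight map (right singular vector) with a session-wise
# temporal pattern (left singular vector); its variance fraction is the
# squared singular value over the sum of all squared singular values.

#' Concatenate session stacks and center
#'
#' @param stacks List of `"session_stack"` objects sharing one geometry.
#' @param centering `"per_individual"` subtracts each individual's own column
#'   means; `"global"` subtracts the grand column means.
#' @return List of class `"concat_matrix"`: `X` (N x V centered matrix),
#'   `blocks` (data frame: individual_id, start, end), `sessions` (data frame
#'   of individual_id, day per row), `centering`, `geometry`.
#' @export
concatenate_and_center <- function(stacks,
                                   centering = c("per_individual", "global")) {
  centering <- match.arg(centering)
  if (length(stacks) < 1L) stop("need at least one stack")
  ids <- vapply(stacks, function(s) s$individual_id, "")
  if (anyDuplicated(ids)) stop("duplicate individual_id in stacks")
  g0 <- stacks[[1]]$geometry
  for (s in stacks) {
    same <- identical(s$geometry$type, g0$type) &&
      identical(s$geometry$shape, g0$shape) &&
      (g0$type != "volume" || identical(s$geometry$mask_idx, g0$mask_idx))
    if (!same) stop("all stacks must share an identical geometry/mask")
  }
  ns <- vapply(stacks, function(s) nrow(s$X), 1L)
  end <- cumsum(ns)
  start <- end - ns + 1L
  X <- do.call(rbind, lapply(stacks, function(s) s$X))
  if (centering == "per_individual") {
    for (i in seq_along(stacks)) {
      r <- start[i]:end[i]
      X[r, ] <- sweep(X[r, , drop = FALSE], 2, colMeans(X[r, , drop = FALSE]))
    }
  } else {
    X <- sweep(X, 2, colMeans(X))
  }
  sessions <- data.frame(
    individual_id = rep(ids, ns),
    day = unlist(lapply(stacks, function(s) s$days)),
    stringsAsFactors = FALSE)
  structure(list(X = X,
                 blocks = data.frame(individual_id = ids, start = start,
                                     end = end, stringsAsFactors = FALSE),
                 sessions = sessions, centering = centering, geometry = g0),
            class = "concat_matrix")
}

#' Spatiotemporal SVD of a concatenated matrix
#'
#' Thin SVD `X = U diag(sigma) V'`, components ordered by decreasing singular
#' value. Signs are fixed so that the largest-magnitude spatial weight of each
#' component is positive. Temporal scores are additionally z-scored within
#' each individual's session block (`temporal_std`), the form used for all
#' downstream temporal statistics.
#'
#' @param cm A `"concat_matrix"`.
#' @return Object of class `"stp_decomposition"`: `spatial` (V x K), `temporal`
#'   (N x K), `temporal_std` (N x K), `d` (singular values),
#'   `variance_fraction`, `blocks`, `sessions`, `geometry`, `retained`
#'   (initially all `TRUE`).
#' @export
stp_decompose <- function(cm) {
  if (!inherits(cm, "concat_matrix")) stop("'cm' must be a concat_matrix")
  X <- cm$X
  if (nrow(X) < 2L) stop("need at least 2 sessions")
  if (any(!is.finite(X))) stop("non-finite entries in the data matrix")
  sv <- svd(X)
  K <- length(sv$d)
  for (k in seq_len(K)) {
    j <- which.max(abs(sv$v[, k]))
    if (sv$v[j, k] < 0) {
      sv$v[, k] <- -sv$v[, k]
      sv$u[, k] <- -sv$u[, k]
    }
  }
  vf <- sv$d^2 / sum(sv$d^2)
  tstd <- sv$u
  for (i in seq_len(nrow(cm$blocks))) {
    r <- cm$blocks$start[i]:cm$blocks$end[i]
    for (k in seq_len(K)) {
      u <- sv$u[r, k]
      tstd[r, k] <- if (sd(u) > 0) (u - mean(u)) / sd(u) else 0
    }
  }
  structure(list(spatial = sv$v, temporal = sv$u, temporal_std = tstd,
                 d = sv$d, variance_fraction = vf, blocks = cm$blocks,
                 sessions = cm$sessions, geometry = cm$geometry,
                 retained = rep(TRUE, K)),
            class = "stp_decomposition")
}

#' Retain the leading components by variance fraction
#'
#' Keeps the leading components whose variance fraction is at least
#' `min_fraction`. The default 0.095 encodes a "10% of variance" rule applied
#' after rounding to integer percent, so a 9.7% component is retained. The top
#' component is always retained (with a warning if it falls below threshold).
#'
#' @param fit An `"stp_decomposition"`.
#' @param min_fraction Retention threshold on the variance fraction.
#' @return The fit with `retained` updated and components subset to the
#'   retained set (full spectrum kept in `variance_fraction_all`, `d_all`).
#' @export
select_components <- function(fit, min_fraction = 0.095) {
  stopifnot(inherits(fit, "stp_decomposition"))
  vf <- fit$variance_fraction
  keep <- vf >= min_fraction
  # leading run only: stop at the first component below threshold
  n_keep <- if (keep[1]) which.min(c(keep, FALSE)) - 1L else 0L
  if (n_keep < 1L) {
    warning("top component below the retention threshold; retaining it anyway")
    n_keep <- 1L
  }
  idx <- seq_len(n_keep)
  fit$d_all <- fit$d
  fit$variance_fraction_all <- vf
  fit$spatial <- fit$spatial[, idx, drop = FALSE]
  fit$temporal <- fit$temporal[, idx, drop = FALSE]
  fit$temporal_std <- fit$temporal_std[, idx, drop = FALSE]
  fit$d <- fit$d[idx]
  fit$variance_fraction <- vf[idx]
  fit$retained <- rep(TRUE, n_keep)
  fit$min_fraction <- min_fraction
  fit
}

#' Threshold spatial weights for display
#'
#' Reporting convention for spatial maps: weights with absolute value below
#' `low` are zeroed (minimal contribution), weights beyond `high` are clipped
#' to the color-bar limit. Display only -- never used for statistics.
#'
#' @param v Spatial weight vector (unit norm).
#' @param low,high Absolute thresholds, `low < high`.
#' @return Thresholded copy of `v`.
#' @export
threshold_spatial <- function(v, low = 0.01, high = 0.1) {
  if (low >= high) stop("'low' must be smaller than 'high'")
  out <- v
  out[abs(out) < low] <- 0
  out[out > high] <- high
  out[out < -high] <- -high
  out
}

#' Z-score temporal scores within individual blocks
#'
#' @param u Temporal score vector over all sessions.
#' @param blocks Block data frame (`individual_id`, `start`, `end`).
#' @return Per-block standardized copy of `u`.
#' @export
standardize_temporal <- function(u, blocks) {
  out <- u
  for (i in seq_len(nrow(blocks))) {
    r <- blocks$start[i]:blocks$end[i]
    if (length(r) < 2L) stop("each block needs at least 2 sessions")
    if (sd(u[r]) == 0) {
      stop(sprintf("constant temporal scores in block '%s'",
                   blocks$individual_id[i]))
    }
    out[r] <- standardize(u[r])
  }
  out
}

#' @export
print.stp_decomposition <- function(x, ...) {
  K <- length(x$d)
  cat(sprintf("Spatiotemporal decomposition: %d sessions, %d locations, %d component(s)\n",
              nrow(x$temporal), nrow(x$spatial), K))
  vf <- x$variance_fraction
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * vf[seq_len(min(K, 5))]), collapse = ", "),
      if (K > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.stp_decomposition <- function(object, ...) {
  data.frame(component = seq_along(object$d),
             singular_value = object$d,
             variance_fraction = object$variance_fraction,
             retained = object$retained)
}

#' @export
plot.stp_decomposition <- function(x, components = seq_len(min(3, length(x$d))),
                                   ...) {
  op <- graphics::par(mfrow = c(length(components) + 1, 1),
                      mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  vf <- if (!is.null(x$variance_fraction_all)) x$variance_fraction_all
        else x$variance_fraction
  graphics::barplot(100 * vf[seq_len(min(10, length(vf)))],
                    ylab = "% variance", names.arg = seq_len(min(10, length(vf))))
  for (k in components) {
    graphics::plot(x$temporal_std[, k], type = "n", ylab = sprintf("STP%d", k),
                   xlab = "session")
    for (i in seq_len(nrow(x$blocks))) {
      r <- x$blocks$start[i]:x$blocks$end[i]
      graphics::lines(r, x$temporal_std[r, k], col = i)
    }
  }
  invisible(x)
}

#' Temporal scores as a long table
#'
#' @param fit An `"stp_decomposition"`.
#' @return Data frame: individual_id, day, component, score, score_std.
#' @export
temporal_scores <- function(fit) {
  K <- ncol(fit$temporal)
  do.call(rbind, lapply(seq_len(K), function(k) {
    data.frame(individual_id = fit$sessions$individual_id,
               day = fit$sessions$day,
               component = k,
               score = fit$temporal[, k],
               score_std = fit$temporal_std[, k],
               stringsAsFactors = FALSE)
  }))
}
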