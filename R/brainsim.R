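# Synthetic structural image stacks.
#
# The generator emulates preprocessed, spatially normalized, smoothed
# gray-matter maps: a static per-individual anatomy (baseline), plus a small
# number of spatial patterns whose session-wise loadings are either coupled to
# square-root hormone levels or follow a smooth AR(1) series, plus i.i.d.
# Gaussian noise, all Gaussian-smoothed within the mask.

#' Volumetric phantom geometry
#'
#' Builds an ellipsoidal "gray-matter" mask inside a regular grid, standing in
#' for an MNI-space brain mask at desk scale. The ellipsoid semi-axes are 45%
#' of each dimension, which fills 30--60% of the bounding box.
#'
#' @param shape Integer vector of 3 grid dimensions, each at least 8.
#' @param voxel_mm Isotropic voxel size in millimetres.
#' @return A list of class `"brain_geometry"` with `type = "volume"`, the
#'   grid `shape`, `voxel_mm`, the logical `mask` array and the in-mask
#'   linear indices `mask_idx`.
#' @export
make_phantom_mask <- function(shape = c(24L, 24L, 24L), voxel_mm = 2) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    stop("'shape' must be 3 dimensions, each >= 8")
  }
  if (voxel_mm <= 0) stop("'voxel_mm' must be positive")
  ctr <- (shape + 1) / 2
  ax <- 0.45 * shape
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  r2 <- ((g$x - ctr[1]) / ax[1])^2 + ((g$y - ctr[2]) / ax[2])^2 +
    ((g$z - ctr[3]) / ax[3])^2
  mask <- array(r2 <= 1, dim = shape)
  structure(list(type = "volume", shape = shape, voxel_mm = voxel_mm,
                 mask = mask, mask_idx = which(mask)),
            class = "brain_geometry")
}

#' Vertex-wise lattice geometry
#'
#' A 2D lattice graph with 4-neighbour adjacency, standing in for a cortical
#' surface mesh carrying per-vertex thickness values.
#'
#' @param nx,ny Lattice dimensions.
#' @return A `"brain_geometry"` with `type = "surface"`, `n_vertices` and a
#'   two-column `edges` matrix (1-based vertex indices).
#' @export
make_lattice_geometry <- function(nx = 32L, ny = 32L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 2L || ny < 1L) stop("lattice needs at least 2 x 1 vertices")
  idx <- matrix(seq_len(nx * ny), nx, ny)
  horiz <- cbind(as.vector(idx[-nx, ]), as.vector(idx[-1, ]))
  vert <- cbind(as.vector(idx[, -ny]), as.vector(idx[, -1]))
  structure(list(type = "surface", n_vertices = nx * ny,
                 shape = c(nx, ny), edges = rbind(horiz, vert)),
            class = "brain_geometry")
}

n_locations <- function(geometry) {
  if (geometry$type == "volume") length(geometry$mask_idx)
  else geometry$n_vertices
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# dense 1D Gaussian convolution matrix (columns sum handled by renormalization)
gauss_kernel_matrix <- function(n, sigma_vox) {
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-d^2 / (2 * sigma_vox^2))
  k / rowSums(k)
}

apply_axis <- function(arr, K, axis) {
  dm <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- K %*% matrix(a, nrow = dm[axis])
  a <- array(m, dim = dm[perm])
  aperm(a, order(perm))
}

#' Gaussian smoothing within a mask
#'
#' Separable Gaussian smoothing with edge renormalization: the image is
#' multiplied by the mask, smoothed, and divided by the smoothed mask, so the
#' kernel is effectively renormalized at mask edges and the mask mean is
#' preserved to within about a percent.
#'
#' @param arr 3D array of values (defined in-mask).
#' @param geometry A volumetric `"brain_geometry"`.
#' @param fwhm_mm Full width at half maximum in millimetres;
#'   `sigma = fwhm / (2 sqrt(2 log 2))`.
#' @return Smoothed 3D array (zero outside the mask).
#' @export
smooth_volume <- function(arr, geometry, fwhm_mm) {
  if (fwhm_mm <= 0) return(arr * geometry$mask)
  sig <- fwhm_to_sigma(fwhm_mm) / geometry$voxel_mm
  Ks <- lapply(geometry$shape, gauss_kernel_matrix, sigma_vox = sig)
  sm <- function(a) {
    for (ax in 1:3) a <- apply_axis(a, Ks[[ax]], ax)
    a
  }
  num <- sm(arr * geometry$mask)
  den <- sm(geometry$mask * 1)
  out <- array(0, dim = geometry$shape)
  out[geometry$mask_idx] <- num[geometry$mask_idx] / den[geometry$mask_idx]
  out
}

smooth_in_mask <- function(values, geometry, fwhm_mm) {
  if (geometry$type != "volume" || fwhm_mm <= 0) return(values)
  a <- array(0, dim = geometry$shape)
  a[geometry$mask_idx] <- values
  smooth_volume(a, geometry, fwhm_mm)[geometry$mask_idx]
}

#' Planted spatiotemporal model
#'
#' Container for the ground truth injected into a simulated stack: mutually
#' orthogonal unit-norm spatial patterns, per-session loading series, the
#' hormone coupling of each component, the i.i.d. noise level and the
#' smoothing kernel width.
#'
#' @param spatial Locations x components matrix; columns are orthonormalized.
#' @param coupling Character vector per component: `"estradiol"`,
#'   `"progesterone"`, `"ratio"` or `"none"`.
#' @param noise_sd Standard deviation of the additive Gaussian noise, map units.
#' @param smoothing_fwhm Smoothing FWHM in millimetres.
#' @return List of class `"planted_model"`.
#' @export
planted_model <- function(spatial, coupling, noise_sd, smoothing_fwhm = 6) {
  spatial <- as.matrix(spatial)
  q <- qr.Q(qr(spatial)) # orthonormalize, preserving column order
  # keep orientation close to the input patterns
  for (k in seq_len(ncol(q))) if (sum(q[, k] * spatial[, k]) < 0) q[, k] <- -q[, k]
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(spatial = q, coupling = coupling, noise_sd = noise_sd,
                 smoothing_fwhm = smoothing_fwhm), class = "planted_model")
}

#' Simulate one individual's session stack
#'
#' Each session map is `baseline + sum_k loadings[t, k] * spatial[, k] + noise`,
#' then Gaussian-smoothed within the mask (volumetric geometry only).
#'
#' @param planted A [planted_model()].
#' @param loadings Sessions x components matrix of loading series.
#' @param days Integer test days, one per session.
#' @param geometry A `"brain_geometry"`.
#' @param baseline Numeric vector over in-mask locations (static anatomy).
#' @param individual_id Label.
#' @param seed Integer seed for the noise.
#' @return A list of class `"session_stack"` with fields `individual_id`,
#'   `days`, `X` (sessions x locations) and `geometry`.
#' @export
simulate_stack <- function(planted, loadings, days, geometry, baseline,
                           individual_id, seed = 1L) {
  loadings <- as.matrix(loadings)
  V <- n_locations(geometry)
  if (nrow(loadings) != length(days)) {
    stop("loading series length must equal the session count")
  }
  if (ncol(loadings) != ncol(planted$spatial)) {
    stop("loadings and planted spatial patterns disagree on component count")
  }
  if (nrow(planted$spatial) != V || length(baseline) != V) {
    stop("planted patterns/baseline do not match the geometry")
  }
  n <- length(days)
  with_seed(seed, {
    signal <- loadings %*% t(planted$spatial)
    X <- matrix(rnorm(n * V, 0, planted$noise_sd), n, V)
    X <- X + signal + rep(baseline, each = n)
    if (geometry$type == "volume" && planted$smoothing_fwhm > 0) {
      for (i in seq_len(n)) {
        X[i, ] <- smooth_in_mask(X[i, ], geometry, planted$smoothing_fwhm)
      }
    }
    structure(list(individual_id = individual_id, days = as.integer(days),
                   X = X, geometry = geometry), class = "session_stack")
  })
}

#' @export
print.session_stack <- function(x, ...) {
  cat(sprintf("Session stack '%s': %d sessions x %d %s\n", x$individual_id,
              nrow(x$X), ncol(x$X),
              if (x$geometry$type == "volume") "voxels" else "vertices"))
  invisible(x)
}

# weekday day pattern: daily scanning with weekend gaps
weekday_days <- function(n) {
  d <- 1:(ceiling(n / 5) * 7 + 7)
  d <- d[((d - 1) %% 7) < 5]
  d[seq_len(n)]
}

smooth_random_field <- function(geometry, fwhm_mm = 8, n_pass = 1L) {
  V <- n_locations(geometry)
  z <- rnorm(V)
  if (geometry$type == "volume") {
    for (i in seq_len(n_pass)) z <- smooth_in_mask(z, geometry, fwhm_mm)
    z
  } else {
    # graph smoothing: a few neighbourhood-averaging sweeps
    nb <- geometry$edges
    for (i in 1:6) {
      acc <- z
      cnt <- rep(1, V)
      acc[nb[, 1]] <- acc[nb[, 1]] + z[nb[, 2]]
      cnt[nb[, 1]] <- cnt[nb[, 1]] + 1
      acc[nb[, 2]] <- acc[nb[, 2]] + z[nb[, 1]]
      cnt[nb[, 2]] <- cnt[nb[, 2]] + 1
      z <- acc / cnt
    }
    z
  }
}

ar1_series <- function(n, rho = 0.5) {
  z <- numeric(n)
  z[1] <- rnorm(1)
  for (i in seq_len(n - 1)) z[i + 1] <- rho * z[i] + sqrt(1 - rho^2) * rnorm(1)
  standardize(z)
}

# variance retained by the mask-renormalized smoother for i.i.d. unit noise,
# estimated once per geometry from a fixed-seed probe field (deterministic)
noise_variance_factor <- function(geometry, fwhm_mm) {
  if (geometry$type != "volume" || fwhm_mm <= 0) return(1)
  with_seed(104729L, {
    z <- rnorm(n_locations(geometry))
    var(smooth_in_mask(z, geometry, fwhm_mm))
  })
}

#' Default four-cycle study design
#'
#' Generates the full synthetic study: four individuals (typical with 25
#' weekday sessions, a 30-consecutive-day typical cycle, endometriosis with 24
#' weekday sessions, oral contraceptive with 25 weekday sessions), their
#' hormone series, and hormone-coupled image stacks with three planted
#' components at target variance fractions of about 0.50 / 0.20 / 0.10 and an
#' overall planted-signal share of about 80%. Component 1 is coupled to
#' square-root progesterone in the typical cycles and to square-root estradiol
#' in the endometriosis and OC cycles; components 2 and 3 carry smooth AR(1)
#' (rho = 0.5) loadings unrelated to hormones.
#'
#' @param seed Integer seed.
#' @param geometry Optional geometry (default 24^3 grid at 2 mm).
#' @param smoothing_fwhm Smoothing FWHM in mm (default 6).
#' @param signal_share Planted share of total centered variance (default 0.8).
#' @return List with `hormones` (list of 4 series), `stacks` (list of 4
#'   session stacks), `planted` (the [planted_model()] plus the per-individual
#'   loading matrices) and `target_fractions`.
#' @export
default_study_design <- function(seed = 1L, geometry = NULL,
                                 smoothing_fwhm = 6, signal_share = 0.8) {
  if (is.null(geometry)) geometry <- make_phantom_mask(c(24L, 24L, 24L), 2)
  V <- n_locations(geometry)
  target <- c(0.50, 0.20, 0.10)

  ids <- c("typical", "b28andme", "endometriosis", "oc")
  templates <- c("typical", "typical_28andme", "endometriosis", "oc")
  days <- list(weekday_days(25), 1:30, weekday_days(24), weekday_days(25))
  coupled <- c(typical = "progesterone", b28andme = "progesterone",
               endometriosis = "estradiol", oc = "estradiol")

  with_seed(seed, {
    hseeds <- sample.int(1e6, 4)
    sseeds <- sample.int(1e6, 5)
    hormones <- vector("list", 4)
    for (i in 1:4) {
      cfg <- hormone_profile(templates[i], seed = hseeds[i])
      hormones[[i]] <- simulate_cycle(cfg, days[[i]], individual_id = ids[i])
    }
    names(hormones) <- ids

    # three smooth orthonormal spatial patterns; repeated smoothing makes them
    # dominated by low spatial frequencies, hence nearly invariant under the
    # 6-mm session smoothing, so the planted directions survive the pipeline
    pats <- with_seed(sseeds[5], {
      sapply(1:3, function(k) {
        f <- smooth_random_field(geometry, fwhm_mm = 8, n_pass = 3L)
        f / sqrt(sum(f^2))
      })
    })
    pats <- qr.Q(qr(pats))

    # loadings: coupled component 1; AR(1) components 2-3, orthogonalized
    # against the preceding columns so the planted variance splits exactly
    loadings <- vector("list", 4)
    for (i in 1:4) {
      h <- hormones[[i]]
      hv <- switch(coupled[[ids[i]]],
                   estradiol = h$estradiol_pmol_l,
                   progesterone = h$progesterone_nmol_l,
                   ratio = h$ratio)
      a1 <- standardize(sqrt_transform(hv))
      a23 <- with_seed(sseeds[i], cbind(ar1_series(nrow(h)), ar1_series(nrow(h))))
      a2 <- standardize(residuals(lm(a23[, 1] ~ a1)))
      a3 <- standardize(residuals(lm(a23[, 2] ~ a1 + a2)))
      loadings[[i]] <- cbind(a1, a2, a3)
    }

    # scale components to the target variance fractions; calibrate the noise
    # so planted signal carries `signal_share` of the total centered variance
    n_tot <- sum(vapply(loadings, nrow, 1L))
    amp1 <- 0.02 # map-unit amplitude of component 1 (~2% GM change)
    pats_sm <- apply(pats, 2, smooth_in_mask, geometry = geometry,
                     fwhm_mm = smoothing_fwhm)
    sm_norm2 <- colSums(pats_sm^2)
    scales <- amp1 * sqrt(target / target[1] * sm_norm2[1] / sm_norm2)
    sig_tot <- sum(vapply(seq_len(4), function(i) {
      nc <- nrow(loadings[[i]]) - 1
      sum(scales^2 * sm_norm2 * nc)
    }, 1))
    q <- noise_variance_factor(geometry, smoothing_fwhm)
    noise_sd <- sqrt(sig_tot * (1 - signal_share) / signal_share /
                       (n_tot * V * q))

    planted <- planted_model(pats,
                             coupling = c(NA, "none", "none"),
                             noise_sd = noise_sd,
                             smoothing_fwhm = smoothing_fwhm)
    planted$coupling <- c(coupled[[1]], "none", "none")
    planted$coupling_by_individual <- coupled
    planted$scales <- scales
    planted$loadings <- loadings

    stacks <- vector("list", 4)
    for (i in 1:4) {
      base <- with_seed(sseeds[i] + 1L,
                        0.45 + 0.03 * smooth_random_field(geometry, 10))
      stacks[[i]] <- simulate_stack(planted,
                                    loadings[[i]] %*% diag(scales),
                                    days[[i]], geometry, base,
                                    individual_id = ids[i],
                                    seed = hseeds[i] + 7L)
    }
    names(stacks) <- ids

    list(hormones = hormones, stacks = stacks, planted = planted,
         target_fractions = target, geometry = geometry)
  })
}

#' Single-individual simulated study (male or any template)
#'
#' Convenience wrapper producing one hormone series and one stack with the
#' same planted structure as [default_study_design()] but uncoupled loadings
#' throughout when the template is `male` (no hormone-driven component).
#'
#' @param template Hormone template name.
#' @param n_sessions Number of sessions (weekday pattern).
#' @param seed Integer seed.
#' @param geometry Optional geometry (default 16^3 grid for speed).
#' @param coupled Hormone coupled to component 1, or `"none"`.
#' @return List with `hormones`, `stack`, `planted`.
#' @export
simulate_individual <- function(template = "male", n_sessions = 25,
                                seed = 1L, geometry = NULL,
                                coupled = "none") {
  if (is.null(geometry)) geometry <- make_phantom_mask(c(16L, 16L, 16L), 2)
  V <- n_locations(geometry)
  target <- c(0.50, 0.20, 0.10)
  with_seed(seed, {
    hseed <- sample.int(1e6, 1)
    cfg <- hormone_profile(template, seed = hseed)
    h <- simulate_cycle(cfg, weekday_days(n_sessions), individual_id = template)
    pats <- sapply(1:3, function(k) {
      f <- smooth_random_field(geometry, fwhm_mm = 8)
      f / sqrt(sum(f^2))
    })
    a1 <- if (coupled == "none") ar1_series(n_sessions) else {
      standardize(sqrt_transform(switch(coupled,
        estradiol = h$estradiol_pmol_l,
        progesterone = h$progesterone_nmol_l,
        ratio = h$ratio)))
    }
    loadings <- cbind(a1, ar1_series(n_sessions), ar1_series(n_sessions))
    amp1 <- 0.02
    scales <- amp1 * sqrt(target / target[1])
    pats_sm <- apply(pats, 2, smooth_in_mask, geometry = geometry, fwhm_mm = 6)
    sig_tot <- sum(scales^2 * colSums(pats_sm^2) * (n_sessions - 1))
    q <- noise_variance_factor(geometry, 6)
    noise_sd <- sqrt(sig_tot * 0.25 / (n_sessions * V * q))
    planted <- planted_model(pats, coupling = c(coupled, "none", "none"),
                             noise_sd = noise_sd, smoothing_fwhm = 6)
    planted$scales <- scales
    planted$loadings <- loadings
    base <- 0.45 + 0.03 * smooth_random_field(geometry, 10)
    stack <- simulate_stack(planted, loadings %*% diag(scales), h$day,
                            geometry, base, individual_id = template,
                            seed = hseed + 7L)
    list(hormones = h, stack = stack, planted = planted)
  })
}
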