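# Study manifests, on-disk formats and the end-to-end pipeline.
#
# Volumetric stacks are written as one NIfTI file per session plus a mask
# NIfTI; vertex stacks as a TSV matrix plus an edge-list TSV. A manifest TSV
# maps (individual_id, day) to the per-session file. All tables are
# tab-separated, UTF-8, dot decimal.

#' Write a session stack to disk
#'
#' @param stack A `"session_stack"`.
#' @param dir Output directory (created if needed).
#' @return Data frame of manifest rows (individual_id, day, path).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- stack$geometry
  if (g$type == "volume") {
    maskfile <- file.path(dir, "mask.nii.gz")
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(g$mask), g$shape),
                                       pixdim = rep(g$voxel_mm, 3)), maskfile)
    paths <- vapply(seq_along(stack$days), function(i) {
      a <- array(0, g$shape)
      a[g$mask_idx] <- stack$X[i, ]
      f <- file.path(dir, sprintf("%s_day%03d.nii.gz", stack$individual_id,
                                  stack$days[i]))
      RNifti::writeNifti(RNifti::asNifti(a, pixdim = rep(g$voxel_mm, 3)), f)
      f
    }, "")
  } else {
    edgefile <- file.path(dir, "edges.tsv")
    write.table(data.frame(vertex_a = g$edges[, 1], vertex_b = g$edges[, 2]),
                edgefile, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- vapply(seq_along(stack$days), function(i) {
      f <- file.path(dir, sprintf("%s_day%03d.tsv", stack$individual_id,
                                  stack$days[i]))
      write.table(data.frame(value = stack$X[i, ]), f, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      f
    }, "")
  }
  data.frame(individual_id = stack$individual_id, day = stack$days,
             path = paths, stringsAsFactors = FALSE)
}

#' Read a session stack back from manifest rows
#'
#' @param rows Manifest rows for one individual (individual_id, day, path).
#' @param geometry The study geometry.
#' @return A `"session_stack"`.
#' @export
read_stack <- function(rows, geometry) {
  rows <- rows[order(rows$day), ]
  X <- t(vapply(rows$path, function(f) {
    if (grepl("\\.nii(\\.gz)?$", f)) {
      a <- as.array(RNifti::readNifti(f))
      a[geometry$mask_idx]
    } else {
      read.delim(f)$value
    }
  }, numeric(n_locations(geometry))))
  dimnames(X) <- NULL
  structure(list(individual_id = rows$individual_id[1],
                 days = as.integer(rows$day), X = X, geometry = geometry),
            class = "session_stack")
}

#' Write / read a study manifest
#'
#' @param manifest Data frame: individual_id, day, path.
#' @param path Manifest TSV path.
#' @export
write_manifest <- function(manifest, path) {
  write.table(manifest, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Exclude sessions from a manifest
#'
#' Removes the listed (individual_id, day) sessions from the manifest so that
#' they drop out of both imaging and hormone analyses (for example a scan
#' removed for artifacts).
#'
#' @param manifest Manifest data frame.
#' @param exclusions Data frame with columns `individual_id` and `day`.
#' @return The reduced manifest.
#' @export
exclude_sessions <- function(manifest, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) return(manifest)
  key <- paste(manifest$individual_id, manifest$day)
  exkey <- paste(exclusions$individual_id, exclusions$day)
  missing <- setdiff(exkey, key)
  if (length(missing)) {
    stop("unknown session(s): ", paste(missing, collapse = "; "))
  }
  manifest[!(key %in% exkey), , drop = FALSE]
}

#' Default run configuration
#'
#' All defaults equal the documented analysis conventions: per-individual
#' centering, 9.5% retention, spline basis size 10, TFCE E = 0.5 / H = 2 with
#' 100 steps and 26-connectivity, 1000 permutations at alpha 0.01, and
#' per-individual FDR families.
#'
#' @param ... Overrides.
#' @return Named list.
#' @export
default_run_config <- function(...) {
  cfg <- list(centering = "per_individual", min_fraction = 0.095, k = 10L,
              tfce_E = 0.5, tfce_H = 2, tfce_steps = 100L,
              n_perm = 1000L, alpha = 0.01, gm_cutoff = 0.1,
              run_masswise = TRUE, masswise_predictors = "progesterone",
              seed = 1L)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full analysis pipeline
#'
#' Validates the inputs, then executes decomposition, the temporal
#' fluctuation screen, the hormone association analysis and (optionally) the
#' mass-univariate TFCE inference, writing all tables plus a run log to
#' `out_dir`. Reruns with identical inputs, config and seed produce identical
#' outputs.
#'
#' @param stacks Named list of session stacks (or a manifest data frame with
#'   `geometry` supplied, in which case stacks are read from disk).
#' @param hormones Named list of hormone series or a combined hormone table.
#' @param out_dir Output directory; `NULL` skips writing.
#' @param config A [default_run_config()].
#' @param geometry Required when `stacks` is a manifest.
#' @return List: `decomposition`, `gam`, `association`, `masswise` (or NULL),
#'   `config`.
#' @export
run_full_pipeline <- function(stacks, hormones, out_dir = NULL,
                              config = default_run_config(),
                              geometry = NULL) {
  if (is.data.frame(stacks)) {
    if (is.null(geometry)) stop("reading from a manifest requires 'geometry'")
    stacks <- lapply(split(stacks, stacks$individual_id), read_stack,
                     geometry = geometry)
  }
  if (is.data.frame(hormones)) hormones <- split(hormones, hormones$individual_id)

  # validate everything before computing anything
  problems <- character(0)
  for (s in stacks) {
    h <- hormones[[s$individual_id]]
    if (is.null(h)) {
      problems <- c(problems,
                    sprintf("no hormone series for '%s'", s$individual_id))
    } else if (!identical(as.integer(h$day), as.integer(s$days))) {
      extra <- setdiff(s$days, h$day)
      problems <- c(problems, sprintf(
        "hormone/session day mismatch for '%s'%s", s$individual_id,
        if (length(extra)) paste0(" (sessions without hormones: day ",
                                  paste(extra, collapse = ", "), ")") else ""))
    }
  }
  if (length(problems)) stop(paste(problems, collapse = "\n"))

  cm <- concatenate_and_center(stacks, centering = config$centering)
  fit <- select_components(stp_decompose(cm),
                           min_fraction = config$min_fraction)
  gam_tab <- screen_fluctuations(fit, k = config$k)
  assoc <- associate_all(fit, hormones)

  mass <- NULL
  if (isTRUE(config$run_masswise)) {
    loc_idx <- if (stacks[[1]]$geometry$type == "volume") {
      apply_absolute_threshold(stacks, cutoff = config$gm_cutoff)
    } else NULL
    mass <- lapply(config$masswise_predictors, function(pred) {
      permutation_fwe(stacks, hormones, stacks[[1]]$geometry,
                      predictor = pred, loc_idx = loc_idx,
                      n_perm = config$n_perm, alpha = config$alpha,
                      E = config$tfce_E, H = config$tfce_H,
                      n_steps = config$tfce_steps, seed = config$seed)
    })
    names(mass) <- config$masswise_predictors
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(summary(fit), "components.tsv")
    wt(temporal_scores(fit), "temporal_scores.tsv")
    wt(gam_tab, "gam.tsv")
    wt(assoc, "association.tsv")
    if (!is.null(mass)) {
      for (pred in names(mass)) {
        m <- mass[[pred]]
        wt(data.frame(location = m$loc_idx, t = m$t_map,
                      tfce_pos = m$tfce_pos, tfce_neg = m$tfce_neg,
                      fwe_p_pos = m$fwe_p_pos, fwe_p_neg = m$fwe_p_neg),
           sprintf("masswise_%s.tsv", pred))
      }
    }
    cfg_flat <- vapply(config, function(v) paste(format(v), collapse = ","), "")
    log <- c(sprintf("cyclebrain run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("individuals: %s",
                     paste(vapply(stacks, function(s) s$individual_id, ""),
                           collapse = ", ")),
             paste0(names(cfg_flat), " = ", cfg_flat))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(decomposition = fit, gam = gam_tab, association = assoc,
       masswise = mass, config = config)
}
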