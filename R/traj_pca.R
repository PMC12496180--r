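#' Pooled essential-dynamics PCA of Cα coordinates
#'
#' All frames of all replicates of the included systems are superposed onto
#' one common reference over the shared residue IDs (minus any excluded
#' residues), flattened to 3k-dimensional coordinate vectors, mean-centered
#' and decomposed by covariance PCA. Component signs are fixed by making the
#' largest-magnitude loading positive, so results are deterministic.
#'
#' @param ensemble a `traj_ensemble` with >= 2 systems (or >= 1 when only a
#'   subset is analyzed).
#' @param exclude_residues residue IDs excluded before the decomposition
#'   (e.g. a divergent loop); the remaining set must have >= 2 residues.
#' @param n_components number of components to retain (default 10).
#' @param systems system labels to pool (default all).
#' @param reference_system system whose starting structure is the
#'   superposition target (default the first pooled system).
#' @return object of class `pca_result`: orthonormal `components` (3k x
#'   ncomp), `eigenvalues` (all), `ratios` (explained-variance fractions of
#'   the retained components), `total_variance`, `projections` data.frame
#'   (`system`, `replicate`, `frame`, `time`, `PC1..`), `residue_ids` used,
#'   `excluded_residues`, `center`.
#' @export
pooled_pca <- function(ensemble, exclude_residues = integer(),
                       n_components = 10, systems = NULL,
                       reference_system = NULL) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  systems <- systems %||% names(ensemble$systems)
  shared <- sort(Reduce(intersect,
                        lapply(ensemble$systems[systems], `[[`,
                               "residue_ids")))
  use <- setdiff(shared, exclude_residues)
  if (length(use) < 2) stop("excluded set leaves fewer than 2 residues")
  reference_system <- reference_system %||% systems[1]
  ref_sys <- ensemble$systems[[reference_system]]
  ref <- ref_sys$reference[match(use, ref_sys$residue_ids), , drop = FALSE]

  blocks <- list()
  meta <- list()
  for (s in systems) {
    sys <- ensemble$systems[[s]]
    sel <- match(use, sys$residue_ids)
    if (anyNA(sel)) stop("system ", s, " lacks shared residues")
    for (r in seq_along(sys$replicates)) {
      rep_ <- sys$replicates[[r]]
      n <- dim(rep_$coords)[2]
      fl <- flatten_frames(rep_$coords)[, c(sel, n + sel, 2 * n + sel),
                                        drop = FALSE]
      fl <- superpose_frames_cpp(fl, ref)$coords
      blocks[[length(blocks) + 1L]] <- fl
      meta[[length(meta) + 1L]] <- data.frame(
        system = s, replicate = r, frame = seq_len(nrow(fl)),
        time = rep_$times, stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, blocks)
  meta <- do.call(rbind, meta)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  N <- nrow(Xc)
  d3k <- ncol(Xc)

  if (d3k <= 600 || d3k <= N) {
    C <- crossprod(Xc) / (N - 1)
    ee <- eigen(C, symmetric = TRUE)
    values <- pmax(ee$values, 0)
    vectors <- ee$vectors
  } else {
    sv <- svd(Xc)
    values <- sv$d^2 / (N - 1)
    vectors <- sv$v
  }
  ncomp <- min(n_components, ncol(vectors), N - 1)
  comps <- vectors[, seq_len(ncomp), drop = FALSE]
  for (j in seq_len(ncomp)) {
    i <- which.max(abs(comps[, j]))
    if (comps[i, j] < 0) comps[, j] <- -comps[, j]
  }
  proj <- Xc %*% comps
  colnames(proj) <- paste0("PC", seq_len(ncomp))
  structure(
    list(components = comps, eigenvalues = values,
         ratios = values[seq_len(ncomp)] / sum(values),
         total_variance = sum(values),
         projections = cbind(meta, as.data.frame(proj)),
         residue_ids = use, excluded_residues = exclude_residues,
         center = center),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Pooled PCA:", nrow(x$projections), "frames,",
      length(x$residue_ids), "residues;",
      sprintf("PC1 %.1f%%, PC2 %.1f%%\n", 100 * x$ratios[1],
              100 * (if (length(x$ratios) > 1) x$ratios[2] else NA)))
  invisible(x)
}

#' Extreme frames on selected principal components
#'
#' @param result a [pooled_pca()] result.
#' @param pcs component indices (default 1 and 2).
#' @return data.frame with one row per (system, replicate, PC, extreme):
#'   `frame` index and projection `value`.
#' @export
extreme_frames <- function(result, pcs = c(1, 2)) {
  proj <- result$projections
  groups <- unique(proj[, c("system", "replicate")])
  out <- list()
  for (g in seq_len(nrow(groups))) {
    sel <- proj$system == groups$system[g] &
      proj$replicate == groups$replicate[g]
    sub <- proj[sel, , drop = FALSE]
    if (!nrow(sub)) stop("empty replicate")
    for (pc in pcs) {
      v <- sub[[paste0("PC", pc)]]
      for (side in c("max", "min")) {
        i <- if (side == "max") which.max(v) else which.min(v)
        out[[length(out) + 1L]] <- data.frame(
          system = groups$system[g], replicate = groups$replicate[g],
          pc = pc, extreme = side, frame = sub$frame[i], value = v[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Flag outlier replicates in the PC1-PC2 plane
#'
#' Each replicate is summarized by its centroid in (PC1, PC2). A replicate is
#' flagged when its centroid's distance from the median centroid exceeds
#' `k` times the median absolute deviation of the per-frame projection
#' distances from that median centroid. The frame-level MAD sets the scale of
#' the conformational cloud, so replicates sampling the same basin are
#' essentially never flagged (their centroids concentrate at cloud-scale /
#' sqrt(frames)), while a structurally divergent replicate is.
#'
#' @param result a [pooled_pca()] result with >= 3 replicates.
#' @param k flag multiplier (default 3).
#' @param pcs components used (default 1 and 2).
#' @return data.frame per replicate: centroid coordinates, `distance`,
#'   `threshold`, logical `outlier`.
#' @export
flag_outlier_replicates <- function(result, k = 3, pcs = c(1, 2)) {
  proj <- result$projections
  cols <- paste0("PC", pcs)
  key <- paste(proj$system, proj$replicate)
  groups <- unique(key)
  if (length(groups) < 3) stop("need at least 3 replicates")
  centroids <- t(vapply(groups, function(g)
    colMeans(proj[key == g, cols, drop = FALSE]), numeric(length(cols))))
  med <- apply(centroids, 2, median)
  d_cent <- sqrt(rowSums(sweep(centroids, 2, med)^2))
  d_frames <- sqrt(rowSums(sweep(as.matrix(proj[, cols]), 2, med)^2))
  thr <- k * mad(d_frames)
  first <- match(groups, key)
  data.frame(system = proj$system[first], replicate = proj$replicate[first],
             centroid_pc1 = centroids[, 1], centroid_pc2 = centroids[, 2],
             distance = d_cent, threshold = thr, outlier = d_cent > thr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Loop divergence across replicates
#'
#' Frames are superposed onto the reference over the full shared domain;
#' the RMSD restricted to the loop residues (without re-fitting) is then
#' averaged over frames for each replicate. The spread (max - min of the
#' per-replicate means) measures replicate convergence of the loop.
#'
#' @param ensemble a `traj_ensemble`.
#' @param loop_residues residue IDs of the loop.
#' @param systems system labels (default all).
#' @param reference_system superposition target (default first system).
#' @return data.frame per replicate with `mean_rmsd`; the cross-replicate
#'   `spread` is attached as an attribute.
#' @export
loop_divergence <- function(ensemble, loop_residues, systems = NULL,
                            reference_system = NULL) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  systems <- systems %||% names(ensemble$systems)
  shared <- sort(Reduce(intersect,
                        lapply(ensemble$systems[systems], `[[`,
                               "residue_ids")))
  loop <- intersect(shared, loop_residues)
  if (!length(loop)) stop("empty loop")
  reference_system <- reference_system %||% systems[1]
  ref_sys <- ensemble$systems[[reference_system]]
  ref <- ref_sys$reference[match(shared, ref_sys$residue_ids), ,
                           drop = FALSE]
  loop_idx0 <- match(loop, shared) - 1L
  out <- list()
  for (s in systems) {
    sys <- ensemble$systems[[s]]
    sel <- match(shared, sys$residue_ids)
    for (r in seq_along(sys$replicates)) {
      rep_ <- sys$replicates[[r]]
      n <- dim(rep_$coords)[2]
      fl <- flatten_frames(rep_$coords)[, c(sel, n + sel, 2 * n + sel),
                                        drop = FALSE]
      fl <- superpose_frames_cpp(fl, ref)$coords
      rms <- rmsd_nofit_cpp(fl, ref, loop_idx0)
      out[[length(out) + 1L]] <- data.frame(
        system = s, replicate = r, mean_rmsd = mean(rms),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  attr(out, "spread") <- max(out$mean_rmsd) - min(out$mean_rmsd)
  out
}
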