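#' Kabsch superposition of two coordinate sets
#'
#' Optimal proper rotation (determinant +1) and translation of `mobile` onto
#' `target` after centroid removal; the returned RMSD is the minimized value.
#'
#' @param mobile,target n x 3 coordinate matrices (Å), n >= 3 and
#'   non-collinear.
#' @return list with `coords` (superposed mobile) and `rmsd`.
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3)
  if (nrow(mobile) != nrow(target)) stop("atom counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 atoms")
  for (m in list(mobile, target)) {
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2] <= 1e-10 * max(sv[1], 1))
      stop("degenerate (collinear) configuration")
  }
  kabsch_superpose_cpp(mobile, target)
}

#' Superpose every frame of a replicate onto a target structure
#'
#' @param replicate a `traj_replicate`.
#' @param target n x 3 matrix; default the replicate's first frame.
#' @return list with the superposed `replicate` and per-frame `rmsd`.
#' @export
superpose_replicate <- function(replicate, target = NULL) {
  stopifnot(inherits(replicate, "traj_replicate"))
  target <- target %||% replicate$coords[1, , ]
  stopifnot(nrow(target) == dim(replicate$coords)[2])
  res <- superpose_frames_cpp(flatten_frames(replicate$coords),
                              as.matrix(target))
  replicate$coords <- unflatten_frames(res$coords, dim(replicate$coords)[2])
  list(replicate = replicate, rmsd = as.numeric(res$rmsd))
}

#' Radius of gyration
#'
#' `Rg = sqrt(sum |r_i - centroid|^2 / n)` with uniform weights over the
#' selected atoms (mass weighting is a no-op on a single-atom-type Cα
#' selection, up to a constant).
#'
#' @param coords n x 3 coordinate matrix (Å), n >= 1.
#' @return Rg in Å.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (!nrow(coords)) stop("empty selection")
  c0 <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, c0)^2)))
}

#' Per-frame radius-of-gyration series
#'
#' @param replicate a `traj_replicate`.
#' @return data.frame with `time` (ps) and `value` (Å).
#' @export
rg_series <- function(replicate) {
  stopifnot(inherits(replicate, "traj_replicate"))
  vals <- apply(replicate$coords, 1, radius_of_gyration)
  data.frame(time = replicate$times, value = vals)
}

#' Per-frame RMSD series after superposition
#'
#' Each frame is superposed onto the reference (default: the first frame,
#' standing in for the system starting structure) and the minimized RMSD
#' recorded.
#'
#' @param replicate a `traj_replicate`.
#' @param reference n x 3 matrix; default the replicate's first frame.
#' @return data.frame with `time` (ps) and `value` (Å).
#' @export
rmsd_series <- function(replicate, reference = NULL) {
  stopifnot(inherits(replicate, "traj_replicate"))
  reference <- reference %||% replicate$coords[1, , ]
  if (nrow(reference) != dim(replicate$coords)[2]) stop("atom mismatch")
  res <- superpose_frames_cpp(flatten_frames(replicate$coords),
                              as.matrix(reference))
  data.frame(time = replicate$times, value = as.numeric(res$rmsd))
}

#' Per-residue RMSF of one replicate
#'
#' Frames are superposed to the reference (the replicate's first frame by
#' default, i.e. the starting structure; `reference = "mean"` re-fits to the
#' time-average structure) and the fluctuation of each Cα about its
#' time-average position is computed:
#' `RMSF_i = sqrt(mean_t |r_i(t) - <r_i>|^2)`.
#'
#' @param replicate a `traj_replicate` with at least 2 frames.
#' @param reference `"start"` (default) or `"mean"`.
#' @param fit superpose frames before measuring (set `FALSE` for
#'   pre-aligned coordinates).
#' @return data.frame with `residue` and `rmsf` (Å).
#' @export
rmsf_profile <- function(replicate, reference = c("start", "mean"),
                         fit = TRUE) {
  stopifnot(inherits(replicate, "traj_replicate"))
  reference <- match.arg(reference)
  fl <- flatten_frames(replicate$coords)
  if (nrow(fl) < 2) stop("need at least 2 frames")
  n <- dim(replicate$coords)[2]
  if (fit) {
    fl <- superpose_frames_cpp(fl, replicate$coords[1, , ])$coords
    if (reference == "mean") {
      mu <- matrix(colMeans(fl), ncol = 3)
      fl <- superpose_frames_cpp(fl, mu)$coords
    }
  }
  mu <- colMeans(fl)
  dev2 <- sweep(fl, 2, mu)^2
  msf <- colMeans(dev2)
  rmsf <- sqrt(msf[1:n] + msf[n + 1:n] + msf[2 * n + 1:n])
  data.frame(residue = replicate$residue_ids, rmsf = as.numeric(rmsf))
}

#' Aggregate per-replicate RMSF profiles
#'
#' @param profiles list of data.frames from [rmsf_profile()] sharing residue
#'   IDs.
#' @return object of class `residue_profile`: data.frame with `residue`,
#'   `mean`, `sd`, `sem` (`sem = sd / sqrt(n_replicates)`); the per-replicate
#'   matrix is attached as attribute `"replicates"`.
#' @export
aggregate_rmsf <- function(profiles) {
  ids <- profiles[[1]]$residue
  for (p in profiles) stopifnot(identical(p$residue, ids))
  m <- vapply(profiles, `[[`, numeric(length(ids)), "rmsf")
  m <- matrix(m, nrow = length(ids))
  out <- data.frame(residue = ids, mean = rowMeans(m),
                    sd = apply(m, 1, sd),
                    sem = apply(m, 1, sd) / sqrt(ncol(m)))
  attr(out, "replicates") <- m
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' Per-system per-replicate RMSF matrices for an ensemble
#'
#' @param ensemble a `traj_ensemble`.
#' @param ... passed to [rmsf_profile()].
#' @return named list per system: `list(residue_ids =, rmsf = residues x
#'   replicates matrix)`.
#' @export
system_rmsf <- function(ensemble, ...) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  lapply(ensemble$systems, function(sys) {
    profs <- lapply(sys$replicates, rmsf_profile, ...)
    list(residue_ids = sys$residue_ids,
         rmsf = vapply(profs, `[[`, numeric(length(sys$residue_ids)),
                       "rmsf"))
  })
}

#' Remove equilibration (burn-in) frames
#'
#' Drops frames with `time < burn_in` (times in ps, burn-in given in ns).
#' `burn_in = "auto"` picks the smallest time at which the expanding forward
#' running mean of the RMSD series stays within `delta` Å of the mean over
#' the final 20% of frames.
#'
#' @param replicate a `traj_replicate`.
#' @param burn_in burn-in in ns (default 400), or `"auto"`.
#' @param delta convergence tolerance in Å for `"auto"` (default 0.5).
#' @return the trimmed `traj_replicate`; the applied burn-in (ns) is attached
#'   as attribute `"burn_in_ns"`.
#' @export
trim_equilibration <- function(replicate, burn_in = 400, delta = 0.5) {
  stopifnot(inherits(replicate, "traj_replicate"))
  times <- replicate$times
  duration_ps <- max(times) - min(times) +
    if (length(times) > 1) diff(times)[1] else 0
  if (identical(burn_in, "auto")) {
    r <- rmsd_series(replicate)$value
    F_ <- length(r)
    tail_mean <- mean(r[max(1, ceiling(0.8 * F_)):F_])
    stride <- max(1L, F_ %/% 1000L)
    grid <- unique(c(seq(1L, F_, by = stride), F_))
    S <- cumsum(r)
    pick <- F_
    for (t in grid) {
      js <- grid[grid >= t]
      mu <- (S[js] - if (t > 1) S[t - 1] else 0) / (js - t + 1)
      if (max(abs(mu - tail_mean)) <= delta) {
        pick <- t
        break
      }
    }
    burn_in_ps <- times[pick] - min(times)
  } else {
    burn_in_ps <- burn_in * 1000
    if (burn_in_ps >= duration_ps)
      stop("trajectory shorter than the requested burn-in")
  }
  keep <- times - min(times) >= burn_in_ps
  if (!any(keep)) stop("trajectory shorter than the requested burn-in")
  out <- trajectory_replicate(
    replicate$coords[keep, , , drop = FALSE], times[keep],
    replicate$residue_ids)
  attr(out, "burn_in_ns") <- burn_in_ps / 1000
  out
}

#' Apply burn-in trimming to every replicate of an ensemble
#'
#' @param ensemble a `traj_ensemble`.
#' @inheritParams trim_equilibration
#' @return the trimmed ensemble.
#' @export
trim_ensemble <- function(ensemble, burn_in = 400, delta = 0.5) {
  stopifnot(inherits(ensemble, "traj_ensemble"))
  ensemble$systems <- lapply(ensemble$systems, function(sys) {
    sys$replicates <- lapply(sys$replicates, trim_equilibration,
                             burn_in = burn_in, delta = delta)
    sys
  })
  ensemble
}

#' Location and SEM of the maximum between-system difference
#'
#' Finds the axis location (time frame for RMSD, Cα position for RMSF) where
#' the spread (max - min) of the per-system mean series is largest and
#' returns the standard error of the system means there
#' (`SD across systems / sqrt(n_systems)`).
#'
#' @param series_by_system named list (>= 2 systems) of equal-length numeric
#'   vectors on a shared axis.
#' @param axis optional axis labels (times or residue IDs).
#' @return list with `location`, `index`, `value` (the SEM) and `spread`.
#' @export
sem_of_max_dif <- function(series_by_system, axis = NULL) {
  stopifnot(length(series_by_system) >= 2)
  lens <- vapply(series_by_system, length, integer(1))
  if (length(unique(lens)) != 1) stop("series lengths differ (axis mismatch)")
  m <- do.call(rbind, series_by_system)
  spread <- apply(m, 2, function(v) max(v) - min(v))
  idx <- which.max(spread)
  vals <- m[, idx]
  list(location = if (!is.null(axis)) axis[idx] else idx,
       index = idx, value = sd(vals) / sqrt(length(vals)),
       spread = spread[idx])
}
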