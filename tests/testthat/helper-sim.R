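# Shared simulation drivers for the statistics suites.

# Null four-system world: every system has the same sigma profile. Returns
# the fraction of windows rejected (BH within comparison), averaged over
# the four comparisons, for one seed.
null_fdr_fraction <- function(seed, n_residues = 202, n_frames = 120,
                              n_replicates = 5, sigma = 1, alpha = 0.05) {
  spec <- trajectory_spec(
    n_residues = n_residues, duration_ns = n_frames / 10,
    frame_interval_ps = 100, n_replicates = n_replicates, sigma = sigma,
    seed = seed)
  ens <- generate_trajectories(spec)
  cmp <- compare_systems(system_rmsf(ens), alpha = alpha)
  mean(cmp$peaks$significant)
}

# Planted-difference world: wt-like systems have sigma_base everywhere,
# del-like systems sigma_base * sigma_ratio at `planted` residues. The
# planted RMSF difference is sigma_base * (sigma_ratio - 1) * sqrt(3).
# Returns whether the fully-planted window is BH-significant AND flagged
# above the resolution in the wt vs del comparison.
power_detect <- function(seed, sigma_base = 2, sigma_ratio = 2,
                         planted = 14:16, n_residues = 30,
                         n_frames = 2000, n_replicates = 5,
                         resolution = 2.5) {
  sig_del <- rep(sigma_base, n_residues)
  sig_del[planted] <- sigma_base * sigma_ratio
  spec <- trajectory_spec(
    n_residues = n_residues, duration_ns = n_frames / 10,
    frame_interval_ps = 100, n_replicates = n_replicates,
    systems = c("wt", "del"),
    sigma = list(wt = rep(sigma_base, n_residues), del = sig_del),
    seed = seed)
  ens <- generate_trajectories(spec)
  cmp <- compare_systems(system_rmsf(ens),
                         comparisons = list(c("wt", "del")),
                         consistency_pair = c(1, 1),
                         resolution = resolution)
  label <- sprintf("%d-%d", planted[1], planted[length(planted)])
  row <- cmp$peaks[cmp$peaks$window == label, ]
  row$significant && row$above_resolution
}

# One-replicate ensemble whose frames move along a single fixed
# displacement mode (plus nothing else): PC1 carries all variance. The mode
# is projected out of the 6 rigid-body directions of the reference so the
# pre-PCA superposition leaves it (to first order) untouched.
single_mode_ensemble <- function(seed = 40, n_residues = 10, F_ = 200) {
  spec <- trajectory_spec(n_residues = n_residues, duration_ns = F_ / 10,
                          frame_interval_ps = 100, n_replicates = 1,
                          systems = "wt", sigma = 0, seed = seed)
  ens <- generate_trajectories(spec)
  ref <- ens$systems$wt$reference
  rc <- sweep(ref, 2, colMeans(ref))
  zero <- rep(0, n_residues)
  one <- rep(1, n_residues)
  rigid <- cbind(c(one, zero, zero), c(zero, one, zero), c(zero, zero, one),
                 c(zero, -rc[, 3], rc[, 2]), c(rc[, 3], zero, -rc[, 1]),
                 c(-rc[, 2], rc[, 1], zero))
  rigid_q <- qr.Q(qr(rigid))
  withr::with_seed(seed, {
    mode <- rnorm(n_residues * 3)
    mode <- mode - rigid_q %*% crossprod(rigid_q, mode)
    mode <- as.numeric(mode / sqrt(sum(mode^2)))
    amp <- rnorm(F_, sd = 1)
  })
  rep_ <- ens$systems$wt$replicates[[1]]
  fl <- vgbarrel:::flatten_frames(rep_$coords) + outer(amp, mode)
  rep_$coords <- vgbarrel:::unflatten_frames(fl, n_residues)
  ens$systems$wt$replicates[[1]] <- rep_
  ens
}

# One-system ensemble with a rigidly displaced loop in one replicate.
planted_outlier_ensemble <- function(seed, n_residues = 40, loop = 20:29,
                                     displacement = 8, n_frames = 300,
                                     n_replicates = 6, sigma = 0.5) {
  spec <- trajectory_spec(
    n_residues = n_residues, duration_ns = n_frames / 10,
    frame_interval_ps = 100, n_replicates = n_replicates,
    systems = "wt", sigma = sigma, seed = seed)
  ens <- generate_trajectories(spec)
  out_rep <- ens$systems$wt$replicates[[3]]
  out_rep$coords[, loop, 1] <- out_rep$coords[, loop, 1] + displacement
  ens$systems$wt$replicates[[3]] <- out_rep
  ens
}
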