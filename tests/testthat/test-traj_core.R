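make_coords <- function(n, seed = NULL) {
  gen <- function() matrix(rnorm(n * 3, sd = 4), ncol = 3)
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

test_that("superposition recovers rigid motions and rejects bad input", {
  a <- make_coords(12, seed = 1)
  expect_equal(superpose(a, a)$rmsd, 0, tolerance = 1e-10)
  withr::with_seed(2, {
    moved <- a %*% random_rotation() +
      matrix(rnorm(3), nrow = 12, ncol = 3, byrow = TRUE)
  })
  res <- superpose(moved, a)
  expect_lt(res$rmsd, 1e-8)
  expect_equal(res$coords, a, tolerance = 1e-8)
  expect_error(superpose(a[1:2, ], a[1:2, ]), "at least 3")
  expect_error(superpose(a[1:4, ], a), "atom counts")
  line <- cbind(1:5, 1:5, 1:5)
  expect_error(superpose(line, line), "degenerate")
})

test_that("Kabsch RMSD is minimal against the random-rotation oracle", {
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- make_coords(10)
      b <- make_coords(10)
      fit <- superpose(a, b)$rmsd
      bc <- sweep(b, 2, colMeans(b))
      ac <- sweep(a, 2, colMeans(a))
      oracle <- min(vapply(1:500, function(k)
        raw_rmsd(ac %*% random_rotation(), bc), numeric(1)))
      expect_lte(fit, oracle + 1e-12)
    }
  })
})

test_that("radius of gyration matches closed forms", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), ncol = 3)), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(radius_of_gyration(two), 1)
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(square), sqrt(2) / 2)
  expect_error(radius_of_gyration(matrix(numeric(), ncol = 3)), "empty")
})

test_that("RMSD series is zero for rigid motion and matches brute force", {
  base <- make_coords(8, seed = 4)
  static <- trajectory_replicate(
    array(rep(base, each = 5), c(5, 8, 3)), (0:4) * 100, 1:8)
  expect_equal(rmsd_series(static)$value, rep(0, 5), tolerance = 1e-10)
  # rigidly rotated frames
  withr::with_seed(5, {
    rot <- array(NA_real_, c(5, 8, 3))
    for (f in 1:5) rot[f, , ] <- base %*% random_rotation()
  })
  rot_rep <- trajectory_replicate(rot, (0:4) * 100, 1:8)
  expect_lt(max(rmsd_series(rot_rep)$value), 1e-8)
  # noisy 5-frame toy vs per-frame Kabsch
  noisy <- trajectory_replicate(
    array(rnorm(5 * 8 * 3, sd = 1) + rep(base, each = 5), c(5, 8, 3)),
    (0:4) * 100, 1:8)
  vals <- rmsd_series(noisy, reference = base)$value
  brute <- vapply(1:5, function(f)
    superpose(noisy$coords[f, , ], base)$rmsd, numeric(1))
  expect_equal(vals, brute, tolerance = 1e-10)
})

test_that("RMSF closed forms: static, single-atom oscillation, Gaussian", {
  base <- make_coords(10, seed = 6)
  static <- trajectory_replicate(
    array(rep(base, each = 6), c(6, 10, 3)), (0:5) * 100, 1:10)
  expect_equal(rmsf_profile(static)$rmsf, rep(0, 10), tolerance = 1e-10)
  # one atom alternating +/- eps along x, no fitting
  eps <- 0.25
  osc <- array(rep(base, each = 6), c(6, 10, 3))
  osc[, 4, 1] <- osc[, 4, 1] + eps * c(1, -1, 1, -1, 1, -1)
  osc_rep <- trajectory_replicate(osc, (0:5) * 100, 1:10)
  prof <- rmsf_profile(osc_rep, fit = FALSE)
  expect_equal(prof$rmsf[4], eps)
  expect_equal(prof$rmsf[-4], rep(0, 9), tolerance = 1e-12)
  expect_error(rmsf_profile(trajectory_replicate(
    array(base, c(1, 10, 3)), 0, 1:10)), "2 frames")
})

test_that("Rg, RMSD and RMSF are invariant to rigid motion of frames", {
  spec <- trajectory_spec(n_residues = 12, duration_ns = 3,
                          frame_interval_ps = 100, n_replicates = 1,
                          systems = "wt", sigma = 0.4, seed = 7)
  rep_ <- generate_trajectories(spec)$systems$wt$replicates[[1]]
  moved <- rep_
  withr::with_seed(8, {
    R <- random_rotation()
    tr <- rnorm(3, sd = 10)
  })
  for (f in seq_len(dim(moved$coords)[1]))
    moved$coords[f, , ] <- moved$coords[f, , ] %*% R +
      matrix(tr, 12, 3, byrow = TRUE)
  expect_equal(rg_series(moved)$value, rg_series(rep_)$value,
               tolerance = 1e-8)
  ref <- rep_$coords[1, , ]
  expect_equal(rmsd_series(moved, ref)$value, rmsd_series(rep_, ref)$value,
               tolerance = 1e-8)
  expect_equal(rmsf_profile(moved)$rmsf, rmsf_profile(rep_)$rmsf,
               tolerance = 1e-8)
})

test_that("mean squared displacement equals mean squared RMSF", {
  spec <- trajectory_spec(n_residues = 9, duration_ns = 5,
                          frame_interval_ps = 100, n_replicates = 1,
                          systems = "wt", sigma = 0.6, seed = 9)
  rep_ <- generate_trajectories(spec)$systems$wt$replicates[[1]]
  sup <- superpose_replicate(rep_, rep_$coords[1, , ])$replicate
  fl <- vgbarrel:::flatten_frames(sup$coords)
  mu <- colMeans(fl)
  msd <- mean(rowSums(sweep(fl, 2, mu)^2)) / 9
  prof <- rmsf_profile(rep_)
  expect_equal(msd, mean(prof$rmsf^2), tolerance = 1e-10)
})

test_that("burn-in trimming follows the frame arithmetic", {
  spec <- trajectory_spec(n_residues = 4, duration_ns = 3000,
                          frame_interval_ps = 100, n_replicates = 1,
                          systems = "wt", sigma = 0.1, seed = 10)
  rep_ <- generate_trajectories(spec)$systems$wt$replicates[[1]]
  expect_equal(dim(rep_$coords)[1], 30000)
  trimmed <- trim_equilibration(rep_, burn_in = 400)
  expect_equal(dim(trimmed$coords)[1], 26000)
  expect_equal(min(trimmed$times), 400 * 1000)
  expect_error(trim_equilibration(rep_, burn_in = 3000), "shorter")
  expect_error(trim_equilibration(rep_, burn_in = 5000), "shorter")
})

test_that("auto burn-in is near zero without drift, positive with drift", {
  spec <- trajectory_spec(n_residues = 20, duration_ns = 100,
                          frame_interval_ps = 100, n_replicates = 1,
                          systems = "wt", sigma = 0.3, seed = 11)
  rep_ <- generate_trajectories(spec)$systems$wt$replicates[[1]]
  trimmed <- trim_equilibration(rep_, burn_in = "auto")
  expect_lt(attr(trimmed, "burn_in_ns"), 2)
  # conformational relaxation: half the atoms carry a decaying offset
  # (a rigid whole-frame drift would be removed by the superposition)
  repd <- generate_trajectories(
    trajectory_spec(n_residues = 20, duration_ns = 100,
                    frame_interval_ps = 100, n_replicates = 1,
                    systems = "wt", sigma = 0.3,
                    seed = 12))$systems$wt$replicates[[1]]
  decay <- 12 * pmax(0, 1 - repd$times / (40 * 1000))
  repd$coords[, 1:10, 1] <- repd$coords[, 1:10, 1] + decay
  trimd <- trim_equilibration(repd, burn_in = "auto")
  expect_gt(attr(trimd, "burn_in_ns"), 5)
})

test_that("sem_of_max_dif matches hand computation", {
  # identical series -> 0
  expect_equal(sem_of_max_dif(list(a = 1:4, b = 1:4))$value, 0)
  res <- sem_of_max_dif(list(wt = c(1, 2, 5), del = c(1, 2, 3)))
  expect_equal(res$index, 3)
  expect_equal(res$value, 1) # SEM of {5, 3} = sqrt(2)/sqrt(2)
  expect_equal(res$spread, 2)
  four <- sem_of_max_dif(list(a = 1:3, b = 1:3, c = 1:3, d = 1:3))
  expect_equal(four$value, 0)
  expect_error(sem_of_max_dif(list(a = 1:3, b = 1:4)), "axis mismatch")
  # axis labelling
  expect_equal(sem_of_max_dif(list(a = c(0, 1), b = c(0, 3)),
                              axis = c(10, 20))$location, 20)
})
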