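test_that("sliding windows respect contiguity in residue-ID space", {
  w5 <- sliding_windows(1:5)
  expect_equal(nrow(w5), 3) # 5 - 3 + 1
  expect_equal(w5$label, c("1-3", "2-4", "3-5"))
  # renumbered gap: only the contiguous 156-158 run supports a window
  wgap <- sliding_windows(c(151L, 152L, 156L, 157L, 158L))
  expect_equal(wgap$label, "156-158")
  expect_error(sliding_windows(c(1L, 3L, 5L)), "contiguous")
  # constant profile -> every window mean equals the constant
  wm <- window_means(matrix(2.5, nrow = 6, ncol = 4), 1:6)
  expect_true(all(wm == 2.5))
  expect_equal(dim(wm), c(4, 4))
})

test_that("pooled t test matches hand computation and conventions", {
  res <- two_sample_t(1:5, 2:6)
  expect_equal(res$statistic, -1)
  expect_equal(res$df, 8)
  expect_equal(res$p_value, 2 * pt(-1, 8))
  # cross-check against stats::t.test
  withr::with_seed(21, {
    a <- rnorm(5)
    b <- rnorm(5, 1)
  })
  ref <- t.test(a, b, var.equal = TRUE)
  mine <- two_sample_t(a, b)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # identical groups -> t 0, p 1
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # zero variance conventions
  expect_equal(two_sample_t(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(two_sample_t(c(1, 1), c(2, 2))$p_value, 0)
  # strong shift
  expect_lt(two_sample_t(1:3, 101:103)$p_value, 1e-6)
  expect_error(two_sample_t(1, 1:3), "at least 2")
})

test_that("BH step-up equals brute-force enumeration and p.adjust", {
  expect_equal(bh_adjust(numeric())$adjusted, numeric())
  res <- bh_adjust(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_equal(res$adjusted, c(0.03, 0.03, 0.04))
  expect_true(all(res$reject))
  expect_false(any(bh_adjust(c(0.5, 0.6))$reject))
  withr::with_seed(22, {
    for (m in 1:5) {
      for (rep in 1:20) {
        p <- round(runif(m), 3)
        mine <- bh_adjust(p)
        oracle <- bh_oracle(p)
        expect_equal(mine$adjusted, oracle$adjusted)
        expect_equal(mine$reject, oracle$reject)
        expect_equal(mine$adjusted, p.adjust(p, "BH"))
        expect_true(all(mine$adjusted >= p - 1e-12)) # fp slack at m/j ~ 1
      }
    }
  })
})

make_rmsf_list <- function(means, ids = 1:5, n_rep = 5, noise = 0.01,
                           seed = 30) {
  withr::with_seed(seed, {
    out <- lapply(means, function(mu)
      list(residue_ids = ids,
           rmsf = matrix(rep(mu, n_rep), ncol = n_rep) +
             matrix(rnorm(length(ids) * n_rep, sd = noise),
                    ncol = n_rep)))
    out
  })
}

test_that("compare_systems finds planted differences and intersections", {
  mu_flat <- rep(1, 5)
  mu_bump <- c(1, 1, 4, 4, 4) # window 3-5 differs by 3 (> 2.5)
  sys <- make_rmsf_list(list(wt = mu_flat, del = mu_bump, wtg = mu_flat,
                             delg = mu_bump))
  cmp <- compare_systems(sys)
  p35 <- cmp$peaks[cmp$peaks$window == "3-5", ]
  expect_true(all(p35$significant[p35$comparison %in%
                                    c("wt_vs_del", "wtg_vs_delg")]))
  expect_true(all(p35$above_resolution[p35$comparison %in%
                                         c("wt_vs_del", "wtg_vs_delg")]))
  expect_true("3-5" %in% cmp$consistent$window)
  expect_true(all(cmp$consistent$concordant))
  expect_equal(cmp$conclusion, "consistent_effect")
  expect_error(compare_systems(sys[c("wt", "del")]), "missing system")
})

test_that("the four-condition discordant scenario yields no consistent effect", {
  # planted: deletion raises the peak without glycan, lowers it with glycan,
  # both below the 2.5 A resolution (the Table-2-style qualitative setup)
  sys <- make_rmsf_list(list(wt = rep(0.59, 5), del = rep(0.67, 5),
                             wtg = rep(0.69, 5), delg = rep(0.56, 5)),
                        noise = 0.005, seed = 31)
  cmp <- compare_systems(sys)
  expect_gt(nrow(cmp$consistent), 0)
  expect_false(any(cmp$consistent$concordant))
  expect_false(any(cmp$consistent$above_resolution_both))
  expect_equal(cmp$conclusion, "no_consistent_effect")
  # consistency is an intersection and symmetric in comparison order
  cmp_swapped <- compare_systems(sys,
                                 comparisons = list(c("wtg", "delg"),
                                                    c("wt", "del"),
                                                    c("wt", "wtg"),
                                                    c("del", "delg")))
  expect_setequal(cmp_swapped$consistent$window, cmp$consistent$window)
})

test_that("windows and BH operate within each comparison", {
  sys <- make_rmsf_list(list(wt = rep(1, 7), del = rep(1, 7)),
                        ids = c(1:3, 10:13), seed = 32)
  cmp <- compare_systems(sys, comparisons = list(c("wt", "del")),
                         consistency_pair = c(1, 1))
  # runs 1-3 (1 window) and 10-13 (2 windows)
  expect_equal(cmp$peaks$window, c("1-3", "10-12", "11-13"))
})

test_that("null-world BH rejections are rare (scaled-down check)", {
  fracs <- vapply(1:5, function(s)
    null_fdr_fraction(s, n_residues = 52, n_frames = 100), numeric(1))
  expect_lt(mean(fracs), 0.05)
})

test_that("loop flexibility test behaves at the extremes", {
  ids <- 1:10
  flat <- make_rmsf_list(list(wt = rep(1, 10), del = rep(1, 10)), ids = ids,
                         noise = 0, seed = 33)
  res <- loop_flexibility_test(flat, loop_residues = 3:7,
                               pairs = list(c("wt", "del")))
  expect_equal(res$p, 1) # identical ensembles
  expect_error(loop_flexibility_test(flat, loop_residues = 99:100,
                                     pairs = list(c("wt", "del"))),
               "empty loop")
  # single-residue loop reduces to that residue's comparison
  one <- loop_flexibility_test(flat, loop_residues = 4,
                               pairs = list(c("wt", "del")))
  expect_equal(one$n_loop_residues, 1)
  # planted 3x sigma difference is detected across seeds
  hits <- vapply(1:10, function(s) {
    spec <- trajectory_spec(n_residues = 8, duration_ns = 40,
                            frame_interval_ps = 100, n_replicates = 5,
                            systems = c("wt", "del"),
                            sigma = list(wt = rep(0.5, 8),
                                         del = rep(1.5, 8)),
                            seed = 100 + s)
    rmsf <- system_rmsf(generate_trajectories(spec))
    loop_flexibility_test(rmsf, loop_residues = 2:7,
                          pairs = list(c("wt", "del")))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("secondary-structure occupancy counts label fractions", {
  allh <- list(matrix("H", nrow = 4, ncol = 3))
  occ <- ss_occupancy(allh)
  expect_equal(occ$helix, rep(1, 3))
  half <- list(rbind(matrix("H", 2, 3), matrix("C", 2, 3)))
  expect_equal(ss_occupancy(half)$helix, rep(0.5, 3))
  # richer alphabets map G/H/I -> H and E/B -> E
  rich <- list(matrix(c("G", "I", "B", "E", "T", "S"), nrow = 3, ncol = 2))
  occ_rich <- ss_occupancy(rich)
  expect_equal(occ_rich$helix, c(2 / 3, 0))
  expect_equal(occ_rich$strand, c(1 / 3, 1 / 3))
  expect_equal(occ_rich$helix + occ_rich$strand + occ_rich$other, c(1, 1))
  expect_error(ss_occupancy(list(matrix("H", 2, 3), matrix("H", 2, 4))),
               "mismatch")
})

test_that("planted occupancy differences are recovered", {
  wt <- ss_occupancy(generate_ss_labels(1500, 2, 4, helix_prob = 0.5,
                                        seed = 34))
  del <- ss_occupancy(generate_ss_labels(1500, 2, 4, helix_prob = 0.1,
                                         seed = 35))
  delta <- compare_occupancy(wt, del)
  expect_equal(delta$delta_helix, rep(0.4, 4), tolerance = 0.05)
})
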