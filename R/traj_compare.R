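#' Sliding windows over contiguous residue IDs
#'
#' Windows of `w` consecutive residue IDs with the given step, built only
#' inside runs of consecutive IDs: a window never straddles a gap in residue
#' numbering (e.g. the renumbered deleted-loop gap).
#'
#' @param ids sorted integer residue IDs.
#' @param w window size (default 3).
#' @param step start increment (default 1).
#' @return data.frame with `start_id`, `end_id`, `label` and an `idx` list
#'   column of positions into `ids`.
#' @export
sliding_windows <- function(ids, w = 3, step = 1) {
  stopifnot(!is.unsorted(ids))
  run <- cumsum(c(1L, as.integer(diff(ids) != 1L)))
  out <- list()
  for (r in unique(run)) {
    pos <- which(run == r)
    if (length(pos) < w) next
    starts <- seq(1L, length(pos) - w + 1L, by = step)
    for (s in starts) {
      idx <- pos[s:(s + w - 1L)]
      out[[length(out) + 1L]] <-
        list(start_id = ids[idx[1]], end_id = ids[idx[w]], idx = idx)
    }
  }
  if (!length(out))
    stop("no contiguous run of at least ", w, " residues")
  data.frame(start_id = vapply(out, `[[`, integer(1), "start_id"),
             end_id = vapply(out, `[[`, integer(1), "end_id"),
             label = vapply(out, function(o)
               sprintf("%d-%d", o$start_id, o$end_id), character(1)),
             idx = I(lapply(out, `[[`, "idx")))
}

#' Per-window per-replicate mean RMSF (Cα peaks)
#'
#' The Cα-peak value of a window is the arithmetic mean of its residues'
#' RMSF within one replicate.
#'
#' @param rmsf residues x replicates matrix of per-replicate RMSF.
#' @param ids residue IDs (rows of `rmsf`).
#' @inheritParams sliding_windows
#' @return windows x replicates matrix with window labels as rownames.
#' @export
window_means <- function(rmsf, ids, w = 3, step = 1) {
  rmsf <- as.matrix(rmsf)
  stopifnot(nrow(rmsf) == length(ids), ncol(rmsf) >= 1)
  wins <- sliding_windows(ids, w, step)
  out <- t(vapply(wins$idx, function(idx) colMeans(rmsf[idx, , drop = FALSE]),
                  numeric(ncol(rmsf))))
  out <- matrix(out, nrow = nrow(wins))
  rownames(out) <- wins$label
  out
}

#' Two-sample pooled-variance Student's t test
#'
#' Two-sided, with `nA + nB - 2` degrees of freedom. Degenerate conventions:
#' zero pooled variance with equal means gives `t = 0, p = 1`; zero pooled
#' variance with unequal means gives `p = 0`.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / df
  ma <- mean(a)
  mb <- mean(b)
  if (sp2 == 0) {
    if (ma == mb) return(list(statistic = 0, p_value = 1, df = df,
                              mean_a = ma, mean_b = mb))
    return(list(statistic = sign(ma - mb) * Inf, p_value = 0, df = df,
                mean_a = ma, mean_b = mb))
  }
  t <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  list(statistic = t, p_value = 2 * pt(-abs(t), df), df = df,
       mean_a = ma, mean_b = mb)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj_(i) = min_{j >= i} p_(j) * m / j`, capped at 1; hypotheses with
#' adjusted p at or below `alpha` are rejected.
#'
#' @param p raw p values in `[0,1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` (same order as `p`) and logical `reject`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (!m) return(list(adjusted = numeric(), reject = logical()))
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  adjusted <- numeric(m)
  adjusted[o] <- adj_sorted
  list(adjusted = adjusted, reject = adjusted <= alpha)
}

#' Four-condition sliding-window RMSF comparison
#'
#' For each requested pairwise comparison, per-window Cα-peak means of the
#' replicates are compared with a pooled-variance t test; BH adjustment is
#' applied within each comparison (the family is that comparison's windows).
#' Windows are built over the residue IDs shared by all compared systems.
#' The consistency filter intersects the significant windows of the
#' `consistency_pair` comparisons (by default wt vs del and wtg vs delg),
#' and the direction check compares `sign(mean_del - mean_wt)` against
#' `sign(mean_delg - mean_wtg)`. The analysis-level `conclusion` is
#' `"consistent_effect"` only when a consistent window is concordant and
#' above the resolution in both comparisons; `"no_consistent_effect"` when
#' consistent windows exist but fail those checks; `"no_effect"` otherwise.
#'
#' @param rmsf_by_system named list from [system_rmsf()].
#' @param comparisons list of label pairs (default the four condition
#'   comparisons wt/del, wtg/delg, wt/wtg, del/delg).
#' @param window,step Cα-peak window size and increment.
#' @param alpha significance level on BH-adjusted p (default 0.05).
#' @param resolution structural margin of error in Å (default 2.5, the
#'   starting-model resolution); windows are flagged `above_resolution` when
#'   `|Δ group mean| > resolution`.
#' @param consistency_pair indices into `comparisons` whose significant
#'   windows are intersected (default `c(1, 2)`).
#' @return object of class `peak_comparison`: `peaks` data.frame (one row
#'   per comparison x window), `consistent` data.frame with direction
#'   concordance, `conclusion`, `alpha`, `resolution`.
#' @export
compare_systems <- function(rmsf_by_system,
                            comparisons = list(c("wt", "del"),
                                               c("wtg", "delg"),
                                               c("wt", "wtg"),
                                               c("del", "delg")),
                            window = 3, step = 1, alpha = 0.05,
                            resolution = 2.5, consistency_pair = c(1, 2)) {
  labels <- unique(unlist(comparisons))
  missing <- setdiff(labels, names(rmsf_by_system))
  if (length(missing))
    stop("missing system label(s): ", paste(missing, collapse = ", "))
  shared <- sort(Reduce(intersect,
                        lapply(rmsf_by_system[labels], `[[`, "residue_ids")))
  wm <- lapply(rmsf_by_system[labels], function(sys) {
    rows <- match(shared, sys$residue_ids)
    window_means(sys$rmsf[rows, , drop = FALSE], shared, window, step)
  })
  wins <- sliding_windows(shared, window, step)

  peaks <- do.call(rbind, lapply(comparisons, function(cmp) {
    A <- wm[[cmp[1]]]
    B <- wm[[cmp[2]]]
    tt <- lapply(seq_len(nrow(wins)), function(i)
      two_sample_t(A[i, ], B[i, ]))
    p <- vapply(tt, `[[`, numeric(1), "p_value")
    bh <- bh_adjust(p, alpha)
    data.frame(
      comparison = paste(cmp, collapse = "_vs_"),
      window = wins$label, start_id = wins$start_id, end_id = wins$end_id,
      mean_a = vapply(tt, `[[`, numeric(1), "mean_a"),
      mean_b = vapply(tt, `[[`, numeric(1), "mean_b"),
      delta = vapply(tt, function(x) x$mean_b - x$mean_a, numeric(1)),
      statistic = vapply(tt, `[[`, numeric(1), "statistic"),
      p = p, p_adj = bh$adjusted, significant = bh$reject,
      above_resolution = abs(vapply(tt, function(x) x$mean_b - x$mean_a,
                                    numeric(1))) > resolution,
      stringsAsFactors = FALSE)
  }))
  rownames(peaks) <- NULL

  cmp1 <- paste(comparisons[[consistency_pair[1]]], collapse = "_vs_")
  cmp2 <- paste(comparisons[[consistency_pair[2]]], collapse = "_vs_")
  p1 <- peaks[peaks$comparison == cmp1 & peaks$significant, ]
  p2 <- peaks[peaks$comparison == cmp2 & peaks$significant, ]
  consistent_windows <- intersect(p1$window, p2$window)
  consistent <- do.call(rbind, lapply(consistent_windows, function(wn) {
    d1 <- p1$delta[p1$window == wn]
    d2 <- p2$delta[p2$window == wn]
    data.frame(window = wn, delta_1 = d1, delta_2 = d2,
               direction_1 = sign(d1), direction_2 = sign(d2),
               concordant = sign(d1) == sign(d2) & sign(d1) != 0,
               above_resolution_both =
                 abs(d1) > resolution & abs(d2) > resolution,
               stringsAsFactors = FALSE)
  }))
  if (is.null(consistent))
    consistent <- data.frame(window = character(), delta_1 = numeric(),
                             delta_2 = numeric(), direction_1 = numeric(),
                             direction_2 = numeric(), concordant = logical(),
                             above_resolution_both = logical(),
                             stringsAsFactors = FALSE)
  conclusion <- if (nrow(consistent) == 0) "no_effect"
  else if (any(consistent$concordant & consistent$above_resolution_both))
    "consistent_effect"
  else "no_consistent_effect"
  structure(list(peaks = peaks, consistent = consistent,
                 conclusion = conclusion, alpha = alpha,
                 resolution = resolution),
            class = "peak_comparison")
}

#' @export
print.peak_comparison <- function(x, ...) {
  cat("Calpha-peak comparison:",
      sum(x$peaks$significant), "significant window rows,",
      nrow(x$consistent), "consistent window(s); conclusion:",
      x$conclusion, "\n")
  invisible(x)
}

#' Deletion-loop flexibility test
#'
#' Per replicate, the mean RMSF over the loop residues (restricted to the
#' IDs each pair shares) is computed; systems are compared with the pooled
#' two-sample t test on those per-replicate means.
#'
#' @param rmsf_by_system named list from [system_rmsf()].
#' @param loop_residues residue IDs of the loop (default 141:167, the
#'   deletion loop).
#' @param pairs list of system-label pairs to test.
#' @return data.frame with one row per pair: means, `statistic`, `p`.
#' @export
loop_flexibility_test <- function(rmsf_by_system, loop_residues = 141:167,
                                  pairs = list(c("wt", "del"),
                                               c("wtg", "delg"))) {
  do.call(rbind, lapply(pairs, function(cmp) {
    shared <- intersect(
      intersect(rmsf_by_system[[cmp[1]]]$residue_ids,
                rmsf_by_system[[cmp[2]]]$residue_ids),
      loop_residues)
    if (!length(shared)) stop("empty loop intersection for ",
                              paste(cmp, collapse = " vs "))
    per_rep <- lapply(cmp, function(s) {
      sys <- rmsf_by_system[[s]]
      colMeans(sys$rmsf[match(shared, sys$residue_ids), , drop = FALSE])
    })
    tt <- two_sample_t(per_rep[[1]], per_rep[[2]])
    data.frame(pair = paste(cmp, collapse = "_vs_"),
               n_loop_residues = length(shared),
               mean_a = tt$mean_a, mean_b = tt$mean_b,
               statistic = tt$statistic, p = tt$p_value,
               stringsAsFactors = FALSE)
  }))
}

map_ss_labels <- function(m) {
  m[m %in% c("G", "H", "I")] <- "H"
  m[m %in% c("E", "B")] <- "E"
  m[!(m %in% c("H", "E"))] <- "C"
  m
}

#' Secondary-structure occupancy per residue
#'
#' Fraction of frames assigned helix (`H`, mapping `G/H/I`) and strand
#' (`E`, mapping `E/B`) per residue, averaged over replicates; everything
#' else counts as coil, so helix + strand + other sums to 1.
#'
#' @param labels list of per-replicate character matrices
#'   (frames x residues) of secondary-structure labels.
#' @param residue_ids residue IDs (default `1:ncol`).
#' @return object of class `ss_occupancy`: data.frame with `residue`,
#'   `helix`, `strand`, `other` and cross-replicate `helix_sd`, `strand_sd`.
#' @export
ss_occupancy <- function(labels, residue_ids = NULL) {
  stopifnot(is.list(labels), length(labels) >= 1)
  nres <- ncol(labels[[1]])
  for (m in labels) if (ncol(m) != nres) stop("residue count mismatch")
  residue_ids <- residue_ids %||% seq_len(nres)
  stopifnot(length(residue_ids) == nres)
  hmat <- vapply(labels, function(m) colMeans(map_ss_labels(m) == "H"),
                 numeric(nres))
  emat <- vapply(labels, function(m) colMeans(map_ss_labels(m) == "E"),
                 numeric(nres))
  hmat <- matrix(hmat, nrow = nres)
  emat <- matrix(emat, nrow = nres)
  out <- data.frame(residue = residue_ids,
                    helix = rowMeans(hmat), strand = rowMeans(emat),
                    other = 1 - rowMeans(hmat) - rowMeans(emat),
                    helix_sd = apply(hmat, 1, sd),
                    strand_sd = apply(emat, 1, sd))
  class(out) <- c("ss_occupancy", "data.frame")
  out
}

#' Per-residue occupancy difference between two systems
#'
#' @param a,b `ss_occupancy` objects.
#' @return data.frame on shared residues with `delta_helix` and
#'   `delta_strand` (`a - b`).
#' @export
compare_occupancy <- function(a, b) {
  shared <- intersect(a$residue, b$residue)
  ia <- match(shared, a$residue)
  ib <- match(shared, b$residue)
  data.frame(residue = shared,
             delta_helix = a$helix[ia] - b$helix[ib],
             delta_strand = a$strand[ia] - b$strand[ib])
}
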