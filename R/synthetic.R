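#' Specification for synthetic Cα trajectory ensembles
#'
#' Defines the stated world for the trajectory generator: per-system
#' per-residue fluctuation scales (the planted analogue of RMSF), replicate
#' and duration bookkeeping, and an optional decaying burn-in drift.
#'
#' @param n_residues number of residues (one Cα per residue).
#' @param duration_ns replicate length in ns.
#' @param frame_interval_ps saving interval in ps; `duration_ns * 1000 /
#'   frame_interval_ps` must be a positive integer (the frame count).
#' @param n_replicates replicates per system.
#' @param systems character vector of system labels (default the four
#'   conditions wt / del / wtg / delg).
#' @param sigma per-residue Gaussian fluctuation scale in Å: a single value,
#'   a length-`n_residues` vector, or a named list per system. Must be >= 0.
#' @param deleted_residues named list mapping system labels to residue IDs
#'   absent from that system (e.g. the deleted loop residues).
#' @param burn_in_drift optional `list(length_ns =, displacement =)`: frames
#'   inside the burn-in window carry an extra rigid displacement (in Å)
#'   decaying linearly to zero at the end of the window.
#' @param reference_coords optional `n_residues` x 3 matrix of reference
#'   coordinates (Å); default is a non-degenerate helical curve.
#' @param residue_start first residue ID (default 1; use 21 for the
#'   beta-barrel numbering).
#' @param seed integer seed for reproducibility.
#' @return object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(n_residues, duration_ns, frame_interval_ps,
                            n_replicates = 5,
                            systems = c("wt", "del", "wtg", "delg"),
                            sigma = 1, deleted_residues = list(),
                            burn_in_drift = NULL, reference_coords = NULL,
                            residue_start = 1L, seed = NULL) {
  fr <- duration_ns * 1000 / frame_interval_ps
  if (fr <= 0 || abs(fr - round(fr)) > 1e-9)
    stop("duration/frame_interval must give a positive integer frame count")
  if (!is.list(sigma)) sigma <- setNames(rep(list(sigma), length(systems)),
                                         systems)
  sigma <- lapply(sigma, function(s) {
    s <- rep_len(s, n_residues)
    if (any(s < 0)) stop("sigma must be >= 0")
    s
  })
  if (!all(names(deleted_residues) %in% systems))
    stop("deleted_residues names must be system labels")
  if (is.null(reference_coords)) reference_coords <- helix_coords(n_residues)
  stopifnot(nrow(reference_coords) == n_residues,
            ncol(reference_coords) == 3)
  if (!is.null(burn_in_drift))
    stopifnot(is.list(burn_in_drift),
              all(c("length_ns", "displacement") %in% names(burn_in_drift)))
  structure(
    list(n_residues = n_residues, duration_ns = duration_ns,
         frame_interval_ps = frame_interval_ps, n_frames = as.integer(fr),
         n_replicates = n_replicates, systems = systems, sigma = sigma,
         deleted_residues = deleted_residues, burn_in_drift = burn_in_drift,
         reference_coords = reference_coords,
         residue_start = as.integer(residue_start), seed = seed),
    class = "trajectory_spec")
}

# Non-degenerate helical reference curve (radius 5 A, 1.5 A rise/residue)
helix_coords <- function(n) {
  t <- seq_len(n)
  cbind(5 * cos(0.6 * t), 5 * sin(0.6 * t), 1.5 * t)
}

#' Generate a synthetic trajectory ensemble
#'
#' Each frame is the reference structure plus isotropic, frame-independent
#' Gaussian noise with per-coordinate standard deviation `sigma[i]` for
#' residue i (so the closed-form RMSF is `sigma * sqrt(3)`). Systems listed
#' in `deleted_residues` lack those residues. When `burn_in_drift` is set,
#' frames with `t < length_ns` carry an additional rigid displacement along a
#' seeded random unit direction, decaying linearly to zero. Frame times start
#' at 0 ps. Deterministic under `spec$seed`.
#'
#' @param spec a [trajectory_spec()].
#' @return object of class `traj_ensemble`: per system a list of replicates
#'   (`coords` frames x atoms x 3 array, `times` ps, `residue_ids`), the
#'   system reference coordinates, plus `frame_interval_ps` and the spec.
#' @export
generate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  F_ <- spec$n_frames
  times <- (seq_len(F_) - 1) * spec$frame_interval_ps
  all_ids <- spec$residue_start + seq_len(spec$n_residues) - 1L
  with_seed(spec$seed, {
    systems <- lapply(spec$systems, function(sys) {
      del <- spec$deleted_residues[[sys]] %||% integer()
      keep <- !(all_ids %in% del)
      ids <- all_ids[keep]
      k <- length(ids)
      ref <- spec$reference_coords[keep, , drop = FALSE]
      sig <- spec$sigma[[sys]][keep]
      reps <- lapply(seq_len(spec$n_replicates), function(r) {
        noise <- array(rnorm(F_ * k * 3), dim = c(F_, k, 3)) *
          rep(sig, each = F_)
        coords <- noise + rep(ref, each = F_)
        if (!is.null(spec$burn_in_drift)) {
          len_ps <- spec$burn_in_drift$length_ns * 1000
          dir <- rnorm(3)
          dir <- dir / sqrt(sum(dir^2))
          amp <- spec$burn_in_drift$displacement *
            pmax(0, 1 - times / len_ps)
          off <- outer(amp, dir) # F x 3
          coords <- coords + aperm(array(off, dim = c(F_, 3, k)), c(1, 3, 2))
        }
        trajectory_replicate(coords, times, ids)
      })
      list(replicates = reps, residue_ids = ids, reference = ref)
    })
    names(systems) <- spec$systems
    structure(list(systems = systems,
                   frame_interval_ps = spec$frame_interval_ps, spec = spec),
              class = "traj_ensemble")
  })
}

#' Construct a single trajectory replicate
#'
#' @param coords frames x atoms x 3 numeric array (Å).
#' @param times frame times in ps, strictly increasing and evenly spaced.
#' @param residue_ids 1-based residue IDs, one per atom.
#' @return object of class `traj_replicate`.
#' @export
trajectory_replicate <- function(coords, times, residue_ids) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] == length(times),
            dim(coords)[2] == length(residue_ids))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6)
      stop("times must be strictly increasing and evenly spaced")
  }
  structure(list(coords = coords, times = times,
                 residue_ids = as.integer(residue_ids)),
            class = "traj_replicate")
}

#' @export
print.traj_replicate <- function(x, ...) {
  cat("Trajectory replicate:", dim(x$coords)[1], "frames,",
      dim(x$coords)[2], "Calpha atoms\n")
  invisible(x)
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat("Trajectory ensemble:", length(x$systems), "system(s)\n")
  for (s in names(x$systems)) {
    sys <- x$systems[[s]]
    cat(sprintf("  %s: %d replicate(s), %d residues\n", s,
                length(sys$replicates), length(sys$residue_ids)))
  }
  invisible(x)
}

#' Residue IDs shared by every system of an ensemble
#' @param ensemble a `traj_ensemble`.
#' @return sorted integer vector of shared residue IDs.
#' @export
shared_residue_ids <- function(ensemble) {
  sort(Reduce(intersect, lapply(ensemble$systems, `[[`, "residue_ids")))
}

#' Specification for synthetic diploid allele sets
#'
#' @param populations data.frame with columns `label`, `n_individuals`,
#'   `frequency` (planted deletion allele frequency in `[0,1]`), optionally
#'   `subspecies`.
#' @param deletion `c(aa_start, aa_end)`: complete codons removed from
#'   carrier haplotypes (1-based inclusive protein coordinates).
#' @param reference_cds optional reference CDS; default a seeded random
#'   stop-free CDS of `n_codons` codons whose context at the deletion
#'   boundary forbids any 3' shift of the planted call.
#' @param n_codons codon count of the default random reference.
#' @param seed integer seed.
#' @return object of class `allele_sim_spec`.
#' @export
allele_sim_spec <- function(populations, deletion, reference_cds = NULL,
                            n_codons = 200, seed = NULL) {
  stopifnot(all(c("label", "n_individuals", "frequency") %in%
                  names(populations)))
  if (any(populations$frequency < 0 | populations$frequency > 1))
    stop("frequency must be in [0, 1]")
  stopifnot(length(deletion) == 2, deletion[1] <= deletion[2])
  structure(list(populations = populations,
                 deletion = as.integer(deletion),
                 reference_cds = reference_cds, n_codons = n_codons,
                 seed = seed),
            class = "allele_sim_spec")
}

# random CDS without stop codons; boundary context prevents 3' shifting of a
# deletion of codons aa_start..aa_end
random_cds <- function(n_codons, aa_start, aa_end) {
  codons <- apply(matrix(sample(c("A", "C", "G", "T"), n_codons * 3,
                                replace = TRUE), ncol = 3), 1, paste,
                  collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  while (any(codons %in% stops))
    codons[codons %in% stops] <- apply(
      matrix(sample(c("A", "C", "G", "T"), sum(codons %in% stops) * 3,
                    replace = TRUE), ncol = 3), 1, paste, collapse = "")
  cds <- paste(codons, collapse = "")
  s <- 3L * (aa_start - 1L) + 1L
  e <- 3L * aa_end
  if (e + 1L <= nchar(cds) && substr(cds, s, s) == substr(cds, e + 1, e + 1)) {
    # re-draw the first base after the deletion so the planted placement is
    # already the 3'-most one (exact round-trip recovery)
    alt <- setdiff(c("A", "C", "G", "T"), substr(cds, s, s))
    repeat {
      b <- sample(alt, 1)
      cand <- cds
      substr(cand, e + 1, e + 1) <- b
      cod_start <- e + 1L - (e %% 3L) # e is a codon boundary, so e + 1
      cod <- substr(cand, cod_start, cod_start + 2L)
      if (!cod %in% stops) {
        cds <- cand
        break
      }
    }
  }
  cds
}

#' Generate a synthetic allele set with a planted deletion
#'
#' Per population, exactly `round(2 * n_individuals * frequency)` haplotypes
#' carry the planted whole-codon deletion; which haplotype slots carry it is
#' a seeded shuffle, so recovered frequencies are exact and homozygotes arise
#' when both slots of one individual are selected. Ground truth (per
#' population carrier and homozygote counts, deletion coordinates) is
#' attached as attribute `"truth"`.
#'
#' @param spec an [allele_sim_spec()].
#' @return an [allele_set()].
#' @export
generate_alleles <- function(spec) {
  stopifnot(inherits(spec, "allele_sim_spec"))
  with_seed(spec$seed, {
    aa_s <- spec$deletion[1]
    aa_e <- spec$deletion[2]
    ref <- spec$reference_cds %||% random_cds(spec$n_codons, aa_s, aa_e)
    ref <- toupper(ref)
    if (nchar(ref) %% 3 != 0) stop("reference CDS not divisible by 3")
    if (3 * aa_e > nchar(ref)) stop("deletion outside the reference")
    nt_s <- 3L * (aa_s - 1L) + 1L
    nt_e <- 3L * aa_e
    del_seq <- paste0(substr(ref, 1, nt_s - 1),
                      substr(ref, nt_e + 1, nchar(ref)))
    rows <- list()
    truth <- list()
    for (i in seq_len(nrow(spec$populations))) {
      p <- spec$populations[i, ]
      n <- p$n_individuals
      k <- round(2 * n * p$frequency)
      slots <- sample(2L * n) # shuffled haplotype slots
      carrier <- logical(2L * n)
      carrier[slots[seq_len(k)]] <- TRUE
      ind <- rep(seq_len(n), each = 2)
      hom <- sum(tapply(carrier, ind, all))
      truth[[i]] <- data.frame(label = p$label, carriers = k,
                               total = 2L * n, homozygotes = hom,
                               frequency = if (n > 0) k / (2 * n) else NA,
                               stringsAsFactors = FALSE)
      rows[[i]] <- data.frame(
        individual_id = sprintf("%s_I%03d", p$label, ind),
        haplotype_index = rep(1:2, times = n),
        population_id = p$label,
        subspecies = if ("subspecies" %in% names(p)) p$subspecies
                     else paste0("ssp_", p$label),
        recombinant = FALSE,
        sequence = ifelse(carrier, del_seq, ref),
        stringsAsFactors = FALSE)
    }
    aset <- allele_set(ref, do.call(rbind, rows))
    attr(aset, "truth") <- list(
      deletion_aa = c(aa_s, aa_e), nt_start = nt_s, nt_end = nt_e,
      nt_length = nt_e - nt_s + 1L,
      per_population = do.call(rbind, truth))
    aset
  })
}

#' Specification for synthetic multiple sequence alignments
#'
#' @param n_sequences number of rows.
#' @param length number of columns.
#' @param conservation_profile per-column target score in `[0,1]`: 1 gives a
#'   single-residue gap-free column, 0 draws uniformly over the 20 residues,
#'   intermediate values mix a consensus residue with uniform noise
#'   monotonically in the target.
#' @param gap_rate per-cell gap probability (suppressed in target-1 columns).
#' @param seed integer seed.
#' @return object of class `msa_sim_spec`.
#' @export
msa_sim_spec <- function(n_sequences, length, conservation_profile,
                         gap_rate = 0, seed = NULL) {
  conservation_profile <- rep_len(conservation_profile, length)
  if (any(conservation_profile < 0 | conservation_profile > 1))
    stop("conservation_profile values must be in [0, 1]")
  stopifnot(gap_rate >= 0, gap_rate < 1)
  structure(list(n_sequences = n_sequences, length = length,
                 conservation_profile = conservation_profile,
                 gap_rate = gap_rate, seed = seed),
            class = "msa_sim_spec")
}

#' Generate a synthetic MSA with planted per-column conservation
#'
#' Row 1 is the gap-free consensus sequence (a natural reference row).
#' Target column scores are attached as attribute `"truth"`.
#'
#' @param spec an [msa_sim_spec()].
#' @return an [msa()].
#' @export
generate_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_sim_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    n <- spec$n_sequences
    consensus <- sample(AA20, L, replace = TRUE)
    mat <- matrix("", nrow = n, ncol = L)
    mat[1, ] <- consensus
    for (c in seq_len(L)) {
      tgt <- spec$conservation_profile[c]
      take_cons <- runif(n - 1) < tgt
      col <- ifelse(take_cons, consensus[c],
                    sample(AA20, n - 1, replace = TRUE))
      if (tgt >= 1) col <- rep(consensus[c], n - 1)
      if (spec$gap_rate > 0 && tgt < 1) {
        gap <- runif(n - 1) < spec$gap_rate
        col[gap] <- "-"
      }
      mat[-1, c] <- col
    }
    out <- msa(ids = c("reference", sprintf("seq%04d", seq_len(n - 1))),
               seqs = apply(mat, 1, paste, collapse = ""))
    attr(out, "truth") <- spec$conservation_profile
    out
  })
}

#' Generate synthetic per-frame secondary-structure label matrices
#'
#' Independent per-frame draws with planted per-residue helix and strand
#' occupancies; everything else is coil.
#'
#' @param n_frames frames per replicate.
#' @param n_replicates number of replicates.
#' @param helix_prob per-residue helix probability (recycled).
#' @param strand_prob per-residue strand probability (recycled).
#' @param n_residues number of residues.
#' @param seed integer seed.
#' @return list of `n_replicates` character matrices (frames x residues) over
#'   the alphabet `H`/`E`/`C`.
#' @export
generate_ss_labels <- function(n_frames, n_replicates, n_residues,
                               helix_prob = 0, strand_prob = 0, seed = NULL) {
  h <- rep_len(helix_prob, n_residues)
  s <- rep_len(strand_prob, n_residues)
  if (any(h + s > 1)) stop("helix_prob + strand_prob must be <= 1")
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      u <- matrix(runif(n_frames * n_residues), nrow = n_frames)
      lab <- matrix("C", nrow = n_frames, ncol = n_residues)
      lab[u < rep(h, each = n_frames)] <- "H"
      lab[u >= rep(h, each = n_frames) &
            u < rep(h + s, each = n_frames)] <- "E"
      lab
    })
  })
}
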