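#' Pipeline configuration
#'
#' Collects every tunable threshold with its study default: significance
#' level 0.05 on BH-adjusted p, structural resolution margin 2.5 Å, Cα-peak
#' window 3 / step 1, burn-in 400 ns, conservation threshold 0.70, DOPS
#' diversity cut 0.80, identity clustering 0.70, length filter 0.2, scan
#' window 3, per-residue impact flag -0.3.
#'
#' @param traj_spec a [trajectory_spec()] (synthetic trajectory stage).
#' @param allele_spec an [allele_sim_spec()] (synthetic allele stage).
#' @param msa_spec an [msa_sim_spec()] (synthetic MSA stage).
#' @param scan_sequence domain sequence for the deletion scan (default: the
#'   translated synthetic reference CDS without its terminal residue when it
#'   is a stop).
#' @param stages stage names to run, in pipeline order.
#' @param alpha,resolution,window,step,burn_in_ns thresholds (see
#'   description).
#' @param conservation_tau,dops_cut,identity_threshold thresholds (see
#'   description).
#' @param length_max_rel_diff,scan_window,scan_step,delta_flag thresholds
#'   (see description).
#' @param loop_residues deletion-loop residue IDs for the loop test.
#' @param seed master seed; stage seeds are derived deterministically.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(traj_spec = NULL, allele_spec = NULL,
                            msa_spec = NULL, scan_sequence = NULL,
                            stages = c("variants", "conservation",
                                       "traj_core", "traj_compare",
                                       "traj_pca", "indel_scan"),
                            alpha = 0.05, resolution = 2.5, window = 3,
                            step = 1, burn_in_ns = 400,
                            conservation_tau = 0.70, dops_cut = 0.80,
                            identity_threshold = 0.70,
                            length_max_rel_diff = 0.2, scan_window = 3,
                            scan_step = 1, delta_flag = -0.3,
                            loop_residues = 141:167, seed = 1L) {
  cfg <- structure(
    list(traj_spec = traj_spec, allele_spec = allele_spec,
         msa_spec = msa_spec, scan_sequence = scan_sequence,
         stages = stages, alpha = alpha, resolution = resolution,
         window = window, step = step, burn_in_ns = burn_in_ns,
         conservation_tau = conservation_tau, dops_cut = dops_cut,
         identity_threshold = identity_threshold,
         length_max_rel_diff = length_max_rel_diff,
         scan_window = scan_window, scan_step = scan_step,
         delta_flag = delta_flag, loop_residues = loop_residues,
         seed = as.integer(seed)),
    class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos <- c("alpha", "resolution", "window", "step", "conservation_tau",
           "identity_threshold", "scan_window", "scan_step")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be positive")
  if (cfg$alpha > 1 || cfg$conservation_tau > 1 ||
      cfg$identity_threshold > 1)
    stop("alpha, conservation_tau and identity_threshold must be <= 1")
  if (cfg$burn_in_ns < 0 || cfg$length_max_rel_diff < 0)
    stop("burn_in_ns and length_max_rel_diff must be >= 0")
  invisible(cfg)
}

#' Scaled-down synthetic demonstration configuration
#'
#' A complete stated world small enough to run end-to-end in seconds: four
#' systems x 2 replicates of 30 ns at 100 ps (300 frames; burn-in scaled to
#' 5 ns accordingly), a 60-residue domain with a planted 3-residue deletion
#' at residues 33-35, three populations with planted allele frequencies
#' 0.5 / 0.1 / 0, and a 40-column MSA with a planted conservation gradient.
#'
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  n_res <- 60L
  del <- 33:35
  pipeline_config(
    traj_spec = trajectory_spec(
      n_residues = n_res, duration_ns = 30, frame_interval_ps = 100,
      n_replicates = 2, sigma = 0.8,
      deleted_residues = list(del = del, delg = del),
      burn_in_drift = list(length_ns = 5, displacement = 3),
      seed = seed + 11L),
    allele_spec = allele_sim_spec(
      populations = data.frame(label = c("popA", "popB", "popC"),
                               n_individuals = c(16L, 10L, 10L),
                               frequency = c(0.5, 0.1, 0)),
      deletion = c(33L, 35L), n_codons = n_res, seed = seed + 23L),
    msa_spec = msa_sim_spec(
      n_sequences = 60, length = 40,
      conservation_profile = seq(0, 1, length.out = 40),
      gap_rate = 0.05, seed = seed + 37L),
    burn_in_ns = 5, loop_residues = 30:40, seed = seed)
}

#' Total simulated time bookkeeping
#'
#' @param spec a [trajectory_spec()].
#' @return list with `n_systems`, `n_replicates`, `replicate_us`,
#'   `per_system_us` and `total_us` (microseconds of simulated time).
#' @export
simulated_time_summary <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  rep_us <- spec$duration_ns / 1000
  list(n_systems = length(spec$systems),
       n_replicates = spec$n_replicates,
       replicate_us = rep_us,
       per_system_us = rep_us * spec$n_replicates,
       total_us = rep_us * spec$n_replicates * length(spec$systems))
}

#' Build the run manifest
#'
#' Records everything needed to reproduce a run: package and R versions,
#' the master seed, a hash of the canonicalized configuration, and the
#' simulated-time bookkeeping of the trajectory stage. No timestamps are
#' included so reruns are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return named list.
#' @export
build_manifest <- function(config) {
  cfg_json <- jsonlite::serializeJSON(unclass(config))
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  list(package = "vgbarrel",
       package_version =
         as.character(utils::packageVersion("vgbarrel")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       seed = config$seed,
       config_md5 = hash,
       simulated_time_us = if (!is.null(config$traj_spec))
         simulated_time_summary(config$traj_spec) else NULL,
       n_frames_per_replicate = if (!is.null(config$traj_spec))
         config$traj_spec$n_frames else NULL)
}

#' Run the end-to-end synthetic pipeline
#'
#' Executes the requested stages in order (variants, conservation,
#' traj_core, traj_compare, traj_pca, indel_scan) on the synthetic inputs
#' described by the configuration, writing TSV/JSON outputs and a run
#' manifest to `out_dir`. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()

  if ("variants" %in% config$stages) {
    if (is.null(config$allele_spec)) stop("variants stage needs allele_spec")
    aset <- generate_alleles(config$allele_spec)
    calls <- call_indels_set(aset)
    freq <- allele_frequency(calls, aset$haplotypes)
    write_tsv(calls, file.path(out_dir, "indel_calls.tsv"))
    write_tsv(freq$per_population,
              file.path(out_dir, "allele_frequency_per_population.tsv"))
    write_tsv(freq$per_indel, file.path(out_dir, "indel_summary.tsv"))
    results$variants <- list(allele_set = aset, calls = calls,
                             frequency = freq)
  }

  if ("conservation" %in% config$stages) {
    if (is.null(config$msa_spec)) stop("conservation stage needs msa_spec")
    aln <- generate_msa(config$msa_spec)
    prof <- conservation_profile(aln, tau = config$conservation_tau)
    d <- dops(prof)
    write_tsv(prof$table, file.path(out_dir, "conservation_profile.tsv"))
    jsonlite::write_json(
      list(dops = d, high_diversity = d > config$dops_cut,
           tau = config$conservation_tau,
           n_conserved = sum(prof$table$conserved)),
      file.path(out_dir, "conservation_summary.json"), auto_unbox = TRUE,
      digits = NA)
    results$conservation <- list(msa = aln, profile = prof, dops = d)
  }

  traj_stages <- intersect(c("traj_core", "traj_compare", "traj_pca"),
                           config$stages)
  if (length(traj_stages)) {
    if (is.null(config$traj_spec))
      stop("trajectory stages need traj_spec")
    ens <- generate_trajectories(config$traj_spec)
    ens <- trim_ensemble(ens, burn_in = config$burn_in_ns)
    rmsf <- system_rmsf(ens)
    results$trajectories <- ens

    if ("traj_core" %in% config$stages) {
      shared <- shared_residue_ids(ens)
      rg_mean <- lapply(ens$systems, function(sys)
        mean(vapply(sys$replicates, function(r) mean(rg_series(r)$value),
                    numeric(1))))
      rmsd_stats <- lapply(ens$systems, function(sys) {
        vals <- vapply(sys$replicates,
                       function(r) mean(rmsd_series(r)$value), numeric(1))
        list(mean = mean(vals), sem = sd(vals) / sqrt(length(vals)))
      })
      rmsf_mean_series <- lapply(rmsf, function(sys)
        rowMeans(sys$rmsf[match(shared, sys$residue_ids), , drop = FALSE]))
      smd <- sem_of_max_dif(rmsf_mean_series, axis = shared)
      per_res <- do.call(rbind, lapply(names(rmsf), function(s) {
        agg <- data.frame(system = s, residue = rmsf[[s]]$residue_ids,
                          mean = rowMeans(rmsf[[s]]$rmsf),
                          sd = apply(rmsf[[s]]$rmsf, 1, sd))
        agg$sem <- agg$sd / sqrt(ncol(rmsf[[s]]$rmsf))
        agg
      }))
      write_tsv(per_res, file.path(out_dir, "rmsf_per_residue.tsv"))
      jsonlite::write_json(
        list(rg_mean = rg_mean, rmsd = rmsd_stats,
             rmsf_sem_of_max_dif = smd),
        file.path(out_dir, "trajectory_summary.json"), auto_unbox = TRUE,
        digits = NA)
      results$traj_core <- list(rg_mean = rg_mean, rmsd = rmsd_stats,
                                sem_of_max_dif = smd)
    }

    if ("traj_compare" %in% config$stages) {
      cmp <- compare_systems(rmsf, window = config$window,
                             step = config$step, alpha = config$alpha,
                             resolution = config$resolution)
      loop <- loop_flexibility_test(rmsf,
                                    loop_residues = config$loop_residues)
      write_tsv(cmp$peaks, file.path(out_dir, "peak_table.tsv"))
      write_tsv(loop, file.path(out_dir, "loop_flexibility.tsv"))
      jsonlite::write_json(
        list(conclusion = cmp$conclusion,
             n_consistent = nrow(cmp$consistent)),
        file.path(out_dir, "comparison_summary.json"), auto_unbox = TRUE,
        digits = NA)
      results$traj_compare <- cmp
      results$loop_test <- loop
    }

    if ("traj_pca" %in% config$stages) {
      pca <- pooled_pca(ens)
      ext <- extreme_frames(pca)
      flags <- flag_outlier_replicates(pca)
      write_tsv(pca$projections, file.path(out_dir, "pca_projections.tsv"))
      write_tsv(ext, file.path(out_dir, "pca_extreme_frames.tsv"))
      write_tsv(flags, file.path(out_dir, "pca_outlier_flags.tsv"))
      jsonlite::write_json(list(explained_variance = pca$ratios),
                           file.path(out_dir, "pca_variance.json"),
                           digits = NA)
      results$traj_pca <- list(pca = pca, extremes = ext, flags = flags)
    }
  }

  if ("indel_scan" %in% config$stages) {
    seq_ <- config$scan_sequence
    if (is.null(seq_)) {
      if (!is.null(results$variants)) {
        seq_ <- sub("\\*$", "", results$variants$allele_set$reference_protein)
      } else stop("indel_scan stage needs scan_sequence or variants stage")
    }
    scan <- run_scan(seq_, hydrophobicity_scorer(), w = config$scan_window,
                     step = config$scan_step)
    write_tsv(scan$variants[, c("pos_start", "pos_end", "hgvs", "score",
                                "rank")],
              file.path(out_dir, "deletion_scan.tsv"))
    jsonlite::write_json(
      list(mean_score = scan$mean_score, wt_score = scan$wt_score,
           n_variants = nrow(scan$variants)),
      file.path(out_dir, "scan_summary.json"), auto_unbox = TRUE,
      digits = NA)
    results$indel_scan <- scan
  }

  manifest <- build_manifest(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
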