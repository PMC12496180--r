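#' Read sequences from FASTA
#'
#' @param path file path.
#' @param type `"DNA"` or `"AA"`.
#' @return named character vector.
#' @export
read_fasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::readDNAStringSet(path)
  else Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write haplotypes of an allele set to FASTA
#'
#' Headers are `individual|haplotype|population|subspecies`.
#'
#' @param aset an [allele_set()].
#' @param path file path.
#' @export
write_haplotype_fasta <- function(aset, path) {
  stopifnot(inherits(aset, "allele_set"))
  h <- aset$haplotypes
  write_fasta(setNames(h$sequence,
                       paste(h$individual_id, h$haplotype_index,
                             h$population_id, h$subspecies, sep = "|")),
              path)
}

#' Read haplotypes written by [write_haplotype_fasta()]
#'
#' @param path FASTA path.
#' @param reference_cds the reference coding sequence.
#' @param recombinant optional logical vector (default all `FALSE`).
#' @return an [allele_set()].
#' @export
read_haplotype_fasta <- function(path, reference_cds, recombinant = NULL) {
  seqs <- read_fasta(path, "DNA")
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(parts) != 4))
    stop("headers must be individual|haplotype|population|subspecies")
  allele_set(reference_cds, data.frame(
    individual_id = vapply(parts, `[[`, "", 1),
    haplotype_index = as.integer(vapply(parts, `[[`, "", 2)),
    population_id = vapply(parts, `[[`, "", 3),
    subspecies = vapply(parts, `[[`, "", 4),
    recombinant = recombinant %||% FALSE,
    sequence = unname(seqs), stringsAsFactors = FALSE))
}

#' Read a sample sheet
#'
#' Tab-separated, columns `individual_id`, `haplotype_index`,
#' `population_id`, `subspecies`, `recombinant`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "haplotype_index", "population_id",
            "subspecies", "recombinant")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  df$recombinant <- as.logical(df$recombinant)
  df
}

#' Write an MSA to aligned FASTA
#'
#' @param x an [msa()].
#' @param path file path.
#' @export
write_msa_fasta <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  write_fasta(setNames(x$seqs, x$ids), path)
}

#' Read an aligned FASTA into an MSA
#'
#' @param path file path.
#' @return an [msa()].
#' @export
read_msa_fasta <- function(path) {
  seqs <- read_fasta(path, "AA")
  msa(names(seqs), unname(seqs))
}

#' Write a Cα replicate as a multi-model PDB
#'
#' One MODEL per frame, CA atoms only, residue IDs preserved. PDB stores no
#' times; supply the frame interval when reading back.
#'
#' @param replicate a `traj_replicate`.
#' @param path file path.
#' @param chain chain identifier.
#' @export
write_trajectory_pdb <- function(replicate, path, chain = "A") {
  stopifnot(inherits(replicate, "traj_replicate"))
  con <- file(path, "w")
  on.exit(close(con))
  ids <- replicate$residue_ids
  F_ <- dim(replicate$coords)[1]
  for (f in seq_len(F_)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- replicate$coords[f, , , drop = TRUE]
    xyz <- matrix(xyz, ncol = 3)
    writeLines(sprintf(
      "ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_along(ids), chain, ids, xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a multi-model Cα PDB into a replicate
#'
#' Only `CA` atoms are kept; skipped atoms are reported with a message.
#' Every model must contain the same residues in the same order.
#'
#' @param path PDB path.
#' @param frame_interval_ps time between frames (ps); frame f gets time
#'   `(f - 1) * frame_interval_ps`.
#' @return a `traj_replicate`.
#' @export
read_trajectory_pdb <- function(path, frame_interval_ps = 100) {
  lines <- readLines(path)
  atom <- startsWith(lines, "ATOM")
  if (!any(atom)) stop("no ATOM records")
  is_ca <- atom & substr(lines, 13, 16) == " CA "
  n_skipped <- sum(atom) - sum(is_ca)
  if (n_skipped > 0) message("skipped ", n_skipped, " non-CA atom records")
  model_idx <- cumsum(startsWith(lines, "MODEL"))
  if (max(model_idx) == 0) model_idx <- rep(1L, length(lines))
  frames <- split(which(is_ca), model_idx[is_ca])
  ids_ref <- NULL
  coords <- NULL
  for (f in seq_along(frames)) {
    ln <- lines[frames[[f]]]
    ids <- as.integer(substr(ln, 23, 26))
    if (is.null(ids_ref)) {
      ids_ref <- ids
      coords <- array(NA_real_, dim = c(length(frames), length(ids), 3))
    } else if (!identical(ids, ids_ref)) {
      bad <- c(setdiff(ids_ref, ids), setdiff(ids, ids_ref))
      stop("model ", f, " residue mismatch vs model 1 (residue ",
           paste(unique(bad), collapse = ", "), ")")
    }
    coords[f, , 1] <- as.numeric(substr(ln, 31, 38))
    coords[f, , 2] <- as.numeric(substr(ln, 39, 46))
    coords[f, , 3] <- as.numeric(substr(ln, 47, 54))
  }
  trajectory_replicate(coords,
                       (seq_along(frames) - 1) * frame_interval_ps,
                       ids_ref)
}

#' Write a replicate to the plain-text coordinate container
#'
#' Format (one item per line): a magic line, `natoms`, space-separated
#' `residues`, `frame_interval_ps`, space-separated `times` (ps), then one
#' line per frame holding 3n full-precision floats in atom blocks
#' (x_1..x_n y_1..y_n z_1..z_n), units Å. Round-trips bit-exactly.
#'
#' @param replicate a `traj_replicate`.
#' @param path file path.
#' @export
write_coord_container <- function(replicate, path) {
  stopifnot(inherits(replicate, "traj_replicate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#vgbarrel-traj v1",
               paste("natoms", dim(replicate$coords)[2]),
               paste("residues",
                     paste(replicate$residue_ids, collapse = " ")),
               paste("times",
                     paste(sprintf("%.17g", replicate$times),
                           collapse = " "))), con)
  fl <- flatten_frames(replicate$coords)
  writeLines(apply(fl, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read a replicate from the plain-text coordinate container
#'
#' @param path file path.
#' @return a `traj_replicate`.
#' @export
read_coord_container <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#vgbarrel-traj"))
    stop("unreadable header: not a coordinate container")
  get_field <- function(name, i) {
    if (!startsWith(lines[i], paste0(name, " ")))
      stop("unreadable header: expected '", name, "' on line ", i)
    strsplit(sub(paste0("^", name, " "), "", lines[i]), " ")[[1]]
  }
  n <- as.integer(get_field("natoms", 2))
  ids <- as.integer(get_field("residues", 3))
  times <- as.numeric(get_field("times", 4))
  body <- lines[-(1:4)]
  body <- body[nzchar(body)]
  fl <- do.call(rbind, lapply(strsplit(body, " "), as.numeric))
  if (ncol(fl) != 3 * n) stop("frame width inconsistent with natoms")
  trajectory_replicate(unflatten_frames(fl, n), times, ids)
}

#' Write secondary-structure labels as plain text
#'
#' One line per frame, one character per residue.
#'
#' @param labels character matrix (frames x residues).
#' @param path file path.
#' @export
write_ss_labels <- function(labels, path) {
  writeLines(apply(labels, 1, paste, collapse = ""), path)
  invisible(path)
}

#' Read secondary-structure labels written by [write_ss_labels()]
#'
#' @param path file path.
#' @return character matrix (frames x residues).
#' @export
read_ss_labels <- function(path) {
  lines <- readLines(path)
  do.call(rbind, strsplit(lines, ""))
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
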