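#' Construct an allele set
#'
#' Container for a reference coding sequence and a table of haplotype coding
#' sequences with population metadata. Each diploid individual contributes at
#' most two haplotypes. Coordinates throughout are 1-based inclusive.
#'
#' @param reference_cds reference coding nucleotide sequence; length must be
#'   divisible by 3.
#' @param haplotypes data.frame with columns `individual_id`,
#'   `haplotype_index` (1 or 2), `population_id`, `subspecies`,
#'   `recombinant` (logical) and `sequence`.
#' @param aligned optional data.frame of pre-aligned rows (`reference`,
#'   `haplotype`) parallel to `haplotypes`; all rows must share one column
#'   count.
#' @return object of class `allele_set`.
#' @export
allele_set <- function(reference_cds, haplotypes, aligned = NULL) {
  reference_cds <- toupper(reference_cds)
  if (nchar(reference_cds) %% 3 != 0)
    stop("reference CDS length must be divisible by 3")
  need <- c("individual_id", "haplotype_index", "population_id",
            "subspecies", "recombinant", "sequence")
  miss <- setdiff(need, names(haplotypes))
  if (length(miss)) stop("missing haplotype columns: ",
                         paste(miss, collapse = ", "))
  tab <- table(haplotypes$individual_id)
  if (any(tab > 2)) stop("an individual has more than 2 haplotypes")
  if (!is.null(aligned)) {
    nc <- unique(nchar(aligned$reference))
    if (length(nc) != 1L || !all(nchar(aligned$haplotype) == nc))
      stop("aligned rows must share one column count")
  }
  structure(
    list(reference_cds = reference_cds,
         reference_protein = translate_cds(reference_cds),
         haplotypes = haplotypes, aligned = aligned),
    class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat("Allele set:", nrow(x$haplotypes), "haplotypes,",
      length(unique(x$haplotypes$population_id)), "populations, CDS",
      nchar(x$reference_cds), "nt /", nchar(x$reference_protein), "aa\n")
  invisible(x)
}

#' Translate a coding sequence
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return amino-acid string (stop codons as `*`).
#' @export
translate_cds <- function(cds) {
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(cds)),
                                     if.fuzzy.codon = "X"))
}

#' Call insertions and deletions from an aligned pair
#'
#' Maximal runs of gap columns in the haplotype row become deletion calls;
#' runs in the reference row become insertion calls. Ambiguously placed calls
#' inside sequence repeats are normalized to the 3'-most equivalent placement
#' (HGVS convention). The amino-acid span of a deletion covers every codon
#' overlapping the deleted nucleotide span. HGVS-style names are
#' `p.<aa><start>del` / `p.<aa><start>_<aa><end>del` for in-frame deletions
#' (when a reference protein is available), otherwise nucleotide-level
#' `c.<start>_<end>del` / `c.<pos>_<pos+1>ins<SEQ>`.
#'
#' @param aligned a `pairwise_alignment` (from [align_to_reference()]) or a
#'   list with equal-length `reference` and `haplotype` aligned strings.
#' @param reference_protein optional amino-acid string; derived by
#'   translation of the ungapped reference row when absent and in frame.
#' @param normalize normalize ambiguous placements to the 3'-most position.
#' @return data.frame with one row per call: `kind`, `nt_start`, `nt_end`,
#'   `nt_length`, `in_frame`, `aa_start`, `aa_end`, `aa_letters`, `hgvs`.
#'   Zero rows for a gapless alignment.
#' @export
call_indels <- function(aligned, reference_protein = NULL, normalize = TRUE) {
  ra <- strsplit(aligned$reference, "")[[1]]
  ha <- strsplit(aligned$haplotype, "")[[1]]
  if (length(ra) != length(ha))
    stop("reference and haplotype rows differ in column count")
  refseq <- paste(ra[ra != "-"], collapse = "")
  nref <- nchar(refseq)
  if (is.null(reference_protein) && nref %% 3 == 0)
    reference_protein <- translate_cds(refseq)
  # reference position of each alignment column (position consumed, 0 before)
  refpos <- cumsum(ra != "-")

  empty <- data.frame(kind = character(), nt_start = integer(),
                      nt_end = integer(), nt_length = integer(),
                      in_frame = logical(), aa_start = integer(),
                      aa_end = integer(), aa_letters = character(),
                      hgvs = character(), stringsAsFactors = FALSE)
  out <- empty

  rchar <- function(i) substr(refseq, i, i)
  pchar <- function(i) substr(reference_protein, i, i)

  runs <- rle(ha == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    cols <- starts[k]:ends[k]
    s <- refpos[cols[1]]
    e <- refpos[cols[length(cols)]]
    len <- e - s + 1L
    if (normalize) {
      while (e + 1L <= nref && rchar(s) == rchar(e + 1L)) {
        s <- s + 1L
        e <- e + 1L
      }
    }
    aa_s <- as.integer(ceiling(s / 3))
    aa_e <- as.integer(ceiling(e / 3))
    in_frame <- len %% 3 == 0
    letters <- if (!is.null(reference_protein))
      substr(reference_protein, aa_s, aa_e) else NA_character_
    hgvs <- if (in_frame && !is.null(reference_protein)) {
      if (aa_s == aa_e) sprintf("p.%s%ddel", pchar(aa_s), aa_s)
      else sprintf("p.%s%d_%s%ddel", pchar(aa_s), aa_s, pchar(aa_e), aa_e)
    } else if (s == e) sprintf("c.%ddel", s) else sprintf("c.%d_%ddel", s, e)
    out <- rbind(out, data.frame(
      kind = "deletion", nt_start = s, nt_end = e, nt_length = len,
      in_frame = in_frame, aa_start = aa_s, aa_end = aa_e,
      aa_letters = letters, hgvs = hgvs, stringsAsFactors = FALSE))
  }

  runs <- rle(ra == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in which(runs$values)) {
    cols <- starts[k]:ends[k]
    ins <- paste(ha[cols], collapse = "")
    p <- if (cols[1] == 1L) 0L else refpos[cols[1] - 1L]
    if (normalize) {
      while (p + 1L <= nref && substr(ins, 1, 1) == rchar(p + 1L)) {
        ins <- paste0(substr(ins, 2, nchar(ins)), substr(ins, 1, 1))
        p <- p + 1L
      }
    }
    len <- nchar(ins)
    out <- rbind(out, data.frame(
      kind = "insertion", nt_start = p, nt_end = p + 1L, nt_length = len,
      in_frame = len %% 3 == 0, aa_start = NA_integer_, aa_end = NA_integer_,
      aa_letters = NA_character_,
      hgvs = sprintf("c.%d_%dins%s", p, p + 1L, ins),
      stringsAsFactors = FALSE))
  }
  out[order(out$nt_start), , drop = FALSE]
}

#' Call indels for every haplotype of an allele set
#'
#' Aligns each haplotype to the reference (or uses pre-aligned rows when
#' present) and calls indels, attaching the haplotype metadata to every call.
#'
#' @param aset an [allele_set()].
#' @param ... passed to [align_to_reference()].
#' @return data.frame of calls with `individual_id`, `haplotype_index`,
#'   `population_id`, `subspecies`, `recombinant` columns prepended.
#' @export
call_indels_set <- function(aset, ...) {
  stopifnot(inherits(aset, "allele_set"))
  hap <- aset$haplotypes
  res <- vector("list", nrow(hap))
  for (i in seq_len(nrow(hap))) {
    aln <- if (!is.null(aset$aligned))
      list(reference = aset$aligned$reference[i],
           haplotype = aset$aligned$haplotype[i])
    else align_to_reference(aset$reference_cds, hap$sequence[i], ...)
    calls <- call_indels(aln, reference_protein = aset$reference_protein)
    if (nrow(calls)) {
      meta <- hap[rep(i, nrow(calls)),
                  c("individual_id", "haplotype_index", "population_id",
                    "subspecies", "recombinant"), drop = FALSE]
      rownames(meta) <- NULL
      res[[i]] <- cbind(meta, calls)
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(individual_id = character(), haplotype_index = integer(),
                      population_id = character(), subspecies = character(),
                      recombinant = logical(), kind = character(),
                      nt_start = integer(), nt_end = integer(),
                      nt_length = integer(), in_frame = logical(),
                      aa_start = integer(), aa_end = integer(),
                      aa_letters = character(), hgvs = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Allele frequencies and homozygote counts per indel
#'
#' Summarizes per-haplotype indel calls into per-population allele
#' frequencies (carrier haplotypes / observed haplotypes) and per-indel
#' homozygote counts (individuals whose two haplotypes both carry the call).
#' Tallies are emitted both including and excluding haplotypes flagged as
#' recombinant.
#'
#' @param calls data.frame from [call_indels_set()] (needs `individual_id`,
#'   `haplotype_index`, `hgvs`).
#' @param haplotypes the haplotype metadata table (one row per observed
#'   haplotype, with `individual_id`, `haplotype_index`, `population_id`,
#'   `recombinant`).
#' @return object of class `frequency_table`: list with `per_population` and
#'   `per_indel` data.frames.
#' @export
allele_frequency <- function(calls, haplotypes) {
  hap_key <- paste(haplotypes$individual_id, haplotypes$haplotype_index)
  if (nrow(calls)) {
    call_key <- paste(calls$individual_id, calls$haplotype_index)
    unknown <- setdiff(call_key, hap_key)
    if (length(unknown))
      stop("calls reference haplotypes absent from the sample table: ",
           paste(unique(unknown), collapse = "; "))
    calls$population_id <-
      haplotypes$population_id[match(call_key, hap_key)]
    calls$recombinant <- haplotypes$recombinant[match(call_key, hap_key)]
  }
  pops <- sort(unique(haplotypes$population_id))
  variants <- sort(unique(calls$hgvs))

  per_pop <- do.call(rbind, lapply(variants, function(v) {
    do.call(rbind, lapply(pops, function(p) {
      in_pop <- haplotypes$population_id == p
      total <- sum(in_pop)
      total_nr <- sum(in_pop & !haplotypes$recombinant)
      cc <- calls[calls$hgvs == v & calls$population_id == p, , drop = FALSE]
      carriers <- nrow(cc)
      carriers_nr <- sum(!cc$recombinant)
      data.frame(population_id = p, hgvs = v, carriers = carriers,
                 total = total, frequency = carriers / total,
                 carriers_norecomb = carriers_nr, total_norecomb = total_nr,
                 frequency_norecomb =
                   if (total_nr > 0) carriers_nr / total_nr else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(per_pop))
    per_pop <- data.frame(population_id = character(), hgvs = character(),
                          carriers = integer(), total = integer(),
                          frequency = numeric(),
                          carriers_norecomb = integer(),
                          total_norecomb = integer(),
                          frequency_norecomb = numeric(),
                          stringsAsFactors = FALSE)

  per_indel <- do.call(rbind, lapply(variants, function(v) {
    cc <- calls[calls$hgvs == v, , drop = FALSE]
    n_hap <- tapply(cc$haplotype_index, cc$individual_id,
                    function(h) length(unique(h)))
    hom <- sum(n_hap >= 2)
    cc_nr <- cc[!cc$recombinant, , drop = FALSE]
    n_hap_nr <- tapply(cc_nr$haplotype_index, cc_nr$individual_id,
                       function(h) length(unique(h)))
    data.frame(hgvs = v, carriers = nrow(cc), homozygotes = hom,
               carriers_norecomb = nrow(cc_nr),
               homozygotes_norecomb = sum(n_hap_nr >= 2),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_indel))
    per_indel <- data.frame(hgvs = character(), carriers = integer(),
                            homozygotes = integer(),
                            carriers_norecomb = integer(),
                            homozygotes_norecomb = integer(),
                            stringsAsFactors = FALSE)
  structure(list(per_population = per_pop, per_indel = per_indel),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat("Allele frequency table:", nrow(x$per_indel), "indel(s) across",
      length(unique(x$per_population$population_id)), "population(s)\n")
  print(x$per_indel)
  invisible(x)
}
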