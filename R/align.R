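#' Global affine-gap pairwise alignment
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap costs and
#' deterministic tie-breaking (diagonal, then gap in `b`, then gap in `a`).
#' A gap of length L costs `gap_open + (L - 1) * gap_extend`.
#'
#' @param a,b character scalars, the two sequences.
#' @param match,mismatch,gap_open,gap_extend alignment scores (gap scores are
#'   negative).
#' @param ambiguous characters that never count as a match (scored as
#'   mismatch even against themselves), e.g. `"N"` for nucleotides.
#' @return list with aligned strings `a` and `b` (gaps as `-`), `score`,
#'   `matches` and `columns`.
#' @export
align_global <- function(a, b, match = 2, mismatch = -3,
                         gap_open = -11, gap_extend = -1, ambiguous = "") {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  gotoh_align_cpp(a, b, match, mismatch, gap_open, gap_extend,
                  paste(ambiguous, collapse = ""))
}

#' Align a haplotype coding sequence to the reference
#'
#' Global alignment of one haplotype against the reference CDS with scoring
#' chosen so that a clean multi-nucleotide deletion aligns as one contiguous
#' gap rather than split gaps (defaults: match +2, mismatch -3, gap open -11,
#' gap extend -1). `N` is accepted but never counted as a match.
#'
#' @param reference,haplotype nucleotide strings over `A/C/G/T/N`.
#' @inheritParams align_global
#' @return object of class `pairwise_alignment`: aligned `reference` and
#'   `haplotype` rows, `score`, and `identity` (matches / alignment columns).
#' @export
align_to_reference <- function(reference, haplotype, match = 2, mismatch = -3,
                               gap_open = -11, gap_extend = -1) {
  reference <- toupper(reference)
  haplotype <- toupper(haplotype)
  for (s in list(reference, haplotype)) {
    if (!nzchar(s)) stop("empty sequence")
    bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T", "N"))
    if (length(bad))
      stop("non-nucleotide symbols: ", paste(bad, collapse = ", "))
  }
  aln <- align_global(reference, haplotype, match, mismatch, gap_open,
                      gap_extend, ambiguous = "N")
  structure(
    list(reference = aln$a, haplotype = aln$b, score = aln$score,
         identity = aln$matches / aln$columns),
    class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise global alignment: score", x$score,
      sprintf("identity %.3f\n", x$identity))
  invisible(x)
}

# Fractional identity of two unaligned protein sequences under global
# alignment (matches / alignment columns). Used by identity clustering.
protein_identity <- function(a, b, match = 2, mismatch = -1,
                             gap_open = -10, gap_extend = -1) {
  aln <- align_global(toupper(a), toupper(b), match, mismatch,
                      gap_open, gap_extend, ambiguous = "X")
  aln$matches / aln$columns
}
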