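#' Construct a multiple sequence alignment object
#'
#' @param ids sequence identifiers.
#' @param seqs aligned amino-acid strings (gaps as `-`), equal lengths.
#' @return object of class `msa`.
#' @export
msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs), length(seqs) >= 1)
  nc <- unique(nchar(seqs))
  if (length(nc) != 1) stop("aligned rows must have equal length")
  structure(list(ids = as.character(ids), seqs = toupper(seqs),
                 ncol = nc), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("MSA:", length(x$seqs), "sequences x", x$ncol, "columns\n")
  invisible(x)
}

msa_matrix <- function(x) {
  do.call(rbind, strsplit(x$seqs, ""))
}

#' Length filter for homolog candidates
#'
#' Keeps candidates whose length differs from the query length by at most
#' `max_rel_diff` (relative to the query): `|len(s) - q| / q <= max_rel_diff`.
#'
#' @param query_length query sequence length (> 0).
#' @param candidates character vector of (unaligned) sequences.
#' @param max_rel_diff maximum relative length difference (default 0.2).
#' @return the retained subset of `candidates`.
#' @export
length_filter <- function(query_length, candidates, max_rel_diff = 0.2) {
  stopifnot(query_length > 0)
  keep <- abs(nchar(candidates) - query_length) / query_length <= max_rel_diff
  candidates[keep]
}

#' Greedy identity clustering of unaligned sequences
#'
#' Sequences are processed longest-first (stable on ties); a sequence joins
#' the first cluster whose representative has global-alignment identity
#' (matches / alignment columns) at or above `threshold`, otherwise it founds
#' a new cluster. The representative is the founding (longest) member.
#' Deterministic for a given input set.
#'
#' @param sequences named character vector of amino-acid sequences.
#' @param threshold identity threshold in `[0,1]` (default 0.70).
#' @param ... alignment parameters passed through to the protein aligner.
#' @return object of class `identity_clusters`: list of clusters, each with
#'   `representative` (name) and `members` (names).
#' @export
cluster_by_identity <- function(sequences, threshold = 0.70, ...) {
  if (!length(sequences)) stop("empty input")
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  ord <- order(-nchar(sequences))
  clusters <- list()
  for (i in ord) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      rep_seq <- sequences[[clusters[[k]]$representative]]
      if (protein_identity(rep_seq, sequences[[i]], ...) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members,
                                   names(sequences)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <-
        list(representative = names(sequences)[i],
             members = names(sequences)[i])
  }
  structure(clusters, class = "identity_clusters")
}

#' @export
print.identity_clusters <- function(x, ...) {
  cat("Identity clusters:", length(x), "cluster(s),",
      sum(vapply(x, function(c) length(c$members), integer(1))),
      "sequence(s)\n")
  invisible(x)
}

#' Position-based (Henikoff) sequence weights
#'
#' Per column, each sequence receives `1 / (r * s)` where `r` is the number
#' of distinct symbols in the column (gaps count as a symbol type) and `s`
#' the count of the sequence's own symbol; the per-sequence sums are
#' normalized so the weights sum to the number of sequences. A single
#' sequence gets weight 1.
#'
#' @param x an [msa()].
#' @return numeric weight vector, one per sequence, summing to `n`.
#' @export
sequence_weights <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- msa_matrix(x)
  n <- nrow(m)
  if (n == 1) return(1)
  raw <- numeric(n)
  for (c in seq_len(ncol(m))) {
    col <- m[, c]
    counts <- table(col)
    r <- length(counts)
    raw <- raw + 1 / (r * as.numeric(counts[col]))
  }
  n * raw / sum(raw)
}

#' Per-residue conservation profile of an MSA
#'
#' For each reference (non-gap) column, the score is
#' `(1 - H / ln 20) * (1 - g)` where `H` is the weighted Shannon entropy over
#' the 20 standard residues (gaps and non-standard symbols excluded from the
#' entropy) and `g` the weighted gap fraction of the column. A single-residue
#' gap-free column scores 1; an equal-frequency column over all 20 residues
#' scores 0; an all-gap column scores 0 by convention. Positions with score
#' at or above `tau` are flagged conserved.
#'
#' @param x an [msa()].
#' @param reference index of the reference row (default 1); scores are
#'   reported for its non-gap columns only.
#' @param tau conservation threshold (default 0.70).
#' @param weights optional per-sequence weights; default [sequence_weights()].
#' @param column_score optional plug-in: `function(counts, gap_fraction)`
#'   returning a score in `[0,1]`, where `counts` is a named vector of
#'   weighted residue frequencies (summing to 1 over standard residues).
#' @return object of class `conservation_profile`: data.frame `table` with
#'   `position` (1-based in reference coordinates), `column`, `score`,
#'   `gap_fraction` and `conserved`, plus `tau`.
#' @export
conservation_profile <- function(x, reference = 1, tau = 0.70,
                                 weights = NULL, column_score = NULL) {
  stopifnot(inherits(x, "msa"))
  m <- msa_matrix(x)
  w <- weights %||% sequence_weights(x)
  stopifnot(length(w) == nrow(m), all(w > 0))
  ref_cols <- which(m[reference, ] != "-")
  if (!length(ref_cols)) stop("reference row is all gaps")
  score <- gapf <- numeric(length(ref_cols))
  for (i in seq_along(ref_cols)) {
    col <- m[, ref_cols[i]]
    std <- col %in% AA20
    g <- sum(w[!std]) / sum(w)
    gapf[i] <- g
    if (!any(std)) {
      score[i] <- 0
      next
    }
    p <- tapply(w[std], factor(col[std], levels = AA20), sum)
    p <- p[!is.na(p) & p > 0] / sum(w[std])
    if (!is.null(column_score)) {
      score[i] <- column_score(p, g)
    } else {
      H <- -sum(p * log(p))
      score[i] <- (1 - H / log(20)) * (1 - g)
    }
  }
  structure(
    list(table = data.frame(position = seq_along(ref_cols),
                            column = ref_cols, score = score,
                            gap_fraction = gapf, conserved = score >= tau),
         tau = tau),
    class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile:", nrow(x$table), "positions,",
      sum(x$table$conserved), "conserved at tau =", x$tau,
      sprintf("; DOPS %.3f\n", dops(x)))
  invisible(x)
}

#' Diversity of positions score (DOPS)
#'
#' Fraction of distinct column scores (after rounding to 3 decimals) among
#' the scored columns; lies in `(0, 1]`. Values above 0.80 indicate a highly
#' diverse alignment in which conservation calls are robust.
#'
#' @param profile a [conservation_profile()].
#' @param digits rounding applied before counting distinct values.
#' @return scalar DOPS.
#' @export
dops <- function(profile, digits = 3) {
  s <- profile$table$score
  if (!length(s)) stop("no scored columns")
  length(unique(round(s, digits))) / length(s)
}
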