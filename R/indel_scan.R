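#' Enumerate sliding-window deletion variants
#'
#' All deletions of `w` consecutive residues across a domain sequence, start
#' positions `1 .. L - w + 1` with the given step: `floor((L - w)/step) + 1`
#' variants in deterministic order.
#'
#' @param sequence amino-acid string of length L >= w.
#' @param w deletion window size (default 3).
#' @param step start increment (default 1).
#' @param numbering_from domain numbering of the first residue (default 1;
#'   use 21 for the beta-barrel).
#' @param allow_empty permit `w == L` (an empty mutated sequence).
#' @return data.frame with `start`, `end` (sequence indices), `pos_start`,
#'   `pos_end` (domain numbering), `hgvs` and `mutated`.
#' @export
enumerate_deletions <- function(sequence, w = 3, step = 1,
                                numbering_from = 1, allow_empty = FALSE) {
  L <- nchar(sequence)
  if (w > L) stop("window larger than the sequence")
  if (w == L && !allow_empty)
    stop("w == L gives an empty mutated sequence; set allow_empty = TRUE")
  starts <- seq(1L, L - w + 1L, by = step)
  aa <- strsplit(sequence, "")[[1]]
  ends <- starts + w - 1L
  pos_s <- starts + numbering_from - 1L
  pos_e <- ends + numbering_from - 1L
  hgvs <- if (w == 1) sprintf("p.%s%ddel", aa[starts], pos_s)
  else sprintf("p.%s%d_%s%ddel", aa[starts], pos_s, aa[ends], pos_e)
  mutated <- vapply(starts, function(s)
    paste0(substr(sequence, 1, s - 1), substr(sequence, s + w, L)),
    character(1))
  data.frame(start = starts, end = ends, pos_start = pos_s,
             pos_end = pos_e, hgvs = hgvs, mutated = mutated,
             stringsAsFactors = FALSE)
}

#' Exhaustive in-silico deletion scan with a pluggable scorer
#'
#' Scores the wild-type domain and every `w`-residue deletion variant with a
#' scorer obeying the contract: `scorer(sequence)` returns
#' `list(score = <scalar>, per_residue = <numeric of length nchar(sequence)>)`,
#' deterministic for a fixed input, lower scalar = more damaging. Per-residue
#' values of each variant are mapped back to wild-type residue positions
#' (positions after the deleted window shift back by `w`; deleted positions
#' are absent), enabling difference maps `mutated - wt` on shared positions.
#' Variants are ranked by descending scalar score; ties break by start
#' position.
#'
#' @inheritParams enumerate_deletions
#' @param scorer the scoring function (see contract above); e.g.
#'   [hydrophobicity_scorer()].
#' @return object of class `scan_result`: `variants` data.frame (with
#'   `score` and `rank`), `wt_score`, `wt_per_residue`, `per_residue`
#'   (variants x L matrix in wild-type coordinates, `NA` at deleted
#'   positions), `mean_score`, `w`, `numbering_from`.
#' @export
run_scan <- function(sequence, scorer, w = 3, step = 1, numbering_from = 1) {
  L <- nchar(sequence)
  check_scored <- function(res, len, what) {
    if (!is.list(res) || !all(c("score", "per_residue") %in% names(res)))
      stop("scorer must return list(score, per_residue)")
    if (length(res$per_residue) != len)
      stop("scorer per-residue length mismatch for ", what)
    if (!is.finite(res$score) || any(!is.finite(res$per_residue)))
      stop("scorer returned non-finite values for ", what)
    res
  }
  wt <- check_scored(scorer(sequence), L, "wild type")
  variants <- enumerate_deletions(sequence, w, step, numbering_from)
  nv <- nrow(variants)
  per_res <- matrix(NA_real_, nrow = nv, ncol = L)
  scores <- numeric(nv)
  for (v in seq_len(nv)) {
    res <- check_scored(scorer(variants$mutated[v]), L - w,
                        variants$hgvs[v])
    scores[v] <- res$score
    s <- variants$start[v]
    if (s > 1) per_res[v, 1:(s - 1)] <- res$per_residue[1:(s - 1)]
    if (s + w <= L) per_res[v, (s + w):L] <- res$per_residue[s:(L - w)]
  }
  variants$score <- scores
  variants$rank <- rank_by_score(scores, variants$start)
  structure(
    list(variants = variants, wt_score = wt$score,
         wt_per_residue = wt$per_residue, per_residue = per_res,
         mean_score = mean(scores), w = w, numbering_from = numbering_from),
    class = "scan_result")
}

# rank 1 = highest score; ties broken by start position
rank_by_score <- function(scores, starts) {
  ord <- order(-scores, starts)
  r <- integer(length(scores))
  r[ord] <- seq_along(scores)
  r
}

#' @export
print.scan_result <- function(x, ...) {
  cat("Deletion scan:", nrow(x$variants), "variants (w =", x$w,
      sprintf("), wt score %.3f, mean variant score %.3f\n",
              x$wt_score, x$mean_score))
  invisible(x)
}

find_variant <- function(result, query) {
  v <- result$variants
  i <- if (is.character(query)) which(v$hgvs == query)
  else if (length(query) == 2) which(v$pos_start == query[1] &
                                       v$pos_end == query[2])
  else as.integer(query)
  if (length(i) != 1 || is.na(i) || i < 1 || i > nrow(v))
    stop("query variant not found in the scan")
  i
}

#' Difference map of a scanned variant
#'
#' `delta_j = mutated_j - wt_j` on the wild-type residue positions shared by
#' the variant (`NA` at the deleted window).
#'
#' @param result a [run_scan()] result.
#' @param variant hgvs string, `c(pos_start, pos_end)`, or variant index.
#' @return named numeric vector over domain positions.
#' @export
delta_map <- function(result, variant) {
  i <- find_variant(result, variant)
  d <- result$per_residue[i, ] - result$wt_per_residue
  names(d) <- seq_along(d) + result$numbering_from - 1L
  d
}

#' Classify a query deletion within the scan distribution
#'
#' Rules: `above_mean` labels the query "benign-leaning" when its score is at
#' or above the mean variant score (ties count as benign-leaning, the
#' constant-scorer convention); `top_k` when its rank is within `k`;
#' `fixed_threshold` when its score is at or above `tau`.
#'
#' @param result a [run_scan()] result.
#' @param query hgvs string, `c(pos_start, pos_end)`, or index.
#' @param rule classification rule.
#' @param k rank cutoff for `top_k` (default 50).
#' @param tau score cutoff for `fixed_threshold`.
#' @return list with `label` ("benign-leaning" / "damaging-leaning"),
#'   `score`, `mean_score`, `rank`, `n_variants`, `rule`.
#' @export
classify <- function(result, query,
                     rule = c("above_mean", "top_k", "fixed_threshold"),
                     k = 50, tau = NULL) {
  rule <- match.arg(rule)
  i <- find_variant(result, query)
  v <- result$variants[i, ]
  benign <- switch(rule,
                   above_mean = v$score >= result$mean_score,
                   top_k = v$rank <= k,
                   fixed_threshold = {
                     if (is.null(tau)) stop("fixed_threshold needs tau")
                     v$score >= tau
                   })
  list(label = if (benign) "benign-leaning" else "damaging-leaning",
       score = v$score, mean_score = result$mean_score, rank = v$rank,
       n_variants = nrow(result$variants), rule = rule)
}

#' Per-residue impact of a scanned variant
#'
#' Positions whose difference-map value falls below `tau_neg` are flagged
#' "negatively affected".
#'
#' @inheritParams delta_map
#' @param tau_neg flag threshold (default -0.3).
#' @return list with `delta` (the difference map), `flagged_positions`
#'   (domain numbering) and `n_flagged`.
#' @export
per_residue_impact <- function(result, variant, tau_neg = -0.3) {
  d <- delta_map(result, variant)
  flagged <- as.integer(names(d)[!is.na(d) & d < tau_neg])
  list(delta = d, flagged_positions = flagged, n_flagged = length(flagged))
}

#' Reference additive hydrophobicity scorer
#'
#' A deterministic position-independent scorer satisfying the scan contract:
#' per-residue values are Kyte-Doolittle hydropathies and the scalar score is
#' their sum, so a variant's score equals the wild-type score minus its
#' window sum (a closed-form oracle for ranking tests). It is a stand-in for
#' an external protein-language-model scorer, not a pathogenicity predictor.
#'
#' @return a scorer function.
#' @export
hydrophobicity_scorer <- function() {
  function(sequence) {
    aa <- strsplit(toupper(sequence), "")[[1]]
    v <- unname(KD_HYDROPATHY[aa])
    if (anyNA(v)) stop("non-standard residue in sequence")
    list(score = sum(v), per_residue = v)
  }
}

#' Adapter for an external command-line scorer
#'
#' Wraps an external command into the scan scorer contract. The command is
#' called with the sequence as its final argument and must print a JSON
#' object `{"score": <number>, "per_residue": [..]}`.
#'
#' @param command path to the executable.
#' @param args extra arguments placed before the sequence.
#' @return a scorer function.
#' @export
external_scorer <- function(command, args = character()) {
  force(command)
  force(args)
  function(sequence) {
    out <- system2(command, c(args, sequence), stdout = TRUE)
    res <- jsonlite::fromJSON(paste(out, collapse = ""))
    list(score = as.numeric(res$score),
         per_residue = as.numeric(res$per_residue))
  }
}
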