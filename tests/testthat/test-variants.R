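test_that("identical sequences align gapless with identity 1", {
  s <- make_test_cds(40, seed = 1)
  aln <- align_to_reference(s, s)
  expect_identical(aln$reference, s)
  expect_identical(aln$haplotype, s)
  expect_equal(aln$identity, 1)
})

test_that("a contiguous 9-nt removal aligns as one 9-column gap", {
  ref <- make_test_cds(40, seed = 2)
  hap <- paste0(substr(ref, 1, 30), substr(ref, 40, nchar(ref)))
  aln <- align_to_reference(ref, hap)
  runs <- rle(strsplit(aln$haplotype, "")[[1]] == "-")
  expect_equal(sum(runs$values), 1)
  expect_equal(runs$lengths[runs$values], 9)
  expect_false(grepl("-", aln$reference, fixed = TRUE))
})

test_that("alignment score matches the brute-force affine DP oracle", {
  withr::with_seed(11, {
    for (i in 1:8) {
      a <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"),
                        sample(12:24, 1), TRUE), collapse = "")
      expect_equal(align_to_reference(a, b)$score, dp_affine_score(a, b))
    }
    # indel-bearing pair exercises the gap states
    a <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    b <- paste0(substr(a, 1, 10), substr(a, 20, 30))
    expect_equal(align_to_reference(a, b)$score, dp_affine_score(a, b))
  })
})

test_that("alignment rejects bad input", {
  expect_error(align_to_reference("", "ACGT"), "empty")
  expect_error(align_to_reference("ACGT", "ACGU"), "non-nucleotide")
  expect_silent(align_to_reference("ACGTN", "ACGTN"))
  # N never counts as a match
  expect_lt(align_to_reference("ANA", "ANA")$identity, 1)
})

test_that("a planted codon 153-155 deletion calls as p.N153_V155del", {
  ref <- make_test_cds(200, seed = 42)
  hap <- paste0(substr(ref, 1, 456), substr(ref, 466, nchar(ref)))
  calls <- call_indels(align_to_reference(ref, hap))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$kind, "deletion")
  expect_equal(calls$nt_length, 9)
  expect_true(calls$in_frame)
  expect_equal(calls$aa_start, 153)
  expect_equal(calls$aa_end, 155)
  expect_equal(calls$hgvs, "p.N153_V155del")
})

test_that("a single-codon deletion at residue 1669 calls as p.R1669del", {
  # build the aligned pair directly: 1700-codon reference, codon 1669 = CGT
  withr::with_seed(3, {
    codons <- apply(matrix(sample(c("A", "C", "G", "T"), 1700 * 3, TRUE),
                           ncol = 3), 1, paste, collapse = "")
    codons[codons %in% c("TAA", "TAG", "TGA")] <- "GCT"
    codons[1669] <- "CGT" # R
    codons[1670] <- "AAA" # 'A' != 'C' blocks a 3' shift
    ref <- paste(codons, collapse = "")
  })
  s <- 3 * 1668 + 1
  hap_row <- paste0(substr(ref, 1, s - 1), "---",
                    substr(ref, s + 3, nchar(ref)))
  calls <- call_indels(list(reference = ref, haplotype = hap_row))
  expect_equal(calls$hgvs, "p.R1669del")
  expect_equal(calls$nt_length, 3)
  expect_true(calls$in_frame)
})

test_that("gapless alignments yield no calls", {
  s <- make_test_cds(30, seed = 4)
  expect_equal(nrow(call_indels(align_to_reference(s, s))), 0)
})

test_that("repeat-unit deletions normalize to the 3'-most placement", {
  # reference with a triple codon repeat GCA GCA GCA flanked by unique seq
  left <- "ATGCCTTGG"
  right <- "TTCGATCAG"
  ref <- paste0(left, "GCAGCAGCA", right)
  n_rep <- nchar(left) # offset of the repeat block
  # enumerate every equivalent placement of a one-unit deletion
  calls <- lapply(0:2, function(u) {
    s <- n_rep + 3 * u + 1
    hap_row <- paste0(substr(ref, 1, s - 1),
                      paste(rep("-", 3), collapse = ""),
                      substr(ref, s + 3, nchar(ref)))
    call_indels(list(reference = ref, haplotype = hap_row))
  })
  for (cl in calls) {
    expect_equal(cl$nt_start, n_rep + 7) # last repeat unit
    expect_equal(cl$nt_end, n_rep + 9)
    expect_equal(cl$hgvs, calls[[1]]$hgvs)
  }
})

test_that("in-frame flag follows nt length mod 3", {
  ref <- make_test_cds(60, seed = 5)
  for (len in c(8, 9, 10)) {
    hap_row <- paste0(substr(ref, 1, 90),
                      paste(rep("-", len), collapse = ""),
                      substr(ref, 91 + len, nchar(ref)))
    cl <- call_indels(list(reference = ref, haplotype = hap_row),
                      reference_protein = translate_cds(ref),
                      normalize = FALSE)
    expect_equal(cl$in_frame, len %% 3 == 0)
  }
})

test_that("insertions are called with 3'-normalized placement", {
  ref <- "ATGCCTTGGTTC"
  # insert CCT after position 6 == equivalent to after 3 given repeat CCT
  aln <- list(reference = "ATGCCT---TGGTTC", haplotype = "ATGCCTCCTTGGTTC")
  cl <- call_indels(aln)
  expect_equal(cl$kind, "insertion")
  expect_equal(cl$nt_length, 3)
  expect_true(cl$in_frame)
  expect_match(cl$hgvs, "^c\\.6_7ins")
})

test_that("allele frequencies, homozygotes and recombinant tallies", {
  hap <- data.frame(
    individual_id = rep(sprintf("I%02d", 1:10), each = 2),
    haplotype_index = rep(1:2, 10),
    population_id = "popA", subspecies = "mel",
    recombinant = rep(c(FALSE, FALSE, FALSE, FALSE, TRUE), 4),
    stringsAsFactors = FALSE)
  # carriers: I01 both haplotypes (homozygote), I02 hap1, I03 hap1 (recomb?)
  calls <- data.frame(
    individual_id = c("I01", "I01", "I02", "I03"),
    haplotype_index = c(1, 2, 1, 1),
    hgvs = "p.N153_V155del", stringsAsFactors = FALSE)
  ft <- allele_frequency(calls, hap)
  pp <- ft$per_population
  expect_equal(pp$carriers, 4)
  expect_equal(pp$total, 20)
  expect_equal(pp$frequency, 0.2)
  expect_equal(ft$per_indel$homozygotes, 1)
  # recombinant haplotypes excluded in the _norecomb tallies
  expect_equal(pp$total_norecomb, 20 - sum(hap$recombinant))
  expect_lte(pp$carriers_norecomb, pp$carriers)
  # order invariance
  ft2 <- allele_frequency(calls[sample(nrow(calls)), ],
                          hap[rev(seq_len(nrow(hap))), ])
  expect_equal(ft2$per_population$frequency, pp$frequency)
  # unknown haplotype errors
  bad <- data.frame(individual_id = "ZZZ", haplotype_index = 1,
                    hgvs = "x", stringsAsFactors = FALSE)
  expect_error(allele_frequency(bad, hap), "absent")
})

test_that("generate -> align -> call -> frequency round trip is exact", {
  spec <- allele_sim_spec(
    populations = data.frame(label = c("a", "b", "c"),
                             n_individuals = c(16L, 10L, 8L),
                             frequency = c(0.5, 0.1, 0)),
    deletion = c(153L, 155L), reference_cds = make_test_cds(200, seed = 42),
    seed = 99)
  aset <- generate_alleles(spec)
  truth <- attr(aset, "truth")
  calls <- call_indels_set(aset)
  expect_true(all(calls$aa_start == 153 & calls$aa_end == 155))
  expect_true(all(calls$nt_length == 9))
  expect_true(all(calls$in_frame))
  expect_true(all(calls$hgvs == "p.N153_V155del"))
  ft <- allele_frequency(calls, aset$haplotypes)
  pp <- ft$per_population[order(ft$per_population$population_id), ]
  expect_equal(pp$frequency, c(0.5, 0.1, 0))
  expect_equal(ft$per_indel$homozygotes,
               sum(truth$per_population$homozygotes))
})
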