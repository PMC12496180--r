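# Independent oracles used across tests. These deliberately re-derive
# results by brute force / closed form, independent of the package code
# paths they check.

# Affine-gap global alignment score by full-matrix dynamic programming
# (score only). Gap of length L costs open + (L - 1) * ext.
dp_affine_score <- function(a, b, match = 2, mismatch = -3,
                            open = -11, ext = -1, ambiguous = "N") {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- open + (i - 2) * ext
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- open + (j - 2) * ext
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (a[i - 1] == b[j - 1] && !(a[i - 1] %in% ambiguous))
        match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + ext,
                     Y[i - 1, j] + open)
      Y[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + open,
                     Y[i, j - 1] + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# BH step-up by direct enumeration: largest k with p_(k) <= k * alpha / m,
# reject the k smallest; adjusted p by the definitional min over j >= i.
bh_oracle <- function(p, alpha = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ks <- which(ps <= seq_len(m) * alpha / m)
  reject <- logical(m)
  if (length(ks)) reject[o[seq_len(max(ks))]] <- TRUE
  adjusted <- numeric(m)
  for (i in seq_len(m)) {
    adjusted[o[i]] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  list(adjusted = adjusted, reject = reject)
}

# Uniform-ish random proper rotation matrix (QR with sign fix)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_aa <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"), n,
               replace = TRUE), collapse = "")
}

# plain RMSD of two coordinate sets without fitting
raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Test CDS with fixed codons at the planted deletion so the 3'-normalized
# call is exactly p.N153_V155del (context forbids any right shift).
make_test_cds <- function(n_codons = 200, seed = 42) {
  withr::with_seed(seed, {
    codons <- apply(matrix(sample(c("A", "C", "G", "T"), n_codons * 3,
                                  TRUE), ncol = 3), 1, paste, collapse = "")
    stops <- c("TAA", "TAG", "TGA")
    while (any(codons %in% stops))
      codons[codons %in% stops] <- "GCT"
    if (n_codons >= 156) {
      codons[152] <- "TGC"
      codons[153] <- "AAT" # N
      codons[154] <- "GGT" # G
      codons[155] <- "GTT" # V
      codons[156] <- "CAC" # H; 'C' != 'A' blocks a 3' shift
    }
    paste(codons, collapse = "")
  })
}
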