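# Independent oracles, coded against the definitions rather than the
# package's internal paths.

# nucleotide diversity by exhaustive pairwise haplotype comparison
# (complete-call matrices only)
oracle_pi <- function(m) {
  n <- ncol(m)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + sum(m[, i] != m[, j])
    }
  }
  total / choose(n, 2)
}

# Tajima's D recomputed from scratch: segregating-site count, pairwise
# pi, constants by direct summation
oracle_tajima_d <- function(m) {
  n <- ncol(m)
  freq <- rowSums(m)
  seg <- freq > 0 & freq < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi <- oracle_pi(m)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  v <- (c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1)
  if (v <= 0) return(NA_real_)
  (pi - S / a1) / sqrt(v)
}

# maximal bipartition support by exhaustive enumeration of all
# 2^(n-1) - 1 nontrivial strain bipartitions (n <= 12)
oracle_best_support <- function(m) {
  n <- ncol(m)
  freq <- rowSums(m)
  poly <- m[freq > 0 & freq < n, , drop = FALSE]
  if (nrow(poly) == 0) return(0L)
  # canonicalize rows so the first strain carries 0
  flip <- poly[, 1] == 1
  poly[flip, ] <- 1 - poly[flip, , drop = FALSE]
  best <- 0L
  grid <- as.matrix(expand.grid(rep(list(0:1), n - 1)))
  for (r in seq_len(nrow(grid))) {
    split <- c(0L, grid[r, ])
    if (all(split == 0L)) next
    hits <- sum(apply(poly, 1, function(row) all(row == split)))
    best <- max(best, hits)
  }
  as.integer(best)
}

# random complete-call haplotype matrix with S polymorphic rows
random_matrix <- function(n, S) {
  m <- matrix(0L, nrow = S, ncol = n)
  for (i in seq_len(S)) {
    j <- sample(seq_len(n - 1), 1)
    m[i, sample.int(n, j)] <- 1L
  }
  m
}

# wrap a haplotype matrix as a variant_table on one chromosome
matrix_table <- function(m, chrom = "I", start = 1) {
  n <- ncol(m)
  S <- nrow(m)
  variant_table(
    sprintf("S%03d", seq_len(n)),
    data.frame(chrom = chrom, pos = seq(start, length.out = S),
               ref = "A", alt = "T", stringsAsFactors = FALSE),
    m
  )
}

# minimal diploid VCF text fixture
write_test_vcf <- function(path, records,
                           samples = c("WS1", "WS2", "WS3")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}
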