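single_exon_tx <- function(cds, chrom = "I", start = 1001, strand = "+",
                           id = "tx1", gene = "srx-1") {
  transcript_cds(id, gene, chrom,
                 data.frame(start = start, end = start + nchar(cds) - 1),
                 strand, cds)
}

test_that("variants classify by codon translation", {
  tx <- single_exon_tx("ATGGGGTGGTAA", start = 101)
  # GGG third position G->A: synonymous (Gly)
  syn <- classify_variant(list(chrom = "I", pos = 106, ref = "G", alt = "A"), tx)
  expect_equal(syn$classification, "synonymous")
  expect_equal(syn$ref_codon, "GGG")
  expect_equal(syn$alt_codon, "GGA")
  # ATG -> ATA: nonsynonymous (Met -> Ile)
  non <- classify_variant(list(chrom = "I", pos = 103, ref = "G", alt = "A"), tx)
  expect_equal(non$classification, "nonsynonymous")
  # TGG second position -> TAG: nonsense counts as nonsynonymous
  stp <- classify_variant(list(chrom = "I", pos = 108, ref = "G", alt = "A"), tx)
  expect_equal(stp$classification, "nonsynonymous")
  expect_equal(stp$alt_aa, "*")
  # outside the exons -> noncoding
  out <- classify_variant(list(chrom = "I", pos = 50, ref = "A", alt = "T"), tx)
  expect_equal(out$classification, "noncoding")
  # reference mismatch is a consistency error naming the site
  expect_error(
    classify_variant(list(chrom = "I", pos = 106, ref = "T", alt = "A"), tx),
    "mismatch at I:106"
  )
})

test_that("classification agrees with exhaustive codon-table lookup (549 cases)", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  bases <- c("A", "C", "G", "T")
  n_checked <- 0
  for (cod in sense) {
    tx <- single_exon_tx(paste0(cod, "TAA"), start = 1)
    for (p in 1:3) {
      for (b in setdiff(bases, substr(cod, p, p))) {
        eff <- classify_variant(
          list(chrom = "I", pos = p, ref = substr(cod, p, p), alt = b), tx
        )
        alt_cod <- cod
        substr(alt_cod, p, p) <- b
        # oracle: translate both codons with an independent routine
        aa_ref <- as.character(Biostrings::translate(
          Biostrings::DNAString(cod), no.init.codon = TRUE))
        aa_alt <- as.character(Biostrings::translate(
          Biostrings::DNAString(alt_cod), no.init.codon = TRUE))
        expected <- if (aa_ref == aa_alt) "synonymous" else "nonsynonymous"
        expect_equal(eff$classification, expected)
        n_checked <- n_checked + 1
      }
    }
  }
  expect_equal(n_checked, 549)
})

test_that("minus-strand transcripts complement alleles correctly", {
  # CDS ATGGGGTAA lies on the minus strand: genomic sequence is its
  # reverse complement, so the genomic base pairing CDS offset 6 (G of
  # GGG) is C
  cds <- "ATGGGGTAA"
  tx <- transcript_cds("tx1", "srx-1", "I",
                       data.frame(start = 201, end = 209), "-", cds)
  # CDS offset 6 maps to genomic position 201 + 9 - 6 = 204
  eff <- classify_variant(list(chrom = "I", pos = 204, ref = "C", alt = "T"),
                          tx)
  expect_equal(eff$classification, "synonymous")  # GGG -> GGA (Gly)
  expect_equal(eff$alt_codon, "GGA")
})

test_that("strand flip leaves every planted classification unchanged", {
  set.seed(66)
  cg <- simulate_coding_gene(4, 6, 60, seed = 67)
  tx <- cg$transcript
  L <- 3 * 60
  g_start <- tx$exons$start
  g_end <- tx$exons$end
  # the same transcript presented on the minus strand of a mirrored
  # genome: position p maps to g_start + g_end - p, alleles complement
  comp <- function(x) chartr("ACGT", "TGCA", x)
  tx_minus <- transcript_cds("tx1m", tx$gene, tx$chrom,
                             data.frame(start = g_start, end = g_end),
                             "-", tx$cds)
  for (i in seq_len(nrow(cg$truth))) {
    v <- cg$truth[i, ]
    plus_eff <- classify_variant(
      list(chrom = tx$chrom, pos = v$pos, ref = v$ref, alt = v$alt), tx)
    minus_eff <- classify_variant(
      list(chrom = tx$chrom, pos = g_start + g_end - v$pos,
           ref = comp(v$ref), alt = comp(v$alt)), tx_minus)
    expect_equal(minus_eff$classification, plus_eff$classification)
    expect_equal(minus_eff$codon_index, plus_eff$codon_index)
  }
})

test_that("potential sites follow the counting convention", {
  # TTT: only TTT->TTC synonymous among the nine changes
  ps <- potential_sites("TTT")
  expect_equal(ps$S_sites, 1 / 3, tolerance = 1e-12)
  expect_equal(ps$N_sites, 8 / 3, tolerance = 1e-12)
  # GGG third position is 4-fold degenerate
  ps_g <- potential_sites("GGG")
  expect_gte(ps_g$S_sites, 1)

  # conservation incl. stop-excluded fractions, over random CDS
  set.seed(14)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (rep in 1:20) {
    k <- sample(5:60, 1)
    cds <- paste(sample(sense, k, replace = TRUE), collapse = "")
    ps <- potential_sites(cds, permissive = TRUE)
    expect_equal(ps$N_sites + ps$S_sites + ps$stop_excluded, 3 * k,
                 tolerance = 1e-9)
  }
  # TGG (Trp): all three stop-reachable changes are excluded
  ps_w <- potential_sites("TGG")
  expect_equal(ps_w$stop_excluded, 2 / 3, tolerance = 1e-12)

  expect_error(potential_sites("ATGTAAAAATGA"), "internal stop")
  expect_silent(potential_sites("ATGTAAAAATGA", permissive = TRUE))
})

test_that("planted inter-lineage substitutions are recovered exactly", {
  set.seed(23)
  for (rep in 1:25) {
    n_plant <- sample(0:10, 1)
    s_plant <- sample(0:30, 1)
    cg <- simulate_coding_gene(n_plant, s_plant, 250,
                               seed = sample.int(1e6, 1))
    if (n_plant + s_plant == 0) next
    sig <- gene_signature(cg$table, cg$gene)
    r <- lineage_dnds(sig, cg$table, cg$transcript)
    expect_equal(r$n_obs, n_plant)
    expect_equal(r$s_obs, s_plant)
    ps <- potential_sites(cg$transcript$cds)
    if (s_plant == 0) {
      expect_true(is.na(r$ratio))
    } else {
      expect_equal(r$ratio,
                   (n_plant / ps$N_sites) / (s_plant / ps$S_sites),
                   tolerance = 1e-12)
    }
  }
})

test_that("planted positions reclassify correctly under exhaustive enumeration", {
  cg <- simulate_coding_gene(5, 20, 300, seed = 91)
  for (i in seq_len(nrow(cg$truth))) {
    v <- cg$truth[i, ]
    eff <- classify_variant(
      list(chrom = "simC", pos = v$pos, ref = v$ref, alt = v$alt),
      cg$transcript
    )
    expect_equal(eff$classification, v$class)
  }
})

test_that("pairwise divergence counts mismatches over compared bases", {
  expect_equal(pairwise_divergence("ACGTACGTAC", "ACGTTCGAAC"),
               list(differences = 2L, compared = 10L, fraction = 0.2))
  d0 <- pairwise_divergence("ACGT", "ACGT")
  expect_equal(d0$differences, 0L)
  expect_equal(d0$fraction, 0)
  # gaps excluded from both counts
  dg <- pairwise_divergence("AC-TA", "ACGTT")
  expect_equal(dg$compared, 4L)
  expect_equal(dg$differences, 1L)
  expect_error(pairwise_divergence("ACG", "ACGT"), "length")
  # a 515-base promoter pair with 35 planted differences
  set.seed(42)
  a <- paste(sample(c("A", "C", "G", "T"), 515, replace = TRUE),
             collapse = "")
  bv <- strsplit(a, "")[[1]]
  idx <- sample(515, 35)
  bv[idx] <- vapply(bv[idx], function(x) {
    sample(setdiff(c("A", "C", "G", "T"), x), 1)
  }, "")
  d <- pairwise_divergence(a, paste(bv, collapse = ""))
  expect_equal(d$differences, 35L)
  expect_equal(d$fraction, 35 / 515)
})
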