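make_scan <- function(d_values, chrom = "I", width = 5000,
                      n_snps = NULL) {
  n <- length(d_values)
  if (is.null(n_snps)) n_snps <- rep(5L, n)
  structure(
    data.frame(chrom = chrom, bin_start = width * (seq_len(n) - 1),
               n_snps = n_snps, pi = NA_real_, theta_w = NA_real_,
               D = d_values, stringsAsFactors = FALSE),
    class = c("tajima_scan", "data.frame"), width = width, panel_n = 10
  )
}

test_that("genes annotate every window they overlap", {
  scan <- make_scan(rep(0, 3))
  genes <- data.frame(
    name = c("srx-1", "srx-2", "srx-3", "clec-1"),
    chrom = "I",
    start = c(4998L, 6000L, 6100L, 11000L),
    end = c(5002L, 6050L, 6200L, 14000L),
    strand = "+",
    family_class = c("chemoreceptor", "chemoreceptor", "chemoreceptor",
                     "fast_evolving"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_bins(scan, genes)
  # boundary-spanning gene hits bins 0 and 5000
  expect_equal(ann$contains_chemoreceptor, c(TRUE, TRUE, FALSE))
  # two genes in bin 5000, flag still a single TRUE with both names listed
  expect_equal(sort(ann$genes_chemoreceptor[[2]]),
               c("srx-1", "srx-2", "srx-3"))
  expect_equal(ann$contains_fast_evolving, c(FALSE, FALSE, TRUE))
})

test_that("genes on chromosomes absent from the scan are skipped with warning", {
  scan <- make_scan(rep(0, 2))
  genes <- data.frame(name = "srx-9", chrom = "X", start = 1L, end = 10L,
                      strand = "+", family_class = "chemoreceptor",
                      stringsAsFactors = FALSE)
  expect_warning(ann <- annotate_bins(scan, genes), "absent from scan")
  expect_false(any(ann$contains_chemoreceptor))
})

test_that("tail enrichment computes fractions and folds as defined", {
  # 100 scored bins; class in 10 of them, 4 of which in the 10-bin low tail
  d <- c(rep(-3, 10), rep(0, 90))
  scan <- make_scan(d)
  genes_in <- c(1:4, 20:25)
  genes <- data.frame(
    name = sprintf("srx-%d", seq_along(genes_in)), chrom = "I",
    start = scan$bin_start[genes_in] + 100L,
    end = scan$bin_start[genes_in] + 200L,
    strand = "+", family_class = "chemoreceptor", stringsAsFactors = FALSE
  )
  ann <- annotate_bins(scan, genes)
  e <- tail_enrichment(scan, ann, "chemoreceptor", "low", -2.5)
  expect_equal(e$n_tail_bins, 10)
  expect_equal(e$n_tail_bins_with_class, 4)
  expect_equal(e$tail_fraction, 0.4)
  expect_equal(e$genome_fraction, 0.1)
  expect_equal(e$fold, 4.0)

  # tail fraction equal to genome fraction -> fold 1
  e_all <- tail_enrichment(scan, ann, "chemoreceptor", "high", -100)
  expect_equal(e_all$fold, 1.0)

  # empty tail -> fold undefined
  e_empty <- tail_enrichment(scan, ann, "chemoreceptor", "high", 100)
  expect_equal(e_empty$n_tail_bins, 0)
  expect_true(is.na(e_empty$fold))

  # no class genes anywhere -> error (genome-wide fraction undefined)
  expect_error(tail_enrichment(scan, ann, "fast_evolving", "low", -2.5),
               "undefined")
})

test_that("printed tail pair implies the genome-wide class fraction", {
  # fold = tail_fraction / genome_fraction, so a 46.1% tail at 6.59x
  # implies a 7.0% genome-wide fraction, matching the 30.1% / 4.30x pair
  expect_equal(0.461 / 6.59, 0.0700, tolerance = 2e-3)
  expect_equal(0.301 / 4.30, 0.0700, tolerance = 2e-3)
})

test_that("tails plus middle partition the scored bins at any threshold", {
  set.seed(12)
  scan <- make_scan(stats::rnorm(200), n_snps = sample(0:5, 200, TRUE))
  scored <- sum(scan$n_snps >= 1)
  genes <- data.frame(name = "srx-1", chrom = "I", start = 1L, end = 50L,
                      strand = "+", family_class = "chemoreceptor",
                      stringsAsFactors = FALSE)
  ann <- annotate_bins(scan, genes)
  for (t in c(-1, 0, 0.7)) {
    lo <- tail_enrichment(scan, ann, "chemoreceptor", "low", t)
    hi <- tail_enrichment(scan, ann, "chemoreceptor", "high", t)
    middle <- sum(scan$n_snps >= 1 & scan$D == t)
    expect_equal(lo$n_tail_bins + hi$n_tail_bins + middle, scored)
  }
})

test_that("duplicating every window leaves fractions and folds unchanged", {
  set.seed(3)
  scan <- make_scan(stats::rnorm(60))
  genes <- data.frame(
    name = sprintf("srx-%d", 1:10), chrom = "I",
    start = scan$bin_start[seq(2, 60, by = 6)] + 10L,
    end = scan$bin_start[seq(2, 60, by = 6)] + 60L,
    strand = "+", family_class = "chemoreceptor", stringsAsFactors = FALSE
  )
  ann <- annotate_bins(scan, genes)
  e1 <- tail_enrichment(scan, ann, "chemoreceptor", "high", 0.5)

  scan2 <- rbind(as.data.frame(scan),
                 as.data.frame(make_scan(scan$D, chrom = "Idup")))
  attr(scan2, "width") <- 5000
  genes2 <- rbind(genes, transform(genes, chrom = "Idup",
                                   name = paste0(name, "b")))
  ann2 <- annotate_bins(scan2, genes2)
  e2 <- tail_enrichment(scan2, ann2, "chemoreceptor", "high", 0.5)
  expect_equal(e2$tail_fraction, e1$tail_fraction)
  expect_equal(e2$genome_fraction, e1$genome_fraction)
  expect_equal(e2$fold, e1$fold)
})

test_that("enrichment report tabulates all classes and returns histogram data", {
  set.seed(5)
  scan <- make_scan(stats::rnorm(100))
  genes <- data.frame(
    name = c("srx-1", "clec-1", "dpy-1"), chrom = "I",
    start = scan$bin_start[c(3, 10, 20)] + 5L,
    end = scan$bin_start[c(3, 10, 20)] + 90L,
    strand = "+",
    family_class = c("chemoreceptor", "fast_evolving", "purifying_proxy"),
    stringsAsFactors = FALSE
  )
  ann <- annotate_bins(scan, genes)
  rep <- enrichment_report(scan, ann, low = -1, high = 1)
  expect_equal(nrow(rep$table), 6)
  expect_setequal(unique(rep$table$class),
                  c("chemoreceptor", "fast_evolving", "purifying_proxy"))
  expect_true(all(c("mid", "chemoreceptor", "other_or_none") %in%
                    names(rep$histogram)))
  # histogram bars account for every scored bin
  expect_equal(sum(rep$histogram[, -1]), 100)
})
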