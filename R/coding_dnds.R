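.BASES <- c("A", "C", "G", "T")

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

#' Construct a spliced coding transcript
#'
#' Carries the spliced coding sequence of one transcript together with
#' the exon intervals that map it back onto the genome, so genomic SNVs
#' can be projected into codons.
#'
#' @param id Transcript id.
#' @param gene Gene name the transcript belongs to.
#' @param chrom Chromosome.
#' @param exons Data frame with 1-based inclusive `start`, `end` columns
#'   (coding portions only), in genomic order.
#' @param strand `"+"` or `"-"`.
#' @param cds Spliced coding sequence, 5'->3' in the transcript frame;
#'   length must be divisible by 3 and equal the summed exon widths.
#' @return Object of class `transcript_cds`.
#' @export
transcript_cds <- function(id, gene, chrom, exons, strand, cds) {
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)),
            strand %in% c("+", "-"))
  if (any(exons$start > exons$end)) stop("exon start > end")
  exons <- exons[order(exons$start), , drop = FALSE]
  cds <- toupper(cds)
  widths <- exons$end - exons$start + 1
  if (sum(widths) != nchar(cds)) {
    stop("summed exon widths (", sum(widths),
         ") != CDS length (", nchar(cds), ")")
  }
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  partial <- substr(cds, 1, 3) != "ATG"
  structure(
    list(id = id, gene = gene, chrom = chrom, exons = exons,
         strand = strand, cds = cds, partial = partial),
    class = "transcript_cds"
  )
}

# 1-based CDS offset of a genomic position, or NA when intronic/outside
.genomic_to_cds <- function(tx, pos) {
  ex <- tx$exons
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 0) return(NA_integer_)
  if (tx$strand == "+") {
    before <- if (hit > 1) sum(ex$end[seq_len(hit - 1)] -
                                 ex$start[seq_len(hit - 1)] + 1) else 0
    as.integer(before + pos - ex$start[hit] + 1)
  } else {
    n_ex <- nrow(ex)
    after <- if (hit < n_ex) sum(ex$end[(hit + 1):n_ex] -
                                   ex$start[(hit + 1):n_ex] + 1) else 0
    as.integer(after + ex$end[hit] - pos + 1)
  }
}

#' Classify a single-nucleotide variant against a coding transcript
#'
#' Projects the variant into the transcript's codon frame (complementing
#' alleles for minus-strand transcripts), substitutes the alternate base
#' into the reference codon, and compares translations under the
#' standard genetic code. Changes creating a stop codon are nonsynonymous
#' (nonsense).
#'
#' @param variant List or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt` (single nucleotides, plus-strand alleles).
#' @param transcript A [transcript_cds()].
#' @return Object of class `coding_effect`: list with `classification`
#'   (`"synonymous"`, `"nonsynonymous"`, `"noncoding"`), `cds_offset`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa` (the
#'   last six `NA` for noncoding).
#' @export
classify_variant <- function(variant, transcript) {
  blank <- structure(
    list(classification = "noncoding", cds_offset = NA_integer_,
         codon_index = NA_integer_, ref_codon = NA_character_,
         alt_codon = NA_character_, ref_aa = NA_character_,
         alt_aa = NA_character_),
    class = "coding_effect"
  )
  if (!identical(as.character(variant$chrom), transcript$chrom)) return(blank)
  off <- .genomic_to_cds(transcript, variant$pos)
  if (is.na(off)) return(blank)
  ref <- toupper(as.character(variant$ref))
  alt <- toupper(as.character(variant$alt))
  if (transcript$strand == "-") {
    ref <- .complement(ref)
    alt <- .complement(alt)
  }
  cds_ref <- substr(transcript$cds, off, off)
  if (cds_ref != ref) {
    stop(sprintf(
      "reference allele mismatch at %s:%d (VCF %s, CDS %s in transcript %s)",
      variant$chrom, variant$pos, variant$ref, cds_ref, transcript$id
    ))
  }
  codon_index <- (off - 1) %/% 3 + 1
  codon_pos <- (off - 1) %% 3 + 1
  ref_codon <- substr(transcript$cds, 3 * codon_index - 2, 3 * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, codon_pos, codon_pos) <- alt
  ref_aa <- .translate_codon(ref_codon)
  alt_aa <- .translate_codon(alt_codon)
  structure(
    list(
      classification = if (ref_aa == alt_aa) "synonymous" else "nonsynonymous",
      cds_offset = off, codon_index = as.integer(codon_index),
      ref_codon = ref_codon, alt_codon = alt_codon,
      ref_aa = ref_aa, alt_aa = alt_aa
    ),
    class = "coding_effect"
  )
}

# per-codon potential-site contributions, cached over the 64 codons:
# every position contributes syn/3 to S and nonsyn-nonstop/3 to N;
# changes creating a stop codon are excluded from both (classic
# counting-method convention), their fraction returned separately
.codon_site_cache <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    codons <- as.vector(outer(
      as.vector(outer(.BASES, .BASES, paste0)), .BASES, paste0
    ))
    tab <- lapply(codons, function(cod) {
      aa <- .translate_codon(cod)
      s <- n <- stp <- 0
      for (p in 1:3) {
        for (b in setdiff(.BASES, substr(cod, p, p))) {
          alt <- cod
          substr(alt, p, p) <- b
          aa2 <- .translate_codon(alt)
          if (aa2 == "*") stp <- stp + 1
          else if (aa2 == aa) s <- s + 1
          else n <- n + 1
        }
      }
      c(S = s / 3, N = n / 3, stop_excluded = stp / 3)
    })
    cache <<- do.call(rbind, tab)
    rownames(cache) <<- codons
    cache
  }
})

#' Potential synonymous and nonsynonymous site counts of a CDS
#'
#' Counting-method site totals: each codon position contributes to the
#' synonymous site count the fraction of its three possible base changes
#' that are synonymous, and the nonsynonymous remainder to the
#' nonsynonymous count; changes that create a stop codon are excluded
#' from both totals (their fractional sites are reported separately, so
#' `N_sites + S_sites + stop_excluded = 3 x codons` exactly).
#'
#' @param cds Coding sequence (character), length divisible by 3.
#' @param permissive Allow internal stop codons in the reference
#'   (default `FALSE`).
#' @return List with `N_sites`, `S_sites`, `stop_excluded`, `codons`.
#' @export
potential_sites <- function(cds, permissive = FALSE) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop("CDS length not divisible by 3")
  k <- nchar(cds) / 3
  codons <- substring(cds, 3 * seq_len(k) - 2, 3 * seq_len(k))
  aas <- vapply(codons, .translate_codon, "")
  if (any(aas == "*" & seq_len(k) < k) && !permissive) {
    stop("internal stop codon in reference CDS at codon ",
         which(aas == "*" & seq_len(k) < k)[1])
  }
  tab <- .codon_site_cache()[codons, , drop = FALSE]
  list(
    N_sites = sum(tab[, "N"]),
    S_sites = sum(tab[, "S"]),
    stop_excluded = sum(tab[, "stop_excluded"]),
    codons = k
  )
}

#' Within-species counting dN/dS on a gene's two haplotype lineages
#'
#' Takes the gene's shared-haplotype signature, restricts to the SNPs
#' supporting the modal strain bipartition (the substitutions that
#' distinguish the two lineages), classifies each independently against
#' the reference codon, and normalizes the observed counts by the
#' potential-site totals of the CDS: `dN = n_obs/N_sites`,
#' `dS = s_obs/S_sites`, `ratio = dN/dS` (undefined when `s_obs = 0`).
#'
#' @param signature A [gene_signature()] result with a best partition.
#' @param table The [variant_table()] the signature was computed on.
#' @param transcript A [transcript_cds()] mapping the gene.
#' @return Object of class `dnds_result`: list with `gene`, `n_obs`,
#'   `s_obs`, `N_sites`, `S_sites`, `dN`, `dS`, `ratio` (`NA` when
#'   undefined), `n_lineage_snps` (partition-supporting SNPs, coding or
#'   not).
#' @export
lineage_dnds <- function(signature, table, transcript) {
  if (is.null(signature$best_partition)) {
    stop("signature has no best partition (no usable SNPs)")
  }
  lo <- min(transcript$exons$start)
  hi <- max(transcript$exons$end)
  reg <- subset_region(table, transcript$chrom, lo, hi)
  n_obs <- s_obs <- 0L
  n_lineage <- 0L
  for (i in seq_len(n_sites(reg))) {
    key <- snp_partition(reg$genotypes[i, ])
    if (is.na(key) || key != signature$best_key) next
    n_lineage <- n_lineage + 1L
    eff <- classify_variant(reg$sites[i, ], transcript)
    if (eff$classification == "synonymous") s_obs <- s_obs + 1L
    if (eff$classification == "nonsynonymous") n_obs <- n_obs + 1L
  }
  ps <- potential_sites(transcript$cds)
  dN <- n_obs / ps$N_sites
  dS <- s_obs / ps$S_sites
  structure(
    list(gene = signature$gene, transcript = transcript$id,
         n_obs = n_obs, s_obs = s_obs,
         N_sites = ps$N_sites, S_sites = ps$S_sites,
         dN = dN, dS = dS,
         ratio = if (s_obs == 0) NA_real_ else dN / dS,
         n_lineage_snps = n_lineage),
    class = "dnds_result"
  )
}

#' @export
print.dnds_result <- function(x, ...) {
  cat(sprintf("dnds_result for %s (transcript %s)\n", x$gene, x$transcript))
  cat(sprintf(" observed: %d nonsynonymous, %d synonymous\n",
              x$n_obs, x$s_obs))
  cat(sprintf(" potential sites: N = %.2f, S = %.2f\n",
              x$N_sites, x$S_sites))
  if (is.na(x$ratio)) {
    cat(sprintf(" dN = %.6f, dS = %.6f, dN/dS undefined (dS = 0)\n",
                x$dN, x$dS))
  } else {
    cat(sprintf(" dN = %.6f, dS = %.6f, dN/dS = %.3f\n",
                x$dN, x$dS, x$ratio))
  }
  invisible(x)
}

#' Pairwise divergence of two aligned sequences
#'
#' Counts mismatching positions between two equal-length aligned
#' sequences; positions where either sequence has a gap (`-` or `.`) are
#' excluded from both the mismatch and the compared-length counts. No
#' alignment is performed.
#'
#' @param a,b Character strings of equal length.
#' @return List with `differences`, `compared`, `fraction`.
#' @export
pairwise_divergence <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    stop("sequences differ in length (", nchar(a), " vs ", nchar(b),
         "); align them first")
  }
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  gap <- av %in% c("-", ".") | bv %in% c("-", ".")
  compared <- sum(!gap)
  differences <- sum(av[!gap] != bv[!gap])
  list(differences = differences, compared = compared,
       fraction = if (compared > 0) differences / compared else NA_real_)
}
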