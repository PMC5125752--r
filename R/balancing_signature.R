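#' Canonical strain bipartition induced by one SNP
#'
#' A fully-called polymorphic SNP splits the strain panel into the
#' reference-carrying and alternate-carrying sets. The split is
#' unordered, so it is canonicalized by flipping alleles such that the
#' first strain carries 0; ref/alt labelling and strain order then do
#' not affect the key.
#'
#' @param row Integer genotype vector over the full panel (0/1/`NA`).
#' @return A character key identifying the bipartition, or `NA_character_`
#'   for rows with any missing call or monomorphic rows.
#' @export
snp_partition <- function(row) {
  if (anyNA(row)) return(NA_character_)
  j <- sum(row == 1L)
  if (j == 0 || j == length(row)) return(NA_character_)
  if (row[1] == 1L) row <- 1L - row
  paste(row, collapse = "")
}

#' Shared-haplotype bipartition signature of one gene
#'
#' The balancing-selection signature: group the gene's usable SNPs
#' (fully called, polymorphic) by the strain bipartition each induces and
#' find the modal bipartition. A gene whose SNPs predominantly segregate
#' on one shared split (`shared_fraction > min_shared`, default 0.5)
#' carries the two-deep-lineage signature. Ties between equally supported
#' bipartitions are broken toward the larger minor-side size, then
#' lexicographically.
#'
#' @param table A [variant_table()].
#' @param gene One-row gene record (needs `name`, `chrom`, `start`, `end`).
#' @param min_shared Candidate threshold on the shared fraction
#'   (default 0.5, strict inequality).
#' @return Object of class `partition_signature`: list with `gene`,
#'   `n_snps` (usable SNPs), `best_partition` (list of two strain-id
#'   vectors, the set containing the first strain first; `NULL` when no
#'   usable SNP), `support`, `shared_fraction`, `is_candidate`.
#' @export
gene_signature <- function(table, gene, min_shared = 0.5) {
  reg <- subset_region(table, gene$chrom, gene$start, gene$end)
  keys <- if (n_sites(reg) > 0) {
    apply(reg$genotypes, 1, snp_partition)
  } else {
    character(0)
  }
  keys <- keys[!is.na(keys)]
  n_usable <- length(keys)
  if (n_usable == 0) {
    return(structure(
      list(gene = gene$name, n_snps = 0L, best_partition = NULL,
           support = 0L, shared_fraction = NA_real_, is_candidate = FALSE),
      class = "partition_signature"
    ))
  }
  tab <- table(keys)
  support <- max(tab)
  modal <- names(tab)[tab == support]
  if (length(modal) > 1) {
    ones <- vapply(strsplit(modal, ""), function(b) sum(b == "1"), 0)
    minor <- pmin(ones, nchar(modal) - ones)
    modal <- modal[minor == max(minor)]
    modal <- sort(modal)[1]
  }
  bits <- strsplit(modal, "")[[1]] == "1"
  structure(
    list(
      gene = gene$name, n_snps = as.integer(n_usable),
      best_partition = list(table$strain_ids[!bits], table$strain_ids[bits]),
      best_key = modal,
      support = as.integer(support),
      shared_fraction = support / n_usable,
      is_candidate = support / n_usable > min_shared
    ),
    class = "partition_signature"
  )
}

#' @export
print.partition_signature <- function(x, ...) {
  cat(sprintf("partition_signature for %s\n", x$gene))
  if (x$n_snps == 0) {
    cat(" no usable (fully called, polymorphic) SNPs\n")
  } else {
    cat(sprintf(
      " %d/%d SNPs on the modal bipartition (shared fraction %.3f)%s\n",
      x$support, x$n_snps, x$shared_fraction,
      if (x$is_candidate) " -- balancing-selection candidate" else ""
    ))
    cat(sprintf(" split sizes: %d | %d strains\n",
                length(x$best_partition[[1]]), length(x$best_partition[[2]])))
  }
  invisible(x)
}

#' Scan for balancing-selection candidate genes
#'
#' A chemoreceptor gene is a candidate when it overlaps at least one
#' window with Tajima's D above `min_d` AND more than `min_shared` of
#' its usable SNPs segregate on one shared strain bipartition.
#'
#' @param table A [variant_table()].
#' @param genes Gene data frame, see [read_gff3_genes()].
#' @param scan A `tajima_scan` of the same table.
#' @param min_d Window D threshold (default 1.0, strict).
#' @param min_shared Shared-fraction threshold (default 0.5, strict).
#' @param class Gene family class screened (default `"chemoreceptor"`).
#' @return Data frame with one row per candidate: `gene`, `chrom`,
#'   `start`, `end`, `n_snps`, `support`, `shared_fraction`,
#'   `max_window_d`; attribute `signatures` holds the full
#'   `partition_signature` objects (named by gene) for downstream dN/dS.
#' @export
candidate_scan <- function(table, genes, scan, min_d = 1.0,
                           min_shared = 0.5, class = "chemoreceptor") {
  width <- attr(scan, "width")
  genes <- genes[genes$family_class == class, , drop = FALSE]
  key <- paste(scan$chrom, scan$bin_start, sep = "\r")
  rows <- list()
  sigs <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    bins <- seq(width * ((g$start - 1) %/% width),
                width * ((g$end - 1) %/% width), by = width)
    idx <- match(paste(g$chrom, bins, sep = "\r"), key)
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) next
    max_d <- suppressWarnings(max(scan$D[idx], na.rm = TRUE))
    if (!is.finite(max_d) || max_d <= min_d) next
    sig <- gene_signature(table, g, min_shared = min_shared)
    if (!isTRUE(sig$is_candidate)) next
    sigs[[g$name]] <- sig
    rows[[g$name]] <- data.frame(
      gene = g$name, chrom = g$chrom, start = g$start, end = g$end,
      n_snps = sig$n_snps, support = sig$support,
      shared_fraction = sig$shared_fraction, max_window_d = max_d,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    gene = character(0), chrom = character(0), start = integer(0),
    end = integer(0), n_snps = integer(0), support = integer(0),
    shared_fraction = numeric(0), max_window_d = numeric(0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "signatures") <- sigs
  out
}
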