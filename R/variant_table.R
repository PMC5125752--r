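#' Construct a variant table
#'
#' The central data container of the package: a panel of biallelic SNVs
#' typed across a set of inbred (haploid-coded) strains.
#'
#' @param strain_ids Character vector of sample names (ordered).
#' @param sites Data frame with columns `chrom`, `pos` (1-based),
#'   `ref`, `alt` (single nucleotides each).
#' @param genotypes Integer matrix, sites x strains, values 0 (reference),
#'   1 (alternate) or `NA` (missing / heterozygous collapsed to missing).
#'
#' @return An object of class `variant_table`: a list with elements
#'   `strain_ids`, `sites`, `genotypes`. Sites are sorted by
#'   (chromosome, position) and duplicates are an error.
#' @export
variant_table <- function(strain_ids, sites, genotypes) {
  stopifnot(is.character(strain_ids), length(strain_ids) >= 1)
  sites <- as.data.frame(sites)
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(sites))) {
    stop("`sites` must have columns chrom, pos, ref, alt")
  }
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(sites) != nrow(genotypes) || ncol(genotypes) != length(strain_ids)) {
    stop("genotype matrix must be (n sites) x (n strains)")
  }
  if (nrow(sites) > 0) {
    if (!all(genotypes %in% c(0L, 1L, NA_integer_))) {
      stop("genotypes must be 0, 1 or NA")
    }
    ord <- order(sites$chrom, sites$pos)
    sites <- sites[ord, , drop = FALSE]
    genotypes <- genotypes[ord, , drop = FALSE]
    if (anyDuplicated(sites[, c("chrom", "pos")])) {
      stop("duplicate (chromosome, position) entries in sites")
    }
    bad <- !(sites$ref %in% c("A", "C", "G", "T")) |
      !(sites$alt %in% c("A", "C", "G", "T"))
    if (any(bad)) stop("ref/alt must be single nucleotides A/C/G/T")
  }
  rownames(sites) <- NULL
  dimnames(genotypes) <- list(NULL, strain_ids)
  structure(
    list(strain_ids = strain_ids, sites = sites, genotypes = genotypes),
    class = "variant_table"
  )
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf(
    "variant_table: %d biallelic SNV site%s x %d strain%s\n",
    nrow(x$sites), if (nrow(x$sites) == 1) "" else "s",
    length(x$strain_ids), if (length(x$strain_ids) == 1) "" else "s"
  ))
  if (nrow(x$sites) > 0) {
    chroms <- unique(x$sites$chrom)
    cat(" chromosomes:", paste(utils::head(chroms, 6), collapse = ", "),
        if (length(chroms) > 6) "..." else "", "\n")
    miss <- mean(is.na(x$genotypes))
    cat(sprintf(" missing genotype fraction: %.4f\n", miss))
  }
  invisible(x)
}

#' Number of sites in a variant table
#' @param table A `variant_table`.
#' @return Integer site count.
#' @export
n_sites <- function(table) nrow(table$sites)

#' Subset a variant table to a genomic interval
#'
#' @param table A `variant_table`.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @return A `variant_table` restricted to sites with
#'   `pos` in `[start, end]` on `chrom`.
#' @export
subset_region <- function(table, chrom, start, end) {
  keep <- table$sites$chrom == chrom &
    table$sites$pos >= start & table$sites$pos <= end
  variant_table(
    table$strain_ids,
    table$sites[keep, , drop = FALSE],
    table$genotypes[keep, , drop = FALSE]
  )
}

#' Row-bind variant tables over the same strain panel
#' @param ... `variant_table` objects sharing identical `strain_ids`.
#' @return A merged `variant_table`.
#' @export
bind_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1)
  ids <- tabs[[1]]$strain_ids
  for (t in tabs) {
    if (!identical(t$strain_ids, ids)) {
      stop("all tables must share the same strain panel")
    }
  }
  variant_table(
    ids,
    do.call(rbind, lapply(tabs, function(t) t$sites)),
    do.call(rbind, lapply(tabs, function(t) t$genotypes))
  )
}
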