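#' Read a multi-sample SNV VCF into a variant table
#'
#' Ingests a VCF of inbred wild strains and normalizes it to the haploid
#' data model: only biallelic single-nucleotide variants are retained;
#' diploid homozygous calls are collapsed to haploid (0/0 -> 0, 1/1 -> 1);
#' heterozygous calls are treated as missing (the panel is assumed to be
#' inbred, so residual heterozygosity is treated as call uncertainty);
#' sites whose missing fraction exceeds `max_missing_fraction` are dropped.
#'
#' @param path Path to a VCF 4.x file (plain or gzipped).
#' @param max_missing_fraction Maximum tolerated fraction of missing calls
#'   per site, in `[0, 1]`. Default 0.05.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path, max_missing_fraction = 0.05) {
  stopifnot(is.numeric(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has zero samples: ", path)
  strain_ids <- colnames(v@gt)[-1]

  ref <- fix$REF
  alt <- fix$ALT
  snv <- !is.na(ref) & !is.na(alt) &
    ref %in% c("A", "C", "G", "T") &
    alt %in% c("A", "C", "G", "T")
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_raw))) gt_raw <- matrix(gt_raw, nrow = nrow(fix))

  sites <- data.frame(
    chrom = fix$CHROM[snv],
    pos = as.integer(fix$POS[snv]),
    ref = ref[snv],
    alt = alt[snv],
    stringsAsFactors = FALSE
  )
  if (any(is.na(sites$pos))) {
    stop("malformed POS field in VCF: ", path)
  }
  gt_raw <- gt_raw[snv, , drop = FALSE]

  # collapse to haploid: homozygous ref/alt keep their allele, anything
  # else (het, other ploidy states, missing) becomes NA
  gt <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  gt[gt_raw %in% c("0", "0/0", "0|0")] <- 0L
  gt[gt_raw %in% c("1", "1/1", "1|1")] <- 1L

  if (nrow(gt) > 0) {
    miss_frac <- rowMeans(is.na(gt))
    keep <- miss_frac <= max_missing_fraction
    sites <- sites[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
  }
  variant_table(strain_ids, sites, gt)
}

#' Write a variant table as a minimal haploid VCF
#'
#' Emits a plain-text VCF 4.2 with haploid GT calls (`0`, `1`, `.`),
#' the exact inverse of the normalization performed by [read_vcf()].
#' Used by the synthetic-data generators; round-trips losslessly.
#'
#' @param table A [variant_table()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tajimascan-synthetic",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", table$strain_ids), collapse = "\t")
  ), con)
  if (nrow(table$sites) > 0) {
    gt_chr <- matrix(".", nrow = nrow(table$genotypes),
                     ncol = ncol(table$genotypes))
    gt_chr[which(table$genotypes == 0L)] <- "0"
    gt_chr[which(table$genotypes == 1L)] <- "1"
    lines <- paste(
      table$sites$chrom, table$sites$pos, ".",
      table$sites$ref, table$sites$alt, ".", "PASS", ".", "GT",
      apply(gt_chr, 1, paste, collapse = "\t"),
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Default gene-family prefix configuration
#'
#' Gene families are recognized by the name token before the first hyphen,
#' case-insensitively. The chemoreceptor set covers the large C. elegans
#' serpentine-receptor families; the fast-evolving set covers F-box,
#' C-type lectin and nuclear hormone receptor families; the
#' purifying-selection proxy set covers classic essential-phenotype genes.
#' All three lists are user-overridable.
#'
#' @return A named list with character vectors `chemoreceptor`,
#'   `fast_evolving`, `purifying_proxy`.
#' @export
gene_prefix_config <- function() {
  list(
    chemoreceptor = c("sra", "srab", "srb", "srbc", "srd", "sre", "srg",
                      "srh", "sri", "srj", "srm", "srn", "srr", "srsx",
                      "srt", "sru", "srv", "srw", "srx", "srxa", "srz",
                      "str"),
    fast_evolving = c("fbxa", "fbxb", "fbxc", "clec", "nhr"),
    purifying_proxy = c("unc", "bli", "let", "dpy", "rol", "egl")
  )
}

#' Classify a gene name into a family class
#'
#' @param name Public gene name (e.g. `"srx-43"`). Vectorized.
#' @param prefix_config Prefix lists, see [gene_prefix_config()].
#' @return Character vector over `{"chemoreceptor", "fast_evolving",
#'   "purifying_proxy", "other"}`.
#' @export
classify_gene_name <- function(name, prefix_config = gene_prefix_config()) {
  token <- tolower(sub("-.*$", "", name))
  out <- rep("other", length(name))
  out[token %in% tolower(prefix_config$purifying_proxy)] <- "purifying_proxy"
  out[token %in% tolower(prefix_config$fast_evolving)] <- "fast_evolving"
  out[token %in% tolower(prefix_config$chemoreceptor)] <- "chemoreceptor"
  out
}

#' Read gene records from a GFF3 annotation
#'
#' Extracts `gene` features, takes the public name from the `Name=`
#' attribute (falling back to `locus=`), and assigns each gene a family
#' class via [classify_gene_name()]. Features without a name attribute are
#' skipped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param prefix_config Prefix lists, see [gene_prefix_config()].
#' @return Data frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`, `family_class` (one row per gene).
#' @export
read_gff3_genes <- function(path, prefix_config = gene_prefix_config()) {
  if (!file.exists(path)) stop("GFF3 not found: ", path)
  g <- ape::read.gff(path, GFF3 = TRUE)
  g <- g[g$type == "gene", , drop = FALSE]
  name <- ifelse(
    grepl("(^|;)\\s*Name=", g$attributes),
    sub(".*(^|;)\\s*Name=([^;]+).*", "\\2", g$attributes),
    ifelse(grepl("(^|;)\\s*locus=", g$attributes),
           sub(".*(^|;)\\s*locus=([^;]+).*", "\\2", g$attributes),
           NA_character_)
  )
  drop <- is.na(name)
  if (any(drop)) {
    warning(sum(drop), " gene feature(s) without a Name attribute skipped")
  }
  g <- g[!drop, , drop = FALSE]
  name <- name[!drop]
  start <- as.integer(g$start)
  end <- as.integer(g$end)
  if (any(is.na(start) | is.na(end)) || any(start > end)) {
    stop("malformed gene coordinates in ", path)
  }
  data.frame(
    name = name,
    chrom = as.character(g$seqid),
    start = start,
    end = end,
    strand = as.character(g$strand),
    family_class = classify_gene_name(name, prefix_config),
    stringsAsFactors = FALSE
  )
}

#' Write gene records as GFF3
#'
#' @param genes Data frame as returned by [read_gff3_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes) > 0) {
    writeLines(paste(
      genes$chrom, "tajimascan", "gene", genes$start, genes$end, ".",
      genes$strand, ".", paste0("ID=", genes$name, ";Name=", genes$name),
      sep = "\t"
    ), con)
  }
  invisible(path)
}

#' Write a window scan as TSV
#'
#' Output dialect follows the classic per-window Tajima's D table:
#' columns `CHROM`, `BIN_START` (0-based window start), `N_SNPS`,
#' `TajimaD` (4 decimal places, `nan` when undefined).
#'
#' @param scan A `tajima_scan` data frame, see [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CHROM\tBIN_START\tN_SNPS\tTajimaD", con)
  if (nrow(scan) > 0) {
    d_chr <- ifelse(is.na(scan$D), "nan", sprintf("%.4f", scan$D))
    writeLines(paste(scan$chrom, scan$bin_start, scan$n_snps, d_chr,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a window-scan TSV written by [write_scan_tsv()]
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `chrom`, `bin_start`, `n_snps`, `D`
#'   (`NA` where the file holds `nan`).
#' @export
read_scan_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer", "integer",
                                        "character"),
                         stringsAsFactors = FALSE)
  data.frame(
    chrom = d$CHROM,
    bin_start = d$BIN_START,
    n_snps = d$N_SNPS,
    D = suppressWarnings(as.numeric(ifelse(d$TajimaD == "nan", NA,
                                           d$TajimaD))),
    stringsAsFactors = FALSE
  )
}
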