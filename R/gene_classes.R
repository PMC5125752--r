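#' Annotate scan windows with the gene families they contain
#'
#' A gene with 1-based span `[start, end]` annotates every window whose
#' 0-based half-open interval intersects `[start - 1, end)`, i.e. every
#' window it overlaps by at least one base ("contains a gene" = any
#' overlap). Genes on chromosomes absent from the scan are skipped with
#' a warning.
#'
#' @param scan A `tajima_scan`, see [scan_genome()].
#' @param genes Gene data frame, see [read_gff3_genes()].
#' @return Data frame keyed like the scan (`chrom`, `bin_start`) with
#'   logical columns `contains_chemoreceptor`, `contains_fast_evolving`,
#'   `contains_purifying_proxy`, `contains_other`, and list columns
#'   `genes_chemoreceptor`, `genes_fast_evolving`,
#'   `genes_purifying_proxy`, `genes_other` holding the gene names.
#' @export
annotate_bins <- function(scan, genes) {
  width <- attr(scan, "width")
  if (is.null(width)) {
    width <- if (nrow(scan) > 1) min(diff(sort(unique(scan$bin_start)))) else 5000
  }
  classes <- c("chemoreceptor", "fast_evolving", "purifying_proxy", "other")
  key <- paste(scan$chrom, scan$bin_start, sep = "\r")
  ann <- data.frame(chrom = scan$chrom, bin_start = scan$bin_start,
                    stringsAsFactors = FALSE)
  lists <- lapply(classes, function(cl) {
    replicate(nrow(scan), character(0), simplify = FALSE)
  })
  names(lists) <- classes

  missing_chrom <- setdiff(unique(genes$chrom), unique(scan$chrom))
  if (length(missing_chrom) > 0) {
    warning("genes on chromosome(s) absent from scan skipped: ",
            paste(missing_chrom, collapse = ", "))
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom %in% missing_chrom) next
    first <- width * ((g$start - 1) %/% width)
    last <- width * ((g$end - 1) %/% width)
    bins <- seq(first, last, by = width)
    idx <- match(paste(g$chrom, bins, sep = "\r"), key)
    idx <- idx[!is.na(idx)]
    for (j in idx) {
      lists[[g$family_class]][[j]] <- c(lists[[g$family_class]][[j]], g$name)
    }
  }
  for (cl in classes) {
    ann[[paste0("contains_", cl)]] <- lengths(lists[[cl]]) > 0
    ann[[paste0("genes_", cl)]] <- I(lists[[cl]])
  }
  ann
}

#' Enrichment of a gene class in one tail of the D distribution
#'
#' Tail bins are scored windows (`S >= 1`, finite D) with `D < threshold`
#' (side `"low"`) or `D > threshold` (side `"high"`). The fold is the
#' fraction of tail bins containing the class divided by the fraction of
#' all scored bins containing it. An approximate 95% confidence interval
#' for the fold is computed on the log scale (delta method over the two
#' binomial fractions).
#'
#' @param scan A `tajima_scan`.
#' @param annotations Output of [annotate_bins()] for the same scan.
#' @param class One of `"chemoreceptor"`, `"fast_evolving"`,
#'   `"purifying_proxy"`, `"other"`.
#' @param side `"low"` or `"high"`.
#' @param threshold D threshold defining the tail.
#' @return Object of class `class_enrichment`: a list with the class,
#'   side, threshold, tail and genome-wide counts and fractions, the
#'   fold, and `fold_ci` (length-2 vector, `NA` when degenerate).
#' @export
tail_enrichment <- function(scan, annotations, class,
                            side = c("low", "high"), threshold) {
  side <- match.arg(side)
  stopifnot(is.finite(threshold))
  flag_col <- paste0("contains_", class)
  if (!flag_col %in% names(annotations)) stop("unknown class: ", class)
  scored <- scan$n_snps >= 1 & !is.na(scan$D)
  if (!any(scored)) stop("no scored windows in scan")
  flags <- annotations[[flag_col]][match(
    paste(scan$chrom, scan$bin_start, sep = "\r"),
    paste(annotations$chrom, annotations$bin_start, sep = "\r")
  )]
  genome_n <- sum(scored)
  genome_with <- sum(flags & scored)
  if (genome_with == 0) {
    stop("no scored bin contains a gene of class '", class,
         "'; genome-wide fraction undefined")
  }
  in_tail <- scored & if (side == "low") scan$D < threshold else
    scan$D > threshold
  tail_n <- sum(in_tail)
  tail_with <- sum(flags & in_tail)
  tail_frac <- if (tail_n > 0) tail_with / tail_n else NA_real_
  genome_frac <- genome_with / genome_n
  fold <- if (tail_n > 0) tail_frac / genome_frac else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (tail_n > 0 && tail_with > 0) {
    se_log <- sqrt((1 - tail_frac) / (tail_n * tail_frac) +
                     (1 - genome_frac) / (genome_n * genome_frac))
    ci <- exp(log(fold) + c(-1.96, 1.96) * se_log)
  }
  structure(
    list(class = class, side = side, threshold = threshold,
         n_tail_bins = tail_n, n_tail_bins_with_class = tail_with,
         tail_fraction = tail_frac, genome_fraction = genome_frac,
         n_scored_bins = genome_n, n_scored_bins_with_class = genome_with,
         fold = fold, fold_ci = ci),
    class = "class_enrichment"
  )
}

#' @export
print.class_enrichment <- function(x, ...) {
  cat(sprintf(
    "%s, %s tail (D %s %g): %d/%d tail bins (%.1f%%) vs %d/%d genome-wide (%.1f%%)\n",
    x$class, x$side, if (x$side == "low") "<" else ">", x$threshold,
    x$n_tail_bins_with_class, x$n_tail_bins, 100 * x$tail_fraction,
    x$n_scored_bins_with_class, x$n_scored_bins, 100 * x$genome_fraction
  ))
  if (is.na(x$fold)) {
    cat(" fold: undefined (empty tail)\n")
  } else {
    cat(sprintf(" fold enrichment: %.2f (approx 95%% CI %.2f-%.2f)\n",
                x$fold, x$fold_ci[1], x$fold_ci[2]))
  }
  invisible(x)
}

#' Enrichment report over classes, tails and thresholds
#'
#' Tabulates tail enrichment for every gene class at the low and high
#' thresholds, and returns histogram data: D histogram bars with the
#' per-bar class composition (display priority chemoreceptor >
#' fast-evolving > purifying-proxy > other/no gene; the underlying flags
#' are independent).
#'
#' @param scan A `tajima_scan`.
#' @param annotations Output of [annotate_bins()].
#' @param low,high Tail thresholds on D (defaults -2.5 and 2.5).
#' @param hist_breaks Number of histogram cells (default 40).
#' @return List with `table` (one row per class x side; fold is `NA`
#'   where undefined) and `histogram` (data frame of D-cell midpoints and
#'   per-class bin counts).
#' @export
enrichment_report <- function(scan, annotations, low = -2.5, high = 2.5,
                              hist_breaks = 40) {
  classes <- c("chemoreceptor", "fast_evolving", "purifying_proxy")
  rows <- list()
  for (cl in classes) {
    for (side in c("low", "high")) {
      thr <- if (side == "low") low else high
      e <- tryCatch(tail_enrichment(scan, annotations, cl, side, thr),
                    error = function(err) NULL)
      rows[[paste(cl, side)]] <- data.frame(
        class = cl, side = side, threshold = thr,
        n_tail_bins = if (is.null(e)) NA_integer_ else e$n_tail_bins,
        n_tail_bins_with_class = if (is.null(e)) NA_integer_ else
          e$n_tail_bins_with_class,
        tail_fraction = if (is.null(e)) NA_real_ else e$tail_fraction,
        genome_fraction = if (is.null(e)) NA_real_ else e$genome_fraction,
        fold = if (is.null(e)) NA_real_ else e$fold,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  scored <- scan$n_snps >= 1 & !is.na(scan$D)
  hist_df <- NULL
  if (any(scored)) {
    d <- scan$D[scored]
    flags <- annotations[match(
      paste(scan$chrom, scan$bin_start, sep = "\r")[scored],
      paste(annotations$chrom, annotations$bin_start, sep = "\r")
    ), ]
    # exclusive display category by priority
    category <- rep("other_or_none", length(d))
    category[flags$contains_purifying_proxy] <- "purifying_proxy"
    category[flags$contains_fast_evolving] <- "fast_evolving"
    category[flags$contains_chemoreceptor] <- "chemoreceptor"
    br <- seq(min(d), max(d), length.out = hist_breaks + 1)
    cell <- cut(d, breaks = br, include.lowest = TRUE)
    counts <- table(cell, factor(category, levels = c(
      "chemoreceptor", "fast_evolving", "purifying_proxy", "other_or_none"
    )))
    hist_df <- data.frame(
      mid = (br[-1] + br[-length(br)]) / 2,
      as.data.frame.matrix(counts),
      stringsAsFactors = FALSE
    )
    rownames(hist_df) <- NULL
  }
  list(table = tab, histogram = hist_df)
}
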