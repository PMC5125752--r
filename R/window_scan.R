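#' Constants of Tajima's D for a panel of n haploid sequences
#'
#' The classic variance-normalization constants: `a1 = sum_{i<n} 1/i`,
#' `a2 = sum_{i<n} 1/i^2`, `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`. For `n = 2` the variance is degenerate
#' (`c1 = c2 = 0`) and D is undefined for every window.
#'
#' @param n Panel size (number of haploid strains), integer `>= 2`.
#' @return Object of class `tajima_constants`: a named list with
#'   `n, a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
harmonic_constants <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 2) {
    stop("panel size n must be an integer >= 2")
  }
  n <- as.integer(n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  structure(
    list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = c1 / a1, e2 = c2 / (a1^2 + a2)),
    class = "tajima_constants"
  )
}

#' @export
print.tajima_constants <- function(x, ...) {
  cat(sprintf("Tajima constants for n = %d haploid sequences\n", x$n))
  cat(sprintf(" a1=%.6f a2=%.6f e1=%.6f e2=%.6f\n", x$a1, x$a2, x$e1, x$e2))
  invisible(x)
}

# per-site alternate-allele count j and called-allele count m
.site_counts <- function(genotypes) {
  if (nrow(genotypes) == 0) {
    return(list(j = integer(0), m = integer(0)))
  }
  list(
    j = as.integer(rowSums(genotypes == 1L, na.rm = TRUE)),
    m = as.integer(rowSums(!is.na(genotypes)))
  )
}

# per-site contribution to pi: expected pairwise difference 2j(m-j)/(m(m-1)),
# computed over called alleles only; sites with <2 calls contribute 0
.site_pi <- function(j, m) {
  out <- numeric(length(j))
  ok <- m >= 2
  out[ok] <- 2 * j[ok] * (m[ok] - j[ok]) / (m[ok] * (m[ok] - 1))
  out
}

#' Segregating sites and nucleotide diversity in one window
#'
#' Windows are 0-based half-open `[bin_start, bin_start + width)` over
#' 1-based site positions shifted by -1, i.e. a site at position `p`
#' belongs to the window starting at `width * floor((p-1)/width)`.
#'
#' @param table A [variant_table()].
#' @param chrom Chromosome name.
#' @param bin_start 0-based window start.
#' @param width Window width in bases (default 5000).
#' @return List `(S, pi)`: count of sites segregating among called strains,
#'   and the sum over sites of mean pairwise differences.
#' @export
window_diversity <- function(table, chrom, bin_start, width = 5000) {
  stopifnot(width > 0)
  keep <- table$sites$chrom == chrom &
    table$sites$pos >= bin_start + 1 &
    table$sites$pos <= bin_start + width
  cnt <- .site_counts(table$genotypes[keep, , drop = FALSE])
  seg <- cnt$j > 0 & cnt$j < cnt$m
  list(S = sum(seg), pi = sum(.site_pi(cnt$j, cnt$m)))
}

#' Tajima's D from window summaries
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Undefined (returns `NA`)
#' when `S = 0` or the variance term vanishes.
#'
#' @param S Number of segregating sites (`>= 0`).
#' @param pi Sum of per-site mean pairwise differences.
#' @param constants A [harmonic_constants()] object for the panel size.
#' @return Numeric D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(S, pi, constants) {
  if (any(S < 0)) stop("S must be non-negative")
  var_term <- constants$e1 * S + constants$e2 * S * (S - 1)
  out <- rep(NA_real_, length(S))
  ok <- S > 0 & var_term > 0
  out[ok] <- (pi[ok] - S[ok] / constants$a1) / sqrt(var_term[ok])
  out
}

#' Windowed Tajima's D scan over a whole variant table
#'
#' Splits every chromosome into fixed-width windows anchored at
#' coordinate 0 and computes per-window segregating sites `S`, nucleotide
#' diversity `pi`, Watterson's `theta_w = S/a1` and Tajima's D. Per-site
#' allele counts use called alleles only, while the constants use the
#' full panel size `panel_n` (a robust default for low missingness).
#'
#' @param table A [variant_table()].
#' @param width Window width in bases (default 5000).
#' @param panel_n Panel size used for the Tajima constants; defaults to
#'   the number of strains in `table`.
#' @param chrom_lengths Optional named numeric vector of chromosome
#'   lengths. When supplied, every window of every named chromosome is
#'   reported (including `S = 0` windows); otherwise only windows from 0
#'   to the last window containing a site on each observed chromosome.
#' @return A data frame of class `tajima_scan` with columns `chrom`,
#'   `bin_start`, `n_snps`, `pi`, `theta_w`, `D`, plus attributes
#'   `panel_n`, `width`, `constants`.
#' @export
scan_genome <- function(table, width = 5000,
                        panel_n = length(table$strain_ids),
                        chrom_lengths = NULL) {
  konst <- harmonic_constants(panel_n)
  sites <- table$sites
  cnt <- .site_counts(table$genotypes)
  seg <- cnt$j > 0 & cnt$j < cnt$m
  pi_site <- .site_pi(cnt$j, cnt$m)
  bin <- as.integer(width * ((sites$pos - 1) %/% width))

  if (!is.null(chrom_lengths)) {
    stopifnot(!is.null(names(chrom_lengths)))
    frame <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
      data.frame(
        chrom = ch,
        bin_start = as.integer(seq(0, width * ((chrom_lengths[[ch]] - 1) %/%
                                                 width), by = width)),
        stringsAsFactors = FALSE
      )
    }))
  } else if (nrow(sites) > 0) {
    last <- tapply(bin, sites$chrom, max)
    frame <- do.call(rbind, lapply(names(last), function(ch) {
      data.frame(
        chrom = ch,
        bin_start = as.integer(seq(0, last[[ch]], by = width)),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    frame <- data.frame(chrom = character(0), bin_start = integer(0),
                        stringsAsFactors = FALSE)
  }

  key <- function(ch, b) paste(ch, b, sep = "\r")
  s_by <- tapply(as.integer(seg), key(sites$chrom, bin), sum)
  pi_by <- tapply(pi_site, key(sites$chrom, bin), sum)
  k <- key(frame$chrom, frame$bin_start)
  S <- ifelse(k %in% names(s_by), unname(s_by[k]), 0L)
  S[is.na(S)] <- 0L
  pi <- ifelse(k %in% names(pi_by), unname(pi_by[k]), 0)
  pi[is.na(pi)] <- 0

  out <- data.frame(
    chrom = frame$chrom,
    bin_start = frame$bin_start,
    n_snps = as.integer(S),
    pi = pi,
    theta_w = S / konst$a1,
    D = tajimas_d(S, pi, konst),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$bin_start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, panel_n = panel_n, width = width, constants = konst,
            class = c("tajima_scan", "data.frame"))
}

#' @export
print.tajima_scan <- function(x, ...) {
  cat(sprintf(
    "tajima_scan: %d windows of %d bp (panel n = %d)\n",
    nrow(x), attr(x, "width"), attr(x, "panel_n")
  ))
  scored <- sum(x$n_snps > 0)
  cat(sprintf(" scored windows (S >= 1): %d\n", scored))
  if (scored > 0) {
    cat(sprintf(" Tajima's D: mean %.3f, range [%.3f, %.3f]\n",
                mean(x$D, na.rm = TRUE), min(x$D, na.rm = TRUE),
                max(x$D, na.rm = TRUE)))
  }
  NextMethod()
}

#' @export
summary.tajima_scan <- function(object, ...) {
  scored <- object[object$n_snps > 0 & !is.na(object$D), , drop = FALSE]
  out <- list(
    n_windows = nrow(object),
    n_scored = nrow(scored),
    width = attr(object, "width"),
    panel_n = attr(object, "panel_n"),
    d_summary = if (nrow(scored)) summary(scored$D) else NULL
  )
  class(out) <- "summary.tajima_scan"
  out
}

#' @export
print.summary.tajima_scan <- function(x, ...) {
  cat(sprintf("Windowed Tajima's D scan (%d bp windows, panel n = %d)\n",
              x$width, x$panel_n))
  cat(sprintf(" %d windows, %d scored (S >= 1)\n", x$n_windows, x$n_scored))
  if (!is.null(x$d_summary)) {
    cat(" D distribution over scored windows:\n")
    print(x$d_summary)
  }
  invisible(x)
}

#' Histogram of the per-window D distribution
#' @param x A `tajima_scan`.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.tajima_scan <- function(x, ...) {
  d <- x$D[!is.na(x$D)]
  graphics::hist(d, breaks = 40, main = "Windowed Tajima's D",
                 xlab = "Tajima's D", ...)
}
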