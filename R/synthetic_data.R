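.strain_names <- function(n) sprintf("S%03d", seq_len(n))

# one neutral coalescent genealogy for n haploid samples:
# returns list of branches, each a list(leaves = leaf index set, len)
.coalescent_tree <- function(n) {
  active <- lapply(seq_len(n), function(i) i)
  birth <- rep(0, n)
  branches <- list()
  t_now <- 0
  k <- n
  while (k > 1) {
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2)
    for (p in pair) {
      branches[[length(branches) + 1]] <-
        list(leaves = active[[p]], len = t_now - birth[p])
    }
    merged <- sort(c(active[[pair[1]]], active[[pair[2]]]))
    active <- c(active[-pair], list(merged))
    birth <- c(birth[-pair], t_now)
    k <- k - 1
  }
  branches
}

# infinite-sites mutations on a genealogy: haplotype matrix sites x n
.coalescent_sites <- function(n, theta) {
  br <- .coalescent_tree(n)
  lens <- vapply(br, function(b) b$len, 0)
  total <- sum(lens)
  n_mut <- stats::rpois(1, theta / 2 * total)
  if (n_mut == 0) {
    return(matrix(integer(0), nrow = 0, ncol = n))
  }
  which_branch <- sample.int(length(br), n_mut, replace = TRUE,
                             prob = lens)
  m <- matrix(0L, nrow = n_mut, ncol = n)
  for (i in seq_len(n_mut)) {
    m[i, br[[which_branch[i]]]$leaves] <- 1L
  }
  m
}

# haplotype matrix -> variant_table rows at distinct positions in
# [bin_start + 1, bin_start + width]
.matrix_to_sites <- function(m, chrom, bin_start, width, strain_ids) {
  n_mut <- nrow(m)
  if (n_mut > width) stop("more mutations than positions in window")
  if (n_mut == 0) {
    return(variant_table(
      strain_ids,
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE),
      matrix(integer(0), nrow = 0, ncol = length(strain_ids))
    ))
  }
  pos <- bin_start + sort(sample.int(width, n_mut))
  ref <- sample(.BASES, n_mut, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.BASES, r), 1), "")
  variant_table(
    strain_ids,
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE),
    m
  )
}

#' Simulate a neutral haploid panel
#'
#' Per window, a genealogy is drawn from the standard n-sample coalescent
#' (exponential waiting times, uniform random pair merges) and mutations
#' are placed on branches under the infinite-sites model at rate
#' `theta/2` per unit branch length. The result is the null model for
#' the windowed D statistic: mean D near 0.
#'
#' @param n Number of haploid strains.
#' @param theta Population mutation rate per window.
#' @param n_windows Number of consecutive windows to simulate.
#' @param width Window width in bases (default 5000).
#' @param chrom Chromosome name (default `"simI"`).
#' @param first_bin 0-based start of the first window (default 0).
#' @param seed Optional integer seed; fixing it makes the output (and
#'   any VCF written from it) fully deterministic.
#' @param strain_ids Optional strain names (default `S001`, `S002`, ...).
#' @return A [variant_table()].
#' @export
simulate_neutral <- function(n, theta, n_windows, width = 5000,
                             chrom = "simI", first_bin = 0, seed = NULL,
                             strain_ids = .strain_names(n)) {
  stopifnot(n >= 2, theta >= 0, n_windows >= 1)
  if (!is.null(seed)) set.seed(seed)
  tabs <- lapply(seq_len(n_windows) - 1, function(w) {
    m <- .coalescent_sites(n, theta)
    .matrix_to_sites(m, chrom, first_bin + w * width, width, strain_ids)
  })
  do.call(bind_tables, tabs)
}

#' Simulate a sweep-like haploid panel
#'
#' Star-genealogy approximation of a recent selective sweep: a neutral
#' genealogy is drawn per window, then each mutation is reassigned to a
#' random single strain (made a singleton) with probability
#' `1 - 1/singleton_excess`. `singleton_excess = 1` leaves the neutral
#' model untouched; large values give a singleton-dominated site
#' frequency spectrum and strongly negative D.
#'
#' @inheritParams simulate_neutral
#' @param singleton_excess Excess factor `>= 1` (default 10).
#' @return A [variant_table()].
#' @export
simulate_sweep <- function(n, theta, n_windows, singleton_excess = 10,
                           width = 5000, chrom = "simII", first_bin = 0,
                           seed = NULL, strain_ids = .strain_names(n)) {
  stopifnot(n >= 2, theta >= 0, n_windows >= 1, singleton_excess >= 1)
  if (!is.null(seed)) set.seed(seed)
  p_single <- 1 - 1 / singleton_excess
  tabs <- lapply(seq_len(n_windows) - 1, function(w) {
    m <- .coalescent_sites(n, theta)
    if (nrow(m) > 0 && p_single > 0) {
      redo <- stats::runif(nrow(m)) < p_single
      for (i in which(redo)) {
        m[i, ] <- 0L
        m[i, sample.int(n, 1)] <- 1L
      }
    }
    .matrix_to_sites(m, chrom, first_bin + w * width, width, strain_ids)
  })
  do.call(bind_tables, tabs)
}

#' Simulate a balanced two-lineage haploid panel
#'
#' Emulates long-term balancing selection: per window, `k` sites are
#' fixed between two strain groups (sizes `n1`, `n2`; every such site
#' induces the same strain bipartition) on top of within-group neutral
#' coalescent variation at rate `theta_w` per group. With `k` large
#' relative to the within-group variation, windows show strongly
#' positive D and genes spanning them carry the shared-haplotype
#' signature.
#'
#' @inheritParams simulate_neutral
#' @param n1,n2 Sizes of the two lineages (`>= 2` each).
#' @param k Inter-lineage fixed differences per window.
#' @param theta_w Within-group mutation rate per window (default 0.5).
#' @return A [variant_table()]; the first `n1` strains form lineage 1.
#' @export
simulate_balanced <- function(n1, n2, k, theta_w = 0.5, n_windows = 1,
                              width = 5000, chrom = "simIII",
                              first_bin = 0, seed = NULL,
                              strain_ids = .strain_names(n1 + n2)) {
  stopifnot(n1 >= 2, n2 >= 2, k >= 0, theta_w >= 0, n_windows >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  tabs <- lapply(seq_len(n_windows) - 1, function(w) {
    inter <- matrix(0L, nrow = k, ncol = n)
    if (k > 0) inter[, (n1 + 1):n] <- 1L
    w1 <- .coalescent_sites(n1, theta_w)
    w2 <- .coalescent_sites(n2, theta_w)
    m <- rbind(
      inter,
      cbind(w1, matrix(0L, nrow = nrow(w1), ncol = n2)),
      cbind(matrix(0L, nrow = nrow(w2), ncol = n1), w2)
    )
    .matrix_to_sites(m, chrom, first_bin + w * width, width, strain_ids)
  })
  do.call(bind_tables, tabs)
}

#' Simulate a class-labelled gene annotation with planted tail enrichment
#'
#' Builds a toy gene set over a completed scan such that the expected
#' enrichment fold of the chemoreceptor class in the extreme-D windows
#' is exactly `e`. Extreme windows are scored windows with
#' `|D| > extreme_d`. Each extreme window receives a chemoreceptor gene
#' with probability `e * g`; each other scored window with probability
#' `g * (W - e*E) / (W - E)` (W scored windows, E extreme), so the
#' genome-wide fraction of windows carrying the class stays `g` and the
#' expected fold is `e`. Control classes (fast-evolving,
#' purifying-proxy, other) are placed uniformly with probability `g`.
#' Genes are placed wholly inside their window.
#'
#' @param scan A `tajima_scan`.
#' @param e Planted enrichment fold (`> 0`, and `e * E < W`).
#' @param g Genome-wide per-window class probability (default 0.12;
#'   `e * g` must be `<= 1`).
#' @param extreme_d Extremeness threshold on `|D|` (default 2).
#' @param gene_length Range of simulated gene lengths (default 500-2000).
#' @param seed Optional integer seed.
#' @return List with `genes` (gene data frame, see [read_gff3_genes()])
#'   and `truth` (list: `e`, `g`, `extreme_key` (chrom/bin keys of
#'   extreme windows), `expected_tail_fraction = e*g`,
#'   `expected_fold = e`).
#' @export
simulate_genome_annotation <- function(scan, e = 1, g = 0.12,
                                       extreme_d = 2,
                                       gene_length = c(500, 2000),
                                       seed = NULL) {
  stopifnot(e > 0, g > 0, e * g <= 1)
  if (!is.null(seed)) set.seed(seed)
  scored <- which(scan$n_snps >= 1 & !is.na(scan$D))
  extreme <- scored[abs(scan$D[scored]) > extreme_d]
  W <- length(scored)
  E <- length(extreme)
  if (W == 0) stop("scan has no scored windows")
  if (e * E >= W) stop("e * (number of extreme windows) must be < scored windows")
  p_non <- g * (W - e * E) / (W - E)
  width <- attr(scan, "width")

  prefix <- c(chemoreceptor = "srx", fast_evolving = "clec",
              purifying_proxy = "dpy", other = "gen")
  counter <- c(chemoreceptor = 0L, fast_evolving = 0L,
               purifying_proxy = 0L, other = 0L)
  rows <- list()
  place <- function(cl, idx) {
    counter[[cl]] <<- counter[[cl]] + 1L
    len <- sample(seq(gene_length[1], gene_length[2]), 1)
    start <- scan$bin_start[idx] + sample.int(width - len, 1)
    rows[[length(rows) + 1]] <<- data.frame(
      name = paste0(prefix[[cl]], "-", counter[[cl]]),
      chrom = scan$chrom[idx], start = start, end = start + len - 1,
      strand = sample(c("+", "-"), 1),
      family_class = cl, stringsAsFactors = FALSE
    )
  }
  for (idx in scored) {
    p_chemo <- if (idx %in% extreme) e * g else p_non
    if (stats::runif(1) < p_chemo) place("chemoreceptor", idx)
    for (cl in c("fast_evolving", "purifying_proxy", "other")) {
      if (stats::runif(1) < g) place(cl, idx)
    }
  }
  genes <- if (length(rows)) do.call(rbind, rows) else data.frame(
    name = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), family_class = character(0),
    stringsAsFactors = FALSE
  )
  list(
    genes = genes,
    truth = list(
      e = e, g = g,
      extreme_key = paste(scan$chrom[extreme], scan$bin_start[extreme],
                          sep = "\r"),
      n_extreme = E, n_scored = W,
      expected_tail_fraction = e * g,
      expected_fold = e
    )
  )
}

#' Simulate a coding gene with planted inter-lineage substitutions
#'
#' Generates a random stop-free CDS (ATG start, TAA stop) and plants
#' `n_plant` nonsynonymous and `s_plant` synonymous substitutions, each
#' at a distinct verified CDS position, fixed between two strain
#' lineages (all planted sites induce the same strain bipartition). The
#' plant is the ground truth against which [lineage_dnds()] recovery is
#' checked.
#'
#' @param n_plant,s_plant Numbers of nonsynonymous / synonymous
#'   inter-lineage substitutions to plant.
#' @param codons CDS length in codons (including start and stop).
#' @param n1,n2 Lineage sizes (default 10 each).
#' @param chrom Chromosome name (default `"simC"`).
#' @param cds_start 1-based genomic start of the (single-exon) CDS.
#' @param seed Optional integer seed.
#' @param strain_ids Optional strain names.
#' @param gene_name Name for the gene (default `"srx-900"`, a
#'   chemoreceptor-classified name).
#' @return List with `transcript` ([transcript_cds()]), `table`
#'   ([variant_table()] of the planted sites), `gene` (one-row gene data
#'   frame), and `truth` (data frame `pos`, `ref`, `alt`, `class`).
#' @export
simulate_coding_gene <- function(n_plant, s_plant, codons, n1 = 10,
                                 n2 = 10, chrom = "simC", cds_start = 101,
                                 seed = NULL,
                                 strain_ids = .strain_names(n1 + n2),
                                 gene_name = "srx-900") {
  stopifnot(n_plant >= 0, s_plant >= 0, codons >= 3)
  if (!is.null(seed)) set.seed(seed)
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  cds <- paste0(
    "ATG",
    paste(sample(sense, codons - 2, replace = TRUE), collapse = ""),
    "TAA"
  )
  k <- codons
  # candidate plants: middle codons only, one substitution per CDS offset
  syn_alts <- list()
  non_alts <- list()
  for (off in 4:(3 * (k - 1))) {
    ci <- (off - 1) %/% 3 + 1
    cp <- (off - 1) %% 3 + 1
    cod <- substr(cds, 3 * ci - 2, 3 * ci)
    aa <- .translate_codon(cod)
    s_here <- character(0)
    n_here <- character(0)
    for (b in setdiff(.BASES, substr(cds, off, off))) {
      alt_cod <- cod
      substr(alt_cod, cp, cp) <- b
      aa2 <- .translate_codon(alt_cod)
      if (aa2 == "*") next
      if (aa2 == aa) s_here <- c(s_here, b) else n_here <- c(n_here, b)
    }
    if (length(s_here)) syn_alts[[as.character(off)]] <- s_here
    if (length(n_here)) non_alts[[as.character(off)]] <- n_here
  }
  syn_off <- as.integer(names(syn_alts))
  if (length(syn_off) < s_plant) {
    stop("cannot plant ", s_plant, " synonymous changes in ", codons,
         " codons; increase the CDS length")
  }
  s_sel <- if (s_plant > 0) sort(sample(syn_off, s_plant)) else integer(0)
  non_off <- setdiff(as.integer(names(non_alts)), s_sel)
  if (length(non_off) < n_plant) {
    stop("cannot plant ", n_plant, " nonsynonymous changes in ", codons,
         " codons; increase the CDS length")
  }
  n_sel <- if (n_plant > 0) sort(sample(non_off, n_plant)) else integer(0)

  offs <- c(s_sel, n_sel)
  cls <- c(rep("synonymous", length(s_sel)),
           rep("nonsynonymous", length(n_sel)))
  ord <- order(offs)
  offs <- offs[ord]
  cls <- cls[ord]
  ref <- substring(cds, offs, offs)
  alt <- vapply(seq_along(offs), function(i) {
    pool <- if (cls[i] == "synonymous") {
      syn_alts[[as.character(offs[i])]]
    } else {
      non_alts[[as.character(offs[i])]]
    }
    if (length(pool) == 1) pool else sample(pool, 1)
  }, "")

  truth <- data.frame(pos = cds_start + offs - 1L, ref = ref, alt = alt,
                      class = cls, stringsAsFactors = FALSE)
  n <- n1 + n2
  m <- matrix(0L, nrow = nrow(truth), ncol = n)
  if (nrow(truth) > 0) m[, (n1 + 1):n] <- 1L
  table <- variant_table(
    strain_ids,
    data.frame(chrom = chrom, pos = truth$pos, ref = truth$ref,
               alt = truth$alt, stringsAsFactors = FALSE),
    m
  )
  tx <- transcript_cds(
    id = paste0(gene_name, ".t1"), gene = gene_name, chrom = chrom,
    exons = data.frame(start = cds_start, end = cds_start + 3 * k - 1),
    strand = "+", cds = cds
  )
  gene <- data.frame(
    name = gene_name, chrom = chrom, start = cds_start,
    end = cds_start + 3L * k - 1L, strand = "+",
    family_class = classify_gene_name(gene_name),
    stringsAsFactors = FALSE
  )
  list(transcript = tx, table = table, gene = gene, truth = truth)
}

#' Write a set of coding transcripts as FASTA
#'
#' Headers carry the transcript-to-gene mapping as
#' `>id gene=NAME chrom=CHR start=S end=E strand=+/-`.
#'
#' @param transcripts List of [transcript_cds()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, function(t) t$cds, ""))
  names(seqs) <- vapply(transcripts, function(t) {
    sprintf("%s gene=%s chrom=%s start=%d end=%d strand=%s",
            t$id, t$gene, t$chrom, min(t$exons$start), max(t$exons$end),
            t$strand)
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read single-exon coding transcripts from a FASTA written by
#' [write_cds_fasta()]
#'
#' @param path FASTA path.
#' @return List of [transcript_cds()] objects, named by transcript id.
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- list()
  for (i in seq_along(seqs)) {
    hdr <- names(seqs)[i]
    fields <- strsplit(hdr, "\\s+")[[1]]
    id <- fields[1]
    kv <- fields[-1]
    kv <- kv[grepl("=", kv)]
    vals <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
    out[[id]] <- transcript_cds(
      id = id, gene = vals[["gene"]], chrom = vals[["chrom"]],
      exons = data.frame(start = as.integer(vals[["start"]]),
                         end = as.integer(vals[["end"]])),
      strand = vals[["strand"]], cds = as.character(seqs[[i]])
    )
  }
  out
}
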