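#' Validated configuration for a full synthetic pipeline run
#'
#' Defaults reproduce the analysis conditions of the reference workflow:
#' 5 kb windows, extreme-tail thresholds -2.5 / +2.5 on D, candidate
#' window threshold D > 1 and shared-haplotype fraction > 0.5. The
#' simulated genome mixes neutral, sweep-like and balanced two-lineage
#' chromosomes over one shared strain panel, plants a chemoreceptor-class
#' enrichment of `enrichment_e` in the extreme windows, and plants one
#' coding chemoreceptor gene with known inter-lineage substitutions.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed driving every stage.
#' @param width Window width in bases.
#' @param tail_low,tail_high Tail thresholds on D.
#' @param min_d Candidate window threshold on D.
#' @param min_shared Candidate shared-haplotype fraction threshold, in
#'   `[0, 1]`.
#' @param n1,n2 Lineage sizes of the strain panel.
#' @param theta Neutral/sweep mutation rate per window.
#' @param windows_neutral,windows_sweep,windows_balanced Number of
#'   simulated windows per regime.
#' @param k_balanced Inter-lineage fixed differences per balanced window.
#' @param theta_w_balanced Within-lineage rate in balanced windows.
#' @param singleton_excess Sweep singleton-excess factor.
#' @param enrichment_e Planted chemoreceptor enrichment fold.
#' @param class_g Genome-wide per-window class probability.
#' @param dnds_n,dnds_s Planted nonsynonymous / synonymous counts for
#'   the coding gene.
#' @param dnds_codons CDS length (codons) of the planted coding gene.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, width = 5000,
                       tail_low = -2.5, tail_high = 2.5, min_d = 1.0,
                       min_shared = 0.5, n1 = 10, n2 = 10, theta = 10,
                       windows_neutral = 400, windows_sweep = 25,
                       windows_balanced = 8, k_balanced = 40,
                       theta_w_balanced = 0.5, singleton_excess = 10,
                       enrichment_e = 5, class_g = 0.12,
                       dnds_n = 5, dnds_s = 20, dnds_codons = 200) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed), width = width,
    tail_low = tail_low, tail_high = tail_high, min_d = min_d,
    min_shared = min_shared, n1 = n1, n2 = n2, theta = theta,
    windows_neutral = windows_neutral, windows_sweep = windows_sweep,
    windows_balanced = windows_balanced, k_balanced = k_balanced,
    theta_w_balanced = theta_w_balanced,
    singleton_excess = singleton_excess, enrichment_e = enrichment_e,
    class_g = class_g, dnds_n = dnds_n, dnds_s = dnds_s,
    dnds_codons = dnds_codons
  )
  if (!is.numeric(cfg$min_shared) || cfg$min_shared < 0 ||
      cfg$min_shared > 1) {
    stop("min_shared must lie in [0, 1]")
  }
  if (cfg$tail_low >= cfg$tail_high) stop("tail_low must be < tail_high")
  if (cfg$width <= 0) stop("width must be positive")
  if (cfg$n1 < 2 || cfg$n2 < 2) stop("each lineage needs >= 2 strains")
  if (cfg$enrichment_e <= 0 || cfg$enrichment_e * cfg$class_g > 1) {
    stop("enrichment_e and class_g must satisfy 0 < e, e*g <= 1")
  }
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full synthetic selection-scan pipeline
#'
#' simulate -> scan -> annotate -> enrich -> signature -> dN/dS ->
#' report. Writes `panel.vcf`, `genes.gff3`, `cds.fa`, `scan.tsv`,
#' `enrichment.tsv`, `candidates.tsv`, `dnds.tsv`, `summary.json`,
#' `config.json` and `manifest.json` into `config$out_dir`. The run is a
#' pure function of the config (same config + seed gives byte-identical
#' outputs).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`table`, `scan`, `annotations`, `enrichment`, `candidates`,
#'   `dnds`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- config$n1 + config$n2
  ids <- .strain_names(n)
  w <- config$width

  sim <- .stage("simulate", {
    neutral <- simulate_neutral(n, config$theta, config$windows_neutral,
                                width = w, chrom = "simI",
                                seed = config$seed + 1L, strain_ids = ids)
    sweep <- simulate_sweep(n, config$theta, config$windows_sweep,
                            singleton_excess = config$singleton_excess,
                            width = w, chrom = "simII",
                            seed = config$seed + 2L, strain_ids = ids)
    balanced <- simulate_balanced(config$n1, config$n2, config$k_balanced,
                                  theta_w = config$theta_w_balanced,
                                  n_windows = config$windows_balanced,
                                  width = w, chrom = "simIII",
                                  seed = config$seed + 3L,
                                  strain_ids = ids)
    coding <- simulate_coding_gene(config$dnds_n, config$dnds_s,
                                   config$dnds_codons, n1 = config$n1,
                                   n2 = config$n2, chrom = "simIV",
                                   cds_start = 101L,
                                   seed = config$seed + 4L,
                                   strain_ids = ids)
    list(table = bind_tables(neutral, sweep, balanced, coding$table),
         coding = coding)
  })
  write_vcf(sim$table, file.path(config$out_dir, "panel.vcf"))

  scan <- .stage("scan", scan_genome(sim$table, width = w, panel_n = n))
  write_scan_tsv(scan, file.path(config$out_dir, "scan.tsv"))

  ann_sim <- .stage("annotate", simulate_genome_annotation(
    scan, e = config$enrichment_e, g = config$class_g,
    seed = config$seed + 5L
  ))
  genes <- rbind(ann_sim$genes, sim$coding$gene)
  write_gff3_genes(genes, file.path(config$out_dir, "genes.gff3"))
  write_cds_fasta(list(sim$coding$transcript),
                  file.path(config$out_dir, "cds.fa"))
  annotations <- annotate_bins(scan, genes)

  enrich <- .stage("enrich", enrichment_report(
    scan, annotations, low = config$tail_low, high = config$tail_high
  ))
  utils::write.table(enrich$table,
                     file.path(config$out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  candidates <- .stage("signature", candidate_scan(
    sim$table, genes, scan, min_d = config$min_d,
    min_shared = config$min_shared
  ))
  utils::write.table(candidates,
                     file.path(config$out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  transcripts <- list(sim$coding$transcript)
  names(transcripts) <- vapply(transcripts, function(t) t$gene, "")
  dnds_rows <- .stage("dnds", {
    sigs <- attr(candidates, "signatures")
    rows <- list()
    for (g in candidates$gene) {
      if (!g %in% names(transcripts)) next
      r <- lineage_dnds(sigs[[g]], sim$table, transcripts[[g]])
      rows[[g]] <- data.frame(
        gene = r$gene, n_obs = r$n_obs, s_obs = r$s_obs,
        N_sites = r$N_sites, S_sites = r$S_sites, dN = r$dN, dS = r$dS,
        ratio = r$ratio, stringsAsFactors = FALSE
      )
    }
    if (length(rows)) do.call(rbind, rows) else data.frame(
      gene = character(0), n_obs = integer(0), s_obs = integer(0),
      N_sites = numeric(0), S_sites = numeric(0), dN = numeric(0),
      dS = numeric(0), ratio = numeric(0), stringsAsFactors = FALSE
    )
  })
  rownames(dnds_rows) <- NULL
  utils::write.table(dnds_rows, file.path(config$out_dir, "dnds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scored <- scan$n_snps >= 1 & !is.na(scan$D)
  defined_ratio <- dnds_rows$ratio[!is.na(dnds_rows$ratio)]
  summary_obj <- list(
    n_windows = nrow(scan),
    n_scored_bins = sum(scored),
    n_low_tail_bins = sum(scored & scan$D < config$tail_low),
    n_high_tail_bins = sum(scored & scan$D > config$tail_high),
    n_candidate_genes = nrow(candidates),
    n_candidates_with_ratio = length(defined_ratio),
    n_candidates_ratio_undefined = sum(is.na(dnds_rows$ratio)),
    fraction_candidates_ratio_below_0.2 =
      if (length(defined_ratio)) mean(defined_ratio < 0.2) else NA,
    planted_enrichment_e = ann_sim$truth$e,
    planted_dnds = list(n = config$dnds_n, s = config$dnds_s)
  )
  # out_dir is implicit from the file location; leaving it out keeps the
  # bundle byte-identical wherever it is written
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_rec <- unclass(config)
  cfg_rec$out_dir <- NULL
  jsonlite::write_json(cfg_rec, cfg_path, auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  manifest <- list(
    package = "tajimascan",
    version = as.character(utils::packageVersion("tajimascan")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    outputs = c("panel.vcf", "genes.gff3", "cds.fa", "scan.tsv",
                "enrichment.tsv", "candidates.tsv", "dnds.tsv",
                "summary.json")
  )
  jsonlite::write_json(summary_obj,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    table = sim$table, coding = sim$coding, scan = scan,
    annotations = annotations, truth = ann_sim$truth,
    enrichment = enrich, candidates = candidates, dnds = dnds_rows,
    summary = summary_obj, manifest = manifest
  ))
}
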