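---
title: "Methods: windowed selection scans, shared-haplotype signatures and within-species dN/dS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans, shared-haplotype signatures and within-species dN/dS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tajimascan)
```

This vignette documents the statistical models behind `tajimascan`, the
choices made where the methodology admits more than one reasonable
convention, and what the synthetic-data tests do and do not demonstrate
about real data.

## The data model: haploid strain panels

All statistics operate on a `variant_table`: biallelic SNV sites by
strains, with genotypes in {0, 1, missing}. The target organisms are
predominantly self-fertilizing nematodes, whose wild isolates are
effectively inbred lines; we therefore treat each strain as a single
haplotype. On VCF ingest (`read_vcf()`):

* indels and multiallelic records are excluded — the window statistics
  and the codon classifier are defined for single-nucleotide biallelic
  variation only;
* diploid homozygous calls collapse to haploid (`0/0 → 0`, `1/1 → 1`);
* heterozygous calls become *missing*, not fractional: in an inbred
  panel residual heterozygosity is more plausibly call uncertainty than
  true heterozygosity, and a haploid data model cannot represent half
  an allele;
* sites with a missing fraction above `max_missing_fraction`
  (default **0.05**) are dropped. The default reflects common windowed-
  scan practice; there is no single published convention, so the
  threshold is exposed as a parameter.

## Windowed Tajima's D

Windows are 0-based half-open intervals `[k·w, (k+1)·w)` anchored at
coordinate 0 of each chromosome, with width `w` = **5000 bases** by
default — the classic bin size for genome-wide scans in compact
genomes, and the binning convention of the widely used vcftools
`--TajimaD` output (our TSV dialect matches its `CHROM`, `BIN_START`,
`N_SNPS`, `TajimaD` columns). A 1-based site at position `p` falls in
bin `floor((p−1)/w)`.

Per window we report `S` (sites segregating among called strains), `π`
(sum over sites of `2j(m−j)/(m(m−1))`, with `j` the alternate count
and `m` the called count at the site), `θ_W = S/a₁`, and

\[ D = \frac{\pi - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}} \]

with Tajima's constants computed in `harmonic_constants()`. Numerical
choices:

* `D` is **undefined** (NA, written as `nan`) when `S = 0` or the
  variance term vanishes — notably for `n = 2`, where `c₁ = c₂ = 0`
  analytically. Undefined windows are excluded from all tail counting.
* Missing-data handling is asymmetric by design: per-site `π` uses
  called alleles only, while the constants use the full panel size `n`.
  At the default 5% missingness cap the distinction is negligible; a
  strict analysis can pre-filter with `max_missing_fraction = 0`.
* Constants are exact finite sums; tests require agreement with direct
  closed-form evaluation to 1e-12 and with an independent brute-force
  implementation (pairwise-difference π, freshly summed constants) to
  1e-8 over random panels.

When chromosome lengths are supplied, zero-SNP windows are reported
too; both "all windows" and "scored windows" (`S ≥ 1`) counts appear in
summaries, because downstream enrichment fractions are defined over
scored windows only (consistency between the tail and its denominator).

## Gene families and tail enrichment

Genes are classified from the name token before the first hyphen,
case-insensitively: chemoreceptor families (`sra`, `srab`, `srb`,
`srbc`, `srd`, `sre`, `srg`, `srh`, `sri`, `srj`, `srm`, `srn`, `srr`,
`srsx`, `srt`, `sru`, `srv`, `srw`, `srx`, `srxa`, `srz`, `str`),
fast-evolving expanded families (`fbxa`, `fbxb`, `fbxc`, `clec`,
`nhr`), and essential-phenotype proxies for purifying selection
(`unc`, `bli`, `let`, `dpy`, `rol`, `egl`). The lists are arguments,
not constants — family nomenclature is genome-project-specific.

"A bin contains a gene" means **any overlap** between the gene span and
the window, the plainer reading of "contained"; a gene spanning a
boundary annotates every window it touches. (Gene-start-in-bin is a
stricter alternative; with 5-kb windows and typical gene lengths the
difference is small, and the overlap rule is the one we commit to.)
Class flags per bin are independent — a bin can contain both an
essential gene and a chemoreceptor; the histogram display uses an
exclusive priority (chemoreceptor > fast-evolving > purifying-proxy)
for colouring only.

The enrichment fold for class `c` in a tail is

\[ \text{fold} = \frac{\Pr(\text{bin contains } c \mid \text{bin in tail})}
                      {\Pr(\text{bin contains } c \mid \text{bin scored})} \]

with default tail thresholds **D < −2.5** and **D > 2.5** — far tails
chosen so that genome-wide demographic shifts of the D distribution
(population expansion, bottlenecks) do not dominate the signal. The
fold's approximate 95% CI is computed on the log scale by the delta
method over the two binomial fractions, ignoring their (positive)
correlation, which makes the interval slightly conservative. A class
absent from every scored bin has an undefined genome-wide fraction and
raises an error; an empty tail reports `fold = NA`.

## The shared-haplotype signature

Long-term balancing selection maintains two deep lineages; SNPs that
accumulated since the split segregate in near-perfect linkage and all
induce the *same* strain bipartition. We operationalize "most SNPs on a
shared haplotype" as follows:

* a fully-called polymorphic SNP induces the unordered bipartition
  {ref carriers} | {alt carriers}, canonicalized so the first strain
  carries 0 (making the key invariant to ref/alt labelling);
* SNPs with any missing call are excluded from numerator and
  denominator — a missing call makes the induced bipartition ambiguous;
* the gene's signature is the modal bipartition, its support, and
  `shared_fraction = support / usable SNPs`; candidates require
  `shared_fraction > 0.5` (strict).

We use **exact identity** of bipartitions (perfect linkage), not a
four-gamete compatibility relation: identity is the simplest reading of
a shared haplotype, and is what the balanced simulator generates.
Ties between equally supported bipartitions break toward the larger
minor side (a deeper, more balanced split is the more interesting
candidate), then lexicographically — deterministic output for any
input. Tests verify the modal support against exhaustive enumeration of
all `2^(n−1) − 1` bipartitions for panels up to n = 12.

The candidate filter is the conjunction of the window criterion
(gene overlaps a window with **D > 1**, a deliberately permissive
threshold that catches balanced regions diluted by their window) and
the signature criterion (shared fraction > 0.5). Gene span is taken
from the annotation as-is, with no promoter flank.

## Within-species counting dN/dS

For a candidate gene, the substitutions that distinguish the two
lineages are the SNPs supporting the modal bipartition. Each is
classified **independently against the reference codon** (the
convention of per-variant effect annotators; compound codon paths with
two variants in one codon are not modelled — at within-species
divergence levels double-hit codons are rare). Minus-strand transcripts
complement the alleles before codon substitution. A variant whose
reference allele disagrees with the transcript sequence raises an
error naming the site rather than silently reclassifying.

Potential-site totals follow the classic counting convention: each
codon position contributes `syn/3` of a site to `S_sites` and
`nonsyn/3` to `N_sites` over its three possible substitutions, with
**stop-creating changes excluded from both** (their fractional sites
are reported separately, so `N + S + stop-excluded = 3 × codons`
exactly). Observed nonsense variants count as nonsynonymous. Then
`dN = n_obs/N_sites`, `dS = s_obs/S_sites`, and the ratio is
**undefined — not zero — when `s_obs = 0`**. No multiple-hit
correction is applied: within-species counts are small and the ratio
of raw normalized counts is the quantity of interest. When a gene has
several transcripts, use the longest CDS (the package operates on
whatever transcript is supplied).

`pairwise_divergence()` is the companion primitive for promoter/locus
comparisons: mismatches over equal-length aligned sequences, gap
positions excluded from both counts; it performs no alignment.

## What the simulator emulates — and what it does not

The generators are first-class, tested code, not fixtures:

* `simulate_neutral()` draws per-window genealogies from the standard
  n-coalescent (exponential waiting times `Exp(k(k−1)/2)`, uniform
  pair merges) and places mutations by infinite sites at rate `θ/2`
  per unit branch length. The coalescent is implemented directly so
  that it is itself under test (site-frequency-spectrum
  goodness-of-fit, mean-D neutrality) rather than delegated to an
  external simulator.
* `simulate_sweep()` approximates a recent sweep by demoting mutations
  to singletons with probability `1 − 1/f` (`f` = `singleton_excess`,
  default **10**); `f = 1` reduces exactly to the neutral model, giving
  a clean null for distributional tests.
* `simulate_balanced()` plants `k` fixed differences between two strain
  groups (one shared bipartition) over within-group coalescent
  variation at `θ_w`; defaults (`k = 40`, `θ_w = 0.5` against panel
  `θ = 10`) give unambiguously positive D without saturating every
  statistic at its extreme.
* `simulate_genome_annotation()` plants a tail-enrichment fold: each
  extreme bin (|D| > 2) receives a chemoreceptor-class gene with
  probability `e·g` and each other scored bin with probability
  `g(W − eE)/(W − E)`, so the genome-wide class fraction is exactly
  `g` (default **0.12**) and the expected fold is exactly `e`. The
  parameter is defined at the *bin* level deliberately: under per-gene
  placement propensities the observable fold saturates below the
  propensity ratio once the enriched tail inflates the genome-wide
  denominator, making the parameter unidentifiable from the fold. The
  bin-level definition keeps planted truth and estimator aligned.
* `simulate_coding_gene()` builds a random stop-free CDS (ATG ... TAA)
  and plants verified synonymous/nonsynonymous substitutions, at most
  one per CDS position, fixed between two lineages. Plants avoid
  stop-creating changes so the analytic ratio
  `(n/N_sites)/(s/S_sites)` is exact; infeasible plants (CDS too
  short) raise an error.

Every generator is a pure function of its arguments and seed;
re-running with the same seed produces byte-identical VCF/GFF3/FASTA.

**Limits of the emulation.** There is no recombination within windows,
no linkage between windows, no gene conversion, no demographic history
(bottlenecks, expansion, population structure beyond the two planted
lineages), no mutation-rate heterogeneity, and annotations place genes
wholly inside single windows. Passing recovery tests therefore shows
the *estimators* are correct under their assumed models — not that
real panels satisfy those models. In real data, genome-wide shifts of
the D distribution are expected and motivate the far-tail thresholds;
hyperdivergent regions may violate the biallelic-SNV data model
(reference-alignment dropout presenting as missingness); and
chemoreceptor-family name prefixes are an imperfect proxy for true
family membership.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on simulated
data at desk scale, chosen to keep every Monte-Carlo check
well-powered: 500 windows per regime for mean-D sign behavior (n = 20,
θ = 10), 100 random panels (n ≤ 12, S ≤ 20) for oracle agreement, all
549 sense-codon single-base changes for the codon classifier, 200-codon
coding genes for dN/dS recovery, a 500-window genome with 25 extreme
bins and 100 seeded placements for enrichment-fold recovery, and an
~18,000-genealogy draw for the site-frequency-spectrum test. The
end-to-end pipeline (`run_pipeline()`) defaults to a 434-window genome
(400 neutral, 25 sweep, 8 balanced, plus the planted coding gene's
window) and writes a manifest with the
seed and a config hash; identical configs yield byte-identical output
bundles, which the acceptance script verifies by rerunning.
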