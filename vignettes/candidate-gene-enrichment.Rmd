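---
title: "Candidate-gene prioritization and the binomial enrichment test: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene prioritization and the binomial enrichment test: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gentos)
```

## The model

`gentos` mines GWAS summary statistics for association signals inside a
pre-specified candidate gene list. Its statistical core is a relaxation of
the genome-wide multiple-testing correction: instead of dividing the
family-wise error probability α by ~10⁶ (the conventional count of
independent common variants genome-wide, giving 0.05/10⁶ = 5×10⁻⁸), α is
divided only by the number of *independent* SNPs inside the candidate
regions. "Independent" is operationalised by LD pruning: no two retained
SNPs that ever shared a pruning window may have squared dosage correlation
r² above a cutoff (default 0.2), so the retained count approximates the
effective number of tests in a region.

Enrichment of the candidate list as a whole is assessed by treating each
gene as a Bernoulli trial. Let

* *n* — number of resolved candidate genes,
* *p* — background probability that a gene is "significant" (contains at
  least one SNP below the threshold), estimated as the proportion of
  significant genes among *all* genes in the annotation store at the same
  fixed threshold,
* *x* — observed number of significant candidate genes.

Then under the null X ~ Binomial(n, p) and the enrichment p-value is the
upper tail P(X ≥ x) = 1 − Σ_{k=0}^{x−1} C(n,k) pᵏ (1−p)^{n−k}.

Assumptions worth stating:

* **Gene-wise independence.** SNP p-values are correlated through LD, but
  the Bernoulli trials are *genes*, and flanked gene regions overlap
  rarely; residual inter-gene LD makes the binomial mildly approximate.
  That is why the package also ships the resampling null
  (`resampling_null()`), which draws random gene lists of the same size
  from the store, recomputes the list-wise Bonferroni threshold for every
  draw (each draw has its own size and LD structure), and rescans. The two
  nulls are compared by pairing their order statistics and computing the
  Spearman rank correlation (`compare_nulls()`); on synthetic null data the
  coefficient stays above 0.9 across thresholds spanning 10⁻² to 10⁻⁵.
* **A single fixed threshold.** The background rate is only meaningful if
  the same threshold applies to every gene, so `enrich()` refuses per-gene
  Bonferroni thresholds and requires the list-wise, fixed or FDR mode.
* **Uniform draws.** Resampled lists are drawn uniformly without
  replacement from the whole store; candidate genes are not excluded from
  the null draws (their influence is O(list/store) and the universe is
  what the background rate is defined on).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `flank_bp` | 10 000 bp | symmetric extension of each gene span; covers promoters and proximal regulatory sequence |
| `alpha` | 0.05 | family-wise type-I error before division by the independent-SNP count |
| `window_size`, `step` | 50, 5 SNPs | pruning window geometry (SNP counts, not bp) |
| `r2_threshold` | 0.2 | maximal allowed pairwise r² among retained windowed SNPs |
| `maf_min` | 0.01 | minor-allele-frequency floor before pruning |
| `iterations` | 2 000 | null-distribution draws; a compromise between runtime and tail precision |

The pruning defaults mirror the common plink invocation
`--indep-pairwise 50 5 0.2 --maf 0.01` on a 1000-Genomes-style reference
panel; ancestry panels (e.g. EUR/AFR/ASN/ALL) are kept side by side in one
store and selected per analysis.

## Coordinate and scanning conventions

* Gene spans are stored 0-based half-open (refFlat native); the annotation
  source is never shifted.
* Summary-file positions are 1-based. A SNP at position q is inside a
  region [s, e) iff s < q ≤ e; the independent-SNP store is queried with
  the equivalent 1-based half-open interval [s+1, e+1).
* Chromosome names are compared after stripping an optional `chr` prefix.
* Hits require **strict** inequality p < threshold.
* A SNP inside k overlapping flanked regions is emitted k times, once per
  gene, and overlapping regions' independent-SNP counts are summed without
  deduplication in the list-wise M — the conservative direction (larger M,
  stricter threshold).

## Numerical choices

* **Tail evaluation.** P(X ≥ x) is computed as
  `pbinom(x - 1, n, p, lower.tail = FALSE)`, not as 1 − CDF; the survival
  form is accurate down to the 10⁻¹⁰-scale tails the test is meant to
  resolve. The test suite checks agreement with term-by-term enumeration of
  the printed sum to ≤10⁻¹² relative error over an exhaustive grid (n ≤ 50,
  all x, p ∈ {0.01, 0.1, 0.5}).
* **FDR mode.** The Benjamini–Hochberg step is applied to the p-values of
  all SNPs inside the candidate regions. BH rejects every p ≤ p₍k₎ (the
  largest passing order statistic), while scanning is strict; the threshold
  is therefore set to p₍k₎·(1 + ε) so that exactly the BH-passing SNPs are
  admitted. With no passing SNP the threshold is the smallest positive
  double, which no valid p-value can undercut.
* **Degenerate inputs.** Summary p-values of exactly 0 are clamped to the
  smallest positive double (with a warning); unparseable p-values or
  positions are skipped and counted. An all-missing genotype column has
  MAF treated as 0 and falls to the MAF filter. r² over fewer than two
  pairwise-complete samples, or with a constant vector, is defined as 0
  (no evidence of linkage). Two constant null-count samples make the QQ
  Spearman coefficient undefined; it is reported as NaN with a warning.
* **Pruning tie-breaks.** Within a window the worst pair (highest r²) is
  resolved by removing the lower-MAF member; on a MAF tie the
  later-positioned member; among equal-r² pairs the first in column-major
  order is processed. These rules are fixed purely for determinism — the
  original plink implementation does not publish its internal choice, so
  bit-identity with plink is not claimed. Correctness is instead defined by
  (a) exact agreement with an independently coded brute-force replay of the
  same greedy rule and (b) the post-hoc guarantee that no retained
  windowed pair exceeds the r² cutoff; both are exercised on random panels
  in the test suite.
* **Length ties in the gene store** are broken by the lexicographically
  smallest transcript id; genes whose transcripts map to more than one
  chromosome are excluded entirely and reported.

## The synthetic data, and what passing tests do (and do not) show

The generators emulate the three external inputs at desk scale:

* `generate_gene_catalog()` — non-overlapping genes with 1–3 transcripts
  (one longest, recorded in a truth table) rendered as refFlat text.
* `generate_ld_panel()` — block-exchangeable LD: each block of SNPs copies
  a latent haplotype pair and flips alleles with probability
  (1 − √r)/2, giving within-block dosage correlation ≈ r and independent
  blocks. This is sufficient to exercise MAF filtering and windowed
  pruning, and the expected retained count per block is analysable (one
  SNP per block when r² exceeds the pruning cutoff).
* `generate_gwas_summary()` — i.i.d. Uniform(0,1) p-values with optional
  planted low-p SNPs inside chosen genes, plus a truth table.

All generators are pure functions of their seed (byte-stable files).

Deliberately **not** emulated: realistic allele-frequency spectra,
population structure, coalescent LD decay, and the LD-induced correlation
of neighbouring p-values in real summary statistics. Consequently the
validation suite demonstrates the correctness of the machinery (thresholds,
counting, tail arithmetic, calibration under the stated null) — it does not
demonstrate that the binomial null is exact on real GWAS data, where the
resampling null remains the reference procedure.

## Problem sizes used in the validation studies

The null-agreement and calibration studies run on a 2,000-gene catalog over
four 5.5-Mb chromosomes (gene lengths 6–10 kb, 1-kb flanks) with a
1.1-million-SNP null summary file — about 500 SNPs per flanked region.
That density was chosen analytically, before any test was run, as the
regime in which every fixed threshold between 10⁻² and 10⁻⁵ leaves a
non-degenerate significant-gene count on 300-gene lists: at 10⁻² a region
escapes significance with probability (1−10⁻²)⁵⁰⁰ ≈ 0.007 (so counts stay
just below saturation), while at 10⁻⁵ the expected count 300·(1−(1−10⁻⁵)⁵⁰⁰)
≈ 1.5 remains positive. Null comparisons use 500 draws of 300-gene lists;
calibration uses 200 draws of 50-gene lists; planted-signal recovery uses
100 replicates of 5 signals in 50 candidates over a 1,000-gene store.

## Known limitations

* Thresholding treats the independent-SNP count as exact; uncertainty in
  the pruning (reference-panel sampling noise) is not propagated.
* The FDR mode is a pragmatic Benjamini–Hochberg over candidate-region
  SNPs; it is not a reconstruction of any particular published FDR variant.
* Gonosomal genes are excluded by default because most public summary
  files omit X/Y; analyses with sex-chromosome coverage must pass
  `exclude_gonosomes = FALSE` consistently.
* Summary files must share one genome build with the annotation; no
  liftover is performed.
* Approximate conditional analysis (distinguishing one signal from several
  per region) is out of scope; a gene counts as significant if any SNP in
  its region passes.
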