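---
title: "Methods: promoter-centric integration of TF binding and expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-centric integration of TF binding and expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promint)
```

`promint` packages the statistical core of a promoter-centric
transcription-factor study: given peaks, a gene annotation, coverage,
CAGE 5′-tag counts, a differential-expression (DE) table and gene sets, it
quantifies whether the factor binds at TSSs, whether its motif is there,
and whether binding predicts transcriptional response. This vignette
documents the models, the parameter choices, and what the synthetic data
generator does and does not establish.

## Coordinates and interval statistics

All coordinates are 0-based, half-open — the native frame of BED and
bedGraph; GTF (1-based, closed) is converted on read. This makes interval
arithmetic uniform: `[0,10)` and `[10,20)` abut without overlapping, and a
TSS is a single base `t` that a peak overlaps iff `start <= t < end`.
Chromosome names that do not match the declared genome layout are a hard
error rather than silently dropped, because silent loss biases every
genome-wide statistic computed afterwards.

The **Jaccard index** is computed at base-pair level on merged sets
(bedtools semantics): counting peaks instead of bases makes the statistic
depend on arbitrary peak fragmentation, and merged-bp Jaccard is the
interpretation consistent with interval sets of unequal width.

The **relative distance** statistic normalises the genome so adjacent
anchors are distance 1 apart: an interval midpoint `x` with flanking
anchors `L <= x <= R` scores `min(x - L, R - x) / (R - L)`. Under spatial
independence the statistic is uniform on `[0, 0.5]`; association with
anchors concentrates it near 0. Midpoints are the default interval
representative (summits optional, `use = "summit"`): the normalised-genome
construction is defined on a single representative point, and midpoints
need no extra peak metadata. Midpoints outside the anchor span are skipped
and reported in `n_skipped` rather than clamped.

**Peak classification** uses full peak extent (not the midpoint) with the
precedence TSS > gene body > intergenic, so that a wide peak that covers a
TSS and downstream exon counts as a TSS peak; classes are mutually
exclusive and exhaustive by construction. Nearest-TSS ties are broken by
the lexicographically smaller gene id, for determinism.

**Genome-wide peak-overlap Fisher tests** need a null cell for "neither
set present". We use the bedtools-fisher construction: `n22 = max(0,
G / mean_width - n11 - n12 - n21)`, with `mean_width` the mean interval
width of the merged union. This synthetic null is crude — it treats the
genome as `G / mean_width` exchangeable slots — so the full 2×2 table is
returned and callers can substitute their own null (e.g. a shuffling-based
one, which is out of scope here).

## Motif scanning

Scores are log₂ odds, `score(b, i) = log2((p(b,i) + c·bg(b)) / bg(b))`
summed over positions, with pseudocount `c = 0.001`. P-values are exact
tail probabilities under the 0-order background, computed by dynamic
programming over per-position scores discretised to 1/1000 bit. The
discretisation error is orders of magnitude below the thresholds in use
(3e-3 for general promoter elements, 2e-4 for the TF's own motifs);
window scores are discretised per position with the same rounded matrix
the DP uses, so every observable score is exactly a support atom of the
distribution and p-value lookup is exact. Hits are windows with
`p <= threshold` on either strand; reverse-strand coordinates are reported
on the forward frame; windows containing N are skipped; overlapping
self-hits of periodic motifs are all reported (no greedy masking), as FIMO
does.

The background defaults to the 0-order composition of the scanned
sequences themselves (FIMO's default), overridable for calibration work.
Packaged motif models are IUPAC-consensus reconstructions (each consensus
letter spreads probability `1 - 0.04` over its allowed bases): the
underlying studies publish logos and consensus strings, not matrices, and
the files say so in their headers. A practical consequence: a
consensus-derived PWM with `k` informative positions cannot reach p-values
below `4^-k` under a uniform background, so thresholds must be chosen with
the motif's information content in mind (the degenerate 7-mer core with
one N has a floor of `4^-6 ≈ 2.4e-4`).

For motif-in-peak statistics a hit must be fully contained in the peak,
and offsets are signed distances from the hit centre to the peak summit
(midpoint when no summit is recorded). When estimating the dispersion of a
planted motif around summits, the per-peak hit nearest the summit is used:
a peak's motif is by construction its central one, and this estimator is
robust to the background hits expected at any finite threshold.

## Coverage and meta-profiles

Tracks store the mean per-base signal in fixed-width bins (5 bp default,
matching common practice for single-bp-resolution browser tracks).
Fragments contribute fractionally to each bin they overlap, so total track
mass equals fragment bp over bin width. BPM normalisation rescales all
bins to sum to 1e6. "ChIP minus input" is BPM-normalised subtraction;
log₂-ratio with pseudocount 1 is available, but subtraction is the default
because the quantity being profiled is reported as a signed difference of
normalised coverage. Replicates are pooled by concatenating fragments
before normalisation; per-replicate runs are a matter of calling the same
functions per replicate.

Reference-point matrices use 2 kb flanks and 25 bp bins by default; rows
are oriented 5′→3′ by anchor strand and bins beyond chromosome ends are
zero (missing-as-zero). Scale-regions (metagene) matrices rescale each
gene body linearly to 4 kb with unscaled flanks. Heatmap rows order by
descending row maximum, stable in anchor order on ties.

## CAGE promoters

CTSS counts are TPM-normalised against the library size. Tag clustering is
single-linkage distance clustering: positions with TPM ≥ 1 on the same
chromosome and strand link when the gap is ≤ 20 bp; singletons are dropped
unless their TPM reaches 5. The density-stability ("paraclu") flavour of
clustering is deliberately replaced by this simpler rule: the downstream
analysis consumes only each cluster's dominant position, which is robust
to the clustering flavour, and the distance parameter is the documented,
interpretable knob. The dominant TSS is the argmax-TPM position, ties
resolved 5′-most on the cluster strand.

Promoter windows are ±200 bp around the dominant TSS (a 401-nt window with
the TSS at offset 0, reverse-complemented for minus-strand clusters so
upstream is negative). 200 was chosen over the narrower 150 sometimes used
for the same analysis because the wider window loses nothing — element
densities are positional, and a wider window only extends the axis.
Element enrichment between promoter groups (e.g. bound vs unbound) is a
two-sided Fisher test on presence/absence with the sample odds ratio.

## Contingency statistics

All 2×2 tests report the **sample odds ratio** `ad/bc`, not the
conditional MLE that `fisher.test()` prints. On every published-scale
table the package reconstructs, the two round identically (2.21, 0.85,
2.8, 0.17), and the cross-product ratio is the estimator whose value a
reader can recompute from the printed cells; a build-time test asserts the
2-d.p. agreement. P-values are two-sided Fisher exact (one-sided for term
enrichment, which is an over-representation test — the direction is part
of the question there). Zero cells flag the odds ratio as infinite or
degenerate rather than being smoothed.

DE classification uses `padj < 0.05` and `|log2FC| > 0.5` (both
exclusive); genes with missing adjusted p (independent filtering upstream)
are `not_de`. The gene universe for binding and gene-set tests is the set
of expressed genes in the DE table and is an explicit argument, never
inferred; term enrichment takes its own custom background and applies
Bonferroni across tested terms, skipping terms with no background members.

## The synthetic-data generator

`simulate_bundle()` emulates the statistical structure the analysis
assumes: non-overlapping genes on both strands of an i.i.d.-uniform
genome; a fraction of genes carrying a peak over the TSS with the core
binding motif written into the sequence at the peak centre plus
`N(0, motif_offset_sd)`; ChIP fragments drawn from a point-source binding
model (enriched fragments centre on the planted motif with Gaussian
shearing spread of a quarter peak width, truncated to the peak) against a
uniform input; CAGE tags spread geometrically around each TSS; DE labels
drawn so binding → up-regulation has a planted odds ratio; and a
"maternal" gene set with a planted odds ratio given up-regulation. The
uniform background genome is a deliberate choice: it makes motif-scan
false-positive rates match their analytic p-values, which the calibration
tests rely on. Fragment length is fixed at 200 bp — profile shapes depend
only weakly on the length distribution.

Default study conditions: 2 chromosomes × 300 kb, 200 genes, 30% bound,
peak width ~N(400, 80) bp, motif offset SD 20 bp, 5× ChIP enrichment,
30k fragments per track, 50 CAGE tags per TSS with geometric spread 0.3,
binding→up odds ratio 2.2 over a 16% baseline up rate, 27% down rate, and
maternal-set odds ratio 2.8 — the magnitudes a promoter-proximal activator
study of this kind reports. Deterministic given the seed.

What passing on synthetic data does **not** show: real genomes have
non-uniform base composition, repeats and copy-number structure (motif
p-values are then only approximate), real peaks have irregular shapes and
widths, CAGE promoters have shape classes (broad vs sharp) the geometric
model ignores, and real DE effect sizes correlate with expression level.
The generator validates the statistical machinery, not biological
conclusions.

`paper_marginals_fixture()` is the deterministic counterpart: synthetic
gene lists realising, exactly, a published set of joint counts (10,804
expressed; 1,994 up; 2,924 down; 2,298 bound; 666 bound∩up; 564
bound∩down; embryo-set cells 1,409/625/3,448), so the published odds
ratios are reproduced end-to-end through `classify_de()`,
`binding_de_association()` and `gene_set_overlap()` rather than asserted.

## Numerical and scale choices

Test-suite and acceptance runs use desk-scale problem sizes chosen so
every property is measurable with comfortable statistical margins:
300–460-gene bundles for pipeline recovery, 5,000 intervals for the
relative-distance null (chi-square goodness of fit on 50 bins), 300 kb of
uniform sequence for scan-rate calibration (3 SE binomial margins),
exhaustive `4^w` enumeration up to `w = 8` for the score-distribution
oracle. Planted-parameter recovery is judged on the log odds-ratio scale
against twice its Woolf standard error `sqrt(sum(1/cells))`.

## Known limitations

- The peak-overlap Fisher null is the synthetic slot model described
  above; shuffling/permutation nulls are out of scope.
- Single-anchor TSS per gene in the annotation-based model; multi-TSS
  resolution is delegated to the CAGE module.
- No BAM or bigWig ingestion: fragments and coverage enter as BED and
  bedGraph.
- 0-order scan backgrounds only; no higher-order Markov backgrounds.
- Paraclu-style density clustering and CAGE promoter-shape statistics are
  not implemented.
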