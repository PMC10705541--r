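# promint

Integrative regulatory genomics for transcription factors that bind at or
near transcription start sites (TSSs), in tidy, pipe-friendly R.

## The problem

A common study design in epigenomics asks whether a DNA-binding protein is a
promoter-proximal activator: ChIP-seq peaks are called for the factor,
RNA-seq contrasts a loss-of-function condition against a rescue, CAGE 5′-tag
data maps the promoters actually used in the tissue, and the question is
whether the factor's peaks sit at TSSs, carry its sequence motif, coincide
with open/active chromatin, and predict a positive transcriptional response.
`promint` implements the statistics this design needs as composable
functions over tibbles:

- **Peak-set concordance** — base-pair Jaccard index
  J(A,B) = |A ∩ B| / |A ∪ B| over merged interval sets, and reciprocal
  overlap counts.
- **Relative distance** — for each peak midpoint *x* between flanking
  anchors *L* ≤ *x* ≤ *R* (TSSs, ORFs, termination sites),
  d = min(x−L, R−x) / (R−L); uniform on [0, 0.5] under spatial
  independence, piled up near 0 when peaks track the anchors.
- **Peak classification** — each peak is TSS / gene-body / intergenic with
  TSS precedence, plus nearest-TSS distances.
- **Motif scanning with exact p-values** — log₂-odds PWM scores with the
  exact tail distribution computed by dynamic programming over discretised
  per-position scores (the FIMO construction), both strands, N-aware.
- **Coverage meta-profiles** — bins-per-million (BPM) normalisation,
  ChIP-minus-input comparison, reference-point and scale-regions
  (metagene) matrices with strand-aware orientation and heatmap row
  ordering.
- **CAGE promoter architecture** — TPM normalisation, distance clustering
  of CTSS positions with dominant-TSS calling, strand-oriented promoter
  windows, positional density of core promoter elements (INR, TATA, DPE,
  MTE, M1BP), and bound-vs-unbound element enrichment.
- **Binding × expression statistics** — DE classification
  (p-adj < 0.05 and |log₂FC| > 0.5 by default), 2×2 Fisher exact tests
  with the sample odds ratio ad/bc, gene-set overlap per DE direction, and
  Bonferroni-corrected term enrichment over a custom background.
- **A seeded synthetic-data generator** — genome, gene models, peaks with a
  planted motif, ChIP/input fragments, CAGE tags, and DE labels with a
  planted binding→up-regulation odds ratio, so every stage runs and can be
  calibrated with no external data.

Results follow broom conventions (`tidy()`, `glance()`) and plot with
`autoplot()` / `plot_*()`.

## Worked example

```r
library(promint)

bundle <- simulate_bundle(sim_config(seed = 42, n_genes = 300, n_chroms = 2,
                                     chrom_length = 500000))
report <- run_pipeline(bundle)
report
#> <promint_report>
#>   peaks: 90 (TSS 90 / gene_body 0 / intergenic 0)
#>   mean reldist to TSS: 0.000; peaks with motif: 100.0%
#>   tag clusters: 300 (90 in peaks); bound genes: 90
#>   binding x DE odds ratios: up 1.45, down 1.02

glance(report$binding_de$up)
#> # A tibble: 1 × 4
#>   odds_ratio p_value direction universe_size
#>        <dbl>   <dbl> <chr>             <int>
#> 1       1.45   0.225 enriched            300
```

Reading the output: all 90 planted peaks overlap a TSS and their mean
relative distance to TSS anchors is ~0 (strong spatial association, against
a null of 0.25); every peak contains the planted binding motif; all 90
CAGE tag clusters at bound genes fall inside peaks; and bound genes are
enriched for up-regulation (odds ratio 1.45 here — a noisy draw around the
generator's planted 2.2 at only 300 genes; larger simulations concentrate
around the planted value).

Individual stages chain on plain tibbles, e.g.

```r
peaks  <- read_bed("peaks.narrowPeak", layout)
genes  <- read_gtf("annotation.gtf", layout)
peaks |> classify_peaks(genes) |> dplyr::count(class)
reldist(peaks, tibble::tibble(chrom = genes$chrom, pos = genes$tss)) |>
  autoplot()
```

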