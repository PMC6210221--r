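# coexbuffer

Protein-level buffering of non-functional mRNA coexpression across tissues.

## The problem

Across a panel of tissues, many housekeeping genes have correlated mRNA
profiles without being functionally related: genes that sit close together
on a chromosome, or whose chromatin carries a similar epigenetic state, are
transcribed up and down together as a side effect of their genomic context.
Functional coexpression — complex subunits, pathway members — propagates to
correlated *protein* abundances; context-driven coexpression largely does
not. Comparing the two layers therefore separates functional from
non-functional coexpression, and tells you which layer to trust for
coexpression-based gene function prediction.

`coexbuffer` is an R package for exactly this comparison on a matched
gene × tissue mRNA (log2 median-ratio TPM) and protein (log2 SILAC ratio)
panel. It computes, for every gene pair and on each layer, the
pairwise-complete Pearson correlation

r_ab = cor(x_a, x_b)  over tissues observed for both genes (≥ 8 required),

calls a pair **coregulated** when r > 0.5 with Benjamini–Hochberg adjusted
p < 0.05, and then explains the calls with:

* **genomic proximity** — TSS distances, close-by pairs (< 50 kb), Pearson
  chi-squared contingency tests, 5-nearest-neighbour positional clustering;
* **epigenetic similarity** — per-gene (histone mark × tissue) gene-body
  signal vectors, similarity = 1 / Mahalanobis distance
  (`1 / sqrt((x_a − x_b)' S⁻¹ (x_a − x_b))`), which accounts for
  co-dependent marks;
* the **coregulation landscape** — a 10 × 10 grid of distance deciles ×
  similarity deciles with resampling Kolmogorov–Smirnov tests of its corner
  sectors against equal-sized random backgrounds;
* **k-means clustering** of correlation profiles (first k explaining 50% of
  the variance), with subcellular-localization and epigenetic cluster
  profiling;
* **expression variability** (CV of offset log2 ratios) versus positional
  clustering and H3K36me3 signal;
* **post-transcriptional features** of buffered (mRNA-only) versus
  sustained (both-layer) pairs: shared miRNAs, CDS-length similarity,
  ribosome-occupancy correlation, translation-rate similarity, NED
  proteins.

Because the real inputs are large external datasets, the package ships a
synthetic-data generator (`simulate_tissue_panel()`) that plants each
mechanism — functional modules shared by both layers, anticorrelated
epigenetic archetypes, proximity co-fluctuation within < 200 kb
neighbourhoods, total protein-level buffering of everything non-functional —
with ground-truth labels, so the entire pipeline is testable by parameter
recovery.

## Worked example

Generate a synthetic 600-gene × 20-tissue panel and run the full pipeline
against its ground truth:

```r
library(coexbuffer)

panel <- simulate_tissue_panel(generator_config(), seed = 42)
panel$mrna
#> ExpressionMatrix [mrna layer]: 600 genes x 20 tissues, 6.3% missing

rec <- recovery_report(panel, seed = 7)
rec
#> Synthetic-panel recovery report
#> planted-mechanism coregulated fractions:
#>       planted      n frac_coregulated_mrna frac_coregulated_protein
#> 1: epigenetic  56496            0.26223095             0.0001416029
#> 2: functional   2337            0.36328626             0.8057338468
#> 3:       null 119985            0.00120015             0.0001583531
#> 4: positional    745            0.86308725             0.0000000000
#> close-by pairs coregulated: mRNA 86.2%, both layers 3.4%
#> ARI mRNA clusters vs archetypes: 0.638; protein clusters vs modules: 1.000
#> buffered/sustained accuracy: 0.992 (n = 16451)
```

Reading the numbers: pairs planted as *positional* (same < 200 kb
neighbourhood) are mRNA-coregulated 86% of the time but protein-coregulated
0% of the time, and *epigenetic* pairs (same chromatin archetype) 26%
versus 0.01% — the buffering the package is built to expose. *Functional*
module pairs, by contrast, are strongly coregulated on the protein layer
(81%), and protein-layer k-means recovers the planted modules perfectly
(adjusted Rand index 1.0). Of the close-by pairs, 86% are mRNA-coregulated
but only 3.4% survive on both layers, so only a small fraction of proximal
mRNA coregulation is functional. The sector tests on the landscape show the
same asymmetry:

```r
rec$sectors
#>    sector             name n_pairs       mean_p   layer
#> 1:      1    close_similar    3260 0.000000e+00    mrna
#> 2:      2      far_similar    3382 0.000000e+00    mrna
#> ...
#> 5:      1    close_similar    3260 1.293836e-01 protein
#> 6:      2      far_similar    3382 4.957252e-01 protein
```

High epigenetic similarity marks strong mRNA coexpression whether genes are
close or far apart (sectors 1 and 2, mean KS p ≈ 0), and none of it is
visible on the protein layer.

The same functions run on real data: `load_expression()` /
`normalize_tpm()` for the expression tables, `aggregate_genebody_signal()`
for bedGraph + BED ChIP-seq input, `load_epigenetic_profile()` for
pre-aggregated signal tables, plus a gene annotation table with
chromosome/TSS/strand/CDS columns.

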