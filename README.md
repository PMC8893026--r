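# seabiome

Statistical analysis of open-ocean bacterioplankton OTU surveys: who is
there, how communities differ across regions and depths, how much of that
difference is environmental selection versus spatial structure, and how
much is explained by neutral assembly.

The package is aimed at microbial ecologists holding the standard outputs
of a 16S rRNA amplicon workflow — an OTU count table, a sample metadata
table (coordinates, depth, temperature, nutrients, ...) and a rooted
phylogeny — and covers the downstream statistics end to end:

- **Pre-processing** — negative-control contaminant screening (an OTU with
  control count *c* is removed iff no sample reaches 10·*c* reads) and a
  single hypergeometric rarefaction to even depth.
- **Alpha diversity** — observed OTUs *S*, Shannon *H′* (base 2), Chao1,
  Heip's evenness *E* = (e^H − 1)/(S − 1) with *H* in nats; Kruskal–Wallis
  group tests, Spearman correlations, and least-squares regression on
  square-transformed metrics.
- **Beta diversity** — weighted UniFrac (raw Σ ℓ_b|A_b − B_b| and
  normalized by Σ ℓ_b(A_b + B_b)) and Bray–Curtis; PCoA with negative
  eigenvalues retained; PERMANOVA (pseudo-F on distance sums of squares,
  seeded label permutations), pairwise PERMANOVA, PERMDISP (betadisper-style
  imaginary-axis correction), ANOSIM, two-way SIMPER, and distance-decay
  regression of similarity (1 − d) on great-circle distance over ordered
  pairs.
- **Spatial analysis** — haversine distance matrices, Mantel tests, and
  PCNM spatial eigenfunctions (minimum-spanning-tree truncation, 4t
  replacement).
- **Constrained ordination** — partial distance-based RDA with
  reduced-model permutation and Ezekiel-adjusted R², forward selection by
  adjusted R² with a double stopping rule, and variation partitioning into
  pure-environment [a], shared [b], pure-space [c] and residual [d]
  fractions with proportional apportioning (a′ = R²·a/(a+c)) when
  collinearity drives the shared fraction negative.
- **Neutral community model** — Sloan's model: a taxon of metacommunity
  abundance *p* is predicted to occur in a fraction
  F = 1 − I_d(Nmp, Nm(1−p)) of communities (regularized incomplete beta,
  detection limit d = 1/N); *m* is fitted by bounded least squares and taxa
  are classified against Wilson 95% envelopes, overall and per depth
  stratum.
- **Synthetic data** — a transect generator with known truth
  (Dirichlet–multinomial neutral assembly, Gaussian temperature niches,
  station-to-station dispersal limitation, planted contaminants) so every
  stage is testable against ground truth.

The central container `OtuExperiment` extends `SummarizedExperiment`; all
statistical functions also accept a plain samples × OTUs matrix.

## Worked example

Simulate a 10-station, two-depth transect under neutral assembly
(m = 0.1), screen the planted contaminants, rarefy, and run the core
analyses:

```r
library(seabiome)

pool <- generateSourcePool(300, 1.5, seed = 42)
cfg  <- simConfig(n_stations = 10, reads_per_sample = 5000,
                  migration_m = 0.1, seed = 42)
ds   <- simulateDataset(cfg, pool = pool, n_contaminants = 2)
ds$table
#> OtuExperiment: 20 samples x 302 OTUs
#>   reads/sample: 5004-5017; tree: 302 tips

scr <- removeContaminants(ds$table, ds$negctrl)
scr$report
#>     otu_id negctrl_count max_sample_count
#> 1 CONTAM01           128                8
#> 2 CONTAM02           122               12

tab <- rarefyTable(otuCounts(scr$table), seed = 1)
head(alphaDiversity(tab), 3)
#>        sample_id observed_otus  shannon    chao1 heip_evenness
#> ST01_S    ST01_S           198 6.413464 212.7000     0.4276159
#> ST01_D    ST01_D           207 6.651919 231.0000     0.4833032
#> ST02_S    ST02_S           204 6.483199 221.6333     0.4357723

dm <- weightedUnifrac(tab, pool$tree)
md <- ds$metadata
permanova(dm, md$region, n_perm = 999, seed = 7)
#> PERMANOVA: pseudo-F = 1.384 (df 3, 16), p = 0.007 [999 permutations]

S <- as.data.frame(pcnmBasis(haversineMatrix(md))$vectors)
variationPartition(dm, md[, c("temperature", "salinity", "nitrate")], S,
                   n_perm = 99, seed = 7)
#> Variation partitioning (adjusted R-squared units)
#>   raw: a (pure env) = -0.002, b (shared) = 0.046, c (pure space) = 0.012, d (residual) = 0.943

fitNcm(frequencyAbundance(tab), n_samples = nrow(tab))
#> Sloan neutral community model fit
#>   m = 0.1292  (Nm = 645.9, N = 5000, detection limit 0.0002)
#>   R-squared = 0.912 over 294 taxa (4 below / 218 within / 72 above the 95% envelope)
```

Reading the output: region membership separates communities weakly but
significantly (small pseudo-F, p < 0.01) — expected, since the simulated
temperature gradient follows latitude; variation partitioning finds almost
no pure environmental or spatial signal under pure neutral assembly; and
the NCM fits the occurrence-frequency curve well (R² = 0.91) with the
fitted immigration probability near the generating value 0.1.

A whole survey can be driven from one configuration with
`runPipeline(pipelineConfig(...))` (or a YAML file via
`readPipelineConfig()`), producing a deterministic, machine-readable JSON
report covering every stage. The methods vignette
(`vignettes/seabiome-methods.Rmd`) documents the models, conventions and
design decisions.

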