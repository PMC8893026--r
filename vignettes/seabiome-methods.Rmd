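---
title: "Methods: diversity, spatial structure and neutral assembly of open-ocean bacterioplankton"
author: "seabiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, spatial structure and neutral assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seabiome)
```

# Scope and data model

`seabiome` implements the statistical core of a bacterioplankton biogeography
survey: it consumes an OTU count table (samples x OTUs), a per-sample
metadata table, and a rooted phylogeny over the OTU identifiers, and carries
them through contaminant screening, rarefaction, alpha- and beta-diversity,
permutation tests, spatially-controlled constrained ordination with
variation partitioning, and a Sloan neutral community model (NCM) fit.
Upstream read processing (primer trimming, quality filtering, chimera
removal, OTU clustering, taxonomy, tree inference) is out of scope — the
package starts where those tools stop.

The central container, `OtuExperiment`, extends `SummarizedExperiment`
(counts assay, sample covariates in `colData`, an `ape::phylo` tree
attached), so the whole Bioconductor tool chain applies. All statistical
functions equally accept a plain samples x OTUs matrix.

# Pre-processing

**Contaminant screen.** An OTU observed in the PCR negative control with
count $c > 0$ is removed unless some real sample carries at least
$10 c$ reads (`factor = 10`, adjustable): removal iff
$\max_s \mathrm{count}_s < 10c$. The alternative literal reading — remove
when *any single* sample is below the threshold — would discard
near-universal taxa because of one shallow sample, contradicting the purpose
of a contamination screen, so it is not used. OTUs absent from the control
are never touched. The screen is applied before rarefaction.

**Rarefaction.** A single rarefaction subsamples every sample without
replacement (hypergeometric, via `vegan::rrarefy`) to a common depth,
by default the smallest sample total. Samples below the target are dropped
with a warning rather than raising an error, which keeps synthetic
edge-case pipelines running. The rarefaction seed is an explicit argument;
all randomized functions in the package take a `seed` and leave the session
RNG untouched when one is supplied.

# Alpha diversity

Per sample: observed richness $S$, Shannon $H'$ (base 2 by default — the
bits convention is the only base consistent with published tables whose
$H'$ values exceed $\ln S$), Chao1
($S + F_1^2 / 2F_2$; bias-corrected fallback $S + F_1(F_1-1)/2$ when no
doubletons; the always-bias-corrected variant is exposed by flag because
upstream software defaults differ), and Heip's evenness
$E = (e^{H} - 1)/(S - 1)$ with $H$ in natural-log units.
`heipFromShannon()` applies the same conversion to published $(H', S)$
pairs. Group comparisons use Kruskal–Wallis (chi-square approximation with
tie correction, via `stats::kruskal.test`), rank correlations use
Spearman's $\rho$, and environmental regressions are ordinary least squares
on square-transformed metrics (a variance-stabilizing choice for
right-skewed diversity values).

# Beta diversity

**Distances.** Bray–Curtis on relative abundances (via `vegan::vegdist`)
and weighted UniFrac computed natively: for every branch $b$ with length
$\ell_b$, with $A_b, B_b$ the fractions of the two samples' reads
descending from $b$, the raw distance is $\sum_b \ell_b |A_b - B_b|$ and
the normalized variant divides by $\sum_b \ell_b (A_b + B_b)$. The
normalized form is the default so that distances lie in $[0,1]$ and
"similarity $= 1 - d$" is well defined for distance-decay analysis. The
implementation is verified against an independent per-branch oracle
(tip-set accumulation through `phangorn::Descendants`) to $10^{-12}$.

**Ordination.** PCoA eigendecomposes the Gower-centred matrix
$-\tfrac12 C D^{(2)} C$. Negative eigenvalues — routine for Bray–Curtis —
are retained with their magnitudes; their eigenvectors are kept as
"imaginary" coordinates for use by dispersion analysis.

**Permutation tests.** One-way PERMANOVA uses
$SS_{total} = \tfrac1N \sum_{i<j} d_{ij}^2$,
$SS_{within} = \sum_g \tfrac{1}{n_g} \sum_{i<j \in g} d_{ij}^2$, and
pseudo-$F = \frac{SS_{among}/(a-1)}{SS_{within}/(N-a)}$; p-values permute
whole-sample labels with $p = (\#\{F^* \ge F\} + 1)/(n_{perm}+1)$ and
default 999 permutations. Pairwise PERMANOVA reports unadjusted p-values
(a Bonferroni column is appended for reference). PERMDISP computes each
sample's distance to its group centroid in the full PCoA embedding,
subtracting squared imaginary-axis components
($z_i = \sqrt{\max(0, \sum_{re}(y-c)^2 - \sum_{im}(y-c)^2)}$, the standard
`betadisper` construction, against which it is tested), then permutes the
$z$ values across groups under a one-way ANOVA F. ANOSIM is provided
because supplementary analyses of such surveys often use it; PERMANOVA is
treated as the primary test. SIMPER decomposes between-group Bray–Curtis
into per-taxon contributions
$100\,|y_{ik}-y_{jk}| / \sum_k (y_{ik}+y_{jk})$ averaged over admissible
pairs; the two-way mode restricts pairs to matching levels of a crossed
factor (e.g. regions compared within each depth stratum), and contributions
sum exactly to the mean dissimilarity.

**Distance decay.** Community similarity $1 - d$ is regressed on
great-circle distance over all *ordered* off-diagonal pairs
($n = N(N-1)$ points, df $(1, N(N-1)-2)$). The ordered-pair convention
double-counts each pair and therefore overstates the residual degrees of
freedom; it is retained deliberately because it is the convention used in
the distance-decay reports this package reproduces, and the
pseudo-replication caveat applies to the p-value, not the slope.

# Spatial structure and constrained ordination

Geographic distances are haversine great-circle distances (IUGG mean Earth
radius 6371.0088 km). Space is horizontal only: sampling depth enters as an
environmental covariate, not a coordinate. PCNM spatial eigenfunctions are
built canonically: truncation threshold $t$ = longest edge of the minimum
spanning tree of the distance matrix (the smallest threshold keeping the
neighbour graph connected), off-neighbourhood distances replaced by $4t$
(adjustable), PCoA of the truncated matrix, positive-eigenvalue axes
retained as unit-norm, mean-zero eigenfunctions.

Distance-based RDA embeds the community distance matrix by PCoA (positive
axes only; negative inertia is recorded and dropped rather than
square-root-corrected — the simplest defensible contract, and normalized
UniFrac rarely produces large negative inertia), residualizes both the
coordinates and the standardized predictors on the conditioning set, and
fits least squares. Significance uses reduced-model permutation (rows of
the residualized response), and explained variance is Ezekiel-adjusted with
conditioned degrees of freedom:
$R^2_{adj} = 1 - (1 - R^2)\frac{n-1-q}{n-1-q-m}$.

**Forward selection** admits, at each step, the candidate with the largest
adjusted-$R^2$ gain if its marginal permutation p-value (conditioned on the
already-selected set) is at most `alpha` (0.05), and stops once the
cumulative adjusted $R^2$ reaches the global (all-candidate) adjusted
$R^2$. The ordering of the two rules matters and was a genuinely open
design point: adjusted $R^2$ is (approximately) unbiased, so a
truth-containing submodel and the truth-containing global model estimate
the same quantity, and rejecting a candidate merely because the submodel's
adjusted $R^2$ edges past the global value would discard true drivers
about half the time. Applying the global-$R^2$ guard *after* admitting a
significant candidate preserves its purpose — stopping the accumulation of
spurious predictors — while keeping selection consistent.

**Variation partitioning** fits the three unconditioned models E, S and
E+S and reports $a = R^2_{adj}(ES) - R^2_{adj}(S)$ (pure environment),
$c = R^2_{adj}(ES) - R^2_{adj}(E)$ (pure space),
$b = R^2_{adj}(E) + R^2_{adj}(S) - R^2_{adj}(ES)$ (shared) and
$d = 1 - R^2_{adj}(ES)$; these close to 1 exactly by construction. When
collinearity between an environmental driver and space (e.g. a temperature
gradient aligned with the transect) makes $b$ negative, proportional
apportioning redistributes the combined explained variance over the pure
fractions preserving their ratio:
$a' = R^2_{adj}(ES)\,a/(a+c)$, $c' = R^2_{adj}(ES)\,c/(a+c)$, $b' = 0$.
This is the unique scale-preserving correction consistent with reported
percentage splits of that form. No attempt is made to orthogonalize
predictors beyond standard conditioning.

# Neutral community model

For each taxon the fit uses its mean relative abundance $p_i$ and observed
occurrence frequency $F_{obs,i}$ across samples of an evenly rarefied
table. Under the Sloan model the local relative abundance of a taxon is
$\mathrm{Beta}(Nmp_i,\ Nm(1-p_i))$ with $N$ reads per community and $m$
the immigration probability, so the predicted detection frequency above a
detection limit $d$ is $F_{pred,i} = 1 - I_d(Nmp_i, Nm(1-p_i))$. The
single scalar $m$ is fitted by bounded least squares over
$(10^{-6}, 1]$ (tolerance $10^{-8}$);
$R^2 = 1 - SSE/\sum_i (F_{obs,i} - \bar F_{obs})^2$ and may be negative.
Defaults: $N$ = mean post-rarefaction total; $d = 1/N$, the smallest
observable relative abundance (both exposed). The 95% envelope uses Wilson
score intervals at $F_{pred}$ with $n$ = number of samples — stable near 0
and 1 where most taxa sit, unlike the normal approximation. Per-stratum
fits (`ncmByStratum`) subset samples before refitting; the combined fit is
computed on the pooled samples, never averaged from strata.

A caveat the package's own simulations expose: when communities are
generated by the Dirichlet–multinomial process (the generative inverse of
the model), read-level detection is effectively binomial,
$1-(1-q)^N$, rather than a sharp threshold at $d$. Fitting with the
conventional sharp threshold $d = 1/N$ then recovers $m$ with a modest
upward bias (about +20% at $m = 0.1$, $N = 15{,}000$, 40 samples); under
the sharp-threshold detection model itself the fit is nearly unbiased. We
keep $d = 1/N$ because it is the field's convention and the parameter is
exposed for sensitivity analysis.

# The synthetic-community generator

`simulateDataset()` emulates the sampling design the statistics target: a
subtropical open-ocean transect of 20 stations spanning 22–36° N, two depth
strata per station (surface, 2 m, and deep chlorophyll maximum, 100 m),
15,000 reads per sample, and a temperature field
$T = 35 - 0.35\,\mathrm{lat} + \mathcal N(0, 0.5^2)$ °C with a
−2.8 °C offset at the DCM — producing the strong negative
temperature–latitude correlation characteristic of such transects. Region
labels follow latitude break points (AC / SSS / NSS / NAtl); salinity,
nitrate, chlorophyll-a and surface Sargassum density are generated with
depth-dependent means and lognormal noise as realistic nuisance covariates.

Three assembly regimes share one mechanism. The source pool draws
metacommunity abundances from a lognormal (sigma 1 by default) and a random
bifurcating topology with exponential(1) branch lengths — UniFrac needs a
valid branch-length tree, not realistic macroevolution, so no birth–death
process is used. Each sample is Dirichlet–multinomial with concentration
$Nm\,p$: a pure-neutral draw whose marginals match the fitted Sloan model.
Niche filtering multiplies the pool by a Gaussian temperature response
$\exp(-w (T - o_i)^2 / 2\tau_i^2)$ before sampling, with a single weight
$w \in [0,1]$ interpolating from pure neutrality to full environmental
determinism. Dispersal limitation lets the log pool perform a random walk
from station to station (sd `dispersal_drift_sd` per station), so
neighbouring stations share similar effective pools while the environment
plays no role. Contaminant taxa can be appended together with a
negative-control count vector to exercise the screen.

What the generator does *not* emulate: sequencing error, chimeras, PCR
bias, compositional library-size artefacts, taxon co-occurrence networks,
or ocean-current anisotropy. Green tests on synthetic data therefore
validate the statistical machinery and its contracts, not the biology of
any particular ocean.

# Validation conditions and numerical choices

The test suite validates each stage against independent oracles
(brute-force UniFrac traversal, `vegan`'s adonis2 / betadisper / anosim /
mantel / simper / pcnm / rda as cross-checks, quadrature of the Beta
density for NCM predictions) and runs the following study-scale
experiments: permutation-test calibration (1,000 null simulations x 999
permutations each for PERMANOVA at $N=20$, Mantel at $N=15$ and db-RDA at
$N=16$; type-I error required in $[0.03, 0.07]$); NCM parameter recovery
(seeds 1–20 at $m = 0.1$, $N = 15{,}000$, 40 samples, 500 taxa — the
detection-model bias discussed above is visible here exactly as
documented); regime discrimination (50 replicates per regime at 15
stations, 1,000 reads, 150 taxa: pure-niche data with spatially
unstructured temperature must yield environment > space, dispersal-limited
data the reverse); and distance-decay sign checks.

Numerical conventions: eigenvalues below $10^{-9} \times$ the spectral
radius are treated as zero; predictors constant after standardization or
absorbed by the conditioning set are dropped with a rank warning;
permutation p-values always use the $+1$ correction; degenerate inputs
(empty samples, constant distance matrices, single groups, all-coincident
coordinates) raise informative errors rather than NaNs. All simulation
sizes above were chosen as desk-scale renditions of the survey design
(about 40 samples), keeping the full suite readily rerunnable.

# Pipeline and interfaces

`runPipeline()` drives the full analysis from one configuration
(`pipelineConfig()` in R, or YAML/JSON via `readPipelineConfig()`; YAML is
used as the configuration format, with paths resolved relative to the
file). One global seed expands to fixed per-stage offsets so stages can be
re-run in isolation; reports exclude wall-clock metadata so repeated runs
are byte-identical. When no tree is supplied the beta stage falls back to
Bray–Curtis with an explicit notice. A thin `Rscript` wrapper
(`inst/scripts/run_pipeline.R`) covers shell use; the exported functions
are the primary interface.

# Known limitations

Unweighted UniFrac, NMDS, dbMEM generalizations with asymmetric weighting
(current directionality), permutation-based adjusted $R^2$, beta-binomial
exact NCM likelihoods, and BIOM-HDF5 are out of scope. PERMANOVA here is
one-way (the pipeline runs one factor at a time); crossed designs are
handled only by SIMPER's two-way pair restriction. The ordered-pair
distance-decay convention overstates residual df, as discussed.
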