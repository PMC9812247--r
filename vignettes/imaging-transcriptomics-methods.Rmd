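---
title: "Spatially constrained inference for imaging transcriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially constrained inference for imaging transcriptomics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imtx)
```

## The scientific problem

Imaging-transcriptomics studies ask whether the spatial pattern of a brain
phenotype — here, a task-fMRI activation map — co-varies with the regional
expression pattern of individual genes. The analysis ranks every gene by the
Spearman correlation between its expression profile and the activation map,
evaluated over parcellated brain regions (or voxels) within the cortex and
subcortex separately, because expression differences between broad anatomical
compartments would otherwise dominate every correlation.

The statistical crux is that brain maps are spatially autocorrelated: nearby
regions carry nearly duplicated information, so the effective sample size is
far below the region count and naive permutation p-values are strongly
anti-conservative. `imtx` addresses this with variogram-matched surrogate
maps: null maps that randomize the gene-to-region assignment while preserving
the empirical spatial-autocorrelation fingerprint of the observed map.

Downstream of the ranked gene table, the package provides the standard
interpretation layers: rank–rank hypergeometric overlap (RRHO) between two
ranked lists, gene-category enrichment against a spatial ensemble null
(GCEA), weighted Kolmogorov–Smirnov gene-set enrichment (GSEA) for a
pre-defined risk-gene set, and master-regulator nomination from a
motif-ranking database via recovery-AUC normalized enrichment scores (NES).

## The synthetic-data generator

All inputs can be generated synthetically so that every stage is testable
end to end. The generator emulates the statistical structure the analysis
assumes, not any particular dataset:

* **Atlas.** A voxel lattice (default $16^3$ voxels of 2 mm) split into a
  central subcortex-like core and a surrounding cortex-like shell, each
  parcellated by nearest-centroid (Voronoi) assignment to randomly placed
  seeds — 100 cortical and 30 subcortical parcels by default. Every parcel
  is nonempty by construction.
* **Expression.** Each gene is a zero-mean Gaussian random field over region
  centroids with exponential covariance $\exp(-d/\lambda)$. The default
  $\lambda = 10$ mm against a ~32 mm field extent makes neighboring regions
  clearly correlated and distant ones nearly independent; real transcriptome
  maps have no published covariance, so $\lambda$ is a free, documented
  choice, not an inference.
* **Planted signal.** A planted subset of genes (10% by default) shares a
  latent field with mixing weight `planted_gene_cor` (default 0.8). This is
  essential: the activation map is built from the *mean* of the planted
  genes, and the mean of $m$ mutually independent fields correlates with
  each member only at $1/\sqrt{m}$ — without the shared latent, no
  individual gene could ever reach a large-effect correlation threshold, and
  planted-signal recovery would be impossible by construction rather than by
  statistical failure. The shared latent leaves each gene's marginal law
  unchanged. Per-gene weights are recorded in the ground truth.
* **Activation.** `planted_effect`·(standardized planted-gene mean) +
  (1 − `planted_effect`)·(independent smooth field) + `noise_sd`·white
  noise. Standardization before mixing makes `planted_effect` interpretable
  on the correlation scale; defaults are 0.9 and 0.2. Two paradigms planted
  on disjoint gene subsets can be generated from one seed, mirroring the
  emotion/reward two-task design the package's outputs are shaped around.
  The paradigms are built to be genuinely distinct systems: on a geometry
  with only ~10–20 effective spatial degrees of freedom, two independently
  drawn smooth fields can show chance spatial correlations of ±0.5, so the
  second paradigm's latent and each activation's smooth background are
  drawn by capped best-of rejection until their cortical cross-correlations
  with the first paradigm's fields — under both the plain inner product and
  the doubly centered covariance-weighted one that governs across-gene
  correlation structure — fall below 0.05. Without this, "the two tasks
  engage different gene programs" would be a coin flip of the seed rather
  than a property of the design.
* **Annotations, risk list, regulons.** 50 random categories with sizes in
  [5, 50], exactly one seeded 80% with planted genes; a 42-gene risk list
  containing the planted regulator and a majority of planted genes; a
  100-motif regulon database of uniform random rankings, except one motif
  that ranks the planted regulator's targets (half of the planted genes) at
  the top.

What the generator does *not* emulate: donor structure, probe selection,
hemispheric mirroring, non-Gaussian expression marginals, and any realistic
anatomical geometry. Passing tests therefore demonstrate the statistical
machinery under idealized spatial structure; they do not certify behavior on
real atlas data.

## Surrogate maps and the variogram

The semivariogram $\gamma(h) = \tfrac12\,\mathrm{mean}[(v_i - v_j)^2]$ over
unit pairs at distance $h$ is the autocorrelation fingerprint surrogates
must preserve. Numerical choices:

* **Equal-count lag bins.** Bin edges are quantiles of the pairwise distance
  distribution, so every lag estimate rests on a similar number of pairs.
  With equal-width bins, the smallest-lag bin on centroid geometries often
  holds one or two pairs and its "estimate" is pure noise.
* **Cutoff at one third of the maximum distance** (the common geostatistics
  convention): distant pairs are few, mutually dependent, and uninformative
  about local structure. Reporting default is 10 bins.

Each surrogate is built by permuting the map, smoothing the permutation with
an exponential distance-decay kernel restricted to each unit's $k$ nearest
neighbors (defaults $k = 20$ cortex, $k = 5$ subcortex) at 25 candidate
scales on a geometric grid, then fitting a multiplicative amplitude and an
additive white-noise variance by least squares so the surrogate's variogram
matches the empirical one, selecting the best-fitting scale, and optionally
rank-remapping the surrogate onto the source's exact value distribution.

One further numerical choice matters for inferential calibration: the binned
variograms are kernel-smoothed across lags (Gaussian, bandwidth twice the
mean lag spacing) before the least-squares fit. Per-bin sampling noise in
the candidate variograms otherwise attenuates the fitted amplitude — the
classic errors-in-variables bias — leaving the surrogate null
under-dispersed and the resulting p-values anti-conservative. The
calibration study in the test suite (independent activation with matched
autocorrelation) verifies that with the smoothed fit the surrogate test's
rejection rate at the nominal 5% level stays near 5%, while naive
permutation on the same data rejects several times too often.

The two-sided spatial p-value is the literal proportion of surrogates whose
absolute correlation strictly exceeds the observed one; zero is reported as
"< 1/n". A `(count+1)/(n+1)` pseudo-count form exists for procedures that
cannot accept exact zeros, off by default.

Two directions of surrogate testing are provided, and the caller chooses:
per-gene ensembles (each gene's map is surrogated; used for the per-gene
p-values in the ranked tables) and activation-map ensembles (one shared
ensemble; used by GCEA, where it makes the cost linear rather than
quadratic in the gene count).

## Ranked-list overlap (RRHO)

For each pair of rank cutoffs the overlap of the two lists' top prefixes is
scored by an exact upper-tail hypergeometric p-value; entries are signed
$-\log_{10} p$, positive when the overlap exceeds its expectation. The
scalar `rho_rrho` is defined here as the Spearman correlation between the
two lists' per-gene correlation values — the upstream tool reports a scalar
of this name without a published formula, so our definition is documented
rather than asserted identical — with a gene-label permutation p-value. The
default cutoff step $\max(1, \lfloor N/100\rfloor)$ yields a roughly
100×100 map at any problem size.

## Enrichment

**Gene scores** rectify correlations one-sidedly (`positive`: $\max(\rho,0)$;
`negative`: $\max(-\rho,0)$; `absolute`), because positively and negatively
associated gene programs are reported separately. **GCEA** scores a category
by the mean gene score of its annotated genes (categories with 5–200
annotations tested, as conventional) and compares it with the same statistic
recomputed against surrogate activation maps, regenerating all gene
correlations per null map. Raw p-values are literal null proportions; exact
zeros are replaced by $1/(2\,n_\mathrm{nulls})$ before Benjamini–Hochberg
adjustment so the correction stays defined — a documented deviation, applied
uniformly.

**GSEA** walks the descending-correlation list, incrementing the running sum
by $|\rho|^w / \sum_{\mathrm{set}} |\rho|^w$ on set members (default
$w = 1$) and decrementing by $1/(N - m)$ otherwise; the enrichment score is
the signed maximum deviation from zero, and the running sum provably returns
to zero at the end (checked on every call). Significance uses gene-label
permutations preserving set size, two-sided, with no multiplicity adjustment
(a single pre-defined set). With $w = 0$ this reduces to the classic
two-sample KS statistic, which the tests verify against an independent ECDF
oracle.

## Master regulators

For each direction, genes past the large-effect threshold ($|\rho| > 0.5$,
strict) form the input set. Every motif's genome-wide ranking yields a
recovery AUC over the top 5% of ranks (`auc_max_fraction` config-exposed),
z-scored across motifs into an NES; motifs with NES strictly above 3 are
retained. A regulator with several qualifying motifs is reported once, with
its best motif. Targets are defined as the input-set genes ranked inside the
AUC window — upstream tools' "high-confidence target" notions are
version-dependent, so this simplest defensible definition is documented, not
asserted identical. The final report intersects retained regulators with the
risk-gene list and prints `regulator (n_targets/n_possible)` cells in a
compartment × direction grid, with `-` for empty cells.

## Degenerate inputs and tie handling

Spearman uses midranks; a constant vector is an error, never a silent zero.
Genes with constant profiles are excluded from rankings (count reported),
not assigned $\rho = 0$, which would distort enrichment ranks. Ranking ties
are broken lexicographically by gene id so tables reproduce byte for byte.
Zero is the background sentinel in volumes — zero-valued voxels are excluded
before any region mean; maps where 0 is a legitimate value must be offset
upstream (documented limitation). Region means are computed after zero
exclusion. Volumes are aligned to an atlas only when shapes are identical or
integer-scale compatible; anything else is a hard error, because silent
resampling hides alignment bugs.

## Determinism and problem sizes

A single seed drives everything; each stage derives a named sub-stream, so
stages can be regenerated independently. Two runs of `run_pipeline()` with
the same configuration and seed produce byte-identical TSV outputs, each
stamped with a hash of the configuration.

The test suite exercises the statistical properties at deliberately chosen
problem sizes: the null-calibration study uses 1000 genes × 1000 surrogates
on the default 100-region cortical geometry; planted-signal recovery uses
the default generator conditions (500 genes, 100 + 30 regions,
`planted_effect` 0.9, `noise_sd` 0.2) across 10 seeds with 200-null GCEA
(the GCEA default in analyses is 1000); cross-parcellation agreement uses a
120-gene, 20-region configuration. The methods scale to paper-sized inputs
(≈18k genes, 210 + 36 regions) linearly in the gene count.

## Known limitations

* Surface-based (vertex) data are unsupported; everything is volumetric.
* The surrogate family is variogram matching only — no spin rotations or
  spectral nulls.
* The exponential covariance of the generator is a modeling convenience;
  conclusions about calibration transfer to real maps only insofar as their
  autocorrelation is captured by a variogram.
* With the conventional $k = 20$ nearest neighbors on small parcellations,
  the smoothing kernel's support truncates long-range autocorrelation,
  which slightly narrows the surrogate null relative to the generating
  process. `k` is capped at $n-1$ on very small compartments.
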