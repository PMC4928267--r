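---
title: "PCA-projection ancestry estimation for interspecific grape hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCA-projection ancestry estimation for interspecific grape hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grapeAncestry)
```

## The problem

Commercial "hybrid" grape cultivars mix ancestry from the domesticated grape
*Vitis vinifera* with one or more wild *Vitis* species. Pedigree records of
that mixing are frequently wrong, so a marker-based estimate of each
cultivar's *V. vinifera* fraction is valuable both for cataloguing breeding
history and for selecting high-vinifera seedlings during introgression
breeding. grapeAncestry implements a complete genotype-to-ancestry pipeline
for this setting: curation of genotyping-by-sequencing (GBS) calls, LD-kNNi
imputation, PCA fitted on small ancestral reference panels, projection of
hybrids, a PC1 distance-ratio ancestry coefficient, and in-silico cross
simulation to calibrate what the coefficient means.

## The estimator

Let the curated data be a samples-by-sites matrix of alternate-allele
dosages $g_{ij} \in \{0, 1, 2\}$. The two ancestral panels (wild *Vitis* and
*V. vinifera*, forced to equal size $n/2$ each) are used to fit principal
axes. Each site is normalized as

$$z_{ij} = \frac{g_{ij} - \bar g_j}{\sqrt{\hat p_j (1 - \hat p_j)}},
\qquad \hat p_j = \frac{1 + \sum_i g_{ij}}{2 + 2n},$$

where the sum runs over the $n$ panel samples. The adjusted frequency
estimator keeps the scale factor strictly positive for any polymorphic
site; it is the standard choice in the eigenanalysis lineage this package
follows. PCs come from the singular value decomposition of the normalized
panel matrix; PC1 is oriented so the vinifera panel mean exceeds the wild
panel mean. Hybrids never enter the fit: they are projected, i.e. scored as
the dot product of their normalized genotypes with the fitted loadings.

For a hybrid with PC1 score $s$, with $a = |s - \mu_{vin}|$ and
$b = |s - \mu_{wild}|$ the distances to the two panel score means along PC1,

$$\%\,V.\,vinifera \;=\; \frac{b}{a + b} \times 100 .$$

Only PC1 enters the estimate; higher PCs are reported for inspection.
Scores outside the inter-mean interval are reported as computed and
flagged, not clipped.

## Curation chain and its thresholds

`run_curation()` applies, in order: per-genotype depth masking (minimum 8
reads; a call at exactly 8 is kept), site missingness (a site is kept only
if its missing fraction is strictly below 20%), sample missingness (a
sample at exactly 20% is kept, above it removed), genome-wide MAF (sites
with MAF below 0.05 removed; exactly 0.05 kept), and an exact
heterozygote-excess Hardy-Weinberg test at $\alpha = 0.001$. Each phrase of
the underlying protocol fixes its own boundary; the package pins them
exactly as worded and the test suite asserts them bit-exactly.

The HWE test conditions on the observed allele counts: given $n$ diploids
and $n_A$ copies of one allele, the heterozygote count follows the
Levene-Haldane distribution, and the excess p-value is the upper tail at
the observed count. Heterozygote excess is the GBS failure signature of
collapsed paralogous loci, which is why the one-sided test is the default;
a two-sided option mirrors common tooling. The implementation is exact (log
space), and is verified against a choose()-based exhaustive enumeration for
every configuration up to 20 diploids.

After these per-site filters the chain computes an IBS similarity matrix
(pairwise-complete, before imputation — this is where replicate and
mislabelling problems show up), imputes with LD-kNNi, balances the
ancestral panels by seeded random downsampling, keeps only sites with
pooled-panel MAF strictly above 0.10, and LD-prunes with 10-site windows
shifted by 3 sites, removing one member of any pair with $r^2 > 0.5$.

Decisions the protocol wording left open, pinned here:

* **Ancestral MAF is pooled** over the 14 panel samples rather than
  computed per panel. The pooled reading retains fixed interspecific
  differences (frequency 0.5 pooled), which carry the ancestry signal; a
  per-panel reading would discard exactly the most informative sites.
  A per-panel computation remains available via `site_maf(samples = ...)`.
* **Pruning removes the lower-MAF member** of a flagged pair, ties broken
  by removing the later position — the dominant convention of the tooling
  lineage the windowed `indep-pairwise` procedure comes from. Windows are
  counted in sites, never span chromosomes, and the whole procedure is
  deterministic; the suite checks it against a literal sliding-window
  reimplementation.
* **Undefined $r^2$** (monomorphic or fewer than two complete pairs) never
  triggers removal: no evidence of correlation.

## LD-kNNi imputation

A missing genotype at site $j$ for sample $i$ is predicted from the $k$
samples most similar to $i$ in the neighbourhood of $j$: similarity is
measured over the $l$ sites in highest $r^2$ with $j$, as the mean absolute
dosage difference over sites where both samples are observed (floored at
$\varepsilon = 10^{-9}$); the $k$ nearest candidates vote for their own
dosage with weight $1/d^2$, ties toward the smaller dosage. Defaults
$l = 6$, $k = 17$ follow the published optimisation of this method on grape
GBS data, and `optimize_parameters()` reproduces that grid search on any
dataset using one fixed mask so all grid points see identical problems.
Imputation is single-pass — every prediction reads only pre-imputation
values — so results are independent of cell order, and a cell with no
informative neighbour stays missing rather than being fabricated.

The mean-versus-sum distance choice and the $1/d^2$ weight are pinned here
(the original method description leaves room for variation); they matter
only in edge cases, and the package's accuracy claims are therefore
relative, not absolute: on haplotype-block data LD-kNNi must beat per-site
modal imputation by at least two points at 5% masking, which the
acceptance suite verifies. Absolute accuracy (the ~91% figure familiar
from real grape GBS) is data-dependent and is deliberately not asserted.

## Cross simulation

`simulate_cohort()` builds F1 offspring by drawing one random parent from
each panel and sampling one allele per parent per site; backcross offspring
cross a freshly simulated F1 with a random panel individual. Linkage
between sites is ignored, exactly as in the protocol this reproduces —
gametes are independent Bernoulli draws per site. Expected vinifera
fractions are 0.5, 0.25 and 0.75 for F1, BC-to-wild and BC-to-vinifera.
The "95% CI" reported by `summarize_cohort()` is the empirical 2.5/97.5
percentile interval of the per-offspring estimates (linear interpolation):
the published intervals are far too wide to be standard errors of a mean
over 10,000 offspring and match the offspring spread, so the percentile
reading is used.

Because projection is linear in the genotype, the expected score of an
offspring is the mean of its parents' scores; offspring of the fitting
samples therefore inherit the panel means exactly, and cohort means recover
50/25/75 without any shrinkage correction. This is the internal consistency
the estimator relies on, and it is why simulated offspring and real hybrids
must be projected identically.

## What the synthetic data emulate — and what they do not

`make_dataset()` generates the study conditions every test runs under: two
ancestral panels of 7 diploids, 2,500 biallelic sites (~2% short indels,
treated identically to SNPs after the biallelic filter), positions uniform
over 19 chromosomes, and hybrids with true vinifera fractions spanning
0.1-0.8. Divergence follows the Balding-Nichols model — population
frequencies are Beta-distributed around a uniform base frequency with
variance $F\,p(1-p)$ — with $F_{ST} = 0.3$ by default, chosen once as a
realistic stand-in for the strong interspecific divergence that makes the
two panels separate cleanly on PC1; the real wild/vinifera split is
comfortably at or above this level. Optional layers add haplotype-block LD
(finite per-population haplotype pools per block, shared by panels and
hybrids), uniform missingness, and Poisson read depth.

The generator does not attempt coalescent-realistic haplotypes, GBS
read-level artefacts (allelic dropout, strand bias), or relatedness within
panels. Passing tests therefore demonstrate that the algorithms are
implemented correctly and that the estimator is calibrated under its own
assumptions — not that any particular real dataset meets those assumptions.

One subtlety documented here because it shapes the validation design: the
admixture-gradient recovery checks draw test individuals' allele copies
from the **empirical panel frequencies** — the marginal equivalent of
sampling alleles from the panel members, as the in-silico crosses do. An
individual drawn instead from the *population* frequencies underlying the
panels projects a few percent inward at extreme ancestry values, because
uncorrected PCA projection shrinks samples that carry none of the fitting
panels' sampling noise. The distance-ratio coefficient is calibrated
relative to the panels themselves; users should read estimates as "fraction
of ancestry attributable to this vinifera panel", which is also how the
simulated-cohort intervals are constructed. On the default conditions the
per-level mean absolute error over a 0-100% truth grid stays below 3
points with a regression slope within 0.9-1.1, which the acceptance suite
recomputes.

## Numerical and degenerate-input choices

* Dosage is always the alternate-allele count; the *minor* allele is
  recomputed wherever a frequency filter needs it.
* Half-calls (`./1`) and `./.` are both treated as missing; phased and
  unphased genotypes are equivalent.
* Sites with zero non-missing calls have undefined MAF and count as MAF 0
  in filters (removed by any positive threshold).
* `fit_pca()` refuses missing dosages, unequal panels and panel-monomorphic
  sites rather than silently patching them; the pipeline stages that fix
  each condition (imputation, downsampling, the ancestral MAF filter) come
  earlier in the chain.
* Projection with missing genotypes (only possible when imputation was
  skipped) restricts the dot product to observed sites and rescales by the
  observed fraction — unbiased under missingness at random — and flags the
  affected samples.
* All stochastic steps (downsampling, masking, simulation, generation) take
  explicit integer seeds and are bit-reproducible.

## Problem sizes used in the shipped checks

The packaged validation runs at the study scale it emulates: 7+7 panels,
2,500 sites before panel-conditioned filtering (~1,500-2,000 after), and
10,000 offspring per simulated design. The admixture-recovery grid uses 50
individuals per level at 11 levels; oracle comparisons enumerate every HWE
configuration to 20 diploids and 100 random pruning instances of up to 12
sites. Imputation checks run on 800-site haplotype-block datasets at 5%
masking. These sizes were chosen so that sampling error is comfortably
below every tolerance asserted.

## Known limitations

* The coefficient is global: a single number per cultivar. Local
  (per-segment) ancestry, and hence generation counting, is out of scope.
* Panels of 7 are small; the coefficient inherits the panels' sampling
  noise, which the simulated intervals quantify but cannot remove.
* IBS values vet replicates and gross mislabelling but do not resolve
  first-degree relationships.
* The imputation distance/weight conventions are pinned choices within the
  cited method family; datasets imputed elsewhere may differ slightly in
  edge cases.
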