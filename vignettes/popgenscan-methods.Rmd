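---
title: "Models and methods behind popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popgenscan implements, as one tested chain, the analyses a
population-genomics study of fine-scale structure and recent selection
runs on a SNP array panel: data curation, structure inference
(PCA/Procrustes/DAPC), formal admixture testing (f3 with block
jackknife), and a three-pronged selection scan (MAF-binned Weir-Cockerham
Fst outliers, bin-standardized iHS, a joint 200-kb window ranking, and
drift-corrected derived-allele-frequency tests). Because array studies of
this kind rarely release genotypes, the package ships a fully
controllable simulator whose output carries planted ground truth for
every downstream detector.

## The simulator

Allele frequencies follow the Balding-Nichols model: given an ancestral
frequency $p$ and a drift parameter $F \in [0, 0.5]$, a descendant
population's frequency is drawn from
$\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, which
has mean $p$ and variance $F\,p(1-p)$; $F=0$ returns $p$ exactly. Drift
is applied twice — ancestor to cluster ($F_\mathrm{cluster}$), cluster to
province ($F_\mathrm{province}$) — and haplotypes are drawn i.i.d.
Bernoulli per province, so the simulated data are in
Hardy-Weinberg/linkage equilibrium except where defects or sweeps are
planted. Allele `a` is ancestral by construction and annotated
explicitly; no downstream code assumes the orientation.

Default design: 4 clusters x 5 provinces x 37 diploids (740 samples,
close to the ~185-per-cluster sampling of the peninsular study the
package emulates), 10,000 SNPs on one 200-Mb chromosome,
$F_\mathrm{cluster} = 0.005$, $F_\mathrm{province} = 0.001$ — i.e.
realized pairwise cluster Fst of a few per mille, the weak
differentiation typical of a single peninsula.

**Expected Fst under drift.** For two populations drifted independently
with parameter $F$ from a shared ancestor,
$E[(p_1-p_2)^2] = 2F\,p(1-p)$ and the two-population Weir-Cockerham
estimator satisfies $E[\hat\theta] \approx
s^2 / (\bar p \bar q + s^2/2) \approx F$ — the estimator recovers the
per-population drift parameter, not its doubling. The package's
parameter-recovery tests pin this Monte-Carlo-verified relationship.

**Topologies.** Independent (star) drift is isotropic: with $K$ clusters
the between-cluster configuration spans $K-1$ dimensions with no spatial
order, so star data cannot reproduce a latitudinal cline and Procrustes
concordance with a linear geography saturates around $t_0 \approx 0.66$.
A stepping-stone (`"serial"`) topology drifts each cluster from its
northern neighbour — a cline, but a random walk rather than a line
($t_0 \approx 0.86$). The `"cline"` topology draws two endpoint pools by
Balding-Nichols drift and mixes them linearly along the north-south
cluster order; cluster centroids are then exactly collinear in frequency
space, which is the sharpest available ground truth for
"geography equals structure" ($t_0 \approx 0.98$ at
$F_\mathrm{cluster} = 0.02$). Geography-concordance checks therefore use
`topology = "cline"`; everything else uses the star default.

**Planted signals.** Differentiated loci are planted by resampling the
target cluster's haplotypes at a locus so its derived-allele frequency
sits a requested shift (default checks use 0.25) above the other
clusters' mean, to within half a haplotype count. Sweeps are planted
structurally rather than by simulating selection dynamics: a fraction of
the target cluster's haplotypes over a window (default 400 kb) is
replaced by copies of one derived-allele core haplotype; copies receive
per-site mutations with probability rising linearly from 0 at the core
to 0.05 at the window edge, plus one crossover onto a random background
haplotype at a uniform distance — yielding the EHH decay with distance
that a recent sweep produces, with full control of frequency and extent.
QC defects (uniform missingness, loci forced under 95% call rate,
all-heterozygote loci in one province, parent-child pairs composed from
transmitted haplotypes) exercise every curation filter.

Simulations are seeded once per run and bit-reproducible; every planted
feature is recorded exactly once in a `GroundTruth` object.

**What the simulator does not emulate:** linkage disequilibrium in the
neutral background (loci are independent), recombination maps, mutation
-rate heterogeneity, ascertainment bias of array SNPs, genuine
selection dynamics, and multi-chromosome genomes (a single chromosome
suffices for the block jackknife at 5-Mb blocks). Passing detection
tests on these data therefore demonstrates correctness of the
statistics and the ranking logic, not power on real LD-structured
genomes.

## Quality control

Filters run in the order call rate, then HWE, then relatedness, then LD
pruning. Defaults mirror standard array curation: loci with call rate
below 95% are removed before samples; the Hardy-Weinberg exact test is
the conditional enumeration over heterozygote counts given allele counts
(two-sided: sum of outcome probabilities no larger than the observed
one). The filter runs within provinces by default — pooling structured
populations depresses heterozygosity (Wahlund effect) and dilutes
batch-confined artefacts — removing a locus when its smallest
per-province p falls under the Bonferroni threshold
$\alpha/(\text{loci} \times \text{provinces})$, with family-wise
$\alpha = 0.01$; a pooled mode is available, and at the curated scale
of 524,738 loci the pooled threshold reproduces the conventional
$1.9\times10^{-8}$ cutoff. Relatedness uses a
method-of-moments IBD estimator on IBS class counts (expected class
probabilities given allele frequencies under IBD 0/1/2, solved
sequentially, truncated to $[0,1]$ and renormalised;
$\hat\pi = P_1/2 + P_2$), with pairs above $\hat\pi = 0.125$
(third-degree relatives) pruned greedily — the sample in most
over-cutoff pairs is dropped first, ties broken by lower call rate then
id, so an isolated pair always loses exactly one member. The estimator
omits the small-sample bias corrections PLINK applies; at the panel
sizes simulated here the moments estimates are within a few percent of
expectation (duplicates ~1, parent-child ~0.5, unrelated ~0). LD
pruning slides a 50-SNP window in steps of 5 and removes the lower-MAF
member of any pair with genotype $r^2 > 0.2$ (defaults exposed, as the
originating protocols leave them to supplementary material).

## Structure

PCA uses Patterson scaling — each locus centered by $2\hat p$ and scaled
by $\sqrt{\hat p(1-\hat p)}$, missing entries contributing zero after
centering — and an SVD of the scaled matrix; monomorphic loci are
dropped with a count. Province centroids are averages of individual
scores on the two leading PCs, computed after the PCA (not a PCA of
centroids). Geographic coordinates are plain (lon, lat) degrees without
projection; at peninsular extents the distortion is far below the
residual noise. The Procrustes fit (via vegan) centers and scales both
configurations to unit sum of squares, allows reflections, and reports
$t_0 = \sqrt{1 - D}$ with $D$ the symmetric residual sum of squares;
the permutation test permutes provinces and reports
$(\text{hits}+1)/(n_\mathrm{perm}+1)$, deterministic under a seed.
Rank-deficient (collinear) configurations are flagged but fitted;
constant configurations are an error because symmetric scaling is
undefined. DAPC reduces to the smallest number of PCs explaining 80% of
the retained variance (default), fits a shared-covariance linear
discriminant on the scores, and reports Gaussian posterior memberships
per individual and averaged per province.

## Admixture f3

For target $c$ and sources $a, b$, the per-locus term is
$(c-a)(c-b) - h_c$ with $h_c = c(1-c)/(2n_c-1)$ the finite-sample
correction for the target (toggleable; the statistic is exactly
symmetric in the sources). Loci with undefined frequencies are skipped.
Standard errors come from a weighted delete-one-block jackknife over
contiguous 5-Mb blocks (weights proportional to loci per block), and
$Z = \hat{f_3}/\mathrm{SE}$; a single block is an error, zero variance
is flagged degenerate rather than yielding a silent 0/0. Trios are
ranked by ascending $Z$ (ties by $f_3$) and the lowest 1% flagged. A
significantly negative $f_3$ marks the target as admixed; drift makes
$f_3$ positive for unadmixed targets, which is why power and
specificity are asserted jointly (admixed targets with mixing
proportions 0.3-0.7 at 20k loci give $Z \ll -3$; independently drifted
targets stay positive).

## Selection scan

**Fst outliers.** Per-locus two-population Weir-Cockerham variance
components $a$ (among populations), $b$ (among individuals within), $c$
(within individuals) are computed from frequencies, observed
heterozygosity and sample sizes; $\theta = a/(a+b+c)$, with
monomorphic-in-both loci flagged undefined. Because $\theta$ depends on
allele frequency, loci are binned by pooled MAF (width 0.05) and the
top 1% per bin flagged (ties: higher MAF, then id), so moderate-MAF
outliers are not swamped by high-MAF loci.

**iHS.** EHH for a carrier set is the probability that two random
carriers are identical over all markers from the core out to a
position; it starts at 1 and is non-increasing outward. Integrated
haplotype homozygosity iHH is the trapezoid integral of EHH over
physical bp (no genetic map is assumed), stopped when EHH falls below
0.05, truncated at inter-marker gaps over 20 kb, and flagged when the
chromosome end is hit first. The unstandardized score is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$, so sweeps on the derived allele
are negative. Scores are standardized to mean 0, SD 1 within 10%-wide
derived-allele-frequency bins; loci with DAF < 0.2 are excluded (poor
power at low frequency inflates false positives), sparse bins (< 20
loci) are merged with their nearest neighbour, and the top 1% of
|standardized iHS| genome-wide is flagged. iHS is computed per cluster;
loci monomorphic in the cluster are skipped there.

**Joint windows.** 200-kb windows sliding in 50-kb steps (closed,
1-based intervals; BED export converts to 0-based half-open) count SNPs
flagged outlier in *both* scans. Windows with fewer than 10 SNPs are
excluded; survivors are grouped into SNP-count deciles and ranked
within class by joint-outlier fraction, flagging the top 1% per class
with a non-zero fraction — the class grouping prevents sparse windows
from dominating by small-denominator effects. Defaults (step, floor,
deciles) are config-exposed since the protocols this follows leave them
unspecified.

**Drift-corrected delta-DAF.** The Fisher exact test of derived-allele
counts answers "is there any differentiation", which conflates drift
with selection. The correction tests the observed difference against
the drift expectation: under the null,
$\mathrm{Var}(p_1-p_2) = \bar p(1-\bar p)\,(2F + \tfrac{1}{2n_1} +
\tfrac{1}{2n_2})$ where $F$ is the genome-wide mean pairwise
Weir-Cockerham theta of the cluster pair, and
$(p_1-p_2)^2/\mathrm{Var}$ is referred to $\chi^2_1$. At $F=0$ this is
exactly the two-proportion chi-square. The cited correction is a
method, not a printed formula, so the contract here is the calibration
property: on neutral data whose cluster drift matches the background
$F$, the corrected test's type-I rate at $\alpha = 0.05$ is 0.03-0.07
while the uncorrected Fisher test is anticonservative. The Bonferroni
denominator for the delta-DAF scan is a required input: the implied
genome-wide test count of the originating protocol is not recoverable,
so it is never guessed.

## Numerical and design choices

* Coordinates are 1-based with closed intervals everywhere except BED
  output; missing genotypes are never imputed — every statistic uses
  pairwise-complete observations, and zero-call groups yield flagged
  `NA` frequencies rather than zeros.
* Exact tests sum probabilities "no larger than observed" with a
  $10^{-12}$ relative slack on the comparison to absorb floating-point
  ties in the enumeration.
* The HWE family-wise alpha (0.01) is inferred from the reproduced
  $0.01/524{,}738 \approx 1.9\times10^{-8}$ cutoff and exposed as a
  parameter.
* The permutation p floor is $1/(n_\mathrm{perm}+1)$; the Procrustes
  permutation kernel recomputes $t_0$ as the sum of singular values of
  the cross-product of unit-normalized configurations, verified against
  the vegan fit to $10^{-12}$.
* Problem sizes in the shipped checks (10-20k SNPs, 200 diploids per
  cluster, 20 replicates for detection rates, 999-permutation tests)
  are the desk-scale equivalents of the study design: large enough for
  the asserted rates to be stable under the fixed seeds, small enough
  to run on a laptop in minutes. Sweep-scan simulations place 10k SNPs
  on 50 Mb so that 200-kb windows hold ~40 SNPs and inter-marker gaps
  stay well under the 20-kb iHS gap cap.

## Known limitations

No statistical phasing (haplotype input must be phased; the simulator
generates phased data), no multi-allelic sites, no binary PLINK (.bed),
no X chromosome, no external reference-panel projection, no tree or
ancestry-proportion estimation, no admixture dating, and no GO
enrichment of candidate regions. The IBD estimator assumes approximate
linkage equilibrium (use the LD-pruned set). Window-scan and iHS power
statements are conditional on the simulator's no-background-LD
assumption and transfer to real data only qualitatively.
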