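---
title: "Mapping QTL by pooled sequencing of phenotypic extremes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping QTL by pooled sequencing of phenotypic extremes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsascan)
```

## The method

Bulked segregant analysis by sequencing (BSA-seq) maps quantitative trait
loci without genotyping individuals. In a large segregating population
derived from two inbred parents, the individuals at the two phenotypic
extremes are pooled and each pool is sequenced as a whole. At a SNP that is
unlinked to the trait, both pools estimate the same population allele
frequency; at a SNP linked to a causal locus, truncation selection drags
the two pools' frequencies apart. The scan statistic at SNP $j$ is the
standardized difference of the pooled reference-parent allele frequencies

$$z_j = \frac{\hat p_{j,\mathrm{top}} - \hat p_{j,\mathrm{bottom}}}
  {\sqrt{\hat p_j (1-\hat p_j)\left(\frac{1}{n_{j,\mathrm{top}}}
  + \frac{1}{n_{j,\mathrm{bottom}}}\right)}},
\qquad
\hat p_j = \frac{x_{j,\mathrm{top}} + x_{j,\mathrm{bottom}}}
  {n_{j,\mathrm{top}} + n_{j,\mathrm{bottom}}},$$

where $x$ counts reads carrying the reference-parent allele and $n$ all
reads at the SNP in that pool. Because a single SNP at 20–60x pool depth is
noisy, $z_j$ is averaged over a centered sliding window of $d$ consecutive
scan SNPs ($d = 15$ by default: the focal SNP plus 7 neighbors per side),

$$Z'_j = \frac{1}{d} \sum_{m \in \mathrm{window}(j)} z_m,$$

and $Z'_j$ is referred to the standard normal for a two-sided p-value.
Alongside it, the same window mean of the raw frequency difference
($\hat p_\mathrm{top} - \hat p_\mathrm{bottom}$) is reported as the
direction profile: its sign at a peak says which parent contributes the
trait-increasing allele.

Significant SNPs are declared by an *empirical outlier* rule rather than a
formal multiple-testing correction: the threshold is the 99.5th percentile
(`q = 0.005`) of all $-\log_{10}(p)$ values by the nearest-rank convention,
and SNPs strictly above it are significant. Each maximal run of significant
SNPs is extended by 7 scan SNPs on each side (those SNPs contributed to the
windowed estimate at the run's ends), and regions whose boundary SNPs are
closer than 5 Mb are merged, iterating until stable.

## Why these choices

**Unscaled window mean.** $Z'$ is the mean of $d$ standard-normal-like
quantities, so under independence its standard deviation is $1/\sqrt d$,
and comparing it to $N(0,1)$ without rescaling is conservative by design.
The neighboring SNPs in a window are in unknown linkage disequilibrium
within the sequenced pools; rescaling by $\sqrt d$ would be exact only
under independence and anti-conservative under positive correlation, which
is the realistic case. A `scale_window = TRUE` switch in `scan_config()`
exposes the $\sqrt d$-scaled variant, but the conservative unscaled form is
the default, and the empirical outlier threshold — which adapts to the
realized null distribution — is the primary significance device, making
the absolute calibration of the window p-value secondary.

**Empirical quantile convention.** An outlier threshold is only defined up
to a quantile convention, and tie handling at the threshold is likewise a
convention. We fix nearest-rank (the sorted value at rank
$\lceil (1-q) N \rceil$) and strict exceedance, chosen for determinism;
both are conventions of this package, not facts about the method.

**Window over scan SNPs, not physical distance.** Missing cells are removed
from the SNP sequence *before* windowing, so every window holds exactly
$d$ participating SNPs. The alternative (propagating missingness through
windows anchored on physical positions) loses resolution wherever coverage
fluctuates; windowing the index space keeps the statistic's null behavior
homogeneous along the genome. Windows never span chromosome boundaries,
and SNPs within $\lfloor d/2\rfloor$ scan SNPs of a chromosome end get no
windowed value.

**Strict filter bounds.** All coverage and control-frequency comparisons
are strict — a cell is masked when depth is *less than* 20 or *greater
than* the upper bound, and a row is dropped when the control frequency is
*less than* 0.25 or *greater than* 0.75 — so boundary values survive. The
upper coverage bound is the mean plus `max_cov_k` (default 1) sample
standard deviations of depth pooled over every (SNP, pool) cell jointly;
per-pool bounds are deliberately not offered. High-coverage cells are
masked because excess depth flags collapsed repeats and paralogous
mapping, where the frequency estimate is biased rather than merely noisy.

**Control-pool filter.** A random (unselected) pool estimates the
population allele frequency; markers whose control frequency leaves
[0.25, 0.75] — or is missing — are removed entirely, since segregation
distortion or mapping artifacts there corrupt the tail contrast too. A
consequence is that each trait contrast uses only the SNPs non-missing in
*both* of its tail pools, so different traits scan slightly different SNP
sets even from one sequencing experiment.

**Degenerate statistics.** A SNP monomorphic across both pools
($\hat p \in \{0,1\}$) has an undefined standard error and is treated as
missing, not $\pm\infty$; a zero numerator gives $z = 0$; two-sided
p-values are floored at $10^{-300}$ before the log to keep
$-\log_{10}(p)$ finite. Peak ties within a region are broken leftmost.
Interval lengths in kb are rounded half away from zero (10,335 bp is 10 kb;
15,867 bp is 16 kb).

**Sign of the direction profile.** The windowed frequency difference and
$Z'$ agree in sign wherever the signal is non-trivial, but exactly at zero
they may differ, because $z$ weights each SNP's difference by its pooled
standard error while the direction profile weights SNPs equally. Direction
calls are made at region peaks, where the distinction is immaterial.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `d` | 15 | scan SNPs | window width; odd so the window is centered |
| `min_call_depth` | 10 | reads | summed-depth floor for calling a SNP |
| `min_call_maf` | 0.25 | fraction | minor-allele floor for calling a SNP |
| `min_cov` | 20 | reads | per-pool depth floor for a frequency estimate |
| `max_cov_k` | 1 | SDs | upper depth bound = mean + k·SD over all cells |
| `control_low`, `control_high` | 0.25, 0.75 | fraction | retained control-frequency band |
| `q` (quantile) | 0.005 | fraction | empirical outlier fraction |
| `flank_snps` | 7 | scan SNPs | boundary extension of significant runs |
| `merge_bp` | 5 Mb | bp | minimum non-significant gap between regions |

The boundary extension is in scan-SNP index space while the merge test is
in physical bp between boundary SNP positions; mixing the two spaces is
intentional — the extension exists because of the SNP-indexed window, the
merge because linkage blocks are physical.

## The synthetic-data generator

`simulate_bsa()` emulates the experimental design end to end so the whole
pipeline can be validated against known truth:

1. **Population.** Two fully homozygous founders are crossed; the F1 is
   randomly mated to give the F2, followed by `generations` (default 14)
   further rounds of random mating with two distinct parents per
   offspring. Meiosis is Haldane: Poisson crossover counts with uniform
   breakpoint placement on the genetic map and no interference — the
   simplest standard model; the real organism's interference and
   heterogeneous recombination landscape are not modeled. The default map
   is a constant 0.5 cM/Mb.
2. **Trait.** Planted QTL contribute $a(c-1) + a\,k\,[c{=}1]$ to the
   genetic value ($c$ = reference-allele dosage, $a$ = additive effect,
   $k$ = dominance degree, default 0); Gaussian noise is scaled to a
   target heritability (default 0.7). Dominance is not planted by default
   because it weakens pooled-extreme detection and the additive case is
   the cleanest validation target.
3. **Selection.** The `n_selected` (default 46) most extreme individuals
   per tail form the top and bottom pools; `n_control` (default 92)
   individuals are drawn uniformly from the whole population, possibly
   overlapping the tails, as when control tissue is sampled before
   phenotyping.
4. **Sequencing.** Per SNP and pool, depth is Poisson (default mean 40)
   and the reference read count is binomial at the error-perturbed pool
   frequency $f(1-e) + (1-f)e$ with symmetric flip rate $e$ (default
   0.001). There is no read-level simulation, no mapping bias, and no
   overdispersion beyond Poisson-binomial sampling — real pooled data are
   typically overdispersed (unequal DNA contributions, library effects),
   so passing simulations demonstrate correctness of the machinery, not
   field-realistic power.

All stochastic stages derive child seeds deterministically from one master
seed, so a full run is exactly reproducible.

## Validation scales

The test suite exercises the pipeline at desk scale, chosen to finish in
minutes while leaving the statistical checks well-powered: null
calibration uses 10,000 SNPs at depth 40 (the per-SNP $z$ has mean within
±0.05, SD within [0.9, 1.1], and a 1.96-exceedance fraction near 5%, while
the unscaled window p-value is strongly conservative); end-to-end recovery
uses 20 replicates of a 2,000-individual population on two 150-Mb
chromosomes with 5,000 SNPs and a single QTL explaining 20% of phenotypic
variance, requiring the region caller to hit the QTL within 5 Mb in at
least 80% of replicates. Window means are verified against a brute-force
loop to $10^{-12}$ on random fixtures up to 10,000 SNPs.

## Map expansion

To compare designs, the package implements the classical expansion factors
for effective recombination per individual: $j/2 + (2^i-1)/2^i$ for a
design with $j$ generations of intermating and $i$ of inbreeding, and
$(2^{i+1}-1)/2^i$ for inbreeding alone. With the fully-inbred limit
($i\to\infty$) the factors for $j = 4$ and $j = 14$ are 3 and 8, so a
recombinant-inbred-line population carrying 57 effective events per
individual implies $57 \times 8/3 = 152$ in a 14-generation intermated
population. Note the convention: applying the limit $i\to\infty$ to a
*noninbred* intermated population is what yields 152; taking $i = 0$
literally gives $57 \times (7/2)/3 \approx 133$. The functions default to
the $i=\infty$ convention and expose $i$ so users can choose deliberately.

## Known limitations

* Frequencies are plug-in read-count ratios; there is no genotype-likelihood
  or overdispersion model, so standard errors are optimistic on real data.
* The empirical outlier threshold always calls something: on a pure null
  scan roughly 0.5% of SNPs exceed it, clustered by the window into a few
  spurious regions. Interpretation must lean on effect direction,
  replication, or orthogonal mapping (e.g. the interval-overlap report
  against linkage QTL in `run_compare()`).
* Region boundaries inherit the window's resolution: they are accurate to
  a handful of inter-SNP distances, not base pairs.
* The simulator's idealizations (no interference, uniform recombination
  rate, Poisson depth, symmetric error) make it a correctness harness, not
  a power calculator for a specific field experiment.
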