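---
title: "Stripe-slope GC-bias correction: model, estimator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stripe-slope GC-bias correction: model, estimator and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcstripe)
```

## The model

Sequencing depth depends on local GC content, and the dependence differs in
shape between a tumor library and its matched normal. `gcstripe` writes the
expected depth of a segment with GC fraction $g$ as

$$D^N = f(g)\, d_1\, g\, e^{-a_1 g}, \qquad
  D^S = f(g)\, d_2\, g\, e^{-a_2 g} \cdot \frac{\bar C}{2},$$

with $f$ a GC response shared by both libraries, $(a, d)$ a per-sample
curvature and scale, and $\bar C = \phi C + (1-\phi)\,2$ the average copy
number of a segment carried by a fraction $\phi$ of cells at tumor copy
number $C$. Everything shared cancels in the log ratio
$Y = \log(D^S/D^N)$:

$$Y_i - Y_j \;=\; \log\frac{\bar C_i}{\bar C_j}
  \;+\; (a_2 - a_1)\,(g_j - g_i),$$

so segments sharing one $\bar C$ lie on a line in the $(g, Y)$ plane with
slope $a_1 - a_2$, and distinct $\bar C$ values produce parallel *stripes*
separated by $\log(\bar C_i/\bar C_j)$. Natural logarithms are used
throughout; the stripe-gap identity holds in any base, but base $e$ keeps
the fitted slope directly comparable to $a_1 - a_2$.

The key assumptions, in decreasing order of importance:

* one common stripe slope genome-wide (a single pair of library
  curvatures; no per-chromosome bias);
* segment counts large enough that $Y$ is well defined and approximately
  continuous (SCNA-scale segments, not kilobase bins);
* at germline heterozygous SNPs, the non-reference allele is maternal or
  paternal with equal probability, making each segment's BAF distribution
  symmetric — about $1/2$ exactly when the segment has equal maternal and
  paternal copy ($\mu = 1/2$), which at every $\phi$ forces the tumor BAF
  $\xi = \frac{\phi C \mu + (1-\phi)}{\bar C} = \tfrac12$.

## The slope estimator

A regression of $Y$ on GC estimates the *mixture* trend, which coincides
with the stripe slope only when stripe membership is independent of GC. In
tumors it is not (amplified regions are GC-shifted), and a fitted line that
crosses stripes leaves residual bias exactly where the subclonal signal
lives. The estimator here instead scores a candidate slope $m$ by how
sharp the stripes become after removing it:

$$Y' = Y - (mX + c) + \operatorname{median}(Y), \qquad
  \log p(Y, X \mid m) = \log \sum_{k=1}^{K} h_k(Y'),$$

where $h_1 \ge h_2 \ge \dots$ are the heights of the local maxima of a
Gaussian kernel density of $Y'$ and $K = \tau \cdot \max(cn)$ caps how many
peaks may contribute ($\tau$ assumed subclone count, $\max(cn)$ maximum
copy number). The intercept $c$ only translates $Y'$ and provably cannot
change the likelihood, so it is held fixed. The prior on $m$ is uniform on
$[a - \delta, a + \delta]$ around an *anchor line* through the (median GC,
median $Y$) points of the low- and high-GC tails; a Gaussian random-walk
Metropolis sampler explores the window, and the reported slope is the MAP
over every evaluated proposal (the posterior is one-dimensional and each
evaluation is exact, so burn-in visits are legitimate candidates).

Numerical choices:

* **Kernel and bandwidth.** Gaussian kernel, Silverman's rule
  (`bw.nrd0`) by default, on a 1024-point grid spanning
  $[\min - 3h, \max + 3h]$. The bandwidth is overridable
  (`kde_bandwidth`): stripe resolution at very low purity is
  bandwidth-limited.
* **Peaks.** Strict interior local maxima of the gridded curve, no
  minimum-separation filter. Spurious micro-peaks have small heights and
  the top-$K$ sum is insensitive to them; $K$ is additionally capped at 24.
* **Sampler.** `n_iter = 5000`, `burn_in = 1000`,
  `proposal_sd` $= \delta/10$ with $\delta = 1$; out-of-window proposals
  are rejected, which is the hard uniform prior. An exhaustive grid search
  (`grid_search_slope`) over the same window serves as an independent
  check of the sampler in the test suite.
* **Anchor areas.** GC quantiles 0.10 / 0.90. Medians make the anchor
  robust to minority stripes, but when the two tails' medians land in
  different stripes the anchor can tilt by roughly
  $\pm\,\mathrm{gap}/\Delta g$; $\delta = 1$ is chosen wide enough that
  the window still contains the true slope in the common cases, and the
  recovery test uses the *median* error across replicate genomes for this
  reason.
* **Degenerate input.** Constant $Y$ short-circuits to slope 0 with a
  warning; a point-mass density is reported as a single peak of infinite
  height rather than an error.

## Baseline selection and ploidy

After correction the package (1) keeps segments with at least `min_sites`
heterozygous-site BAFs whose median $|BAF - \tfrac12| \le$ `baf_tol`; (2)
clusters their corrected log-ratios by average-linkage hierarchical
clustering, cutting the tree at the largest relative gap in merge heights
(at most `max_clusters`); (3) takes the eligible cluster (holding at least
`min_cluster_frac` of candidates) with the **smallest mean** corrected
log-ratio as baseline. Balanced gains such as $(C, b) = (4, 2)$ also have
$\xi = 1/2$, which is precisely why the lowest cluster — not the BAF filter
alone — defines the baseline. "Smallest" is read as smallest *mean* (the
plausible alternative, smallest minimum, is more outlier-sensitive); ties
go to the larger cluster, then to the cluster containing the earliest
candidate.

Defaults `baf_tol = 0.08`, `min_sites = 5`, `het_low/het_high = 0.4/0.6`,
`min_depth = 10`: at $\sim$30× site depth the binomial sd of a single BAF
is $\approx 0.09$, so the median of a handful of sites at $\xi = 1/2$ sits
within 0.08 of $\tfrac12$ with high probability while the nearest
unbalanced states ($\xi \approx 0.64$ at $\phi = 0.8$, $C = 3$) do not.

Ploidy is a deliberately simple anchor-based summary: each segment's
relative copy estimate is $r_i = 2\exp(Y'_i - \bar Y'_{\mathrm{base}})$
and the genome ploidy is the segment-length-weighted mean of $r_i$
(baseline segments contribute exactly 2). It is isolated in
`estimate_ploidy()` so a more elaborate procedure can replace it without
touching the selection logic. Subclone frequency inverts the copy-number
mixture, $\phi = (\bar C - 2)/(C - 2)$; for $C = 2$ (e.g. copy-neutral
LOH) the ratio carries no frequency information and the function refuses
rather than guesses.

## What the simulator emulates — and what it does not

`simulate_genome()` draws, per segment: a log-uniform length in
$[10^5, 10^7]$ bp (SCNA scale), a GC fraction, a lognormal efficiency
factor $\theta$ (sd `theta_sd = 0.05`) applied to *both* samples — it
stands for mappability and length effects and cancels in the ratio, as the
depth model implies — a copy state from `copy_number_states`, and Poisson
read counts around the model means anchored at `depth_scale = 0.3`
reads/bp at reference GC 0.45 (30× coverage at 100 bp reads). Het sites
are placed at `snp_rate = 0.2`/kb — a deliberately conservative
post-filtering density of usable germline heterozygous sites — with
Poisson(30) site depths and binomial B-counts at $\xi$ or $1 - \xi$ with a
fair coin (the maternal/paternal symmetry). Copy states may carry their
own GC range, reproducing the GC/copy-state correlation of real tumors;
this is the configuration in which a plain regression line demonstrably
tilts while the stripe-sharpness estimator does not.

The generator deliberately does **not** emulate: segmentation error
(breakpoints are exact), count overdispersion beyond the shared $\theta$
(no negative binomial; ratio noise is purely Poisson), read-level
artifacts (duplicates, mapping errors, reference bias at SNPs), LOH
genotyping subtleties, or multi-subclone genomes (a single $\phi$ per
dataset). Passing tests therefore demonstrate correctness of the
estimators *under the stated model*, not robustness to segmentation or
alignment pathology; on real data the upstream segmentation quality is the
binding constraint.

Fixed default bias parameters are the displayed curvature/scale pairs
$(1.3, 2.3)$ and $(2, 3)$; which pair is tumor and which normal is a
configuration choice (the assignment here puts $(2, 3)$ on the tumor,
giving stripe slope $-0.7$). The shared response $f$ supports `constant`
and `gaussian_bump` shapes; both must — and in the tests do — yield
identical stripe geometry, since $f$ cancels.

## Problem sizes

The validation suite runs genomes of 400 segments (the scale at which
median slope-recovery error is assessed), purity titrations over
$\{0.95, 0.8, 0.6, 0.4, 0.2, 0.05\}$, and replicate seeds for the
recovery and oracle-agreement checks; smaller genomes (80–250 segments)
cover I/O, clustering and pipeline behavior. These sizes were chosen so
that each estimator's sampling noise is well below the tolerance it is
tested against.

## Known limitations

* A single genome-wide slope: chromosome- or arm-level bias differences
  are averaged over.
* $\tau$ (subclone count) and $\max(cn)$ are inputs, not estimated; they
  only enter through the peak cap $K$, so moderate misspecification is
  benign, but a drastically small $K$ can blind the likelihood to real
  stripes.
* The anchor line can tilt when a GC tail is dominated by a minority
  stripe; the uniform window usually still covers the truth, but
  pathological stripe layouts can pin the MAP at a window boundary — the
  chain file makes this visible.
* Ploidy from the baseline anchor inherits any baseline mis-selection;
  in near-triploid genomes the rounding is genuinely ambiguous.
* BAF symmetry is assessed per segment in aggregate; allele-specific
  phasing is out of scope.
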