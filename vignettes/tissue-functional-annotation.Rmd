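---
title: "Tissue-specific functional annotation and GWAS prioritization with TissueMix"
author: "TissueMix authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific functional annotation and GWAS prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TissueMix)
```

# The annotation model

TissueMix scores every nucleotide of a genome for *tissue-specific
functionality* from eight binarized epigenetic features: peak calls for
seven histone modifications (H3K4me1, H3K4me3, H3K36me3, H3K27me3,
H3K9me3, H3K27ac, H3K9ac) and DNase I hypersensitivity. For one tissue
group, each mark's coverage is the union of peak intervals across that
tissue's samples; at a nucleotide this yields a binary observation vector
$A = (A_1, \dots, A_8)$.

The model is an unsupervised two-component mixture. A latent indicator
$Z \in \{0, 1\}$ marks functionality, marks are conditionally independent
given $Z$, and each is Bernoulli:

$$ f(A \mid Z = c) = \prod_{i=1}^{8} p_{ic}^{A_i} (1 - p_{ic})^{1 - A_i},
   \qquad \pi = P(Z = 1). $$

That is 17 free parameters per tissue ($\pi$, $p_{11..81}$,
$p_{10..80}$), estimated by EM from a genome sampling: positions of
trait-associated SNPs expanded into fixed-width 1 kb windows
(`buildTrainingSample`, 500 bp flank on each side; symmetric windows are
the natural reading of "1 kb around a position"). Overlapping windows are
merged so each bp contributes exactly one observation. The per-bp
posterior

$$ P(Z = 1 \mid A) =
   \frac{\pi f(A \mid Z=1)}{\pi f(A \mid Z=1) + (1-\pi) f(A \mid Z=0)} $$

is the GS score, computed genome-wide as a run-length-encoded track.

## Estimation details

Everything genome-scale runs over the $\le 256$ distinct mark patterns
with bp multiplicities, never per bp; `scoreGenome` overlays the eight
binary tracks into an integer pattern code per bp and maps codes through
a 256-entry posterior lookup. This is exact — the test suite asserts
bit-identical agreement with naive per-bp evaluation — and makes whole
genomes cheap.

Choices the model statement leaves open were fixed as follows:

* **Initialization and restarts.** $p_{i1} \sim U(0.5, 0.9)$,
  $p_{i0} \sim U(0.05, 0.3)$, $\pi = 0.5$, five random restarts under a
  fixed seed, keeping the best final log-likelihood. Restarts guard
  against local optima; the asymmetric ranges encode only that the
  functional component is annotation-rich, which is also enforced after
  fitting by swapping components (and $\pi \mapsto 1 - \pi$) if
  $\overline{p_1} < \overline{p_0}$.
* **Numerical safety.** Rates and $\pi$ are clipped to
  $[10^{-6}, 1 - 10^{-6}]$ each M-step, preventing $\log 0$ and
  degenerate posteriors; component log-densities are accumulated in log
  space with a log-sum-exp E-step. A component that receives no
  responsibility mass keeps uninformative rates (0.5) rather than NaN.
* **Convergence.** Relative log-likelihood change below $10^{-8}$, cap
  1000 iterations. The per-iteration log-likelihood is recorded
  (`EmTrace`) and is non-decreasing up to $10^{-9}$ relative tolerance.
* **Coordinates.** In memory everything is Bioconductor-native
  (1-based, closed `GRanges`/`Rle`); BED-family files (0-based,
  half-open) are converted only at parse/serialize boundaries. Positions
  not covered by any score interval read as 0, matching the convention
  that absence of signal enrichment is evidence of non-functionality.

# SNP prioritization

A GWAS SNP falls in one of three disjoint cases: (I) functional for the
trait and the tissue ($Z_D = 1, Z_T = 1$), (II) tissue-functional but not
trait-relevant, (III) not tissue-functional. The GSP score is the case-I
posterior given the SNP's p-value:

$$ P(Z_D=1, Z_T=1 \mid p) =
   \frac{f_1(p)\, w\, t}
        {f_1(p)\, w\, t + f_0(p)\,(1-w)\, t + f_{T0}(p)\,(1-t)} $$

with components:

* $t$, the per-SNP tissue prior $P(Z_T = 1)$: the mean GS score over the
  surrounding 10 kb window (`assignPriors`; windows are clipped at
  chromosome ends and the mean is taken over the clipped window).
* $f_{T0}(p) = f(p \mid Z_T = 0)$: a histogram density estimated from
  the SNPs whose tissue prior falls below 0.1. Because functional
  annotation makes the priors bimodal, the partition is insensitive to
  the exact threshold. The low-prior null is estimated once globally yet
  applied with per-SNP weight $(1 - t)$, which is the intended scheme.
* $f_0(p) = f(p \mid Z = 0)$: the same construction on a *general*
  (non-tissue-specific) functionality track; SNPs functional in a tissue
  but irrelevant to the trait are assumed to behave like non-functional
  SNPs, so this density also stands in for $f(p \mid Z_D=0, Z_T=1)$.
* $f_1(p) = \alpha p^{\alpha - 1}$, a Beta($\alpha$, 1) density
  ($0 < \alpha < 1$) for trait-functional SNPs, and the global weight
  $w = P(Z_D = 1 \mid Z_T = 1)$: both estimated by EM on the high-prior
  SNPs, whose p-values follow the mixture
  $w f_1(p) + (1 - w) f_0(p)$. Both M-step updates are closed form:
  $w = \bar r$ and $\alpha = -\sum r_j / \sum r_j \log p_j$.

The NSFP score is the analogous two-case posterior built from the general
track alone, with per-SNP prior $g = \mathrm{PRIOR\_G} \cdot w_{general}$:
$P(Z_D = 1 \mid p) = f_1(p) g / [f_1(p) g + f_0(p)(1 - g)]$. The general
track is an opaque input; when none is supplied the tissue track is
substituted with a warning, making NSFP a same-track baseline.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| prior window | 10,000 | bp | scale over which association signals tag nearby regulatory elements |
| prior threshold | 0.1 | probability | splits the bimodal window-mean priors; insensitive within the bimodal gap |
| histogram bins | CV over {5, 10, 20, …, 200} | bins | 10-fold CV on held-out log-likelihood; ties go to fewest bins; +0.5 pseudocount per bin keeps densities positive |
| $\alpha$ clip | $(10^{-4}, 1 - 10^{-4})$ | — | keeps the Beta density proper and $\log p$ terms finite |
| p-value clip | $[10^{-300}, 1]$ | — | genome-wide p-values can underflow; $p = 1$ is retained (the beta density there equals $\alpha$) |
| GS cutoff | 0.5 | probability | conventional functional call for fractions and BED export |
| tie tolerance | $10^{-4}$ | posterior | two tissues within this of the locus maximum tie (reporting precision) |

## Locus analytics

`localMaxGsp` takes, per tissue, the maximum GSP among the SNPs inside a
risk locus; the tissue with the largest local maximum is the predicted
relevant tissue, with ties flagged rather than broken arbitrarily.
`bestRankAtLoci` ranks SNPs genome-wide (competition ranking: ties share
the minimum rank, preserving "best at locus" semantics) and takes each
locus's best rank. `rankImprovementTest` counts loci whose best rank
strictly improves between two scoring schemes, drops ties (if no ties
occur the denominator is the full locus count), and computes the exact
one-sided binomial tail at success probability 1/2. An "increased rank"
is read as an improvement, i.e. a numerically smaller rank; the binomial
framing only uses the success count, so the reading affects labels, not
the test. `enrichmentCurve` reports the ratio of the target rate in the
top N SNPs to the genome-wide target rate.

# The synthetic-data generator

`simulateTracks`/`simulateGwas` generate data with exactly the structure
the two models assume, so every pipeline stage is testable without
external downloads:

* Functional regions are planted with geometric lengths (mean 1 kb) until
  the target functional fraction (default 0.10) is reached; the final
  segment is truncated so the realized fraction is exact. Gaps are placed
  by integer stars-and-bars, giving uniform random placement.
* Marks are drawn *block-wise* — one Bernoulli draw per planted segment
  (rate $p_{i1} = 0.7$) and per background block (rate $p_{i0} = 0.1$)
  per mark — so peak files contain realistic contiguous intervals while
  per-bp marginals match the mixture. The default rates give
  well-separated components: the GS score distribution is strongly
  bimodal (about 5% of bp fall between 0.1 and 0.9).
* SNP positions are uniform; on functional bp a SNP is case I with
  probability $w = 0.3$ and draws $p \sim$ Beta($0.3$, 1), otherwise
  (cases II/III) $p \sim U(0, 1)$.
* One master seed keys everything; per-stage sub-seeds are derived
  deterministically from it, so a workspace regenerates bit-identically.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: linkage disequilibrium among SNPs (each
p-value is independent), correlated or hierarchically organized marks
(real histone marks co-occur in characteristic chromatin states),
chromosome-scale heterogeneity, allele-frequency-dependent power, and
per-bp mark noise within peaks. In particular, planted 1 kb regions
diluted in 10 kb prior windows make the simulated priors less bimodal
than real annotation tracks, which attenuates the fitted $w$ relative to
its generating value; the ranking comparisons the tests assert are
robust to this, the absolute $w$ is not.

# Problem sizes and verification

The shipped tests and the acceptance script use desk-scale problems
chosen to make estimator noise small relative to the tolerances asserted:
EM recovery of ($\pi = 0.1$, $p_{i1} = 0.7$, $p_{i0} = 0.1$) from 200,000
multinomially drawn observations (recovered within ±0.01/±0.02);
beta-uniform recovery of ($\alpha = 0.3$, $w = 0.3$) from 50,000
p-values (±0.05/±0.02); exact pattern-table vs per-bp equivalence on
100 kb genomes; and the full pipeline on a 1 Mb genome with 10,000 SNPs,
where planted case-I SNPs rank substantially better under GSP than under
raw p-values. The worked binomial example (67 improved loci of 105,
$p \approx 0.003$) is computed exactly by `binomialImprovementTest`.

# Known limitations

* Exactly eight marks, binary inputs, two components; continuous signal,
  missing marks and richer chromatin-state models are out of scope.
* The general-functionality track is consumed, never produced; without
  one, NSFP degenerates to a same-track baseline.
* No LD-aware modeling, effect-size estimation, or locus-boundary
  inference; loci are taken as given intervals.
* The conditional weight $w$ is a single global constant per
  (trait, tissue) pair, while the prior $t$ is per-SNP; this asymmetry is
  inherent to the estimation scheme.
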