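# TissueMix

Tissue-specific functional annotation of the genome from binarized
epigenetic marks, and prioritization of GWAS signals with the resulting
annotation tracks.

## What it does

Regulatory function is tissue-specific: an enhancer active in brain may be
silent chromatin in blood. TissueMix integrates, for one tissue group,
eight binarized epigenetic features — peak calls for H3K4me1, H3K4me3,
H3K36me3, H3K27me3, H3K9me3, H3K27ac, H3K9ac and DNase I hypersensitivity
— into a single per-nucleotide posterior probability of tissue-specific
functionality, and then uses that annotation to re-weight GWAS association
signals. It is intended for statistical geneticists and regulatory
genomicists working with peak-call files (BED/narrowPeak) and GWAS summary
statistics.

The annotation model is a two-component Bernoulli mixture. Let
*A* = (*A₁*, …, *A₈*) be the binary mark indicators at a nucleotide and
*Z* ∈ {0, 1} its latent functionality. Marks are conditionally independent
given *Z*, with

  *P*(*Aᵢ* = 1 | *Z* = *c*) = *p\_{ic}*,  π = *P*(*Z* = 1),

giving 17 free parameters per tissue, estimated by EM from a genome
sampling (1 kb windows around trait-associated positions). The **GS
score** at a nucleotide is the posterior

  *P*(*Z* = 1 | *A*) = π f(*A*|*Z*=1) / [π f(*A*|*Z*=1) + (1−π) f(*A*|*Z*=0)].

For prioritization, each SNP falls in one of three cases — (I) disease-
and tissue-functional, (II) tissue-functional only, (III) not
tissue-functional. With a per-SNP tissue prior *t* (mean GS score over the
surrounding 10 kb), a Beta(α, 1) density for disease-functional p-values,
histogram null densities estimated from low-prior SNPs, and the EM-estimated
global weight *w* = *P*(*Z_D*=1 | *Z_T*=1), the **GSP score** is the case-I
posterior

  *P*(*Z_D*=1, *Z_T*=1 | *p*) =
  f₁(*p*)·*w*·*t* / [f₁(*p*)·*w*·*t* + f₀(*p*)·(1−*w*)·*t* + f_T0(*p*)·(1−*t*)].

An analogous two-case posterior (**NSFP score**) uses a general,
non-tissue-specific functionality track. Locus-level utilities assign each
risk locus its most relevant tissue via the local maximum GSP score (with
tie handling), compare per-locus rank improvements between scoring schemes
with an exact one-sided binomial test, and compute fold-enrichment curves
of a target SNP set among top-ranked SNPs.

## Worked example

Everything below runs on synthetic data generated by the package itself
(1 Mb genome, 10% planted functional bp, 10,000 SNPs):

```r
library(TissueMix)

cfg  <- simConfig(seed = 1)                 # study conditions
sim  <- simulateTracks(cfg)                 # 8-mark peak tracks + truth
gwas <- simulateGwas(cfg, sim$truth[[1]])   # p-values by planted case

## fit the annotation mixture from windows around top associations
seeds   <- gwas[order(gwas$P)[1:2000], c("CHR", "BP")]
tsample <- buildTrainingSample(seeds, sim$tracks[[1]])
fit     <- emFit(tsample)
fit$params
#> MixtureParams (17 free parameters)
#>   pi = 0.105
#>    H3K4me1 H3K4me3 H3K36me3 H3K27me3 H3K9me3 H3K27ac H3K9ac  DNase
#> p1  0.7813  0.7635   0.6555   0.6439  0.5278  0.6760 0.7215 0.5880
#> p0  0.0976  0.1010   0.1160   0.1173  0.0960  0.1031 0.0910 0.1333

track <- scoreGenome(fit$params, sim$tracks[[1]])
functionalFraction(track, 0.5)
#> [1] 0.094029

## prioritize the GWAS SNPs with the fitted track
scored <- prioritize(gwas[, c("SNP", "CHR", "BP", "P")], track)
head(scored$GSP[gwas$CASE == 1], 3)
#> [1] 0.07024488 0.04863369 0.01498257

## planted disease SNPs rank far better under GSP than under raw p-values
mean(rank(-scored$GSP)[gwas$CASE == 1]); mean(rank(scored$P)[gwas$CASE == 1])
#> [1] 1755.64
#> [1] 2431.111

## the worked locus-rank comparison: 67 improved loci out of 105
binomialImprovementTest(67, 105)$pValue
#> [1] 0.003008041
```

A command-line pipeline (`simulate`, `fit`, `score`, `prioritize`,
`locus`) wrapping the same functions ships in `inst/scripts/tissuemix`:

```sh
Rscript inst/scripts/tissuemix simulate --out demo --seed 1
Rscript inst/scripts/tissuemix locus --selftest 67,105
```

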