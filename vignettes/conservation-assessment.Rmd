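---
title: "Genomic conservation assessment: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic conservation assessment: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdassess)
```

## The problem

Small, closed livestock populations — conservation-farm herds of a few dozen
breeding males, for instance — lose genetic diversity through drift and
inbreeding. When pedigrees are unrecorded or unreliable, medium-density SNP
arrays (~50K markers) allow the key conservation parameters to be estimated
directly from genotypes: who is related to whom, how inbred each animal is,
and how large the effectively breeding population has been over recent
history. `herdassess` implements that full chain for diploid biallelic
autosomal genotypes, and pairs it with a forward simulator that produces
datasets with *known* truth so every stage can be validated quantitatively.

## Quality control

Filters run in a fixed sequence, because exclusion counts are only meaningful
relative to an ordering: individuals with more than 10% missing genotypes are
removed first, then SNPs with (1) unrecognized position (chromosome 0, above
the configured autosome count, or non-positive coordinate), (2) call rate
below 0.95, (3) minor allele frequency below 0.05 (recomputed on the current
data, missing genotypes ignored), (4) a Hardy–Weinberg exact-test p-value
below 1e-5. The HWE test is the conditional exact test (the probability of
all heterozygote counts no more likely than the one observed, given the
allele counts). It is applied to the pooled sample by default — defensible
when the panel is analysed as one dataset — with `hwe_by_population = TRUE`
available, since pooling mixes populations and can flag differentiated loci
(a Wahlund effect) rather than genotyping failures. The report object
guarantees the accounting identity: exclusions per step plus the final count
reproduce the initial count, a property the test suite fuzzes.

## Relationship and structure

The genomic relationship matrix follows VanRaden's first method,
G = ZZ′ / 2Σpᵢ(1−pᵢ), with Z the dosage matrix column-centered by 2p.
Reference frequencies default to the pooled sample, matching the joint
analysis of several populations at once; missing dosages are mean-imputed
(centered value zero), the standard treatment, which biases an almost-empty
profile's relationships toward zero rather than inventing signal. The
diagonal minus one is the genomic inbreeding coefficient; dividing G_jk by
√(G_jj G_kk) gives a correlation-like matrix used for family detection.
Note that with frequencies estimated from the sample itself the mean
off-diagonal sits near −1/(n−1), not 0 — a centering constraint, not a bias.

Families are defined operationally: within each population, connect pairs
whose normalized relationship is at least a threshold and take connected
components. The default threshold 0.25 sits between full sibs (≈0.5) and
second-degree relatives (≈0.25); realized relationships scatter around their
pedigree expectations with a variance that shrinks with genetic map length,
which is why validation uses a realistically long genome (≈24 Morgans; see
below). No published clustering rule exists for the family counts this
mirrors, so the thresholded-components formalization is one defensible
choice, and family counts are treated as descriptive, not as targets.

Population structure is summarized two ways: principal components of G
(eigenvectors scaled by the square root of their eigenvalues, variance
shares relative to the positive spectrum), and a neighbor-joining tree on
allele-sharing distance d = 1 − IBS. NJ is implemented exactly
(Saitou–Nei Q-criterion, deterministic lowest-index tie-break, negative
branch lengths clamped to zero with a warning) and cross-checked against an
independent implementation in the test suite.

## Runs of homozygosity and inbreeding

ROH are detected by a consecutive-SNP scan, not a sliding window: the
parameter set used in this style of analysis (per-run allowances, a gap
limit, a minimum SNP count) belongs to the consecutive-runs method. A run
extends over homozygous calls; one heterozygote and one missing call may be
absorbed (both configurable); a gap above 1 Mb between adjacent SNPs or an
allowance overflow closes the run. Absorbed calls at the edges are trimmed
so every reported segment starts and ends on homozygous evidence —
non-evidential endpoints would otherwise inflate lengths; the scan then
resumes after the closing violation. Segments are kept when they span at
least 1 Mb *and* contain at least l SNPs, where
l = ⌈ln(α/(nₛ·nᵢ)) / ln(1−het)⌉ controls the expected number of chance runs
(α = 0.05 by default; het is the dataset's mean observed heterozygosity;
the ceiling is taken because a count must be integral and conservative,
with a 1e-9 guard so exactly-integral ratios are not rounded up by
floating-point noise). At the parameters typical of a 45K panel on ~100
individuals (het ≈ 0.385) this gives l = 38.

Genome-wide F_ROH divides each individual's total ROH length by the
autosomal genome length (2399.4 Mb for the goat, the default). Chromosomal
F_ROH instead divides by the SNP-covered length of each chromosome (last
minus first marker). Length classes 0–5 / 5–15 / 15–30 / >30 Mb are
half-open with inclusive lower bounds (the first class is effectively
[1, 5) Mb given the minimum length); all classes share the genome-wide
denominator, so per-class values sum exactly to the genome-wide F_ROH.

F_HOM is the method-of-moments estimate from homozygosity excess,
(O_HOM − E_HOM)/(L − E_HOM), with E_HOM = Σ(1 − 2pq·n/(n−1)) over the
individual's non-missing SNPs. The sign convention deserves a note: the
homozygosity-*excess* form is used, so positive values mean more homozygous
genotypes than Hardy–Weinberg expects — the orientation consistent with the
reported population tables this statistic mirrors (where the population with
lowest observed relative to expected heterozygosity is the most inbred
one); the small-sample factor n/(n−1) can be disabled. Reference
frequencies default to the individual's own population.

## Effective population size from LD decay

Under drift, the expected squared correlation between loci at genetic
distance c Morgans is E(r²) = 1/(1 + 4Nₑc) (Sved), and LD at distance c
reflects the effective size roughly t = 1/(2c) generations ago. The pipeline
computes dosage-correlation r² (the composite estimator — the data are
unphased, and phasing is out of scope) for all intra-chromosomal pairs, bins
pairs by c, subtracts the 1/n finite-sample inflation, inverts Sved's
formula per bin, and maps each bin's mean distance to a time horizon. The
defaults are ~30 logarithmic bins spanning t ≈ 13–1000 generations, at
least 300 pairs per bin, α_model = 1 (drift only, matching the mutation-free
simulator; 2.2 is available for mutation-inclusive modelling), and a uniform
1 cM/Mb map — no genetic map is assumed available, and the rate is
configurable. Bins whose adjusted r² is non-positive are unusable and
dropped. Because binning choices, correction mode and map rate all shift
absolute estimates, published absolute Nₑ values from other datasets are not
reproduction targets; the validation standard is parameter recovery on
simulated truth (below).

## The simulator and what validation does (and does not) show

`simulate_wf` is a discrete-generation diploid Wright–Fisher model: each
offspring draws two distinct parents uniformly (no selfing; effective size
N + 1/2, a negligible distinction at the tolerances used); gametes recombine
as a Poisson process on the uniform genetic map; founder haplotypes are
drawn site-wise (linkage equilibrium) with frequencies uniform on
[0.05, 0.5], mimicking an ascertained array rather than a neutral site
spectrum. There is no mutation, matching α_model = 1. The default genome is
goat-like: 29 autosomes × ~82.7 Mb ≈ 2399.4 Mb, ~1550 SNPs each (~45K
total). `simulate_breeds` splits one ancestral run into isolated populations
drifting apart; `simulate_pedigree` drops gametes through an explicit mating
plan with full origin tracking, so true autozygous segments (both haplotypes
from one founder haplotype) and exact path-counting F are known. Everything
is seed-deterministic.

Validation problem sizes are chosen to make Monte-Carlo noise small relative
to the assertion margins: full-sib cohorts of ≥200 offspring on a 1 Gb /
10k-SNP genome for F_ROH ≈ 0.25 recovery; five replicate constant-N = 100
runs (50 chromosome replicates, 5000 SNPs, 50 sampled, 150 generations so
LD at the probed distances has equilibrated) for Nₑ recovery within ±35%
over t ∈ [10, 50]; a 29-chromosome genome for exact family recovery, where
realized full-sib relationships (sd ≈ 0.02 at 24 Morgans) stay clear of the
0.25 cutoff. What passing these tests shows is that the estimators recover
truth under the model's own assumptions. Real array data differ in ways the
simulator does not emulate: site-frequency ascertainment by breed panels,
genotyping error, non-uniform recombination and SNP spacing, mutation,
migration and selection. Absolute estimates on real data inherit those
caveats — most acutely for LD-Nₑ, whose absolute scale depends on the map
rate assumption.

## Numerical choices and degenerate inputs

Dosage counts the minor-by-observation allele (alphabetical tie-break), so
every statistic is invariant to allele-label swaps — the suite asserts this.
SNPs with no non-missing genotypes get undefined frequencies and are
excluded from denominators; all-monomorphic data make the VanRaden
denominator zero, an error; pairs of individuals sharing no genotyped SNP
get an undefined IBS distance with a warning; chromosomes with fewer than
two SNPs have undefined coverage and are dropped from chromosomal F_ROH.
Correlations of groups with fewer than three members or zero variance are
flagged undefined rather than computed. NJ validates symmetry and
non-negativity before running. The `assess()` wrapper propagates any stage
failure with the stage name attached and flags populations whose most
recent usable Nₑ estimate falls below 100, the conventional sustainability
threshold for livestock populations (configurable).

## Known limitations

Sex chromosomes, multi-allelic markers, phased haplotypes and VCF input are
out of scope. ROH islands and between-population differentiation statistics
(F_ST) are not computed. Model-based ancestry estimation (admixture-style
clustering) is deliberately excluded; the NJ tree, PCA and GRM views cover
the structure questions this package addresses. Confidence intervals for
the Nₑ trajectory (e.g. by chromosome jackknife) are not implemented.
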