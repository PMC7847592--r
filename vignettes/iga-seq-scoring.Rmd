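---
title: "Quantifying taxon-level IgA binding from IgA-Seq experiments"
author: "IgASeqTools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying taxon-level IgA binding from IgA-Seq experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(IgASeqTools)
```

## The problem

IgA-Seq couples flow sorting with amplicon sequencing to ask which members
of an intestinal microbiota are coated by host immunoglobulin A. A stained
community is sorted into an IgA-bound (IgA$^+$) and an unbound (IgA$^-$)
fraction, each fraction is profiled by 16S rRNA gene sequencing, and the
sorted-fraction abundances are combined into a per-taxon binding score.

The difficulty is compositional. Sequencing yields *relative* abundances:
a taxon's abundance in the IgA$^+$ fraction depends not only on how much
of it is bound but on how much of everything else is bound. Two scores in
wide use — here called the Palm index and the Kau index after the studies
that introduced them — are built only from the two fraction abundances,
so a shift in community composition between samples or between study
groups changes scores for taxa whose binding never changed. In
case-control designs, where composition differs between groups by
definition, this manufactures spurious "differential binding".

`IgASeqTools` implements those two indices alongside two posterior-probability
scores that correct for composition, a simulator with known ground-truth
binding for benchmarking all four, the contamination-filtering recipe that
sorted-fraction (low-biomass) amplicon tables need, and exact-permutation
group statistics suited to the small group sizes typical of these
experiments.

## Data model

An experiment is an `IgASeqExperiment`, a `SummarizedExperiment` whose
assays are the taxa-by-sample relative-abundance tables of up to three
entities: the pre-sort community (`presort`), and the `igapos` and
`iganeg` sorted fractions. Per-sample flow-cytometry gate proportions
(`pos_size`, `neg_size`: the fraction of sorted bacteria falling inside
each gate, recorded at the cytometer) and optional group labels live in
`colData`. The constructor aligns inputs to the union of taxa — a taxon
unobserved in a table legitimately has abundance 0 — and the intersection
of samples, since a sample missing a fraction cannot be scored. All
analyses assume columns sum to 1 (tolerance $10^{-6}$, loose enough for
published rounded tables, tight enough to catch real errors);
`normalizeAbundances()` converts counts.

## The four scores

Write $IgA^+_{ij}$, $IgA^-_{ij}$, $PreSort_{ij}$ for taxon $i$'s relative
abundance in sample $j$'s entities, $F^+_j$, $F^-_j$ for the gate
proportions, and $c$ for a pseudo count.

**Palm index** — the ratio of fraction abundances,
$IgA^+_{ij} / IgA^-_{ij}$, with $c$ added to the denominator only when it
is zero (exactly as originally defined; `palmIndex()`).

**Kau index** — the centred log contrast
$$Kau_{ij} = -\frac{\log(IgA^+_{ij}+c) - \log(IgA^-_{ij}+c)}
                   {\log(IgA^+_{ij}+c) + \log(IgA^-_{ij}+c)},$$
positive when the taxon is enriched in the IgA$^+$ fraction. The base of
the logarithm cancels between numerator and denominator; natural logs are
used. The familiar $[-1, 1]$ range is a theorem only while every shifted
abundance $x + c$ stays at or below 1 — guaranteed for any pseudo count
below the smallest nonzero abundance provided no fraction column is a
single-taxon community. In that corner case the raw value (marginally
outside the range) is reported rather than clamped.

**IgA$^+$ probability** — Bayes' theorem applied to the sort. The fraction
abundance is the probability of the taxon *given* the gate; the gate
proportion is the prior probability of the gate; the pre-sort abundance
is the probability of the taxon. The posterior probability that a
bacterium is in the IgA$^+$ gate *given* its taxon is then
$$P^{IgA^+}_{ij} = \frac{IgA^+_{ij}\,F^+_j}{PreSort_{ij}},$$
which is not influenced by the abundances of other taxa. Amplification
and other technical biases can push the numerator above the pre-sort
abundance, so by default the denominator is floored at the numerator
(capping), yielding probability 1 there; the uncapped form is available
(`cap = FALSE`) and then surfaces raw values above 1 rather than silently
capping, because such cells are worth inspecting. The IgA$^-$ probability
is the same construction on the negative fraction.

**Probability ratio** — the two posteriors share $PreSort_{ij}$ as
denominator, so their ratio eliminates it:
$$PR_{ij} = \log_2\frac{IgA^+_{ij}F^+_j + c}{IgA^-_{ij}F^-_j + c},$$
a single centred score covering both directions of binding that needs no
pre-sort sequencing yet still corrects for composition. Because the
attainable range depends on $c$, scores are by default divided by
$\log_2((1+c)/c)$ — the value attained when all sorted bacteria are in
one fraction and one taxon — bounding them in $[-1, 1]$. The scaled form
is the package default throughout.

**Pseudo count.** `defaultPseudoCount()` implements the rule used for all
methods that need one: the largest power of ten strictly below the
smallest nonzero abundance observed in any supplied table. It perturbs
real signal as little as possible while keeping ratios finite; a pseudo
count *above* observed abundances would dominate rare taxa's scores.

**Missing scores.** A taxon with zero abundance in both sorted fractions
carries no information about binding and is scored `NA` — never 0, which
would be a claim of equal binding. Downstream statistics exclude `NA`
pairwise.

## The simulator

`simulateIgASeq()` generates experiments in which the truth is known, at
the scale of a real study: per species a mean binding value
$2^{X}$, $X \sim \mathrm{Exp}(1)$ (the exponentiation spreads species so
communities hold a few strong binders and many weak ones; the values are
arbitrary units of relative binding); per sample a log-normal
($\mu=0,\sigma=1$) pre-sort composition; then 100,000 bacteria per sample
assigned to species multinomially, each drawing an individual binding
value from $\mathcal{N}(\text{species mean}, 1)$. Gates at binding
$> 4$ (IgA$^+$) and $< 2$ (IgA$^-$) cut the tails of the pooled
distribution, as a cytometrist would draw them; they are fixed constants
rather than re-derived per run so ground truth stays comparable across
seeds. Fraction sizes and fraction abundances are computed from the gated
bacteria exactly as in a real run, and the realized (not expected)
multinomial counts define the pre-sort table so all three tables share
one sampling process. The case-control variant adds 0.5 to one species'
pre-sort abundance in the case samples before renormalizing — a pure
composition shift with *no* binding change, so any flagged species is a
false positive by construction.

The simulator reproduces sampling noise, gating, and compositionality. It
deliberately does not model sequencing error, PCR/primer bias, 16S
copy-number variation, or sort impurity; a score that passes these
benchmarks is necessary, not sufficient, for correctness on real data.
One RNG stream drives means, then compositions, then binding draws, so a
seed reproduces an experiment bit for bit. Empty gated fractions
(possible at small `nBacteria`) are kept as flagged all-zero columns
rather than dropped, so benchmark denominators stay honest.

## Benchmarks the package tests itself against

The test suite regenerates, per run, ten default simulations
(10 species × 30 samples × 100,000 bacteria) and ten case-control
simulations (30 + 30 samples), sizes chosen to match the simulated study
design while keeping a full test run in well under a minute of
simulation time. On these it checks: that per-species median scores rank
species by true binding (Spearman); that the probability ratio's
per-species absolute coefficient of variation — the meaningful dispersion
measure when methods differ in scale and sign — is below the Palm and Kau
indices' for nearly all species; that the Kau index flags the boosted
species in the case-control design while the probability ratio flags
(almost always) none; and that the posterior probability recovers
analytically constructed per-taxon binding probabilities exactly
($10^{-12}$), independent of composition. Every score formula is also
checked cell-by-cell against an independent brute-force evaluation on
randomized small experiments.

Two honest caveats surfaced by these benchmarks. First, a perfect
(Spearman $\rho = 1$) ranking is not attainable in every random draw of
species means: the exponential draw regularly produces species whose true
means differ by less than ~0.05, i.e. gate probabilities differing by
~$3\times10^{-5}$, which is below multinomial resolution at $10^5$
bacteria — no score can rank such pairs, and misrankings in practice are
confined to them. Second, the probability ratio is not perfectly immune
to composition shifts: for rare taxa the pseudo count dominates the
posterior numerators, shrinking scores toward 0 by an abundance-dependent
amount, so large cohorts can detect small spurious shifts in rare taxa.
Both behaviours are properties of the methods, not of this
implementation.

## Filtering sorted-fraction tables

Sorted fractions are low-biomass samples, so reagent contaminants that
are negligible pre-sort can dominate a fraction. The recipe, applied in
order by `runFilter()` or step-wise:

1. `removeBlankTaxa()` — drop taxa observed in a no-template extraction /
   library blank, everywhere.
2. `filterMinAbundance()` — zero cells below an abundance threshold, drop
   taxa that become all-zero, renormalize. The threshold is chosen by a
   human from `thresholdReport()`, which tabulates taxa and observation
   mass surviving each candidate — the aim is removing rare contaminants
   while retaining the large majority of total observations. Zeroing is
   per cell because fraction contamination is sample-wise: a contaminant
   can be predominant in one sample's fraction and absent elsewhere.
3. `screenAgainstPresort()` — per sample, zero fraction abundances of
   taxa absent from that sample's own pre-sort community (fractions are
   subsets of it), then renormalize the fraction columns.

Tables are renormalized after every step, because the scores assume
relative abundances summing to 1, and every step returns a `FilterReport`
so the analysis remains auditable. Each step is idempotent and commutes
with row/column reordering.

## Group comparisons

With three or four animals per group, asymptotic tests are not
trustworthy, so `exactPermutationTest()` enumerates all
$\binom{n_1+n_2}{n_1}$ assignments of group labels and reports the exact
proportion whose group-mean difference reaches the observed one. The
observed assignment is included, so $p$ is never 0, and ties count as
reaching the observed statistic (assessed with a relative tolerance of
$10^{-8}$ so float noise cannot split exact ties). The default statistic
is the two-sided $|\Delta\text{mean}|$; one-sided alternatives are
available. Note the granularity: at 3 vs 3 the smallest two-sided $p$ is
$2/20 = 0.1$, so significance thresholds must respect the attainable
set. Taxa with fewer than `minPerGroup` (default 3) scored samples per
group are flagged untested rather than tested badly, and
Benjamini–Hochberg adjustment (via `p.adjust`) runs over tested taxa
only. Effect sizes use the strictly standardised mean difference
$(\mu_1-\mu_2)/\sqrt{\sigma_1^2+\sigma_2^2}$, which is comparable across
scores on different scales; its degenerate cases are defined explicitly
(0 for identical constant groups, signed infinity with a warning for
constant groups at different values, `NA` when a variance is
inestimable).

## A worked example

```{r example}
set.seed(7)
sim <- simulateIgASeq(nSamples = 12, nBacteria = 20000)
x <- experiment(sim)
x
pr <- igaScore(x, "prob_ratio")
pr
head(round(scores(pr)[, 1:4], 3))
# species with higher true binding score higher
cor(apply(scores(pr), 1, median), trueBindingMeans(sim),
    method = "spearman")
```

## Choosing a score

The probability ratio is the recommended default: it corrects for
composition, covers both binding directions, and needs only the two
fraction tables plus the two gate proportions (no pre-sort sequencing).
The IgA$^+$ probability is preferred when only the positive fraction was
sequenced and interest is in strongly bound taxa; it requires the
pre-sort table. The Palm and Kau indices are provided for comparability
with the existing literature; within a single homogeneous cohort they
rank taxa adequately, but between-group comparisons on them conflate
composition with binding. All scores quantify *relative* binding within a
sample — none estimates absolute IgA affinity or per-cell coating.
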