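---
title: "Relatedness from forced-homozygote genotypes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relatedness from forced-homozygote genotypes: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(pseudokin)
```

## The problem

Shotgun sequencing of degraded skeletal material — ancient remains,
historical forensic cases — routinely yields genome coverages of 0.04–0.1X.
At that depth almost every SNP that is covered at all is covered by a single
read, so heterozygotes cannot be observed: a naive diploid genotype call
would be homozygous at essentially every locus, and the apparent excess
homozygosity would wreck any relatedness estimator that models diploid
genotypes. Likelihood-based tools designed for modern data need orders of
magnitude more loci than such samples provide.

`pseudokin` implements the *forced homozygote* (pseudo-haploid) strategy:
embrace the limitation instead of fighting it. Every locus in **every**
individual — including well-covered modern relatives — is reduced to a
single allele: one randomly selected read with phred quality ≥ 30 for
sequencing data, or one randomly deleted allele for diploid genotypes. The
reduced data are internally consistent (all loci homozygous in all
individuals), and their statistical behaviour is exactly characterizable by
simulation.

## The estimator

For two individuals x and y genotyped at shared biallelic loci with
*external* reference allele frequencies, the symmetric Queller–Goodnight
relatedness estimator is a ratio of sums over loci. Writing x = (a, b),
y = (c, d) and p for the reference frequency of a carried allele, the focal-x
terms at one locus are

$$
\mathrm{num}_x = \tfrac12\big(\mathbb{1}_{a=c} + \mathbb{1}_{a=d} +
\mathbb{1}_{b=c} + \mathbb{1}_{b=d}\big) - p_a - p_b,
\qquad
\mathrm{den}_x = 1 + \mathbb{1}_{a=b} - p_a - p_b,
$$

and the symmetric estimator is
$R_{xy} = (\sum \mathrm{num}_x + \sum \mathrm{num}_y) /
(\sum \mathrm{den}_x + \sum \mathrm{den}_y)$, summing across loci before
dividing (a mean of per-locus ratios is a different, worse-behaved
statistic; a test asserts the two disagree on crafted input). Under forced
homozygosity (a = b, c = d) both focal terms coincide and the per-locus
contributions reduce to $2\,\mathbb{1}_{a=c} - p_a - p_c$ over
$2 - p_a - p_c$; `rxy_forced()` implements this fast path and
`rxy_general()` the full diploid form, and the two agree exactly (to
floating-point) on duplicated-allele input. At a biallelic locus a
heterozygous focal individual has $p_a + p_b = 1$ and contributes zero to
both sums, which is why the general form skips and counts such
"uninformative" loci rather than erroring.

Because only one allele per locus is interrogated, pseudo-haploid data see
half of each genome: the expectation of $R_{xy}$ is halved, from 0.5 to
0.25 for first-order pairs (parent–offspring, full siblings) and from 0.25
to 0.125 for second-order pairs (half siblings, avuncular). Estimates are
reported raw — negative values are legitimate sampling outcomes for
unrelated pairs and are never clamped.

Reference frequencies are used exactly as supplied (a 1000-Genomes-style
external panel read from `.frq`); there is no within-sample re-estimation
and no bias correction, matching how the estimator is used in practice with
an external frequency file.

## Calibration by simulation

An observed coefficient means little without the sampling distribution it
came from, which depends on the exact set of shared loci and their
frequencies. `simulate_rxy_distribution()` builds that distribution for a
relatedness class on a given panel:

* founders are drawn locus-wise in Hardy–Weinberg proportions from the
  panel frequencies;
* relatives are produced by Mendelian gene-dropping (one uniformly chosen
  allele from each parent, independently across loci);
* first order is simulated as full siblings (two offspring of the same
  founder pair; `first_order = "parent_offspring"` gives the
  same-expectation, lower-variance alternative), second order as half
  siblings sharing one founder;
* the final dyad members — and only they — are forced pseudo-haploid, then
  scored with `rxy_forced()` against the generating frequencies.

Forcing only the final dyad members (rather than forcing founders before
breeding) is a deliberate design choice: it reproduces the halved
expectations that make the forced coefficients interpretable, and mirrors
what happens to real data, where forcing is applied to the observed
individuals. Pedigrees themselves are fully diploid.

With 2000 dyads per class (the default) on panels of a few thousand loci,
the class means recover 0 / 0.25 / 0.125 (forced) and 0.5 (diploid full
siblings) to within Monte-Carlo error, and the spread shrinks roughly as
$1/\sqrt{n_\mathrm{loci}}$:

```{r calibration}
frq <- simulate_frq_panel(1000)
glance(simulate_rxy_distribution(frq, "first_order", n_dyads = 300, seed = 1))
glance(simulate_rxy_distribution(frq, "second_order", n_dyads = 300, seed = 2))
```

## Trio hypothesis testing

For three individuals A, B, C there are eleven canonical hypotheses
combining Unrelated, Parent/Full Sibling (first order) and Uncle/Half
Sibling (second order) across the three dyads; `default_hypotheses()`
enumerates them. Named relationships that share a class are
likelihood-equivalent for a single dyad but are kept as distinct rows, so
the report reads in pedigree terms.

Each dyad gets its own empirical distributions — its shared-locus panel
differs, so nine simulated data sets back a trio test. Each distribution is
summarised by a normal fit: `fit_normal()` uses the sample mean and the
maximum-likelihood standard deviation (divisor n; at n = 2000 the
difference from the unbiased divisor is far below Monte-Carlo noise), with
a floor of `sigma_floor = 1e-6` so degenerate samples still yield a proper
density. The log-likelihood of a hypothesis is the sum over dyads of the
log normal density of the observed coefficient under the assigned class;
densities can exceed 1, so positive log-likelihoods are normal. Posteriors
use a flat prior by default (a `prior` argument accepts weights) and are
normalized through log-sum-exp, making them invariant to shifting all
log-likelihoods by a constant. `odds_ratio()` compares summed posteriors of
disjoint hypothesis subsets and flags a zero denominator as divergent
rather than erroring.

## Synthetic data: what it does and does not emulate

`simulate_frq_panel()` emulates an ascertained common-SNP panel: loci
`rs1..rsN` with random distinct allele pairs and minor-allele frequency
uniform on (0.05, 0.5) by default — a reasonable proxy for a genotyping
array's frequency spectrum; real panel frequencies can always be supplied
via `read_frq()`. `simulate_trio_pileups()` emulates the low-coverage
regime: per-locus, per-individual Bernoulli coverage (at mean depths of
0.04–0.1X a Poisson depth model leaves almost only 0/1 depths, so a
Bernoulli hit with matching probability is the simplest faithful
reduction), mostly single reads with an occasional second read to exercise
random read selection, and a small fraction of sub-threshold qualities.
Supported trio structures are the pedigree-consistent ones the package
tests end to end: `avuncular` (A is the sibling of B and C's parent —
second/second/first order), `siblings`, and `unrelated`.

The generator deliberately does **not** emulate: linkage between loci (the
intended panels are genome-wide and sparse, making LD negligible at these
counts), inbreeding, population structure or frequency misspecification,
post-mortem damage (C→T/G→A) or sequencing error in read bases, and strand
ambiguity. Passing tests therefore demonstrate correctness of the estimator
and of the calibration machinery under the stated model — not robustness to
damaged bases or to a mismatched reference population. Two practical risks
are documented rather than modelled: strand-ambiguous A/T and C/G SNPs are
*not* excluded by default (mismatching alleles are excluded, never
complemented), and no transition-SNP filter is applied; both can matter for
real degraded data and can be handled upstream by filtering the panel.

## Numerical and interface choices

* "Phred quality above 30" is implemented inclusively (≥ 30) and exposed as
  `min_qual`.
* Randomness uses R's global RNG stream: `set.seed()` before a pipeline (or
  the `seed` arguments / `--seed` flags) makes runs bit-reproducible.
  `force_pileup()` consumes the stream one site at a time in file order, so
  a run can be replayed call-by-call with `force_site()`.
* Loci are excluded — with per-reason counts on the dyad object — when
  uncalled in either individual, absent from the panel, monomorphic
  (frequency not strictly inside (0, 1)), or carrying an off-panel allele;
  nothing is imputed or recoded.
* An empty intersection is an error ("no shared loci"), as is a
  non-positive estimator denominator.
* Default simulation sizes follow the study conditions the package
  calibrates against: 2000 dyads per class; the worked analyses use panels
  of 1328–3480 loci, the shared-SNP counts of the motivating case. Tests
  use smaller panels (hundreds of loci, hundreds of dyads) chosen to keep
  the statistical assertions sharp at 3–4 standard errors.

## Known limitations

The normal summary of the empirical distributions is an approximation; it
is excellent at thousands of loci but thins out in the far tails, exactly
where extreme posterior claims live — posteriors like $1 - 8\times10^{-7}$
should be read as "overwhelming", not as literal seven-digit probabilities.
The hypothesis set covers three individuals; larger pedigrees are out of
scope. Frequencies are trusted as supplied: a mismatched reference
population biases all coefficients, and no diagnostic for that is built in.
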