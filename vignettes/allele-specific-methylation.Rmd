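---
title: "Allele-specific D4Z4 methylation from bisulfite clone sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific D4Z4 methylation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Contraction of the D4Z4 macrosatellite array at 4q35 on a permissive 4qA
haplotype causes facioscapulohumeral muscular dystrophy (FSHD1), and the
contracted allele is characteristically hypomethylated. Bisulfite sequencing
of cloned PCR amplicons (BSS) reads out CpG methylation of the distal D4Z4
repeat one chromosome molecule at a time: each sequenced clone is a single
amplified molecule, so a heterozygous 4qA/4qA sample yields a roughly 50/50
mixture of clones from the two alleles. Average methylation across all
clones can then mask hypomethylation of the contracted allele behind high
methylation of the non-contracted one. This package estimates methylation
for *just the less-methylated allele*, and compares it across disease
classes (FSHD-affected, nonmanifesting carriers, healthy controls) in
family-structured cohorts.

The pipeline has three stages, each usable on its own:

1. **Methylation calling** (`call_sample()`): clone sequences against an
   assay reference, yielding per-clone CpG call vectors with QC filters.
2. **Allele mixture model** (`fit_alleles()` / `sample_posterior()`): a
   Bayesian two-component beta-binomial mixture over per-clone methylated
   counts.
3. **Cohort statistics** (`cohort_compare()`, `sign_test()`): logit-scale
   mixed-effects comparison of disease classes, and an exact paired sign
   test for familial manifesting/nonmanifesting pairs.

A synthetic-data generator (`simulate_counts()`,
`simulate_clone_sequences()`, `simulate_cohort()`) stands in for clone
sequences that were never deposited; every stage is tested against data it
generates.

## Methylation calling

Bisulfite treatment converts unmethylated C to T while 5-methylcytosine is
protected. `bisulfite_convert_reference()` therefore turns the reference
amplicon into an expected-read template with every non-CpG C as `T` and
every CpG C as the ambiguity code `Y`. Clone reads are aligned end-to-end
against this template (`align_clone()`, via `Biostrings::pairwiseAlignment`)
with match +1, mismatch −2, and affine gaps costing 5 + 1 per base; a read C
or T opposite `Y` scores as a match (methylated/unmethylated). Both the
given orientation and the reverse complement are tried and the better one
kept, so calling is orientation-invariant. At each reference CpG the aligned
read base gives the call: C → `METH`, T → `UNMETH`, anything else (gap,
N, other base) → `MISSING`.

Three QC filters mirror the published assay's specificity rules, in order
of precedence:

* **`HOMOLOG`** — any mismatch at a homolog-diagnostic position (positions
  whose base distinguishes 4q from non-4q/10q D4Z4 homologs). If no
  diagnostic annotation is supplied the filter degrades to identity
  filtering only.
* **`LOW_IDENTITY`** — bisulfite-aware identity below 0.98. Identity counts
  bisulfite-expected substitutions (T or C opposite `Y`; the deterministic
  non-CpG C→T conversions are already in the template) as matches, and
  excludes gap-only columns at the ends (primer-trimming tolerance).
  Whether the original BISMA tool computed identity before or after
  bisulfite-aware matching is not documented; we adopt the bisulfite-aware
  version, since raw identity of a bisulfite read against an unconverted
  reference would be far below 98% for any clone.
* **`TOO_MANY_MISSING`** — more than 3 missing CpG calls. One to three
  missing sites per clone are routinely observed and tolerated; the
  assayable site count N is decreased accordingly downstream.

Coordinates are 1-based in R objects and outputs (CpG columns are numbered
1..56 left to right, as in the published figures); BED annotation is
converted from 0-based half-open on input.

## The allele mixture model

For clone *j* of allele *i*, the methylated-CpG count is beta-binomial:
a per-clone methylation probability $p_{ij} \sim \mathrm{Beta}(a_i, b_i)$
and $m_j \mid p_{ij} \sim \mathrm{Binomial}(N_j, p_{ij})$. Clone counts are
strongly overdispersed relative to the binomial — typically around 4× the
binomial variance at the same mean (`overdispersion_ratio()` measures this;
the theoretical beta-binomial inflation is $1 + (N-1)/(s+1)$). Only the
total count is modelled, not site-specific probabilities.

The model is parameterized by $r_i = \log(a_i/b_i)$ (the logit of the mean
methylation fraction $\mu_i = a_i/(a_i+b_i)$) and $s_i = a_i + b_i$
(inverse overdispersion). Writing $\bar r = (r_1 + r_2)/2$ and
$d = r_2 - r_1 \ge 0$ (allele 1 is the less methylated — note the ordering
is imposed through $d \ge 0$), the priors are

* $\bar r \sim N(0, \sigma = 2)$,
* $d$: spike-and-slab — a point mass of 0.5 at $d = 0$ (so 4qA/4qB and
  unknown genotypes are handled by the same model) and a
  $\mathrm{Gamma}(k = 1, \mathrm{rate} = 0.5)$ slab for $d > 0$,
* $s_1, s_2 \sim \mathrm{Gamma}(k = 1, \mathrm{rate} = 0.025)$,
* each clone belongs to either allele with fixed probability 0.5 (no
  learned mixture weight: each allele is equally likely to be amplified).

The gamma $\beta$ parameters are read as **rates** (prior means
$s = 40$, $d = 2$); the scale reading would put the prior mean of $s$ at
0.025, i.e. absurdly overdispersed. The posterior probability that
$d > 0$ is reported as the evidence for allele-specific methylation.

### Sampler

`sample_posterior()` runs Metropolis-within-Gibbs (C++ via Rcpp): Gibbs
draws of the clone indicators given parameters; random-walk Metropolis on
$\bar r$, $\log s_1$, $\log s_2$; and for the spike, jump moves between
$d = 0$ and $d > 0$ that propose from the slab prior (so the gamma densities
cancel and the acceptance ratio reduces to a likelihood ratio times the
mass ratio), plus a log-scale random walk on $d$ within the slab. Proposal
scales adapt toward ~44% acceptance during burn-in only, preserving
detailed balance afterwards. Defaults follow the published schedule: 3
chains, 1,000 burn-in + 30,000 inference iterations, convergence requiring
Gelman–Rubin PSRF < 1.01 on $\bar r$, $d$, $s_1$, $s_2$. On
non-convergence the run is re-done with doubled length up to 3 times, then
returned with `converged = FALSE` and a warning. Given a seed, results are
bit-reproducible. Allele means are reported as the posterior mean of
$100\,\mathrm{expit}(r_i)$ averaged over draws (not the expit of the mean),
the correct posterior expectation of the mean methylation fraction.

### Independent oracle

`grid_oracle_posterior()` recomputes posterior expectations for small
datasets by deterministic quadrature, with the $d = 0$ spike as a separate
mixture branch. Because the clone indicators are independent given the
parameters (fixed 0.5 mixing), the sum over all $2^n$ assignments equals
the product over clones of the two-component mixture pmf, so the
"enumeration" is carried out exactly in closed form. The remaining
integral over $(\bar r, d, s_1, s_2)$ uses trapezoidal quadrature:
$\bar r$ and $d/2$ share one logit-scale lattice (spacing 0.16) so the
allele logits land on precomputed nodes, and $s_1, s_2$ use 33 log-spaced
nodes on [0.1, 400]. The test suite checks the MCMC against this oracle on
six-clone datasets to within 3 Monte-Carlo standard errors (batch-means
MCSE, pooled over chains).

### Mono-allelic model and Q1

`fit_monoallelic()` fits a single beta-binomial with $r \sim N(0,2)$,
$s \sim \mathrm{Gamma}(1, 0.025)$, reported alongside the mixture. The
`q1_score()` is the lower quartile of per-clone percent methylation — a
quick non-model proxy for the lower allele, computed with the type-7
(interpolating, $(j-1)/(n-1)$) convention; the convention is configurable
since the original choice is undocumented.

### Spike-and-slab behaviour on mono-allelic data

A caution established with the quadrature oracle: for realistic
overdispersion (e.g. 50 clones at $\mu = 0.7$, $s = 15$, $N = 56$), the
*exact* posterior leaves substantial mass in the slab — $P(d>0)$ is
typically 0.2–0.4 but exceeds 0.5 in roughly a third of simulated
mono-allelic datasets, and the two reported allele means then separate by
several points. This is not a sampler artifact (the MCMC matches the
oracle to within Monte-Carlo error); it is a property of the prior: the
gamma(1, 0.5) slab keeps ~22% of its mass below $d = 0.5$, where the
likelihood cannot distinguish the two components, so the Bayes factor for
the spike is bounded. The average of the two allele estimates remains an
excellent estimate of the single allele (it tracks the mono-allelic fit to
within ~0.1–0.5 points), and $P(d>0)$ should be interpreted as graded
evidence, not a detector with a guaranteed false-positive rate.

### Degenerate inputs

Zero clones is an error; fewer than 5 passing clones sets a
`low_confidence` flag. Allele means of exactly 0 or 1 in the generator are
clipped to $(10^{-4}, 1-10^{-4})$. The overdispersion diagnostic uses only
clones at the common (maximal) N, since mixing unequal N has no clean
binomial reference variance, and needs at least two of them.

## Cohort statistics

Per sample and assay, the analysis value is $y$, the posterior mean logit
($r$) of the lesser allele; when both the 4qA and 4qA-L assays were run,
the assay with the smaller $y$ is chosen and recorded
(`select_lower_allele()`). The logit scale avoids compression near 0% and
100%; reports back-transform with $100\,\mathrm{expit}(\cdot)$, which makes
the ±SE intervals asymmetric on the percent scale (`group_report()`).

`fit_lme()` fits, by **maximum likelihood** (not REML, because
likelihood-ratio tests compare fixed-effect structures),

$$ y \sim 0 + \text{cell type} \times \text{disease class} + \text{assay} + (1 \mid \text{family}) $$

with disease classes Control, NonMfst (nonmanifesting carriers), FSHD(b)
(affected with a nonmanifesting first-degree relative in the cohort) and
FSHD(a) (affected without one). The assay effect is additive only — the
4qA and 4qA-L assays interrogate different CpG sets with different baseline
methylation, and there is too little 4qA-L data to support interactions.
`lrt()` compares the full model with models collapsing two disease classes
(or the two cell types): statistic $2\Delta\ell$, chi-squared reference.
Each sample contributes one row (its lesser allele); optimizer noise that
would make the statistic negative triggers a refit and truncation at zero.

`sign_test()` is the exact two-sided paired test over family cohorts:
count families where the nonmanifesting member is more methylated than the
manifesting one, $p = \min(1,\, 2\sum_{k \ge \max(n_+, n-n_+)}
\binom{n}{k} 2^{-n})$. Where a family has two members on one side, every
choice of which to include is evaluated; ties are excluded from $n$. On the
packaged nine-cohort table, every choice gives 9/9 and
$p = 2 \cdot 2^{-9} = 0.00390625$.

`ru_from_fragment()` converts an EcoRI/BlnI fragment to D4Z4 repeat units,
$(kb - 2)/3.3$, rounded to the nearest half unit (ties up). The
half-unit rounding is inferred from the published genotyping table (30 kb →
8.5 but 29 kb → 8); the raw formula alone never yields half-integers.

## What the synthetic generator does and does not emulate

`simulate_counts()` mirrors the fitted model exactly (beta-binomial draws
per allele, 50/50 allele sampling, ≤3 missing sites per clone), so
parameter-recovery tests validate inference, not model adequacy.
`simulate_clone_sequences()` renders states into bisulfite-converted
sequences with iid substitution errors, missing sites as destroyed CpGs,
homolog contaminants carrying 5 diagnostic-position changes (echoing the
handful of 4q/10q sequence differences), and random read orientations. It
does not emulate chromatogram noise, PCR bias, chimeras or indel errors.
`simulate_cohort()` reproduces the published study layout (9
affected+nonmanifesting families: 4 myocyte, 5 blood; 11 affected+control
families: 8 myocyte, 3 blood; one cell type per family) with defaults at
published-scale group means (Control 71%, NonMfst 25%, affected 7% — the
published estimates), no cell-type effect (the published myocyte/blood
difference was not significant), a +0.5 logit 4qA-L offset, and family and
residual SDs of 0.5 on the logit scale (chosen once as a realistic
between-family spread; the published study reports no variance components). A green
cohort test therefore establishes correct inference under the model's own
assumptions at the study's size, not robustness to model misspecification.

Synthetic reference fixtures (`synthetic_reference()`) have the correct CpG
counts (56/30/59) and QC structure but are otherwise random sequences; real
4qA/4qA-L/DUX4-5′ references are external and can be supplied as FASTA +
BED.

## Known limitations

* The published per-sample estimates and real-data LRT p-values cannot be
  reproduced: the underlying clone sequences are not deposited. The
  packaged familial table (percent methylation, fragment sizes, repeat
  units) is the only real data shipped.
* The spike-and-slab posterior is prior-sensitive (see above); users
  testing for allele-specific methylation should treat $P(d>0)$
  accordingly, and can tighten or loosen `zero_mass` and `d_rate` in
  `mixture_prior()`.
* The quadrature oracle is limited to ≤12 clones by contract (it is meant
  for validation, not analysis).
* Identity filtering assumes substitution-dominated Sanger error; heavy
  indel error would depress identity through gap columns in ways the 0.98
  threshold was not calibrated for.
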