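---
title: "Methods: diversity, neutrality and domestication-selection screening of small RNA loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, neutrality and domestication-selection screening of small RNA loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapop)
```

## The problem

Plant miRNAs and other endogenous small RNAs regulate many developmental
and stress-response genes, and crop domestication is a strong, recent
episode of artificial selection. `srnapop` implements a resequencing-style
survey of sequence variation at small-RNA loci in domesticated rice
(*Oryza sativa*, the independently domesticated indica and japonica
subgroups), its wild progenitor (*O. rufipogon*) and an outgroup
(*O. barthii*): per-locus and per-region nucleotide diversity, neutrality
testing, and a screen for loci whose variation pattern suggests selection
during domestication. A coalescent generator produces complete synthetic
panels with the same structure, so the entire pipeline is testable without
any sequence download.

Inputs are one aligned FASTA per locus (all sequences the same length), a
panel table assigning each accession to a population
(cultivated/wild/outgroup) and subgroup (indica/japonica/none), and a
BED-like annotation table of functional regions (mature miRNA, precursor,
flanks, ta-siRNA phases, miR390 binding sites) with a locus class and a
conservation class.

## Core alignments and coordinates

Every statistic operates on the *core alignment*: the subset of columns at
which every analysed sequence carries an unambiguous base. Both `-` and
`N` count as missing, and a column containing either in any retained
sequence is dropped. Because each analysis re-extracts the core on its own
accession subset (indica-only, japonica-only, wild-only, or
ingroup+outgroup), the usable length `L` legitimately differs between
analyses of the same locus.

Annotation files use the BED convention (0-based, half-open); internally
the package uses R's native 1-based closed intervals, and report files
print 1-based inclusive coordinates. Indels never enter the diversity
statistics: a maximal run of gap-containing columns is catalogued as one
indel event for the mutation catalogue and otherwise ignored, which
matches defining diversity on gap-free core sites.

## Diversity estimators

For `n` sequences with `S` segregating sites on `L` core sites:

* Watterson's estimator, per locus: `theta_W = S / a1(n)` with
  `a1(n) = sum_{i=1}^{n-1} 1/i`.
* Pairwise diversity, per locus: `pi = k-hat`, the mean count of differing
  sites over all `n(n-1)/2` unordered pairs, computed from per-column
  allele counts (algebraically identical to the explicit pairwise
  recount, which the test suite verifies exactly). No `n/(n-1)` sample
  correction is applied — `pi` is the plain mean over pairs.
* Per-site values divide by `L`; SNP density is `1000 * S / L`.

A column with three or four alleles counts as one segregating site.
Aggregation across loci reports the mean and the standard error of the
mean; a single-locus group is assigned SEM 0 so report tables stay total.

## Tajima's D and its fixed-S significance

`D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the 1989 coefficient
set. Two degeneracies are handled explicitly: `S = 0` leaves D undefined,
and at `n = 3` the variance coefficients are exactly zero because `pi` is
then identically `S/a1` — D is undefined there too.

Significance is assessed by simulation conditional on the observed number
of segregating sites (the fixed-S null): each replicate draws a neutral
coalescent genealogy and places exactly `S` mutations multinomially by
branch length; the two-tailed p-value is the add-one rank
`p = (1 + #{|D_sim| >= |D_obs|}) / (n_reps + 1)`. The null depends only on
`(n, S)`, so null tables are cached and shared across loci within a run
(they are drawn from one seeded stream). Default 10,000 replicates;
the suite verifies that the test's empirical size at `alpha = 0.05` lies
near the nominal level on neutral data. The beta-distribution
approximation sometimes used for D is avoided: the simulation null is
self-consistent and testable.

## The multi-locus HKA test

The HKA test asks whether within-species polymorphism and between-species
divergence are proportional across loci, as neutrality predicts. We use
the reduced formulation with one species' polymorphism plus net divergence
to a single outgroup lineage (the two sequenced outgroup accessions are
averaged; no outgroup-polymorphism term and no multiple-hit correction).
Both `S` and the divergence `D` are measured on the shared
ingroup-plus-outgroup core, so one length `L_i` underlies both counts at
each locus.

With `theta_i` the per-locus population mutation rate and `T` the
divergence time in units of `2N` generations (ancestral population equal
in size to the current one):

```
E[S_i] = theta_i a1(n_i)      Var[S_i] = E[S_i] + theta_i^2 a2(n_i)
E[D_i] = theta_i (T + 1)      Var[D_i] = E[D_i] + theta_i^2
```

Method-of-moments estimation enforces `sum E[S_i] = sum S_i` and
reproduces every per-locus total `S_i + D_i` exactly, leaving one
monotone equation in `T`; it is solved in closed form when all loci share
one sample size and by bisection (tolerance `1e-10`) otherwise. The
statistic is `X2 = sum_i (S_i - E[S_i])^2/Var[S_i] +
(D_i - E[D_i])^2/Var[D_i]`; the saturated one-locus fit gives `X2 = 0`
exactly. Boundary datasets (all-zero polymorphism or all-zero divergence)
are perfect fits in the limit (`T` to its boundary) and are assigned
`X2 = 0`.

Each candidate locus is tested together with the neutral reference loci
(one test per candidate, which is what yields one p-value per locus and
population). Significance comes from parametric simulation at the fitted
parameters: per locus, a structured genealogy (ingroup lineages to the
split at `T`, then joined by the outgroup lineage) receives Poisson
mutations at rate `theta_i`, and the model is re-estimated on every
simulated dataset; `p = (1 + #{X2_sim >= X2_obs}) / (n_sim + 1)`. Loci
are ordered canonically before simulation so the p-value cannot depend on
how the references were passed. Default 10,000 simulations. The suite
verifies the empirical size at `alpha = 0.05` on jointly neutral 5-locus
data.

An important, deliberate limitation: the null model assumes a
constant-size ingroup population. Under the domestication bottleneck the
across-locus dispersion of `S` exceeds the equilibrium expectation and
the test becomes anti-conservative (we measure roughly a five-fold
inflation of the rejection rate at the default bottleneck). This is the
classic demography/selection confounding that diversity-based screens
cannot escape and is why the end-to-end recovery experiment below is run
on an equilibrium background.

## The selection screen

A population shows a *positive-selection signal* when its Tajima's D is
significantly **negative** (a significantly positive D indicates
balancing selection and is not counted) or its HKA p-value is below
`alpha`. A locus is a `Putative` domestication candidate when at least one
cultivated subgroup shows a signal and the wild population shows none
(the wild column uses the same two tests); otherwise `ND`, or `NA` when
both cultivated subgroups are untestable. Missing individual tests count
as no-signal for that test only.

Independently of the classification, the fold-reduction screen reports
`pi_wild / pi_cultivated` per subgroup against a baseline equal to the
maximum fold reduction among the neutral reference loci; the two lines of
evidence are printed side by side and never conjoined, since a locus can
be a credible candidate on test signals without exceeding the
fold baseline. `alpha = 0.05` throughout, with no multiple-testing
correction — the output header notes this.

## The synthetic-data generator

The generator emulates the resequencing study design, and its defaults
are the study conditions: ~600 bp loci; 17 indica + 16 japonica cultivated
samples, 15 wild, 2 outgroup; a 21-nt mature miRNA centred in a 120-nt
precursor with flanking regions; per-region mutation-rate multipliers
(0.3 mature, 0.6 precursor, 1.0 flanks) expressing the purifying
selection gradient the survey observes; wild per-site
`theta = 0.01` (within the range reported for *O. rufipogon* nuclear
loci); a cultivated bottleneck (relative size 0.1 for 0.05 x 2N
generations ending at the split, 0.1 x 2N ago) that reduces cultivated
diversity by a factor broadly compatible with the up-to-2.6-fold
reductions seen at neutral rice genes; and an outgroup joining at
`T = 5`. Time is in units of `2N` generations throughout; no
calendar-year conversion is attempted.

Mutations are infinite-sites events mapped onto finite sequences by
sampling distinct positions (probability proportional to the per-site
multipliers; substitution base uniform among the three alternatives), so
every simulated SNP is biallelic. If the Poisson draw exceeds 10% of the
sites the generator warns about saturation, and truncates at `L`.
Sequences are emitted already aligned; an optional indel rate adds short
deletions purely to exercise the core-alignment logic. One mandatory
global seed drives everything; child seeds are derived deterministically
per locus and per operation, so reruns are bit-identical.

The sweep injector replaces one locus' cultivated genealogy with a
star-like (post-sweep) genealogy. By default the sweep has just completed
(`sweep_time = 0`): cultivated polymorphism is zero and the detectable
signal is the HKA diversity deficit. A positive `sweep_time` lets
variants accumulate since the sweep (singleton excess, negative D); in
our measurements this trades away more HKA power than it gains in D
power, which is why the star proper is the default.

What the generator does **not** emulate: recombination and gene
conversion (conservative for ~600 bp loci), real base composition and
mutation-spectrum biases, sequencing or alignment error, heterozygous
wild clones (each sequence is one haplotype), population structure within
subgroups, and selection modelled forward in time (the star genealogy is
a proxy). Passing tests therefore demonstrate the statistical machinery
under the stated model, not robustness to everything real data can do.

## Numerical and design choices

* Fixed-S and HKA p-values use add-one counts, so `p` is never 0 and the
  tests are (very slightly) conservative at simulation resolution.
* The HKA moment fit uses the closed form whenever all sample sizes
  agree, otherwise monotone bisection; convergence tolerance `1e-10`.
* Degenerate inputs are defined, not fatal: empty cores flag their
  statistics `NA`; `S = 0` loci have undefined D and are never
  significant; all-zero HKA totals are an error, one-sided zero totals a
  perfect fit.
* The recovery experiment (one injected sweep among four neutral
  references) runs on an equilibrium background, because under the
  bottleneck the HKA false-positive rate is dominated by demography (see
  above) and the experiment would measure the confounding rather than the
  recovery.
* Problem sizes used by the shipped checks were chosen to keep a full run
  at desk scale: 2,000 neutral loci for estimator calibration (with
  2,000-replicate cached fixed-S null tables), 400 datasets x 250
  simulations for HKA size, 100 replicate panels for sweep recovery, and
  200 loci for the region-stratification contrast.
* The headline quantities of the original survey (mature-miRNA `pi` of
  0.00169, 1.52 SNPs per kb, 12.5% of MIRNAs with mature-sequence
  variants, the MIR399d indica D of -2.37, the 7.0-fold MIR390
  reduction) require the deposited GenBank sequence sets
  (GQ418390-GQ420345, HM138917-HM140183) regrouped into per-locus
  alignments; they are recorded by `download_gated_targets()` with
  `desk_scale = FALSE` rather than recomputed.

## Known limitations

Diversity-reduction and frequency-spectrum signals cannot distinguish
direct selection on a small-RNA locus from a linked sweep or from
demographic history; the screen inherits this. The HKA variance forms are
the classical moment approximations; exact conditional distributions are
not used. The target scanner's penalty weights (mismatch 1, G:U wobble
0.5, no bulges, cap 4) are the standard plant-miRNA pairing rules, stated
as an assumption and configurable — other weightings will shift the hit
list at the margin.
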