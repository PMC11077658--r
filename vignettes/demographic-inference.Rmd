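---
title: "Two-deme demographic inference and conservation-genomic statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-deme demographic inference and conservation-genomic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models and estimators it
implements, the choices that were genuinely open, and what its synthetic
data can and cannot show.  It is written for readers who want to judge or
extend the methods, not only to run them.

## The scientific setting

The package grew out of conservation-genomic assessments of the marbled
teal (*Marmaronetta angustirostris*), a duck whose remnant western
Mediterranean population ("ES") is tiny while its south-west Asian
counterpart ("IQ") remains large.  The questions such an assessment asks
are generic: How long ago did two populations split, and has gene flow
continued since?  How large were the populations before and after the
split?  Do the nuclear and mitochondrial markers agree about diversity
and differentiation?  Which sampled individuals are relatives, and what
do the statistics look like after removing them?  Every stage of that
workflow is implemented here against a simulator, so each estimator can
be checked on data whose truth is known.

## The coalescent model family

All demographic inference is built on one model family: two contemporary
demes of constant haploid size (`theta_ES`, `theta_IQ`) that merge, at
`T_DIV` generations before present, into a single ancestral deme whose
haploid size is piecewise constant with one (`A`), two (`B`) or three
(`C`) epochs (`theta_ANC`, `theta_BOT1`, `theta_BOT2`; changes at
`T_BOT1 < T_BOT2` on the before-present axis).  Gene flow is absent
(strict isolation, level `1`), symmetric (`m_S`, level `2`) or
asymmetric (two rates, level `3`), giving the nine models `A1` ... `C3`
with 3-9 free parameters.  Migration is defined backwards in time: a
lineage in deme *i* jumps to deme *j* at rate `m[i,j]` per generation,
the convention of standard coalescent simulators.

Two unit conventions matter and are easy to get wrong:

* **Sizes are haploid.**  A deme of haploid size *N* means a pair of
  lineages coalesces at rate 1/*N* per generation, and expected
  nucleotide diversity is 2*N*&mu;.  Diploid individuals are formed by
  pairing two simulated haplotypes; nothing is multiplied by two again.
  `theta_from_pi()` therefore returns &pi;/(2&mu;).
* **Times are generations before present**, converted to years only for
  reporting (`generations_to_years()`, default 4 years per generation, a
  typical duck value; the nuclear mutation rate default is 4.83e-9 per
  site per generation, an Anatidae estimate).

The simulator (`simulate_genealogies()`, with a C++ core) is a standard
continuous-time structured coalescent: exponential waiting times between
events, epoch boundaries handled by rate re-evaluation, lineage demes
changing only at migration events and at the split.  Nuclear loci get
infinite-sites mutations (`drop_mutations()`), so every mutation is one
bi-allelic SNP column - the assumption under which SFS theory is exact.
mtDNA evolves under finite-sites Jukes-Cantor (`simulate_mtdna()`), so
parallel and back mutations can and do occur, as in real control-region
fragments; haplotype networks built from such data can contain homoplasy
loops, which is why the network code keeps alternative equal-length
connections.

## What the synthetic data emulate - and what they do not

`simulate_dataset()` defaults describe the study system the package was
built around: 24 + 12 diploid individuals, 32,000 short RAD-style loci
of 300 bp (~2,500 of them polymorphic under the study-like divergence
history), ~10% missing calls inserted independently, one genealogy per
locus (free recombination between, none within), optional Mendelian
relatives appended via `pedigree_spec()`, and mtDNA fragments of 169 bp
at sizes scaled by a configurable factor (default 0.5 of the haploid
nuclear size; the mtDNA mutation rate default 2e-6, a fast
control-region rate, was chosen once so that study-like histories yield
the haplotype richness of real control-region samples - neither value is
estimated from data).  Under a recent-split history with a small
ancestral deme, most coalescence happens in the ancestral epoch, so
diversity is set by the ancestral, not the contemporary, sizes; that is
why the locus count and the mtDNA rate needed explicit calibration
against the observed panel scale rather than a back-of-envelope
equilibrium 2 N mu.

The generator deliberately omits several features of real data:
sequencing and genotype-calling error, allele dropout, linked selection,
within-locus recombination, batch effects, and non-random missingness
(museum samples failing more often).  Green tests against this generator
therefore show that the estimators are correct under their stated
assumptions; they do not show robustness to the technical artefacts of a
real RAD pipeline.

## From genotypes to the folded joint SFS

The SFS path mirrors a stacks-style protocol.  `filter_loci()` applies a
presence threshold (default R = 0.75, computed over all individuals in
the matrix, the stacks convention, not per population), an inclusive
minor-allele-frequency bound (default 0.01, computed over non-missing
calls), and optionally keeps one uniformly random SNP per RAD locus.
`downsample_individuals()` removes missing data the way the study's
protocol did: keep a target number of individuals per population -
default strategy "least-missing" with ties broken by id order, a
deterministic replacement for the study's unspecified custom script; a
seeded random strategy is available - then drop any SNP column that
still has a missing call.  `folded_joint_sfs()` tallies minor-allele
configurations; a configuration and its complement are merged once, with
the half-weight convention at self-complementary cells so the tally is
bit-stable; the monomorphic corners are masked.  `project_sfs()` offers
hypergeometric projection as an alternative to individual-level
downsampling; projection and folding commute, which the tests exploit.

## Composite-likelihood fitting

The expected folded joint SFS under a model is estimated by Monte Carlo
(`expected_sfs_mc()`), but from *expected branch lengths* rather than
sampled mutations: under infinite sites, the probability that a
polymorphic SNP has configuration (i, j) is proportional to the expected
genealogy length subtending i + j leaves in that configuration, so
tallying branch lengths gives a much lower-variance estimate than
simulating SNPs.  Monomorphic outcomes carry no branch length, so
conditioning on polymorphism is automatic; this matches an observed SFS
built only from variable sites, and is also why one deme size must be
fixed externally (`theta_IQ`, from all-sites diversity via
`theta_from_pi()`): an SFS without invariant sites carries no overall
rate information.  Empty unmasked cells are floored at 1/(10 x n_trees)
(configurable) before logs.  `composite_loglik()` is the multinomial
log-likelihood over unmasked cells in natural log with the constant
omitted; AIC differences are unaffected.  The published model table this
package reproduces in its tests is arithmetically consistent with
natural-log likelihoods, which resolved the log-base question
empirically.

`fit_model()` maximizes this objective by multi-start Nelder-Mead on log
parameters (epoch times parameterised as increments so the epoch
ordering holds by construction), with common random numbers - a fixed
per-replicate seed for the Monte-Carlo expectation - making each
replicate's objective deterministic.  The original analysis tool's
expectation-conditional-maximization cycles are replaced by this direct
search deliberately: fidelity is to the estimand (the maximum composite
likelihood), not to the algorithm.  Search bounds are sizes 1e2-1e6
haploid, times 1-1e5 generations, migration 1e-9-1e-2 per generation,
with log-uniform random starts plus one moment-informed start anchored
on `theta_IQ`.

One surface feature deserves emphasis.  Conditioned on polymorphism,
the folded joint SFS is almost invariant to rescaling every size and
time by a common factor (with migration rescaled inversely) when only
one deme is anchored; the likelihood ridge along that scale direction is
shallow - tens of log units per 1e5 SNPs.  This is a property of the
estimation problem, not of the optimizer, and it is the reason published
intervals for such fits can exclude their own point estimates.
`fit_model()` addresses it explicitly: after the replicate search it
profiles the global scale on a one-dimensional grid evaluated with many
more genealogies (`n_trees_profile`), refines the profile quadratically,
and polishes.  All replicate and profile candidates are compared at a
shared, data-derived evaluation seed so that fits of different models to
the same spectrum are comparable; `model_selection()` then applies
AIC = 2k - 2lnL, rescaled differences, and Akaike weights.
`parametric_bootstrap()` simulates spectra of the observed polymorphic
count from the fitted model by multinomial draws, refits each with a
reduced replicate budget, and reports percentile intervals - which, being
percentile intervals of a weakly identified scale, need not contain the
point estimate.

Default replicate counts in the tests are 1-3 (the full published
protocol used 100); the parameter-recovery checks run 20 independent
datasets of 1e5 SNPs, sizes chosen so the whole suite stays at
minutes-scale on one CPU while Monte-Carlo error remains well below the
tolerances being asserted.

## Stairway-style reconstruction

For a single population, the expected folded SFS under piecewise-
constant size is computed analytically (`expected_sfs_analytic_1pop()`):
the time the genealogy spends with k ancestral lineages follows from the
classical lineage-count distribution integrated epoch by epoch (computed
with log-gamma arithmetic; the alternating series is well behaved at the
sample sizes used here, n <= ~60), and a branch present while k lineages
survive subtends i of n leaves with probability
C(n-i-1, k-2)/C(n-1, k-1).  Constant size recovers the 1/i spectrum
exactly, which is a frozen test.  `fit_stairway()` maximizes per-epoch
sizes on a user-supplied epoch schedule (underdetermined schedules -
more epochs than folded classes - are rejected), and bootstraps by
multinomial resampling of SNPs.  Absolute size identification deserves
care: a constant-size history has an N-independent SFS *shape*, so a
polymorphism-normalized fit cannot recover absolute N_e.  When the
mutational opportunity is known (`mu` and `total_sites`, the total
sequenced length behind the SFS), the fit therefore uses the absolute
Poisson likelihood of the class counts, which anchors the scale the way
stairway methods do; without it, only the trajectory's shape relative to
the schedule's absolute times is meaningful.  Trajectories are reported
in generations and years.  This is a transparent, few-epoch
reconstruction in the spirit of stairway plots, not a reimplementation
of that program's automatic breakpoint machinery.

## Nuclear and mitochondrial statistics

`diversity()` computes per-site observed heterozygosity, unbiased
expected heterozygosity 2pq·n/(n-1) (n = sampled alleles), and
nucleotide diversity as the average pairwise difference - which for a
bi-allelic site is the same unbiased quantity, computed through an
independent route as a cross-check.  Population values are
ratios-of-sums, and `F_IS = 1 - mean(H_O)/mean(H_E)` is a
ratio-of-averages, the stacks convention; per-locus-ratio averaging
gives different values and would not match RAD-pipeline tables.
All-positions mode divides the same sums by the supplied total sequenced
length.  `kinship_king()` implements the KING-robust pairwise estimator
over the SNPs both individuals share; `select_unrelated()` resolves the
positive-kinship graph by repeatedly dropping, within each connected
component, the member with the most missing data (ties drop the later
id), which keeps the least-missing member of each related pair and is
deterministic.  The threshold deserves thought: with a few thousand SNPs
the estimator's noise is ~0.02, so in a perfectly panmictic sample about
half of all unrelated pairs sit above zero by chance and a strict
"any positive kinship" rule cascades into removing much of the panel.
That rule is appropriate for real data, where substructure shifts
unrelated pairs negative; on clean simulations the third-degree
boundary (phi > 0.0884) is the sensible screen, and the analysis
scripts use it.  `fst_wc()` is the Weir-Cockerham variance-components
estimator summed over loci with a label-permutation test; permutation
p-values throughout the package use the add-one convention, so p is
never exactly zero.  The study text mentions Fisher's exact tests "after
permutations", an internally contradictory description; permutation
testing is what is implemented.  Permutation tests are exact but
discrete: when the data carry little variation - e.g. Phi_ST on a short,
low-diversity mtDNA fragment with a handful of distinct haplotypes - the
permutation distribution is heavily tied, a large share of p-values
equals 1, and realized type-I error falls well below the nominal level.
That conservatism is a property of exact tests under ties, not an
implementation artefact; calibration checks of the machinery itself
should use data variable enough that the statistic is effectively
continuous.

On the mtDNA side, `collapse_haplotypes()` treats N as mismatching by
default (a conservative choice for museum-grade sequences; a wildcard
flag is available), `hap_diversity()` returns the unbiased estimator
with its standard sampling variance so Welch-style comparisons are
possible downstream, `tajimas_d()` uses complete deletion of sites with
N or gaps, and `phi_st()`/`amova()` decompose molecular variance with
pairwise difference counts as squared distances, two- or three-level,
with the standard per-level permutation schemes (populations across
groups; individuals across populations within groups; individuals across
everything).  Negative variance components are reported as such -
they are a known property of the estimators, and published AMOVA tables
contain them.

`tcs_network()` builds a statistical-parsimony network: pairs are
connected in increasing distance order; within a distance tier, every
pair that linked two components at the tier's start is connected, so
alternative equal-length paths are kept as cycles while longer
redundant connections are suppressed; multi-step edges gain inferred
intermediate nodes.  The full original parsimony-probability machinery
is reduced to a documented approximation: the automatic connection limit
is the largest step count j for which the expected number of hidden
(superimposed) changes - the excess of the Jukes-Cantor-corrected
substitution count over j - has Poisson probability >= 0.95 of being
zero.  This is more conservative than the classical recursion for short
fragments; a fixed-limit override is provided, and the small, fully
resolved networks typical of control-region data are unaffected.

## Numerical choices and degenerate inputs

* Folding uses half-weight merging at self-complementary cells; spectra
  round-trip bit-exactly through the flat-text serialisation.
* Expected-SFS cells are floored before logs; likelihood cells with zero
  observed count contribute nothing regardless of the floor.
* Zero-duration epochs are collapsed with a warning; all-missing SNP
  columns are dropped with a message; individuals with no calls are
  flagged and excluded from summaries.
* Degenerate designs return exact values, not approximations: one
  population per group zeroes the middle AMOVA component; identical
  sequences make Phi_ST an explicit error rather than 0/0.
* A single integer seed drives every stochastic stage; rerunning any
  pipeline stage with the same seed is bit-identical.

## Known limitations

The composite likelihood treats SNPs as independent, so it is valid for
point estimation and AIC-style ranking, not for classical hypothesis
tests.  The scale direction of the two-deme model is weakly identified
from polymorphism-only spectra at these sample sizes even with
`theta_IQ` fixed; expect wide, sometimes point-excluding bootstrap
intervals for `T_DIV` and `theta_ES`, and treat their point estimates as
order-of-magnitude statements.  The stairway-style fit requires a
user-chosen epoch schedule.  The simulator's missingness and error
models are idealised, as discussed above.  None of the sequence-format
readers attempt repair: inputs are expected aligned, bi-allelic and
well-formed, and violations are errors by design.
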