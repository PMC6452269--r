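---
title: "Modelling and analysing CRISPR-phage arms races with spacerace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing CRISPR-phage arms races with spacerace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(spacerace)
library(dplyr)
```

## The biological problem

When a lytic phage infects a bacterium carrying an active CRISPR-Cas
system, surviving cells can integrate a short (~30 nt) phage-derived
*spacer* into a CRISPR array. The spacer directs cleavage of any phage
genome carrying the matching *protospacer*, provided the protospacer is
flanked by the right protospacer-adjacent motif (PAM). Phage escape this
immunity through point mutations in the PAM or in the PAM-proximal *seed*
region of the protospacer; mutations elsewhere in the protospacer are
tolerated by the interference machinery. Iterating acquisition and escape
produces host-parasite coevolution, and serial-transfer co-cultures of
*Streptococcus thermophilus*-like hosts (two active type II-A loci,
CRISPR1 and CRISPR3) with a virulent phage are the classic laboratory
arena for it.

`spacerace` implements the full analysis pipeline for such experiments —
infection-matrix phenotyping, time-shift (past/present/future) analysis, a
genotype-by-environment variance decomposition that separates arms-race
from fluctuating-selection dynamics, spacer diversity metrics, and
mechanistic infectivity prediction from spacer/SNP genotypes — together
with a synthetic serial-transfer simulator so that every stage is testable
without any sequencing data.

## The infection rule

The mechanistic core is deliberately simple and fully testable:

* a spacer targets the unique catalog locus whose protospacer it matches
  exactly (mismatch-tolerant mapping is refused: the simulator guarantees
  exactness, and ambiguous multi-locus matches raise an error rather than
  being silently resolved);
* a phage *escapes* a spacer iff it carries at least one SNP in that
  locus's seed window or PAM (`escapes_spacer()`); SNPs in the protospacer
  outside the seed are classified (`classify_mutations()`) but confer no
  escape;
* a phage is predicted to infect a host iff it escapes **every** acquired
  spacer of that host (`predict_infection()`); hosts without acquired
  spacers are always predicted infectable, because the wild-type arrays
  contain no spacer matching the phage.

The all-spacers reading of "predicted infective" is a documented
interpretation: with multiple targeted protospacers the complementary
any-spacer reading would make a single escape SNP sufficient, which
contradicts the observed monotone decline of infectivity with the number
of unescaped targets. `count_unevolved_targets()` returns that number,
and `predict_infection()` is exactly its zero set — the package treats
this equivalence as an invariant and tests it.

Two monotonicity properties follow and are enforced by property-style
tests: adding spacers to a host can only reduce predicted susceptibility,
and adding SNPs to a phage can only increase predicted infectivity.

## The serial-transfer simulator

`run_serial_transfer()` is a genotype-count model, not an agent
simulation: the state is a table of host genotypes (ordered spacer
tuples) and phage genotypes (SNP sets) with per-ml abundances, updated in
expectation. Randomness enters only through which locus a new spacer or
SNP hits, so runs are bit-identical per seed. Each simulated day runs
`generations_per_day` update steps (default `log2(100)` = 6.64, the
turnover implied by daily 1:100 transfers, with the fractional remainder
as a fractionally weighted step) of:

1. logistic host growth, `growth_rate` doublings per step at low density,
   braked to zero at carrying capacity;
2. mass-action phage encounters, allocated across host genotypes in
   proportion to abundance;
3. infection wherever the phage's escaped-locus set covers the host's
   spacers: a fraction `acquisition_prob` of infected cells survives and
   appends one new spacer drawn uniformly from the protospacer catalog,
   the rest lyse into `burst_size` progeny, each protospacer locus of
   which mutates with probability `mutation_prob` at a uniform position in
   the protospacer-plus-PAM interval;
4. removal of phage adsorbed to resistant hosts;

followed by 1:100 dilution of both populations. Densities are recorded
daily before dilution; extinction is scored on the first day of a run of
`extinction_window` (4) consecutive days below the 200 PFU/ml plaque
detection limit, after which phage are no longer tracked.

### Two stabilising assumptions

Naive mass action with a ~200-phage burst and 1:100 daily dilution has a
knife-edge: phage either decline deterministically or lyse the entire
culture within one growth window, neither of which matches the observed
multi-day coexistence with gradually rising resistance. Two biologically
motivated assumptions produce the observed regime:

* **Growth-coupled adsorption.** Productive infection requires
  metabolically active cells. The realized per-step encounter probability
  is `adsorption_prob * 4 f (1 - f)` with `f = N / K`: it peaks at half
  capacity and vanishes in stationary phase, confining phage
  amplification to the post-transfer regrowth window.
* **Stationary-phase refuge.** Per step, at most the actively growing
  slice of each host genotype can be infected. Phage therefore burn
  through the vulnerable fraction daily instead of exterminating entire
  genotypes, host titres stay near carrying capacity, and sensitive
  genotypes decline over several days rather than instantly — which is
  what makes the time-shift design informative.

### Book-keeping approximations

Exact per-progeny mutation tracking would create thousands of genotypes
of vanishing abundance. Two caps keep the tables desk-scale without
changing the dynamics that matter:

* new **escape-mutant genotypes** are instantiated only at loci currently
  targeted by at least one extant host spacer (at most `mutation_slots`
  per parent per step, chosen weighted by the abundance of hosts carrying
  each locus); mutant mass at untracked loci is phenotypically neutral
  and stays folded into the parent's count. The SNP *position* within the
  tracked locus is still uniform, so roughly half of spawned mutants land
  outside the seed/PAM and fail to escape — mutation supply is not
  secretly biased toward success;
* new genotypes are founded only above mass thresholds
  (`acquisition_threshold`, default 2000 cells/ml, and
  `mutant_threshold`, 0.05 phage/ml), a coarse stand-in for demographic
  stochasticity at low copy number. The host threshold deliberately keeps
  spacer sweeps near-clonal; observed CRISPR genotype richness in this
  kind of experiment is of order 1-2 alleles per 12-clone panel, and
  polyclonal sweeps would (and in earlier parameterisations of this model
  did) dilute every escape mutant's host base below its amplification
  threshold, extinguishing coevolution after one cycle.

### Parameter defaults and provenance

Design constants are taken from the serial-transfer protocol the
simulator emulates: 30 days, 1:100 daily transfer, 1e6 CFU and 1e8 PFU
(of 1e6-1e9 used across treatments) inocula, 200 PFU/ml detection limit,
4-day extinction window, 12 clones of each kind sampled at 1, 4 and 9
dpi, 12 replicates of which up to 8 phage-persistent ones are retained,
spacer length 30 nt, seed window 10 PAM-proximal nt, PAM motifs NNAGAAW
(CRISPR1) and NGGNG (CRISPR3) — the motifs and seed length are
literature-standard for this host's type II-A systems and are
configurable because they are conventions, not measurements. The default
genome length (34,704 nt) matches the scale of a virulent *pac*-type
streptococcal phage genome.

The demographic rates are **placeholders**: no adsorption rate, burst
size, acquisition or mutation probability is available at this
resolution. The defaults (burst 200, peak encounter probability 0.04,
acquisition 1e-4 per infection, protospacer mutation 1e-6 per
replication, K = 1e9/ml, 2 doublings per step) were chosen once, at
literature-plausible orders of magnitude, such that the simulator
reproduces the documented qualitative regime: hosts sensitive at 1 dpi,
a resistance sweep by 4 dpi, escape-SNP phage prominent by 9 dpi, and
median phage extinction around day 11-12. They are not fitted to any
trajectory, and none of the downstream analytics depends on their exact
values.

```{r, fig.width = 6, fig.height = 3}
cfg <- sim_config(days = 14L)
run <- run_serial_transfer(build_reference_genome(8000, rng_seed = 1),
                           cfg, rng_seed = 42)
plot_trajectories(run$trajectory)
```

## What the synthetic data do and do not emulate

The generator reproduces the *structure* of the real data exactly
(36 x 36 binary matrices per replicate with 1/4/9-dpi metadata, ordered
spacer tuples over two CRISPR loci, SNP sets against a reference with a
PAM-flanked protospacer catalog, daily CFU/PFU trajectories with a
detection limit) and the *qualitative dynamics* (arms race, asymmetry,
extinction). It does not emulate: biased spacer acquisition along the
genome (acquisition is uniform over the catalog, whereas real spacers
cluster), phage recombination, back-mutation of hosts to sensitivity,
partial interference, or multi-phage treatments. Passing tests therefore
certify the analytics and the mechanistic rule, not any quantitative
claim about real co-culture rates.

## Phenotype analysis

`infectivity_range()` / `resistance_range()` are clone-level proportions
against all 36 opposing clones of the same replicate (the denominator
spans all three time points, following the range definition used with
this design). `summarize_by_timepoint()` averages clone ranges within
replicate and reports the per-dpi grand mean with a two-level percentile
bootstrap: replicates are resampled in the outer level, clones within
replicate in the inner level, with `reps = 1000` and `alpha = 0.05` by
default and a fixed seed for reproducibility. A mixed logit model with a
replicate random effect estimates the same group-mean proportion; the
bootstrap was chosen because the estimand is identical while the
machinery stays transparent, at the cost of numerically different
interval endpoints — the intervals here are percentile intervals on the
proportion scale, not back-transformed logit-scale Wald intervals.

## Time-shift scoring and the G x E decomposition

`classify_background()` scores each challenge relative to the phage:
phage sampled before their host are the host's past, after it its
future. `timeshift_table()` reports cell means over the 3 x 3 design and
pooled past/present/future means, with the same two-level bootstrap.

To separate arms-race from fluctuating-selection dynamics,
`anova_ms()` computes the classical balanced two-way decomposition for
one replicate and host time point, with G = the 12 host clones of that
day, E = the phage sampling day (3 levels) and the 12 phage clones per
day as replication; the binary outcome is the response. Because the
design is balanced, sums of squares come directly from cell and marginal
means — no iterative fitting — and `ss_g + ss_e + ss_gxe + ss_resid =
ss_total` is enforced as an invariant (tested against `stats::aov` as an
independent oracle). The reported statistic is `ratio = MS_GxE / MS_E`
(`gxe_ratio_series()`): large values mean host genotypes disagree about
which phage environment is dangerous (fluctuating selection); small
values mean a uniform time trend (arms race). The ratio's two possible
readings differ only by reciprocation, and the reciprocal is available
via `glance(x, reciprocal = TRUE)`. Cells with `MS_E = 0` (for example
host panels that are uniformly susceptible at every phage time point)
are flagged and excluded from summaries with a logged count rather than
propagating infinities. Host genotype is the full acquired-spacer tuple
pooled over both CRISPR loci.

## Spacer diversity

`pwd()` measures pairwise difference between clones' acquired-spacer
multisets: for each unordered pair, `1 - |shared| / max(set sizes)`,
averaged — 0 when all clones share the same spacers, 1 when no spacer is
shared. The stated endpoints are set-identity statements, which is why
token mode is the default; a nucleotide mode (mean normalized Hamming
distance between spacer sequences) is available behind a flag. Wild-type
backbone spacers are excluded throughout: only acquired spacers enter
diversity, richness and the infection rule. `genotype_richness()` counts
distinct ordered tuples (acquisition order distinguishes alleles), and
`location_histogram()` bins mapped spacer-target midpoints along the
genome per replicate and day.

## Variants and the contingency analysis

`call_snps()` is a length-preserving positional comparison (indels are
out of scope by design). `classify_mutations()` labels each SNP by locus
geometry with priority PAM > seed > protospacer-non-seed > outside, and
summarises a clone-locus pair by its highest-priority label.
`simulate_measured_matrix()` converts a predicted matrix into a
"measured" one by independent per-cell Bernoulli flips; the default
rates, `fn = 107/348` and `fp = 106/348`, are the discordance rates
observed between sequence-based predictions and plate phenotypes in this
assay family, attributed to partial CRISPR interference and the
crudeness of lysis-zone scoring. No clone-level noise correlation is
modelled because no structure for it is reported.
`contingency_analysis()` then cross-tabulates predicted against measured
challenges; with zero noise the pipeline's predicted and measured
matrices are identical and concordance is exactly 1 — the master oracle
test anchoring the whole chain.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere, in memory and on disk;
  minus-strand loci store plus-strand coordinates with a strand flag.
* Matrices are written as 0/1 integer CSV (never logical words) with a
  clone-metadata sidecar; manifests record md5 checksums with a
  locale-independent file ordering.
* The bootstrap collapses to a point interval for constant data; `pwd()`
  warns and returns `NA` for fewer than two clones; empty populations
  refuse sampling; unbalanced ANOVA layouts are an error, not a silent
  approximation; a spacer matching no catalog locus is an error naming
  the spacer.
* Simulated abundances are floats; genotypes below `prune_threshold`
  (1e-3/ml) are dropped to keep state bounded, and non-finite abundances
  abort the run.

## Problem sizes

The shipped tests simulate 2-3 replicates over 6-10 days for unit
checks and one full 12-replicate, 30-day panel for the arms-race
signature; property suites use 50 random ANOVA layouts and 1000 random
clone panels. The acceptance script runs one full default panel
(12 replicates, 30 days, 8 retained, 10,368 measured challenges) and
500-replicate bootstraps. These sizes were chosen so the whole suite
runs on a laptop in a few minutes while every stochastic check retains
comfortable statistical margin.

## Known limitations

The simulator's expectation updates have no demographic noise beyond the
founding thresholds, so aggregate trajectories vary across seeds only
through which loci get hit — replicate-to-replicate variance in
extinction time is therefore smaller than in real experiments. Uniform
acquisition ignores the known positional biases of spacer sampling.
The phenotype noise model is unstructured. And the G x E ratio is
computed from the balanced decomposition only; unbalanced panels (e.g.
failed clones) must be completed or subsetted before analysis.
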