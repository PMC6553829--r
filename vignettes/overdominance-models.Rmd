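---
title: "Overdominance models and deterministic multi-allele equilibria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overdominance models and deterministic multi-allele equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daasel)
```

## The model

`daasel` studies balancing selection at one autosomal locus with alleles
$A_1,\dots,A_k$ in an effectively infinite, randomly mating population with
discrete, non-overlapping generations.  Genotype $A_iA_j$ has viability
$f_{ij}\in[0,1]$ (0: non-viable; 1: fully protected against all pathogens),
collected in the symmetric genotype fitness matrix $F$ with the *intrinsic
merits* $w_i = f_{ii}$ on the diagonal.  One generation of viability
selection maps allele proportions $p$ to

$$p_i(t+1) = p_i(t)\,\frac{w_i^{(m)}(p(t))}{\bar w(p(t))},\qquad
w_i^{(m)} = (Fp)_i,\quad \bar w = p^\top F p ,$$

where $w_i^{(m)}$ is the marginal fitness of allele $A_i$ and $\bar w$ the
population fitness.  At a polymorphic equilibrium every persisting allele has
marginal fitness equal to $\bar w$, so the equilibrium solves the linear
system $Fx = \mathbf 1$ after normalization.  `solve_equilibrium()`
implements the classical procedure: solve, eliminate every allele whose
solution entry is nonpositive, re-solve on the remaining principal submatrix
$\hat F$, and repeat until all entries are strictly positive.  When $\hat F$
is nonsingular this equilibrium is unique and globally attracting from any
interior state, with $\bar w$ increasing monotonically along trajectories;
when it is singular (reciprocal condition number below
$\sqrt{\epsilon_{mach}}$, or an exactly singular solve) the result is
flagged `status = "singular"` and simulation callers discard the draw and
redraw the allele set.

Three fitness models are built on top of an `allele_set`:

* **Symmetric overdominance** (`fitness_symmetric`): $f_{ij}=1$ for
  $i \ne j$.  All alleles persist regardless of merit; implemented for
  completeness and as a strong invariant test, not as a plausible mechanism.
* **Asymmetric overdominance, AO** (`fitness_ao`):
  $f_{ij} = w_i + w_j - w_i w_j$, i.e. contributions add and an *average*
  overlap $w_i w_j$ is discounted.  For interior merits
  $\max(w_i,w_j) < f_{ij} < 1$.  All $k$ alleles persist iff every merit
  exceeds the threshold $t = \tfrac{k-1}{k}\hat w$ with $\hat w$ the
  harmonic mean of the merits (`ao_threshold`); the threshold forces the
  persisting merits into an ever narrower window as $k$ grows.
* **Divergent allele advantage, DAA** (`fitness_daa`): each allele carries a
  binary recognition pattern over $l_S$ abstract epitope sets; because both
  alleles of a heterozygote are codominantly expressed, $f_{ij}$ is the
  fraction of sites recognized by the *union* of the two patterns.  Here the
  overlap is pair-specific: two mediocre but complementary alleles can form
  a near-perfect heterozygote, which is what lets the DAA model keep alleles
  far below the AO threshold.

With sites drawn independently the expected DAA heterozygote fitness is
$w_i + w_j - w_i w_j$, so AO is exactly the mean-field limit of DAA; the
test suite checks this as a Monte Carlo property at $l_S = 10^4$.

## Equilibrium metrics

For a stable equilibrium the package reports the persisting-allele count
$n_{equil}$, the merit range $r_{equil}$ (max minus min merit of survivors),
the average overdominance

$$\bar h = \frac{\bar w_{het} - \bar w_{hom}}{\bar w_{hom}},\qquad
h_i = \frac{w_{het,i} - w_{hom,i}}{w_{hom,i}},$$

and, when patterns are available, the pairwise recognition overlap
$g_{ij} = r_{ij}/l_S$ ($r_{ij}$ sites recognized by both alleles), the
partner-weighted average overlap
$g_i = \sum_{j\ne i} p_j\, g_{ij}/(1-p_i)$ and the pool mean
$\bar g = \sum_i p_i g_i$.

Two conventions here are genuinely open and are therefore explicit options:

* *Overdominance weighting.*  "Average fitness of heterozygotes at
  equilibrium" can be read as genotype-frequency weighted or as a plain mean
  over genotype classes.  The default weights by Hardy–Weinberg genotype
  frequencies at the equilibrium, renormalized within the heterozygote and
  homozygote classes (`weighted = TRUE`); plain means are available for
  sensitivity analysis.
* *The overlap self term.*  The printed definition of $g_i$ sums over all
  $j$ but normalizes by $1/(1-p_i)$, which only renormalizes the weights
  when the self term is excluded.  We exclude it ($j \ne i$); the regression
  tests pin the convention down, and including the self term would shift
  $g_i$ by exactly $p_i w_i/(1-p_i)$.

## The time-step validator

`iterate_to_convergence()` runs the generation map itself and is the
independent check on the linear solver: for stable systems the two agree to
at least $10^{-8}$ on survivors and proportions, and the iteration is
declared converged when the marginal fitnesses of all non-vanishing alleles
agree with $\bar w$ within `tol` (default $10^{-11}$, matching an
11-decimal quasi-equilibrium).  One numerical subtlety deserves a note:
at a *boundary* equilibrium an eliminated allele's proportion decays only
algebraically (its marginal-fitness gap closes as the survivors converge),
so a naive spread criterion would never trigger.  The iterator therefore
classifies an allele as *vanishing* once its proportion falls below
`vanish_tol` ($10^{-6}$) while still decreasing, excludes it from the spread
criterion, and reports it as eliminated; proportions below `prune`
($10^{-12}$) are removed outright.  The three-allele worked example whose
fitness matrix collapses to a single survivor exercises exactly this path.
All tolerances are arguments with documented defaults.

## The scenario experiments

The simulation layer compares AO and DAA across 80 scenarios
(`scenario_table()`): eight merit ranges $(w_{min}, w_{max})$, five initial
allele counts $n_{ini} \in \{50,100,250,500,1000\}$ and a merit-resolution
factor $f \in \{2,10\}$.  Derived per scenario are the margin
$\epsilon = (w_{max}-w_{min})/(2 n_{ini})$, which keeps useless ($w=0$) and
perfect ($w=1$) alleles out of the draw, and the epitope-sequence length
$l_S = \lceil f\, n_{ini}/(w_{max}-w_{min})\rceil$ — the minimal length that
gives at least $f$ times as many representable merits in the range as
initial alleles.  The published design states the requirement, not the
formula; the ceiling is this package's choice of the minimal satisfying
length.

Each repeat draws merits (uniform on the trimmed range in the *Random*
experiment; the fixed evenly spaced grid in the *Fixed* experiment),
converts them to site counts $m(A_i) = l_S w_i$ — rounded half-to-even by
default, a choice exposed as the `rounding` option because the design leaves
non-integer $l_S w_i$ unspecified — and samples each allele's recognized
sites as a uniform random subset.  Both models are then built from the
*same* quantized merits $m(A_i)/l_S$ and patterns, so the AO/DAA comparison
is exactly paired; range comparisons are made on integer site counts, so
"equal range" means exact equality.  Singular draws are discarded and
redrawn (with a fresh derived seed), mirroring the published redraw policy;
redraw counts are logged.  Per-repeat seeds are a deterministic hash of
(base seed, scenario, repeat, experiment, attempt), so any subset of the
sweep can be reproduced independently and results are invariant to
execution order.

What the generator deliberately does *not* emulate: real MHC data have
mutation, migration, finite population drift, linkage and non-random
pathogen exposure.  Passing tests show that the deterministic viability
framework and the two fitness models behave as published — not that real
loci meet these assumptions.

## Problem sizes and Monte Carlo error

The published sweeps use 10,000 repeats per scenario at
$n_{ini} \le 100$ down to 100 repeats at $n_{ini} = 1000$ (~720,000 paired
solves).  The package's own acceptance runs execute all 80 scenarios of both
experiments at 1% of that schedule with a floor of 20 repeats per scenario.
The floor is a Monte Carlo error-control choice: the pooled "DAA range
wider" fraction is an unweighted mean of 80 per-scenario fractions, and a
scenario estimated from a single repeat contributes a variance of up to
0.25 to that mean.  Flooring every scenario at 20 repeats bounds each
per-scenario standard error at ~11 percentage points and the pooled standard
error at ~1 point, at roughly 200 seconds per experiment on one CPU.  Both
pooling conventions (scenario-averaged and iteration-pooled) are reported by
`pooled_summary()` because the published table does not state which was
used; the scenario-averaged reading is the default interpretation.

## Numerical choices and limitations

* Elimination removes *all* nonpositive-solution alleles each round (the
  plain reading of the published procedure); one-at-a-time removal is
  available via `eliminate = "one"` for sensitivity checks.  Because the
  active set strictly shrinks, the procedure always terminates.
* Singularity is judged by reciprocal condition number
  ($< \sqrt{\epsilon_{mach}}$) rather than an exact zero determinant, for
  floating-point robustness.
* Equilibria with multiple stable boundary states are not analysed beyond
  the nonsingularity condition; the result found by the printed procedure is
  returned and the `eliminations` log supports an audit.
* The finite-population (drift) layer is out of scope; the deterministic
  model treats proportions as exact.
* Pattern storage is a boolean matrix (alleles × sites) in the user-facing
  `allele_set`; the simulation fast path bit-packs patterns in C++ and
  never materializes that matrix, which matters at $n_{ini} = 1000$,
  $l_S = 10^5$.

## A worked example

```{r}
f <- fitness_matrix(rbind(c(0.8, 0.9, 0.9),
                          c(0.9, 0.7, 0.8),
                          c(0.9, 0.8, 0.1)), model = "daa")
eq <- solve_equilibrium(f)
eq
round(100 * eq$proportions, 1)
```

The same three merits under AO lose their weakest allele, as the threshold
predicts:

```{r}
ao_threshold(c(0.8, 0.7, 0.1))
solve_equilibrium(fitness_ao(c(0.8, 0.7, 0.1)))
```
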