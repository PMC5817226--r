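---
title: "Evolutionary design and optimization of multi-factor experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary design and optimization of multi-factor experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evodoe)
```

## The problem

Tuning a biological process — say, the cultivation medium and pH for a
methanol-inducible recombinant-protein strain — means optimizing many
interacting factors at once. Full-factorial design explodes: nine factors at
32 levels each would require $32^9 \approx 3.5\times 10^{13}$ experiments.
`evodoe` implements the alternative used in evolutionary experimental
design: a genetic algorithm (GA) proposes small batches of conditions, the
laboratory measures them, and selection over measured fitness steers the
next batch toward the optimal sub-space. A second stage models the explored
response surface by multigene symbolic regression (SR) and ranks the
factors driving each objective by perturbation analysis.

The human stays in the loop: the package proposes and evaluates; the user
measures, decides when to stop, and reads optimal settings off convergence
diagnostics.

## Encoding and fitness

Each factor $j$ is a *gene* of $b_j$ bits giving $2^{b_j}$ evenly spaced
levels on its physical range $[\min_j, \max_j]$; a *chromosome*
concatenates the genes in declared order ($L=\sum_j b_j$; 45 bits for the
nine-factor, 5-bit reference design). Decoding is affine:
$x_j = \min_j + k\,(\max_j-\min_j)/(2^{b_j}-1)$ with $k$ the gene's integer
value. Plain base-2 encoding is the default; reflected Gray code is
available (`encoding = "gray"`) for users who want single-bit mutations to
always move one level.

Fitness of a condition in generation $i$ is the weighted sum of
min–max-normalized objective responses,

$$\mathrm{score} = \sum_m w_m\, t_m,\qquad
t_m = \begin{cases}
\dfrac{x_m - \min_i x_m}{\max_i x_m - \min_i x_m} & \text{(maximize)}\\[1ex]
1 - \dfrac{x_m - \min_i x_m}{\max_i x_m - \min_i x_m} & \text{(minimize)}
\end{cases}$$

with extremes taken *within the current generation only* — scores rank
conditions against their cohort, which is all selection needs. Weights are
normalized to sum to one, so scores live in $[0,1]$. Replicates are
aggregated by the median after repairing a single missing replicate with
the mean of the remaining ones; two missing replicates in a cell are a
validation error, because a median of one repaired value would no longer be
robust to anything. If an objective is constant across a generation its
term is fixed at 0.5 with a warning: an uninformative objective should
neither reward nor punish.

## The generation loop

* **Selection** — the better-scoring `selection_fraction` (default 0.5) of
  the population forms the mating pool (ties broken by chromosome id so
  replays are stable); within the pool, parents are drawn by roulette
  wheel proportionally to score. The two parents of a pair are forced
  distinct by removing the first from the wheel for the second draw. We
  read the conventional "selection probability 0.5" as this composite of
  truncation and roulette: the truncation supplies the 0.5, the wheel the
  fitness-proportionality.
* **Crossover** — single-point, probability `crossover_rate` (default 0.9)
  per pair: one cut position uniform on the $L-1$ interior boundaries,
  suffixes exchanged.
* **Mutation** — with probability `mutation_rate` per offspring, exactly
  one uniformly chosen bit flips. The default is 0.01; medium-optimization
  practice raises it to about 0.1 for 45-bit chromosomes. Because our
  mutation event flips at most one bit, the *per-bit* pressure is
  `mutation_rate`/L; when comparing against the per-bit rates of roughly
  0.15 recommended in the medium-optimization GA literature, the
  equivalent per-chromosome rate is $\min(1, 0.15\,L)$. Short chromosomes
  therefore need rates near 1 — the small-scale search-quality experiment
  in the test suite (6-bit chromosomes) uses 0.9 for exactly this reason,
  and with rate 0.1 such a search demonstrably stalls on whatever
  generation 1 found.
* **Turnover** — $\lceil N/2\rceil$ pairs produce $N$ offspring with fresh
  ids; duplicates are permitted (forbidding them would bias tiny
  populations). No elitism by default; `elitism = k` copies the best $k$
  unchanged for users who want it.

Population size defaults to $2n-2$ for $n$ factors (16 for nine factors),
the upper part of the customary $[n, 2n]$ band. Every stochastic draw uses
a seed derived deterministically from the session seed and the generation
index, so a session replays bit-identically from its state file.

## Convergence diagnostics and termination

`score_trajectories()` tracks the population mean, the mean of the
better-performing fraction (default 50 %), and the best individual.
`relative_standard_deviation()` (sample SD over mean; the $n-1$ convention
because generations are samples of the search, not populations in the
statistical sense) of the better fraction contracts as the search narrows.
`population_profile()` counts how often each level of each factor appears
per generation, and `occupancy_footprint()` gives the percent occupancy of
levels within the better fraction of the last generation — the lens through
which final settings are read. `improvement_test()` is a one-sided Welch
t-test of the better fraction improving between adjacent generations
(chosen because the score variance shrinks as the search converges, so
equal variances should not be assumed; a Mann–Whitney option is exposed).
Termination is advisory, never automatic: `step()` prints the metrics and
flags `p > 0.1` as "consider stopping", but the user decides.

## Symbolic regression

Each objective is modelled as an intercept plus a least-squares-weighted
sum of up to `max_genes` (default 5) expression trees over the factors,
built from addition, subtraction, multiplication and protected division
(depth at most `max_depth`, default 4). Protected division returns the
numerator when $|\mathrm{denominator}| < 10^{-12}$ — a continuity-preserving
choice (near the singularity the ratio is dominated by the numerator's
sign pattern) that guarantees finite predictions for finite inputs; the
conventional alternative of returning 1 introduces a jump discontinuity.

Evolution is standard multigene GP: ramped half-and-half initialization,
tournament selection (size 2), subtree crossover within a random gene with
an occasional (probability 0.2) high-level swap of whole genes between
models, subtree mutation that may also add or drop a gene, reproduction,
and one elite model per generation; operator mix 0.85/0.10/0.05. Model
fitness is training RMSE after the weight fit — no holdout, since the
interest is describing the explored surface, and complexity is controlled
by the gene and depth caps instead; cross-validation is out of scope.
Rank-deficient gene designs (duplicate genes happen) are solved by the
minimal-norm pseudo-inverse. $R^2$ is reported with the adjusted version
using the number of genes as the predictor count for SR and the number of
factors for the MLR baseline — "predictors" means whatever the model class
actually estimates a coefficient for. Defaults for population and
generations are 500 each, the setting appropriate for datasets of a few
dozen to a few hundred rows; the test suite runs scaled-down searches
(population 100–200, 40–100 generations) whose sizes are stated in each
test.

Batches (`fit_batch()`, default 10 models) rerun the search with derived
seeds on the same data; run-to-run structural variability of GP is
information, and downstream analysis asks how many models agree.

## Sensitivity analysis

`perturb_and_score()` shifts one factor's value at the determined optimum
by ±10 % (both signs, since the response surface need not be symmetric;
the larger response counts) and reports
$\max(|\hat y_+-\hat y_0|, |\hat y_--\hat y_0|)/|\hat y_0|$ per model.
A factor is a *major contributor* to an objective when at least half the
batch's models respond by ≥ 10 % (`classify_contributors()`,
`batch_rule = "majority"`). We evaluated the existential alternative
(`"any"`): it matches a looser reading of "a response observed in the
batch", but a single model carrying a spurious near-zero denominator in a
null factor then flags that factor, and with factors whose optimum value
is near zero this measurably inflates the false-positive rate — majority
aggregation is the robust default, `any`/`all` remain options. Factors
that are structurally absent from an objective's phase (e.g. the inducing
carbon sources before induction) are declared `not_applicable` and
reported as such rather than classified.

A known limitation, visible in the end-to-end tests: a factor whose true
relative response at the optimum sits just above the 10 % threshold is
classified unstably, because individual GP models estimate the local slope
with error and the majority vote then hovers around 50 %. Detection is
reliable for factors well above the threshold and for exact nulls; the
borderline band (roughly 10–25 % true response) is where batch-to-batch
disagreement concentrates. Relatedly, by the time a session has converged,
the data cluster near the optimum and constrain local slopes only through
the early, diverse generations — sensitivity conclusions are only as good
as the coverage of the data the models were fit to.

## The synthetic oracle

`oracle_spec()` binds a design space to deterministic response functions
plus a noise model, standing in for the wet lab so the whole workflow runs
at the desk. Measurement noise is multiplicative lognormal with CV 0.1 by
default — positive-valued biological measurements tend to CV-stable, not
additive, error (an additive-Gaussian option exists). Cells lose a
replicate independently with probability 0.02, never more than one per
(condition, objective), so the repair rule always applies. Three
replicates, as is conventional for this kind of screen.

Three oracles ship with the package:

* `case_study_oracle()` — nine factors (eight medium components + pH),
  four objectives: pre-induction biomass `ODbi` (maximize), induction-phase
  biomass increase `ODd` (minimize), enzyme activity `Ea` (maximize) and
  specific productivity `P = Ea/(ODbi + ODd)` (maximize), equally
  weighted. The responses compose saturating uptake terms, optimal-window
  (Gaussian) substrate terms — glycerol overflow above ~9 g/L hurting
  growth, methanol inducing near 5 g/L but toxic beyond — and offset pH
  optima, so that objectives disagree and the composite optimum sits on
  informative slopes; `ODbi` includes a +2 OD inoculum-carryover floor so
  that specific productivity cannot be gamed by driving biomass to zero.
  Potassium, magnesium, iron and calcium are deliberately null.
  `ODbi` does not depend on methanol or sorbitol (absent pre-induction),
  mirroring the not-applicable entries a real study would report.
* `sensitivity_oracle()` — same nine factors, two objectives, but only pH
  and glycerol enter the responses; the benchmark for factor-recovery
  tests, where correct output is "pH and glycerol, nothing else".
* `tiny_oracle()` — two 3-bit factors, one bell-shaped objective, 64 grid
  points: small enough to enumerate exhaustively, which is what lets tests
  compare the GA against brute force.

At construction each oracle normalizes its objectives over the
representable grid (exact enumeration up to 65 536 points, otherwise a
4096-point fixed-seed sample) and locates the grid condition maximizing
the weighted composite by exhaustive search or multi-start coordinate
ascent — the declared `true_optimum()` that recovery tests measure
against. What the oracles do *not* emulate: time-course dynamics, batch
effects between generations, heteroscedastic instrument floors, or factor
interactions mediated by latent state (pH drift, O₂ limitation). Passing
tests therefore show the machinery recovers known structure under
CV-stable noise — not that any particular real fermentation behaves like
the oracle.

## Problem sizes used by the test suite

Unit tests run in seconds. The end-to-end studies use: GA-vs-brute-force
on the 64-point tiny oracle (N = 6, 10 generations, 20 seeds, mutation
0.9 as derived above); diagnostics on the case-study oracle (N = 16,
5 generations, 20 seeds, mutation 0.1); SR recovery of
$y = 3x_1 + 2x_1x_2 - x_3$ on 64 noiseless rows (population 200, 100
generations, best of 10 seeds); the SR-vs-MLR comparison on an 8×8 pure
interaction grid (10 repetitions, 3-model batches); and sensitivity
recovery on the two-driver oracle (5 pipeline runs: 5 GA generations,
then a 10-model batch per objective at population 100 × 60 generations).
The GP budget scaling check compares (50, 50) against (500, 500) on the
recovery target over 3 seeds.

## Known limitations

* The GA guarantees no global optimum; with small populations the search
  can settle on a local mode, which is why the diagnostics emphasize
  occupancy footprints over a single winner, and why a fine-tuning round
  around the footprint levels is good practice.
* Per-generation score normalization makes scores incomparable across
  generations in absolute terms; cross-generation curves (trajectories,
  RSD) should be read as within-cohort statistics, which is how the
  termination heuristics use them.
* Categorical factors, mixed-radix encodings, multi-point crossover,
  adaptive mutation and Sobol-style global sensitivity are out of scope.
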