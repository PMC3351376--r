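---
title: "The population state model: detecting adaptive events in fluorescence-tracked evolution experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The population state model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertpsm)
```

## The problem

In a VERT (Visualizing Evolution in Real Time) experiment, several isogenic
microbial subpopulations, each carrying a different neutral fluorescent
label, compete in a chemostat (or serial-batch culture) under a selective
pressure for hundreds of generations. When a beneficial mutation arises in
one labeled subpopulation, that subpopulation expands at the expense of the
others; FACS measurements of the label proportions, taken roughly daily,
make the expansion visible as a rising proportion trajectory. Each such
sustained expansion — an *adaptive event* — marks the presence of an
adaptive mutant that the experimenter may want to isolate from frozen
samples.

`vertpsm` automates the two judgment calls an experienced user would
otherwise make by eye: *when* is a subpopulation undergoing an adaptive
event, and *which* archived sample contains the mutant at its highest
frequency.

## Model overview

The analysis has two layers.

**Statistical classifier.** Raw counts $x_{ji}$ for subpopulation $j$ at
sample $i$ are normalized to
$P_{ji} = \dfrac{x_{ji}/\sum_j x_{ji}}{x_{j0}/\sum_j x_{j0}}$, so every
trajectory starts at 1 regardless of seeding proportions. With $t_i$ the
generations elapsed at sample $i$, the expansion rate over an interval is
$r_{pe,ij} = (P_{ji} - P_{j,i-1})/(t_i - t_{i-1})$ (units 1/generation;
sampling need not be evenly spaced). Neutrality experiments — control runs
in which no adaptive events are expected — supply the mean $\mu_r$ and
standard deviation $\sigma_r$ of neutral slopes over $n$ pooled
measurements. Each observed slope is then tested with

$$T = \frac{r_{pe,ij} - \mu_r}{\sigma_r / \sqrt{n}}$$

against Student's $t$ with $n-1$ degrees of freedom (a Gaussian variant is
available for large calibration pools). Slopes rejected at level $\alpha$
become emission symbols **P** (positive) or **N** (negative) by the sign of
$r - \mu_r$; everything else is **Z**. The default is $\alpha = 0.10$,
single-tailed critical value, strict inequality (a slope exactly at the
critical value is not rejected — a conservative, deterministic tie rule).

**Hidden Markov layer.** A two-state HMM — **A** (adaptive event in
progress) and **N** (not) — generates the symbols with per-state emission
distributions $e_A$, $e_N$ and switching probabilities that decay with the
current run of like symbols:

$$P_{AN} = P_{AN}^\circ e^{-C_P}, \qquad P_{NA} = P_{NA}^\circ e^{-C_{!P}},$$

where $C_P$ counts contiguous preceding P symbols and $C_{!P}$ contiguous
N/Z symbols; each counter resets when a symbol outside its set arrives, so
at most one is ever positive. $P_{AA}$ and $P_{NN}$ are the complements of
the *penalized* values. The decay encodes the biology that an expansion
which has survived drift keeps expanding non-randomly for a while; it is a
deliberate departure from a time-homogeneous chain. The shipped defaults
($P_{AN}^\circ = 0.154$, $P_{NA}^\circ = 0.079$,
$e_A = (0.102, 0.150, 0.748)$ and $e_N = (0.434, 0.337, 0.229)$ over
(N, Z, P)) were obtained by supervised training on annotated multicolor
yeast glucose-limited chemostats and can be retrained for any new system
with `train_supervised()`.

## Decoding: why Viterbi, and the greedy alternative

Because the run counters depend only on the emission symbols — never on the
hidden path — the penalized transition matrix at every step is known before
decoding begins. Decoding is therefore a standard Viterbi recursion with
per-step transition matrices, initialized in state N (nothing expands at
inoculation). `decode_states()` implements exactly that, and the test suite
checks it against an independently written path-pruning trace and against
exhaustive enumeration of all $2^n$ paths on short sequences.

A tempting simplification is a *greedy* forward rule: keep one path and, at
each step, compare $P_{ll}\,e_l(O_i)$ (stay) with $P_{lm}\,e_m(O_i)$
(switch). With the shipped parameters this rule is degenerate: the stay
term dominates the switch term pointwise for *every* symbol
($P_{NN}e_N(S) > P_{NA}e_A(S)$, e.g. $0.921 \times 0.229 = 0.211$ versus
$0.079 \times 0.748 = 0.059$ for S = P), so a greedy path never leaves N
and detects nothing. Only path-level likelihood accumulation — several
consecutive P symbols each multiplying the A-branch by
$\approx e_A(P)/e_N(P) = 3.3$ — makes entering A worthwhile. The greedy
rule is retained as `decode_states(..., method = "greedy")` for study, with
this degeneracy documented.

**Back-shift.** Decoded states are translated one position earlier
(`states[k] <- states[k+1]`, last duplicated), an empirical alignment
correction: the slope into sample $k{+}1$ carries information about the
state already in force at sample $k$. Throughout the package, sequence
index $k$ (1-based, length $n-1$) attaches to time point $k{+}1$; decoded
states are compared with annotations at points $2..n$, and supervised
training pairs the emission over $(k, k{+}1)$ with the annotation at point
$k$ — the exact inverse of the back-shift, so a trained decoder reproduces
its training annotations.

## Training, events, sampling, statistics

`train_supervised()` estimates all six free parameters by counting
transitions and per-state symbol frequencies in annotated histories, with a
Laplace-style pseudocount (default 0.5) so that small annotated sets cannot
yield zero probabilities. The `columns` argument restricts training to
named subpopulations; this matters for simulation-based validation (below)
and for excluding unlabeled reference pools.

`extract_events()` reports maximal runs of decoded A per subpopulation.
`suggest_sampling_points()` implements the isolation heuristic: from each
event's end, scan that subpopulation's emissions forward to the first
**N** symbol at position $i$ and suggest $i-1$ — the sample just before the
subpopulation begins to contract, where the mutant's frequency should peak.
If no N occurs (the mutant overran the vessel), the final sample is
suggested; a suggestion that would precede the event's start is clamped to
the event's end.

`compare_annotations()` pools TP/TN/FP/FN fractions against human
annotation (these measure model–annotator agreement, not truth).
`summarize_dynamics()` reports adaptive events per generation per color,
the mean expansion rate inside events, and event lengths; lengths are in
sampling points, the scale on which events are decoded, with a
per-generation variant alongside. `event_distribution()` gives each
subpopulation's length-weighted share of events — replicated bias toward
one label suggests a jackpot mutant or a non-neutral fluorophore.

## The synthetic generator

`simulate_experiment()` emulates the observable of a VERT experiment:
relative lineage competition (residents at fitness 0, planted mutants at
fitness $s$ per generation, logistic frequency dynamics arising from
normalization), FACS observation as a multinomial draw of the configured
total count, and Gaussian jitter on the observed proportions. Ground truth
marks a subpopulation A while a mutant is above a detectability threshold
within its host (default 5% — below that no slope signal exists at
realistic noise) and still gaining at least `min_gain` (default $10^{-3}$)
population-wide frequency per generation. Defaults — 3 labels, 30 samples,
10 generations per sample, $10^5$ FACS events, proportion noise 0.005 —
mirror a daily-sampled chemostat run of ~300 generations.

It deliberately does **not** model mechanistic resource competition,
clonal interference between concurrent mutants beyond exponential
competition, mutation accumulation, or FACS spectral artifacts. Passing
tests on this generator therefore demonstrate correctness of the inference
machinery under idealized sweep dynamics, not performance on every real
dataset.

`simulate_annotated_histories()` drives validation of training: hidden
chains and symbols are drawn from given model parameters, then count data
is constructed that the classifier maps back onto exactly those symbols.
Proportion data is compositional (initial-fraction-weighted slopes sum to
zero at every step), so independently drawn signal trajectories cannot be
realized as counts alone; each history carries a balancing `reference`
column, annotated N and excluded from training via `columns`. Significant
slopes are placed at $\pm 0.012$ with small jitter and null slopes well
inside the acceptance band, comfortably clear of the default threshold
($\approx 0.0029$ at $\sigma_r = 0.018$, $n = 64$, $\alpha = 0.10$).

## Numerical and design choices

* **$n$ in the $T$ statistic** is the calibration sample size (64 for the
  shipped calibration), and degrees of freedom are $n-1$.
* **The classifier is deliberately liberal.** Dividing a *single* slope's
  deviation by the standard error of the calibration mean
  ($\sigma_r/\sqrt{n}$) rejects far more often than $\alpha$: for neutral
  slopes of scale $\sigma_r$ the rejection rate is
  $\approx P(|Z| > t_{1-\alpha,n-1}/\sqrt{n})$ — about 87% at $n = 64$ and
  higher for larger pools, as the acceptance script measures on simulated
  neutral data. This is a property of the published procedure the package
  reproduces, not a bug: the non-adaptive state absorbs the resulting P/N
  chatter through its emission distribution ($e_N$ is nearly flat), and the
  HMM layer, not the classifier, supplies the specificity. Consequently
  $e_N$ trained on one instrument reflects that instrument's noise scale
  and should be retrained together with the calibration.
* **Calibration is pooled** across fluorophores by default; per-label
  calibration can be done by calling `calibrate_neutral()` on single-column
  rate series if labels differ in fitness cost.
* **Counters are capped at 50** before exponentiation; $e^{-50}$ is zero
  for any decision, so this is numerical hygiene only.
* **Ties** in the Viterbi argmax are broken deterministically (first state
  in (A, N) order); exact ties have measure zero for generic parameters.
* **Missing count cells are an error** — there is no defensible imputation
  rule for FACS dropouts at this layer.
* **Zero-variance calibrations are refused** explicitly rather than
  producing infinite $T$ values.
* **Problem sizes in the tests and acceptance script** — $10^4$ neutral
  intervals for the rejection-rate measurement, $10^4$ annotated points for
  parameter recovery, 1,000 random sequences (length ≤ 50) for the decoder
  cross-check, three fixed-seed sweep simulations for end-to-end recovery —
  were chosen so the whole suite runs in seconds while leaving Monte-Carlo
  error well below the tolerances tested.

## Limitations

* Supervised training inherits annotator bias; the shipped parameters come
  from one yeast system and may transfer imperfectly to other species,
  pressures, or mutagenic regimes.
* Slow expansions whose slopes stay below the significance threshold
  (roughly $< 0.003$ per generation at the shipped calibration) are
  invisible to the classifier and hence to the model.
* Unsupervised (Baum–Welch) training, more than two hidden states, and
  continuous-time observation models are out of scope.
* The statistical test for jackpot-biased event distributions is not
  implemented; `event_distribution()` provides the descriptive quantity
  only.
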