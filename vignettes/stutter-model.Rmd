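---
title: "Modelling in vitro STR stutter as a discrete-time Markov chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling in vitro STR stutter as a discrete-time Markov chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strstutter)
```

## The problem

Short tandem repeats (STRs, microsatellites) mutate in vitro during PCR:
polymerase slippage contracts or — less often — elongates the repeat tract,
so sequencing an amplified locus yields a *repeat-number histogram* with
satellite ("stutter") peaks around the true allele instead of a clean peak.
For highly mutable mono- and dinucleotide repeats, and especially after the
extensive amplification that single-cell work requires, the stutter signal
can dwarf the allelic signal, and naive highest-peak genotyping fails.
`strstutter` models the stutter process explicitly and genotypes by matching
measured histograms against model-predicted stutter patterns.

## The model

Let $n \ge 1$ be the repeat number of a molecule. One PCR cycle is modelled
as one step of a discrete-time Markov chain on $n$ with the
**Linear1up3dw** kernel: in a single cycle a tract can elongate by one unit
or contract by one, two or three units, each with probability linear in the
current length,

$$p_{+1}(n) = a_{+1} n + b_{+1}, \qquad
  p_{-k}(n) = a_{-k} n + b_{-k}, \quad k \in \{1,2,3\},$$

and stays unchanged with the remaining probability. This captures the two
classic empirical regularities of slippage — longer tracts are more mutable,
and contraction dominates elongation — with eight coefficients per repeat
class (A, C, AC, AG, AT; classes never share parameters).

Normalisation rules (`step_distribution()`):

* each evaluated probability is clamped to $[0,1]$;
* if the four mutation probabilities sum above 1 they are rescaled to sum
  exactly 1 and the stay probability is 0;
* contractions that would drop the length below one repeat are redirected to
  the largest feasible contraction (to "stay" at $n = 1$).

The clamp-then-rescale order and the boundary redirection are implementation
choices; they only matter far outside the calibrated regime, where the
linear forms are extrapolations anyway.

`predict_histogram()` propagates a point mass at the designed length $n_0$
through $t$ kernel steps: $H_{\text{model}}(t, n_0) = \delta_{n_0} K^t$.
At $t = 0$ this is the perfect-synthesis assumption — the synthesised,
sequence-verified construct carries exactly its designed length. The state
space is truncated to the reachable range plus a 5-state margin; transitions
that would exit it are folded onto the boundary state so that every row of
the kernel sums to exactly 1 (mass conservation makes the probability
bookkeeping in tests exact rather than approximate). Cycle counts are
nonnegative integers throughout: a fractional kernel application has no
process semantics.

Competitor one-cycle models can be registered through
`register_stutter_family()` and then drive every downstream operation; only
`Linear1up3dw` ships with a concrete functional form.

## Comparing histograms

Calibration and genotyping both reduce to a histogram distance. The default
is $d(H_1, H_2) = 1 - r(H_1, H_2)$ with $r$ the Pearson correlation of the
two histograms aligned on the **union** of their supports (zero-filled where
a histogram lacks a bin, no padding beyond observed bins — identical
zero-padding on both sides would inflate the correlation). The metric is
scale invariant, so raw counts and frequencies are interchangeable.
Chi-square, Euclidean and total-variation distances are available behind the
same interface.

A constant aligned vector makes the correlation undefined. The convention
here: positively proportional pairs — including two identical single-bin
histograms — score 0, any other constant-vector pair scores the
"no-information" midpoint 1.0, and either case is flagged as degenerate.
Scoring an identical pair 0 keeps $d(h,h) = 0$ unconditionally (a
zero-cycle prediction against a clean unamplified measurement must be a
perfect match, or the calibration objective could never reach zero), while
the 1.0 sentinel keeps the optimiser finite and marks single-bin comparisons
as uninformative rather than perfect.

## Calibration

Given measured histograms $H_{\text{seq}}$ for a panel of designed lengths
$l$ at amplification time points $t$, the per-class parameters minimise

$$\frac{1}{n}\sum_{l}\sum_{t}
  d\!\left(H_{\text{model}}(t, l),\, H_{\text{seq}}(t, l)\right)^2,$$

the mean squared distance over the $n$ retained records
(`calibration_objective()`). Records whose fraction of reads at exactly the
designed length falls below 5% are excluded first
(`filter_calibration()`): once the designed signal is that eroded, the
measurement is noise-dominated.

Time points map to effective cycle counts. The default fixed mapping is
`T1 = 0` (direct sequencing, no PCR), `T2 = 17` (one 17-cycle indexing
PCR) and `T3 = 47` (a 30-cycle PCR nested inside the same 17-cycle indexing
PCR). Sequencing itself adds noise even at `T1`, and effective cycles may
exceed nominal ones, so `fit_stutter_model(cycles_mode = "free")`
additionally searches integer cycle counts per time point on a user-supplied
outer grid (zero-cycle time points stay pinned) with the continuous fit
nested inside.

The continuous fit is quasi-Newton (BFGS) on the eight coefficients,
optimised in per-coefficient scale units (slopes $\sim 10^{-4}$, intercepts
$\sim 10^{-3}$) so the finite-difference gradient is well conditioned. The
objective is nonconvex and, near its optimum, extremely flat (quartic-like
in the residual), so the local optimiser is restarted from eight seeded
random initialisations around a small-positive prior plus two deterministic
starts: the supplied `init` and a **method-of-moments warm start** — at low
mutational dose the $k$-step satellite peak after $t$ cycles holds roughly
$t\,p_k(n_0)$ of the mass, so satellite fractions at the earliest amplified
time point, regressed against designed length, land the slopes and
intercepts near the correct basin. The best start is then polished with a
Nelder–Mead pass followed by a final BFGS run, which crosses the flat
valley floor that stalls pure gradient steps. Non-convergence returns the
best-so-far result with `converged = FALSE` rather than an error.

No uncertainty quantification is attached to the coefficients; the
calibration is a point fit.

With the genotype known, `fit_simulated_cycles()` inverts the model in the
other direction: the integer cycle count whose prediction best matches a
measured histogram. This "simulated cycles" readout is the model's single
degree of freedom for comparing amplification conditions — enzymes,
template dilutions, protocols — and is deliberately *not* identified with
wall-clock PCR cycles (see the branching-process section).

## Genotyping

`genotype_mono()` implements an exhaustive nearest-predicted-pattern call:

$$\hat{(t, l)} = \arg\min_{t, l}\,
  d\!\left(H_{\text{model}}(t, l),\, H_{\text{seq}}\right),$$

over a cycle grid (default 0–60) and allele range (default 5–60 repeats,
covering mono/di-repeat panels and two nested PCRs). Histograms with fewer
than 5 raw reads are refused (`low_coverage`) — below that the histogram
shape is meaningless. Ties break deterministically toward smaller $t$, then
smaller $l$ (the least-noise, shortest-allele explanation).

`genotype_biallelic()` extends the search to unevenly amplified
heterozygous loci: candidates are overlays
$p\,H_{\text{model}}(t, l_1) + (1-p)\,H_{\text{model}}(t, l_2)$ over all
pairs $l_1 \le l_2$ (homozygous pairs included, so pure signals collapse)
and proportions $p \in \{0.1, 0.2, \dots, 0.9\}$. No allele pair within the
range is excluded. Ties break toward smaller $t$, then smaller
$|l_2 - l_1|$, then smaller $l_1$. Predictions are cached per $(t, l)$
(`genotyper_cache()`), making each mixture a linear combination of two
cached vectors; the search is $O(|t|\,|l|^2\,|p|)$ distance evaluations.

The optimum distance doubles as the call's raw confidence score.
`rank_confidence()` converts it to a batch percentile (0 = best) — a
deliberately minimal confidence metric: monotone, already computed, and
directly comparable across tools via percentile thresholds.

## Validating against a known lineage tree

When cells come from an experiment whose lineage tree $T$ is known, calls
can be scored without per-locus ground truth. For the multiset $A$ of
alleles assigned to genotyped cells,

$$F(T, A) = |A| - 1 - P(T, A) - D(A),$$

where $P$ is the small parsimony of the assignment on $T$ (minimal number
of allele-change events; Sankoff dynamic programming on the rooted
topology after pruning unassigned leaves) and
$D(A) = \sqrt{\sum_a (\#_a A - 1)^2}$ the allele diversity, which
compensates for the fact that diverse loci inherently need more mutations
even when called perfectly. $F$ is calibrated so that both uninformative
extremes — one allele shared by all $m$ cells ($P = 0$, $D = m-1$) and all
alleles distinct ($P = m-1$, $D = 0$) — score exactly zero; loci supporting
the topology score positive, contradicting loci negative.

Two interpretation choices are pinned down here. $|A|$ is the *multiset*
size (number of genotyped cells) — the only reading under which the
single-shared-allele case is exactly zero. Mutation cost is unordered (any
allele change costs 1), matching a count of mutation *events*; a
`"stepwise"` cost weighting changes by repeat difference is exposed for
sensitivity analysis. `batch_tree_fitness()` uses monoallelic calls only:
the metric is designed for haploid/hemizygous loci, where a call is a
single allele per cell.

## The branching-process simulator

`simulate_pcr()` is the package's synthetic-data generator and Monte-Carlo
oracle. It simulates PCR at the molecule level: each cycle every molecule
is copied with probability `efficiency`; each *new* copy mutates once
according to the one-cycle step distribution at its template's length;
templates persist unchanged. After $t$ cycles, `reads` molecules are
sampled — exactly, by sequential multivariate-hypergeometric draws, when
the population allows; with replacement (and flagged) otherwise. Everything
is reproducible per seed, and every run carries an audit record with the
true final population. Expected growth is
`initial * (1 + efficiency)^cycles`; beyond $10^8$ molecules the simulator
stops and points to `simulate_pcr_distribution()`, which propagates the
*expected* length distribution of the branching process exactly via
$v_{t+1} = (v_t + e\,v_t K)/(1+e)$ (at $e = 1$, the binomial mixture
$\sum_k \binom{t}{k} K^k / 2^t$).

The simulator is deliberately richer than the predictor. The Markov-chain
predictor applies one kernel step per cycle to the *whole* population; in
the branching process only newly synthesised molecules acquire slippage, so
a random final molecule has undergone about $t\,e/(1+e)$ synthesis events —
half of $t$ at full efficiency. Consequences, both quantified by the test
suite and the acceptance script:

* at *matched* cycle counts the predictor overstates the mutational dose
  roughly twofold, and the total-variation gap between $K^t\delta_{n_0}$
  and the branching output grows with dose — at the package's
  calibrated-scale parameters it is far from negligible;
* the model family still matches the branching output almost exactly at
  its *best-fitting* simulated cycle count, and fitted simulated cycles are
  linear in true cycles (slope $\approx e/(1+e)$), which is precisely why
  "simulated cycles" is treated as an abstract noise coordinate rather than
  a physical cycle count.

In other words, calibrated parameters are *effective* per-cycle rates under
the whole-population convention; the same convention is used in
calibration and genotyping, so the factor cancels everywhere except when a
cycle count is interpreted literally — which the package never requires.

## Generator defaults (the study conditions)

The synthetic studies use, once and throughout:

* **Kernel coefficients** (`default_stutter_params()`): for dinucleotides,
  `up_slope = 2e-4`, `down_slope_1 = 1e-3`, `down_slope_2 = 2e-4`,
  `down_slope_3 = 5e-5`, intercepts 0 — a per-cycle total mutation
  probability of ≈2.5% at 20 repeats, a realistic magnitude for highly
  mutable dinucleotide tracts under high-fidelity polymerases, and heavy
  enough that a two-PCR protocol visibly erodes the designed peak.
  Mononucleotides use twice these slopes (short-unit tracts are the most
  slippage-prone); AT reuses the dinucleotide scale doubled but is known to
  follow a distinct, poorly Markovian stutter pattern in practice — AT fits
  should be treated as descriptive, not predictive.
* **Calibration panel**: class AC at designed lengths 15/25/35 and time
  points `T1 = 0`, `T2 = 17`, `T3 = 47` cycles — three lengths spreading
  the linear forms, three doses spanning none-to-heavy stutter. Noiseless
  mode scales exact model predictions to the read depth (for parameter
  recovery); sampled mode runs the branching simulator at efficiency 0.25
  (a 47-cycle run from 1000 molecules stays inside the population guard,
  emulating strongly plateau-limited amplification).
* **Recovery studies**: monoallelic — 200 histograms of 500 reads at 30
  true cycles, efficiency 0.5, alleles 15–30; biallelic — 100 mixtures of
  1000 reads with allele separation ≥ 4 repeats and proportions
  0.2/0.5/0.8; cycle-linearity — templates of 20/25/30 repeats at true
  cycles 10/20/30. These sizes keep the complete suite in the minutes
  range while leaving the binomial error of a 95% recovery estimate near
  one percentage point.

What the generator emulates: length-dependent contraction-biased slippage,
amplification efficiency and plateau, read subsampling, uneven two-allele
mixtures. What it does not: flank sequence errors, point mutations within
the repeat, chimeric reads and primer artefacts, the AT anomaly, and any
locus-specific sequence context. Passing the recovery studies therefore
demonstrates correctness of the method under its own model class plus
branching/sampling noise — not performance on real single-cell libraries.

## Reading repeat numbers from reads

`reads_to_histograms()` reproduces the minimal amplicon pipeline feeding
the genotyper: a merged read is assigned to a panel locus when its two
edges match the locus flanks within 2 substitutions each (ambiguous or
unmatched reads are QC-tallied, not errors), and its repeat number is the
$k$ maximising the global alignment score of the read against
`left_flank + unit^k + right_flank` over the search range. Scoring is
match +1, mismatch −1, gap −2 (via `Biostrings::pairwiseAlignment`) — with
these scores a single whole-unit indel always shifts the best $k$ by
exactly one on error-free flanks. Ties break toward the designed length,
then the smaller $k$; scores below 60% of the read length are no-calls.
Panel design enforces that flanks do not begin or end with a partial repeat
unit, which would make the tract boundary ambiguous. Read merging, quality
scores and genome-wide mapping are out of scope.

## Numerical conventions

* Probability vectors and kernel rows sum to 1 within 1e-9 (exactly, up to
  floating point, by construction); frequency normalisation within 1e-9.
* Support margin: 5 states beyond the reachable range.
* Degenerate distances: proportional → 0; otherwise 1.0 sentinel; flagged.
* Tie-breaks are always deterministic and documented per operation, so
  every pipeline is a pure function of (inputs, configuration, seed).
* Optimiser: BFGS with `reltol = 1e-12`, 500 iterations per start,
  Nelder–Mead polish of 4000 iterations; coefficients scaled as above.

## Known limitations

* The whole-population cycle convention means simulated cycles are an
  effective coordinate, not physical cycles (see above).
* AT repeats are fitted with the same family but are known not to follow
  it well.
* Only two-allele mixtures are modelled; copy-number states beyond two are
  out of scope.
* Confidence is a within-batch percentile of the fit distance, not a
  calibrated probability.
* Parsimony cost is unordered by default; stepwise weighting is available
  but the metric's zero-calibration points are derived under the unordered
  reading.
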