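---
title: "Encoding and decoding task variables from spike trains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding and decoding task variables from spike trains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeglm)
```

## The scientific problem

Neurons in associative sensory areas are rarely pure feature detectors:
a single cell's firing can be modulated jointly by a stimulus, the
animal's movements, anticipation of reward, and spatial context. This
package implements a complete, testable pipeline for quantifying such
*mixed selectivity* in trial-based recordings from a go/no-go
virtual-corridor task: a head-fixed mouse runs down an 83-cm aisle into a
33-cm visual context zone, receives a 1-s odour pulse at context entry,
and licks (GO) or keeps running (NO-GO); only the rewarded odour in the
rewarded context pays out. Because event timing is under the animal's
operant control, the relative timings of inhalations, licks and position
vary across trials, and this variability is what lets a regression model
disentangle the rate modulations attached to each variable.

## The encoding model

Spiking is binned at $\Delta$ = 10 ms and modelled as an inhomogeneous
Poisson process whose rate is a product of per-variable gains:

$$\lambda_t = \exp\Big(\sum_i (k_i \otimes x_i)_t\Big), \qquad
r_t \sim \mathrm{Poisson}(\lambda_t \Delta),$$

where each kernel $k_i$ acts on its variable's time course $x_i$ by
convolution. Two kinds of regressors are used:

* **Event kernels** — a delta train at event times convolved with the
  kernel: all inhalation onsets (10 basis functions over 460 ms), odour
  inhalations split by odour identity (10 over 460 ms each), licks
  (15 over 360 ms), reward-consumption licks (15 over 360 ms), an
  anticipatory kernel spanning the 2000 ms *before* the first post-odour
  lick (22 bases, acausal), and odour-by-context interaction kernels
  triggered by the first odour inhalation only in rewarded-context trials
  (20 over 1500 ms each).
* **Tuning kernels** — one-hot occupancy vectors weighted by bumps over
  the value grid: position along the corridor in 4-cm bins (42 bases per
  context, each context kernel active only in its own trials) and running
  speed in 1-cm/s bins up to the session maximum.

Kernels are parametrized by raised-cosine bumps with linearly spaced
centres, the first and last centre at the support edges and a half-width
of twice the centre spacing, so the bumps sum to a constant on the
interior of the support; this makes a flat kernel exactly representable
and keeps each coefficient interpretable as a local gain. A bias column
of ones sets the baseline log-rate. Eight *variables* enter model
selection; the odour, interaction and context variables each carry a pair
of kernels that are added or removed together.

## Fitting, regularization, selection

Weights are fit by maximizing the ridge-penalized log-likelihood
$L(k) = \sum_t [r_t \log(\lambda_t\Delta) - \lambda_t\Delta] -
\xi\lVert k\rVert^2$ with Newton ascent and step halving (tolerance: the
largest gradient entry below $10^{-6}\times$ the spike count; at most 200
iterations; the objective is concave, so the optimum is unique and the
recorded objective trace is non-decreasing). The bias is excluded from
the penalty: penalizing it would bias the recovered mean rate, and the
smoothness prior is meant for the kernels.

The ridge strength is chosen by maximizing the Laplace-approximated
marginal likelihood over a grid (13 log-spaced points from $10^{-2}$ to
$10^4$) on all trials at once. The evidence is evaluated once per neuron
on the full eight-variable model and the selected $\xi$ is reused for
every candidate in the forward search; evaluating it per candidate would
multiply the cost of the search by the grid size while changing $\xi$
little, because the dominant, strongly driven kernels are shared across
the candidates that matter.

Model performance is the held-out log-likelihood under 10-fold
cross-validation, with trials (never bins) assigned to folds by a seeded
uniform partition and each fold's log-likelihood normalized by its spike
count. Forward selection starts from the best single-variable model and
keeps adding the best extension while the paired one-sided Wilcoxon
signed-rank test across the ten folds (exact distribution; read as a
paired test, since fold performances are paired by construction) is
significant at 0.05; a neuron whose best model never beats the
constant-rate model is labelled not modulated. Ties in mean fold
performance break towards the candidate with fewer basis coefficients.
The final model is refit on all trials.

## Contributions, decoding, population structure

A variable's **contribution** is the spike-normalized log-likelihood it
adds over the selected model refit without it (a full refit, not a
weight-zeroing), restricted to the bins where its kernels were active,
in bits per spike; the normalizer `log(2) * (1 + spikes in mask)` guards
empty masks. Relative contributions (the per-neuron profile used for
clustering) divide by the summed contributions; profiles with
non-positive sums are refused rather than silently rescaled.

**Decoding** of a binary variable compares the data's likelihood under
two counterfactual designs that differ only in that variable's category,
accumulating the log-likelihood ratio over bins from trial start; the
sign decodes the category, population evidence is the sum over neurons,
and the equal-prior posterior is the logistic transform of the LLR.
Accuracy is reported against evaluation time (aligned to the first odour
inhalation) and against pseudopopulation size (sampling without
replacement, 50 repeats by default, trial counts matched across
categories by seeded down-sampling, with a label-shuffle control).
"Only-odour" ablation zeroes all non-kept kernel weights while keeping
the bias, matching the idea of removing modulations from an already
fitted model rather than refitting. An independent linear route
(L2-regularized logistic regression on window-averaged responses with
3-fold cross-validation) decodes odour identity without using the GLMs.

**Population analyses** include Gaussian-smoothed event PSTHs (s.d.
30 ms, reflection padding), stitched full-trial PSTHs that average
overlapping aligned segments, Pearson similarity of population activity
vectors, SVD-based condition-averaged trajectories, and a decomposition
of the total trial-averaged variance into residual trial noise and
signal. For the noise term, the per-neuron residual sum of squares is
divided by the per-condition trial count and rebalanced by the neuron's
mean trial count, so sequentially recorded neurons with different trial
counts pool without imputation; the per-neuron noise statistic is
averaged over conditions and scaled back by the number of
condition-time cells, the only dimensionally consistent reading of the
printed formulas (a literal reading would double-count the condition
grid and could exceed the total variance on pure-noise data — our null
simulation with independent Poisson trials gives a signal fraction near
zero, and noise-free input gives exactly 100%).

**Clustering** groups neurons by the correlation distance
($1 - r$) between relative-contribution profiles under UPGMA linkage,
cutting the tree at a height threshold and discarding clusters smaller
than 3. The threshold is selected by split-half generalisability: trials
are halved, models refit per half, each half clustered, test-half
profiles assigned to the nearest train-half centroid (the same
correlation distance as the clustering, keeping the pipeline
metric-consistent), and the upper triangles of the resulting
co-membership matrices correlated; both directions are averaged and the
control permutes the test partitioning. One property of this score is
worth knowing: on independent halves with no shared per-neuron
structure, it does not center at zero but carries a small positive bias
(about 0.15 in our null simulations), because any tight group of test
profiles both co-clusters in the test partition and co-assigns to a
common train centroid whatever the train half contains. The permuted
test partitioning is the proper near-zero null, which is why it is the
control this package (and the score's originators) report. Profiles are
embedded for display with Kruskal's non-metric MDS (stress-1) on
Euclidean distances.

## The synthetic-session generator

Every stage is testable without recordings because the generator
produces full sessions with known ground truth. It emulates: the four
odour-by-context trial types (equal probabilities by default); corridor
running with across-trial speed variability (mean 30, s.d. 6 cm/s) and
within-trial jitter; inhalations as a gamma renewal process (baseline
3 Hz, rising to 5 Hz in the second before a rewarded-context entry under
the expert policy, emulating anticipatory sniffing); odour delivery at
context entry with a guaranteed odour inhalation within the pulse;
behavioural policies (expert: P(GO) = 0.95 in rewarded trials, 0.05
otherwise, matching a d' of 3.29 at the standard correction;
first-session: 0.8 everywhere); lick bouts at 7 Hz with reward delivered
at the second lick of a HIT and 1 s of consumption licking; and Poisson
spiking from kernels drawn exactly in the basis span with peak log-gains
around 1 (multiplicative gains roughly 0.4–2.7). The inter-trial
interval is a 0.5-s gap carrying no regressor bins, so kernels never
span trial boundaries.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes spike-history dependence and
refractoriness, non-Poisson count dispersion, slow drifts in rate or
behaviour within a session, correlated noise across neurons, and
imperfect spike sorting. The generator's role is to verify the
estimator against its own assumptions, exactly the logic of
simulation-based validation of the fitting and selection machinery.

## Numerical choices and degenerate inputs

* Time bins are half-open `[t, t + 10 ms)`, 0-based within trial;
  position bins are half-open 4-cm intervals. Events within one bin of a
  trial edge are truncated, not dropped.
* Rates are computed through a clamped linear predictor
  (`exp(min(eta, 40))`); simulation refuses bins whose expected count
  exceeds $10^6$ and names the offending bin.
* Inhalation detection smooths with a second-order Savitzky–Golay filter
  in 100-ms frames, detrends by a reflection-padded 1-s running median,
  and takes negative-going zero crossings before peaks below 0.5 median
  absolute deviations of the detrended trace (a threshold expressed in
  MADs cannot exceed ~0.95 for periodic breathing, since a sinusoid's
  MAD is about 1.05 times its amplitude); the minimum onset spacing is
  50 ms. Flat traces yield zero onsets; NaNs are errors.
* Hit/false-alarm rates of exactly 0 or 1 receive the standard
  $1/(2N)$ correction before the inverse-normal transform, which
  requires trial counts; bare extreme rates are refused.
* Zero-variance profiles, empty contribution masks, unvisited position
  bins and zero-spike folds are flagged (error, warning or `NA`)
  rather than silently imputed.
* The signed-rank test falls back to the normal approximation when ties
  make the exact distribution unavailable; identical fold vectors give
  p = 1.

## Problem sizes used by the test suite

The shipped tests run the estimator at desk scale, chosen so the suite
completes on a single CPU while leaving the statistical checks
well-powered: kernel recovery uses 30 simulated neurons on one 200-trial
session; decoding checks use 4–6 units on 40–60-trial sessions; the
selection-validity suite runs 50 null neurons and 12 single-variable
neurons on a 40-trial session at a fixed representative ridge (the
zero-variable decision is made by the signed-rank test, not by the
prior); clustering checks operate directly on synthetic
relative-contribution profiles. The same procedures scale unchanged to
recorded sessions.

## Known limitations

* The preGO kernel conditions on the realized first post-odour lick, so
  the model is descriptive, not causal, about anticipation.
* Reward-category decoding needs a counterfactual "rewarded" design for
  trials that had no reward; consumption events are placed at the licks
  following the response event, and trials with no licks carry none.
* Contributions of paired kernels (odour, interaction, context) are
  attributed to the pair as one variable; the pipeline does not split
  credit within a pair.
* The evidence-based $\xi$ is shared across candidate models per neuron
  (see above); per-candidate evidence is a straightforward extension at
  grid-size times the cost.
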