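---
title: "Thermodynamics of stochastic population codes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of stochastic population codes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boltzcode)
library(dplyr)
```

# The model and what the package measures

`boltzcode` studies how a noisy binary population code allocates its coding
space. The encoder is a restricted Boltzmann machine (RBM): a visible layer
`v` of `N_v` binary units driven by stimuli, and a hidden layer `h` of `N_h`
binary units playing the role of a spiking population that must communicate
`v` downstream within one time bin. The joint distribution is energy-based,

$$P(h, v) \propto e^{-\beta E(h,v)}, \qquad
E(h,v) = -B_v^\top v - B_h^\top h - h^\top W v,$$

with energies in nats internally and reported in bits (divide by
$\ln 2$) at every user-facing boundary. Throughout, "energy" is synonymous
with negative log-probability. The inverse temperature $\beta$ multiplies
all parameters (`scale_temperature()` folds it in and returns an equivalent
model at $\beta = 1$, so nothing downstream double-scales); $\beta \to 0$ is
the noisy phase where all states are equiprobable, $\beta \to \infty$ the
frozen phase.

Given a stimulus, the hidden layer is conditionally factorial, which makes
two central quantities exact:

* **Stimulus-conditioned entropy** (`conditional_hidden_entropy()`), the
  channel noise evoked by `v`:
  $H_{h|v} = \sum_j g(a_j) - a_j \sigma(a_j)$ with
  $a = \beta(Wv + B_h)$, $g(x) = \log(1 + e^x)$. This is a sum of per-unit
  binary entropies.
* **Free energy of a stimulus** (`visible_free_energy()`):
  $F(v) = -B_v^\top v - \sum_j g(a_j)$, equal to
  $-\log \sum_h e^{-E(h,v)}$. The identity
  $F(v) = \langle E(h,v) \rangle_{h|v} - H_{h|v}$ holds exactly and is the
  module's central regression test: a well-fit model's $F(v)$ approximates
  the data energy $E_v = -\log P(v)$, so stimuli needing more bits must
  either evoke rarer codewords or less variable ones.

The **codeword energy** $E_h = -B_h^\top h - \sum_i g((W^\top h + B_v)_i)$
is the negative log marginal probability of a hidden pattern up to one
additive constant shared by all patterns. Its conditional expectation
$\langle E_h \rangle_{h|v}$ (`expected_conditional_energy()`) measures how
rare the codewords evoked by `v` are. Because only energy *differences* are
meaningful, reported codeword energies are anchored so the lowest-energy
codeword encountered sits at 0 (the most frequent pattern, found by exact
enumeration for `N_h <= 20` or tracked during conditional sampling
otherwise); the anchor is recorded in the output attributes. Anchoring
shifts intercepts, never slopes.

# The energy-entropy trade-off and how its slope is fit

`energy_entropy_profile()` computes, for every distinct stimulus, its
empirical energy $E_v = -\log_2(\text{frequency})$, its conditional entropy
and its expected codeword energy, then bins stimuli into equal-width $E_v$
bins (default 14, roughly one per bit of the ranges seen in practice;
right edge closed in the last bin). Bin means are frequency-weighted by
default — each *observation* counts equally — with an unweighted option,
since per-stimulus and per-observation averaging are both defensible
readings of a binned scatter.

Four least-squares slopes are reported. Three are fit on bin means
(entropy vs $E_v$, codeword energy vs $E_v$, and energy vs entropy); the
fourth, `energy_vs_entropy_stimulus`, regresses codeword energy on entropy
across the distinct stimuli themselves, frequency-weighted. The distinction
matters and was a genuine design decision. Because both the entropy and the
energy are averaged within bins *defined by* $E_v$, the bin-mean
energy-vs-entropy slope algebraically reduces to the ratio of the two
$E_v$-regression slopes, and we found it unstable under the training
budget: in our Ising experiments it passes through 1 transiently while the
model trains, landing near 0.6 at convergence even when the stimulus-level
relation is sharply 1:1 (slope 1.03, with a constant offset). The
stimulus-level slope is the direct measure of the trade-off — a code at
statistical criticality has codeword energies that track evoked entropies
with unit slope — so onset detection and the acceptance analysis use it,
while the bin-mean slopes drive the model-size trend panels, where only
their sign and ordering matter.

`I_enc` is the frequency-weighted mean of
$\langle E_h \rangle_{h|v} - H_{h|v}$: the average KL divergence between
the stimulus-conditioned and marginal codeword distributions, up to the
shared anchoring constant. It is the vertical offset between the energy and
entropy curves, and becomes constant above the critical model size.

Statistical criticality is cross-checked in codeword space by
`rank_frequency()`: distinct hidden patterns sorted by frequency, with the
log-log slope fit over ranks having at least 5 observations (the sampling
tail below that is dominated by patterns seen once or twice and would bias
the fit). A slope near $-1$ is Zipf's law.

# Fisher information as a criticality diagnostic

The Fisher Information Matrix of an RBM equals the covariance of its
sufficient statistics $(v_i h_j, v_i, h_j)$; `fim_from_samples()` assembles
it from Gibbs-sample moments and `fim_from_moments()` from exact
enumeration on small models. The parameter ordering is a fixed public
convention: weights row-major (hidden row, visible column fastest), then
visible biases, then hidden biases. The FIM is a generalized
susceptibility: `spectrum_sweep()` rescales the model over a grid of
inverse temperatures (each grid point gets fresh samples from the rescaled
model; the FIM is that of the rescaled model with respect to its own
parameters, so the sweep traverses a family of models, not a
reparameterization), and an interior peak of the leading eigenvalue near
$\beta = 1$ indicates the trained model sits at its own phase transition.
Eigenvalues below `1e-5` are truncated from stored spectra. A grid of
fewer than 3 points is rejected since no interior peak is detectable.

Two sensitivity conventions appear in the literature ($w^\top F w$ and its
square root); the package adopts the square root uniformly, so that a unit
eigenvector has sensitivity $\sqrt{\lambda}$ and the $k$-th coordinate
direction $\sqrt{F_{kk}}$. `rank_units()` aggregates the diagonal
sensitivities of each hidden unit's bias and incident weights by root mean
square, breaking ties by unit index; both the leading-eigenvector and
diagonal views are available, and ranking uses the diagonal view. Note that
saturated units have *low* FIM diagonal (their activity barely varies), so
the ranking measures information-geometric importance, not weight norm.

# The synthetic stimulus generators

All inputs are generated in-package; nothing is downloaded.

* `sample_ising()` draws 10x10 (by default) square-lattice Ising
  configurations with periodic boundaries, $J = 1$, $k_B = 1$, mapped to
  bits by $s = (\sigma + 1)/2$. The Swendsen-Wang cluster algorithm is the
  default because it mixes rapidly near the critical temperature
  $T_c = 2/\ln(1 + \sqrt 2) \approx 2.269$ (`onsager_critical_temperature()`);
  a Metropolis sampler targets the same distribution and serves as an
  independent cross-check. One Swendsen-Wang step is one full cluster
  decomposition and flip; one Metropolis step is $L^2$ random single-site
  proposals. Both accept explicit burn-in and thinning (defaults 1000 and
  100); validity is tested against exact enumeration on small lattices and
  against Onsager's magnetization on 10x10.
* `generate_binary_textures()` produces median-binarized smoothed Gaussian
  random fields: a stand-in for binarized grayscale natural images with a
  tunable correlation length, so the dependence of the learned code on
  input statistics can be probed. The median split guarantees per-image
  activation 1/2 up to ties.
* `extract_patches()` cuts circular patches of 13, 21 or 37 pixels
  (integer-offset disks of radius 2, 2.5, 3.5) at uniform random centers,
  in a fixed row-major raster order; lattice sources wrap under the same
  periodic boundaries they were sampled with, image sources require the
  mask to fit.

What the generators do *not* emulate: natural images have heavy-tailed,
scale-free statistics and long-range structure that a single-scale Gaussian
field does not reproduce, and real spiking data have temporal dependencies
outside the synchronous-code setting entirely. Passing tests therefore
demonstrate the encoding phenomena on controlled stimulus ensembles with
known thermodynamics — not that the same quantitative onsets would be
measured on natural images or in vivo recordings.

# Training and sampling conventions

CD1 training (`train_cd1()`) follows a staged learning-rate schedule
(0.2, 0.1, 0.05, 0.01, 5e-3, 1e-3), 8 epochs per stage, minibatch 4 by
default, all overridable. The positive phase uses data-clamped hidden
probabilities; the negative phase is one full Gibbs step with sampled
hidden and sampled visible states and a final hidden-probability step. We
compared a mean-field (probability) reconstruction variant and found it
converged more slowly on Ising patches at small epoch budgets, so the
sampled form is the default. Weights start iid $N(0, 0.01^2)$, biases at 0;
no momentum or weight decay. Non-finite gradients abort with a diagnostic.
Block Gibbs sampling (`gibbs_sample()`) updates hidden then visible, runs
500 chains of iid fair-bit initializations by default, with burn-in 1000
and thinning 150 as the high-accuracy preset. The samplers use a private
deterministic `mt19937_64` stream keyed by the explicit `seed` argument, so
a seed plus parameters fully determines every output independent of R's
global RNG state.

# Numerical choices

* $g(x)$ is evaluated piecewise ($x$ for $x > 30$, $e^x$ for $x < -30$,
  `log1p(exp(x))` between), keeping entropies and energies finite for
  activations up to $|a| = 700$ and beyond.
* Exact enumeration (`enumerate_model()`) is capped at
  $N_v + N_h \le 24$ units and uses a log-sum-exp partition function.
* Conditional codeword sampling needs no chain: the conditional is
  factorial, so draws are exact; Monte Carlo error scales as
  $1/\sqrt{n}$ and is tested to halve appropriately.
* Empirical stimulus energies are left undefined for unseen patterns
  rather than pseudo-counted; only the model-data KL
  (`model_data_kl()`) smooths, with additive pseudocount 0.5 per pattern
  on the union support, since it must compare distributions with
  disjoint tails.
* Equal-width energy bins use `findInterval` with the rightmost edge
  closed; a degenerate (zero-width) range maps all stimuli to one bin and
  slopes are reported `NA` when fewer than two bins are occupied.
* Pearson correlations of constant units are defined as 0 in
  `activity_stats()` (the denominator vanishes; a constant unit carries no
  pairwise dependence).

# Problem sizes used by the test suite

The test suite re-derives every closed form against brute-force oracles on
enumerable models (up to 4 visible and 3 hidden units, 50 random draws),
checks samplers by total-variation distance against enumeration (3x3
lattices, 5-unit joint models), and runs the encoding analyses on
deliberately reduced protocols: 20,000 lattice samples and patches,
hidden-layer families of 5-60 units trained at 3 epochs per schedule stage
with minibatch 8, 2,000 conditional samples per stimulus for profile
estimation, and 20,000 Gibbs samples per inverse temperature for FIM
sweeps (500,000 for the single high-accuracy FIM comparison). These sizes
were chosen so the full suite exercises every pipeline stage at
Monte-Carlo accuracies matched to the tolerances asserted; the package
defaults (90,000-sample ensembles, 8 epochs per stage, minibatch 4,
350,000-state Gibbs protocols) reproduce the converged behavior described
above and are what `run_experiment()` uses unless overridden.

# Known limitations

* Enumeration-based checks stop at 24 total units; beyond that, all
  quantities are Monte Carlo estimates with the usual $1/\sqrt n$ error.
* The critical-onset flags (`slope_vs_model_size()`) are
  tolerance-parameterized (default band $|s - 1| \le 0.2$); the onset size
  depends on the stimulus ensemble and has no universal value.
* `log Z` is never estimated for large models — all reported energies are
  anchored differences, which suffices for every analysis here but means
  absolute likelihoods are unavailable above the enumeration cap.
* The pipeline models synchronous binary codes only: no temporal
  dynamics, no multi-layer models, no real-valued units.
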