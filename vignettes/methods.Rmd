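---
title: "Models, simulation assumptions and numerical choices in mmrlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, simulation assumptions and numerical choices in mmrlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`mmrlearn` is a simulation and analysis pipeline for tri-modal roving
oddball experiments: it generates probabilistic stimulus sequences, derives
single-trial ideal-observer surprise regressors, fits them to channel ×
time amplitude data with variational Bayesian (VB) regression, and compares
model families with random-effects Bayesian model selection (BMS). This
vignette documents the models, the assumptions behind the synthetic data,
and the numerical decisions — including the places where the design was
genuinely open and the package had to choose.

## 1. The stimulus model

The three binary stimulus streams (auditory, somatosensory, visual; low =
0, high = 1) are emitted jointly by one Markov chain over the 8 intensity
combinations, encoded as states 0–7 with the auditory bit most significant.
Transitions in which two or three modalities change simultaneously have
probability exactly zero. For each modality, the probability of a
single-modality change depends on whether the *other two* modalities are
congruent (equal) on the previous trial:

| setting | P(change | others congruent) | P(change | others incongruent) |
|---|---|---|
| `congruent_unlikely` | 0.025 | 0.15 |
| `incongruent_unlikely` | 0.15 | 0.025 |
| `neutral` | 0.0875 | 0.0875 |

The diagonal (tri-modal repetition) carries the remaining mass. Because
these probabilities are symmetric between any state and its
single-bit-flipped neighbor, the chain's stationary distribution is exactly
uniform over the 8 states for all three settings (verified against an
eigen-decomposition oracle in the tests), the congruent and incongruent
contexts each have stationary probability 1/2, and the *marginal* change
probability per modality is 0.0875 in every setting.

**Known discrepancy, documented rather than resolved.** Descriptions of
this paradigm also quote a marginal change probability of .175 and a mean
train length of 5, which is inconsistent with the conditional
probabilities above (they imply 0.0875 and a mean train of ~11.4). The
generator follows the explicit conditional probabilities; nothing in the
package targets the .175 figure. All probabilities are exposed as
parameters of `build_transition_matrix()`.

Runs are 600 stimulus trials; six runs per experiment with each setting
used twice. Six catch trials per run are placed uniformly at random (never
first); they carry no stimulus, the chain continues across them, and they
are excluded from annotations and all regressors. No adjacency constraint
is imposed on catch positions. The first stimulus of each run has no
standard/deviant status and is excluded from all designs; train-length
counters and observer beliefs reset at run boundaries.

**Annotation conventions.** For trial *t* and modality *m*, `train` is the
number of consecutive trials before *t* sharing the value at *t − 1* — for
a deviant this is the length of the standard train it terminates, for a
standard its (position − 1) in the current train. Congruency is evaluated
on the other two modalities at *t − 1*, matching the conditioning of the
transition model (when *m* changes, the others repeat, so this equals
their congruency at *t*). Predictability is event-based: in a coupled
setting, a deviant is *predicted* if its context's change probability was
high and *mispredicted* if low; a standard is *predicted* if change was
unlikely and *mispredicted* if likely; all neutral-setting trials are
*unpredictable*. This is the only reading under which standards populate
all three conditions, as the condition design requires.

## 2. Observers and surprise read-outs

Both learners are conjugate Dirichlet–Categorical estimators over binary
outcomes with a flat prior pseudo-count α₀ = 1 per outcome (the
uninformative conjugate default; it also makes "confidence-corrected equals
Bayesian surprise at the first observation" an exactly testable property).

* **UM (unimodal transitions):** context = previous stimulus value (2
  contexts), outcome = current value.
* **UCM (cross-modal alternations):** context = congruency of the other
  two modalities at *t − 1*, outcome = repeat vs alternate. UCM regression
  models use both the UM and the cross-modal columns.

**Forgetting.** Counts decay by `exp(-τ)` per stimulus (time-based, applied
to all contexts at every observation — not per context visit — so the
half-life `floor(ln 2 / τ)` is in stimulus units; capped at the run length
600, which reproduces the canonical 11-point grid's printed half-life
list including the duplicate 600 for τ = 0 and τ = 0.001). Within a trace
the order is *decay → predict/read out → increment*: surprise at trial *t*
is computed from the decayed belief, before the new count is added. This
choice makes both limiting properties hold exactly (a count of 1 weighs
0.5 at the next observation for τ = ln 2; prediction collapses to the flat
prior for large τ). The vectorized traces (`run_unimodal_observer`,
`run_crossmodal_observer`, implemented with recursive filters) are tested
to machine precision against stepping the single-update API.

**Read-outs** (all in nats): predictive surprise `PS = −ln p(y_t)`;
Bayesian surprise `BS = KL(Dir(prior) ‖ Dir(posterior))` over the updated
context only — under forgetting, the decayed non-updated contexts would
also contribute KL, but are deliberately excluded as a documented
simplification; confidence-corrected surprise
`CS = KL(Dir(prior) ‖ Dir(α₀) + one-hot(y_t))`. The Dirichlet KL uses the
closed form via log-Beta and digamma terms and is verified against simplex
quadrature to 1e-5. The TLCD baseline tracks the repetition counter
`c_t = d_t (c_{t−1} + d_t)` (d = 1 for repetitions) and outputs `−c_t` on
repetitions and `c_{t−1}` on changes, with `c₁ = 0` and no output at the
first trial. All regressors are z-scored over included trials before
fitting (natural-log vs log2 read-outs would be absorbed by this scaling).

## 3. Synthetic EEG: what it emulates and what it does not

`simulate_eeg()` produces `y = β₀ + Σ_k β_k(channel, time) x_k(trial) + ε`
with ε i.i.d. Gaussian — exactly the likelihood the regression stage
assumes. Defaults that define the stated world:

* grid 8 channels × 20 time bins of 30 ms (centers 15–585 ms) — desk-scale
  but preserving the channel × time map structure;
* an MMN-like unimodal window (channels 3–6, 100–200 ms) and a P3-like
  cross-modal window (channels 4–5, 300–350 ms), where scenarios plant
  effects;
* trial noise σ = 10 µV (a realistic single-trial EEG amplitude scale);
  effect amplitudes 0.5 / 1 / 2 µV per regressor SD for weak / medium /
  strong — single-trial effects an order of magnitude below noise, as in
  real mismatch data;
* between-subject SD = half the amplitude, applied to the nonzero β
  entries only (so planted locations stay interpretable; zero-effect cells
  remain exactly null); generating τ = 0.05 (half-life 13 stimuli, inside
  the 5–25 range typical for such data);
* subjects share the stimulus sequence within a simulated experiment
  (individual sequences would only average out sequence idiosyncrasies).

Not emulated: scalp topography and volume conduction, ERP waveform shape,
spatial or temporal noise correlations, artifacts. A green recovery test
therefore establishes that the chain *sequence → regressors → VB evidence
→ family BMS* correctly identifies planted linear structure under the
assumed noise model — not that it is robust to violations of that model.

## 4. VB regression and model evidence

Per subject, channel, time bin and model, `y = Xw + ε` is fit with a
mean-field factorization q(w) q(α) q(λ): Gaussian weights with a single
shared precision α, Gamma hyperpriors on α and the noise precision λ
(shape 1e-2, rate 1e-4 — broad), coordinate-ascent updates, free energy F
as the evidence bound. The method family fixes none of these constants,
so they are package choices; model comparisons are insensitive to them in
the sensitivity checks. Convergence: |ΔF| < 1e-4 or 200 iterations; F is
asserted non-decreasing per sweep. Because all fits at one design share
X'X, the per-cell fits are solved in the eigenbasis of X'X, which reduces
each iteration to O(p × fits) vector work; the batched path is tested
against a plain solve-based implementation.

The eight-model space is NULL (offset), TLCD (offset + 3), UM-PS/BS/CS
(offset + 3), UCM-PS/BS/CS (offset + 6). For the six learner models, τ is
chosen per model, subject and time bin by maximizing F summed over
channels (ties to the smallest τ), and the evidence-inflation penalty —
the mean over subjects, channels and time bins of F(optimized) minus the
grid-average F — is subtracted per model before BMS. TLCD and NULL enter
unpenalized.

## 5. Random-effects BMS and exceedance probabilities

`rfx_bms()` iterates the variational Dirichlet update over population
model frequencies until the α change is below 1e-6. Family inference uses
the family-uniform prior (each model's prior count = 1 / family size) and
aggregates the Dirichlet by family. Exceedance probabilities come either
from 10⁶ Dirichlet samples (the default for `rfx_bms`, seeded) or from an
exact 1-D integral — the argmax of a Dirichlet equals the argmax of
independent Gamma(α_k, 1) variables, so
φ_k = ∫ dGamma(x; α_k) Π_j P(Gamma(α_j) < x) dx. The quadrature route is
deterministic and ~10³× faster, so map-level family BMS uses it; the two
agree to Monte-Carlo error in the tests, and the two-model case is checked
against the analytic Beta integral. The often-quoted correspondence
"φ > 0.95 ≈ r > .7" depends on subject and family counts and is reported,
never enforced.

## 6. Condition GLM stage

The canonical condition designs are over-parameterized by construction
(one-hot blocks plus an intercept), as is conventional in ERP GLM
practice: TrainLength = intercept + 3 modalities × {standard, deviant} ×
6 train bins (1, 2, 3, 4–5, 6–8, >8) + 4 global-standard + 4
global-deviant bins (1, 2, 3, >3) = 45 columns. Fitting uses minimum-norm
least squares (SVD pseudoinverse); downstream contrasts are centered
within blocks and hence estimable. Ordinary least squares stands in for
restricted maximum likelihood because the synthetic noise is i.i.d., where
the two coincide.

The canonical Predictability design counts for this paradigm (37 at the
group level, 36 congruency-split at the subject level) do not decompose
as "intercept + 18"; the package resolves them as: group form =
intercept + modality × role × condition × congruency = 37 columns,
subject form = the same 36 indicators without intercept (they already span
it). Train-length effects are tested with centered linear contrast weights
over the six bins and a one-sample t across subjects; cross-modal overlap
with a minimum-statistic conjunction (significant only where every
modality exceeds threshold); predictability with a balanced two-way
repeated-measures ANOVA (each effect against its subject-interaction
error; verified against `aov()`), Bonferroni-corrected post hoc paired t
tests on the three condition pairs. Cluster correction is a generic
sign-flip permutation test on the channel × time lattice: 4-neighborhood
adjacency (channel index × time; no scalp geometry), two-sided
cluster-forming threshold at α = 0.05, cluster mass = Σ|t|, null = maximal
mass under subject sign flips, p = permutation rank with the +1
correction. Random-field-theory correction and scalp interpolation are
out of scope.

## 7. Recovery experiments and their scale

The recovery tests mirror the real-data model comparison: simulate from a
known generator, run the full evidence + BMS chain, and ask which family
wins where. Replications use a three-run schedule (one run per setting) —
the six-run experiment doubles data volume without changing what the test
establishes — with 32 subjects on the 8 × 20 grid. "Planted locations"
means the cells where the generator's distinctive signature lives; for
UCM generators that is the cross-modal P3 window, since at MMN-window
cells a UCM generator restricts to its unimodal part and UM/UCM are
genuinely indistinguishable there. The recovery confusion matrix is
therefore evaluated per generator at its distinctive cells (whole grid
for NULL; MMN window for TLCD and UM; P3 window for UCM) and is strongly
diagonal at medium SNR.

Calibration checks run at fixed a-priori scales: contrast and ANOVA
type-I error pooled over 200 null replications × 20 independent cells
(band [0.03, 0.07] at nominal 0.05); cluster-permutation family-wise
error over 400 null replications with 200 permutations each, with an
acceptance band of ±3 binomial SEs around 0.05 ([0.017, 0.083]).

## 8. Degenerate inputs, ties, tolerances

Zero-variance regressors (e.g. TLCD on a perfectly alternating run) raise
rather than silently z-scoring to NaN. Empty congruency cells in
`empirical_change_probs()` are flagged `NA` with zero counts. Empty design
bins warn and keep the (all-zero) column so the printed column counts
remain structural invariants. τ ties select the smallest grid value.
Dirichlet KL values are clipped at 0 against floating-point negatives.
Sub-seeds for every stochastic stage derive from one master seed via a
fixed linear-congruential map, keeping all streams below 2³¹ and every
stage independently reproducible.

## 9. Known limitations

No volatility or hierarchical learners; no fixed-effects BMS, Bayesian
omnibus risk or protected exceedance probabilities; no source-space
anything; arrays are stored as flat TSV with JSON sidecars rather than an
HDF5 container (not available in this stack). The BS-under-forgetting
simplification (updated context only) and the decay-then-read-out trace
order are choices on questions the method family leaves open; both are
documented above and pinned by tests.
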