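---
title: "Comparing circadian feedback architectures: models, search, robustness and entrainment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing circadian feedback architectures: models, search, robustness and entrainment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

clockloops asks a structural question about circadian clocks: among
competing transcriptional–translational feedback architectures, which one
is the best *design* for a robust, light-entrainable oscillator — not at
one hand-picked parameter set, but over the whole region of kinetic
parameter space that produces circadian oscillations at all? This vignette
explains the models, the search and robustness machinery, the numerical
choices, and what the package's own tests do and do not establish.

## The four architectures

All four models live in units of nanomolar and hours and share the same
rate-law vocabulary, composed from four primitives (`hill_repression()`,
`michaelis()`, `mass_action()`, and plain first-order terms):

* transcription, either repressed, \(S K^h / (K^h + R^h)\) with repressor
  \(R\) and Hill coefficient \(h = 4\) (fixed), or constitutive, \(S\);
* translation, first order in the mRNA;
* complex association/dissociation by mass action;
* nuclear import and export as Michaelis–Menten transport;
* degradation of every species as a Michaelis–Menten term *plus* a slow
  first-order leak (reference rate 0.01 h\(^{-1}\)).

The **single** model (m = 3: mRNA(X), X, nuclear X) is the classic
one-gene negative feedback: nuclear X represses its own gene. Its output
is nuclear X. The **semi-dual** model (m = 6) adds a second protein Y,
expressed constitutively, which binds X; the nuclear X:Y complex represses
X transcription and is the output. The **dual** model differs from the
semi-dual in exactly one equation: Y transcription is also repressed by
nuclear X:Y, closing a second feedback loop through the shared complex.
The **redundant** model (m = 6) instead runs two *independent* single-type
loops (X represses X, Y represses Y) and reads out total nuclear protein,
nuclear X + nuclear Y.

Parameter names follow per-model index families (`S` transcription and
translation rates, `K` transcription affinities, `A`/`B` association and
dissociation, `T`/`U` import and export vmax/affinity pairs, `D1..Dm`
Michaelis degradation rates, `D(m+1)..D(2m)` first-order leak rates,
`L1..Lm` degradation affinities). Every reference value is 1.0 in its
natural unit except the leak rates (0.01 h\(^{-1}\)) and the fixed Hill
coefficient. The right-hand sides are compiled in C for speed; an R
transcription of the same equations (`clock_derivatives()`) is kept as the
auditable reference, and the test suite holds the two to within rounding
error on random states, so the only hard-to-audit step — transcribing the
equations — is checked in one place.

## Kinetic symmetry

For the dual and redundant models, the search space of every Y-loop
parameter is tied to the value drawn for its X-loop counterpart through
the symmetry parameter \(\rho \ge 0\): the admissible band is
\([x/(1+\rho),\; x(1+\rho)]\), intersected with the global search bounds.
The band collapses to \(\{x\}\) at \(\rho = 0\) (perfectly symmetric
loops) and, because \(\rho = 99\) gives a factor of 100 — exactly the
width of the default 0.1–10-fold global range — it covers the whole
search space for \(\rho \ge 99\) (independent loops). These two limits,
plus monotone growth of the band with \(\rho\), are the contract; the
multiplicative band is the minimal family satisfying them and is what the
package implements.

## Simulation and feature extraction

Trajectories are integrated with `lsoda` (relative tolerance 1e-7,
absolute 1e-9 nM): the Hill exponent of 4 and saturable degradation make
the systems moderately stiff. Non-negativity is respected by construction
(every removal term vanishes at zero substrate) and achieved numerically
by tolerance, never by clamping. All species start at 0.1 nM by default;
the start is irrelevant because features are measured on the attractor:
the default policy integrates 1000 h and discards the first 500 h,
leaving about 20 circadian cycles.

The output signal's local maxima are detected on the dense grid (0.25 h),
refined by three-point parabolic interpolation, and filtered by an
absolute prominence of 1e-3 nM to remove numerical ripple without biasing
the period. The **period** is the mean peak-to-peak interval; the
**amplitude** is max − min of the output over the post-transient window
(peak-to-trough; the 2–6 nM target window is read this way). An
oscillation is **sustained** when at least 10 peaks are found and the
cycle-to-cycle coefficients of variation of period and amplitude are
below 1% and 10% — thresholds chosen to mirror the entrainment constancy
criteria, so "sustained" and "entrained" mean the same kind of
regularity. Damped, constant and numerically failed trajectories are
non-oscillatory by this definition; integration failures are flagged on
the trajectory, not raised, so searches continue.

Grid and transient choices are validated by invariant tests: halving the
grid spacing changes the period by less than 0.1%, and doubling the
discarded transient leaves features unchanged within the period CV.

## The two-phase search

The goal of the search is not optimization but *harvesting*: collect many
distinct parameter sets whose output oscillates with period 23–25 h and
amplitude 2–6 nM. Parameters are searched as log10 values within 0.1–10
fold of the reference values (so the leak rates span 0.001–0.1
h\(^{-1}\)).

Phase one samples log-uniformly (Y-loop parameters conditionally within
their \(\rho\)-band) and scores every candidate with a fitness that is
zero exactly on the target windows: sustained oscillation, period and
amplitude inside their windows, and — for the semi-dual model — the mean
total Y protein (free + complexed, measured on the post-transient window)
inside its configured stratum. Off-window candidates are penalized by
their relative distance to the windows (log-distance for the Y stratum);
non-oscillatory candidates sit on a penalty tier above every oscillatory
one, shaped by the number of detected peaks so the genetic phase can
climb toward oscillation. Phase two seeds a genetic algorithm with the
best random-phase candidates: tournament selection (size 2), BLX-0.5
blend crossover (rate 0.9), per-gene Gaussian mutation (sd 0.1 log10
units, rate 0.1), one elite. Every individual that reaches fitness zero
is archived — two solutions count as duplicates when their largest
absolute log10 parameter ratio is below 0.01 — and is then replaced by a
fresh random sample so the population keeps exploring rather than
collapsing onto one basin. The search stops when the requested number of
distinct solutions is collected; a shortfall is reported with a warning,
never truncated silently. One run seed fans out to per-phase child seeds
through a fixed linear-congruential rule, so each phase is independently
reproducible.

The GA operators are conventional real-coded choices; the archive they
produce is a *sample* of the viable region, with no claim of
exhaustiveness, and the package's distribution-level claims are always
made on such samples.

## QMPS: robustness to uncertainty in all parameters

For a target \(q\) (period or amplitude), the normalized single-parameter
sensitivity is the forward difference
\[
  s_i = \frac{(q(p_i(1+\Delta)) - q(p)) / q(p)}{\Delta},
\]
and the quasi-multiparameter sensitivity is the square sum
\(\mathrm{QMPS} = \sum_i s_i^2\) over all searched parameters (never the
fixed Hill coefficient), at \(\Delta = 0.001\). QMPS approximates the
analytic multiparameter sensitivity (the \(\Delta \to 0\) limit); the
package's tests verify the square-sum identity on monomial targets, where
\(q = \prod p_i^{a_i}\) gives \(\mathrm{QMPS} \to \sum a_i^2\), and check
that \(\Delta = 0.001\) and \(\Delta = 0.005\) agree within 5% on a real
oscillator. A forward difference is used deliberately — it matches the
defining perturbation \(p_i(1+\Delta)\); a central difference would be a
different estimator.

Because the finite difference divides small period changes by a small
\(\Delta\), the baseline and all perturbed measurements are taken under
the *same* protocol: each restarts from the final state of the
unperturbed run (already on the attractor) and measures over a shorter
window (600 h, first 300 h discarded). This costs one extra evaluation
over the minimal n + 1 but removes any systematic offset between baseline
and perturbed measurements, which would otherwise contaminate every
sensitivity. A perturbation that destroys the oscillation makes that
parameter set's QMPS undefined; such sets are excluded and counted, never
imputed.

Ensembles are compared by their empirical cumulative frequency curves
(fraction of QMPS values at or below a threshold) and by the median,
defined as the smallest value whose cumulative frequency reaches 0.5. A
higher curve — or a lower median when curves cross — means the more
robust design.

## Light entrainment

Light acts by accelerating clock-protein turnover: during the light phase
of a square-wave light–dark cycle with forcing period \(\zeta\) and equal
light and dark phases, the Michaelis degradation vmax of cytoplasmic X
(`D2`) — and of the cytoplasmic X:Y complex (`D5`) in the semi-dual and
dual models — is multiplied by \(1 + \delta\). The neutral point is
\(\delta = 0\), named explicitly in the code. In the redundant model only
the X loop is light-modulated; the Y loop runs free, which is exactly why
its entrainment behaves differently. The discontinuous switching is
integrated with event-aligned restarts (the light state is toggled by
integrator events), never stepped over.

A parameter set **entrains** to \((\zeta, \delta)\) when, over the last
40 of 80 forcing cycles, the forced oscillation's period and amplitude
are constant (cycle-to-cycle deviations under 1% and 10%) and the period
matches \(\zeta\) within 1%. Quasiperiodic and chaotic responses both
fail these criteria and are not distinguished further. The entrainment
probability at a grid point is the exact fraction of archived sets that
entrain there, so probability times archive size is always an integer;
per-set booleans are kept for audit. At \(\delta = 0\) the classification
provably reduces to "free-running period within 1% of \(\zeta\)", which
the tests cross-check against archive features without any forced
simulation.

## Problem sizes used by the tests

The package's replication suite re-derives the headline qualitative
results at desk scale, chosen once: 60 accepted parameter sets per
condition (per architecture, \(\rho\) value, and Y stratum) under a
single fixed seed, with QMPS for every set; entrainment maps use the
first 30 sets of each ensemble on a 9 × 9 grid (\(\zeta\) = 16–32 h,
\(\delta\) = 0.1–1 log-spaced) with 60 forcing cycles, classifying on the
last 30. Distribution-level orderings are asserted on medians. Default
budgets exposed in `search_config()` are larger (5000 random trials,
population 100, up to 200 generations); full-scale studies with a
thousand solutions per condition are a matter of configuration, not code.

With these ensembles the suite asserts, among others: the dual model at
\(\rho = 0\) has a lower median period-QMPS than the single model;
semi-dual robustness improves as the Y stratum rises; redundant
robustness is non-monotone in \(\rho\) (worst near 0.1); the
loop-balance statistic \(\gamma = \overline{X_{nuc}} /
(\overline{X_{nuc}} + \overline{Y_{nuc}})\) is bimodal near 0 and 1 for
independent redundant loops, exactly 0.5 at \(\rho = 0\); and the
symmetric dual model entrains over at least as wide a \(\zeta\)–\(\delta\)
region as the single model, with the symmetric redundant model not
exceeding the dual.

Two caveats belong with these assertions. Median orderings between
*adjacent* \(\rho\) values of the same architecture involve small
effects; at this ensemble size their sampling noise is of the same order
(seed-to-seed median variation around 10%), so single links of the dual
\(\rho\) chain are at the edge of resolution. And for the redundant
model near \(\rho = 0.1\), the two *independent* loops must be almost
equally tuned before their summed output passes the sustained test at
all; the accepted sets then have nearly coincident loop periods, so a
perturbation of one loop moves the summed signal's period only about
half as much — the measured *period* is buffered by averaging, and the
fragility of these solutions shows up instead in the amplitude QMPS
(orders of magnitude above every other condition) and in the fraction of
sets that lose oscillation outright under a 0.1% perturbation. The suite
asserts the non-monotone signature for both features and reports both.
Similarly, the *total* entrained area depends on where the
\(\zeta\)–\(\delta\) grid is placed: the symmetric dual model's advantage
over the single model is concentrated at moderate-to-strong light (the
single model is disrupted by strong light first), while at weak light the
single model's tongue is slightly wider, so on the default grid the
area comparison between these two sits within the sampling noise of 30
sets. The redundant model's near-total failure to entrain, by contrast,
is unmistakable at any grid.

## Design decisions and limitations

* **\(\gamma\) is defined for the redundant architecture only.** The
  statistic needs separate nuclear X and nuclear Y species; the dual and
  semi-dual models carry a single shared nuclear complex, so
  `loop_balance()` returns `NA` for them rather than inventing an
  analogue.
* **Amplitude is peak-to-trough** (max − min of the output over the
  window). A peak-to-mean reading would halve the numbers; the 2–6 nM
  window is interpreted under the peak-to-trough definition throughout.
* **Strict positivity of parameters** is enforced at model construction;
  degenerate cases ("a silenced gene") are represented by very small
  rates (e.g. 1e-12), which the absorbing-state and virtual-single-model
  tests use.
* **Deterministic ODEs only**: no stochastic simulation, no
  Floquet/bifurcation analysis — oscillation and entrainment are
  classified purely from simulated signals.
* **Synthetic conditions.** All data are generated by the models
  themselves under the stated reference values, windows and bounds; the
  package's conclusions are statements about these architectures in that
  regime, not about any measured organism. Real clocks face stochastic
  fluctuation, temperature dependence and coupling between cells that
  these models do not represent; passing tests show the *designs* differ
  as claimed, not that any parameter value is biologically measured.
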