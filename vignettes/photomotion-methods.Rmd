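---
title: "Methods: four-state photoswitch kinetics and motion propensities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: four-state photoswitch kinetics and motion propensities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomotion)
```

## The system and its state space

photomotion analyses the photochemistry of a chromophore that combines a
central C=C double bond (Z or E) with an adjacent stable chiral axis, so
that it occupies exactly four thermally stable diastereomers, labelled
`A < B < C < D`. The fixed stereo assignment — A = (Z, ax1), B = (Z, ax2),
C = (E, ax1), D = (E, ax2) — makes every state-to-state photoreaction
classifiable by which descriptors change:

* **SBR** (single-bond rotation): only the axial chirality flips
  (A↔B, C↔D);
* **DBI** (double-bond isomerization): only Z/E flips (A↔C, B↔D);
* **HT** (hula twist): both flip at once (A↔D, B↔C).

For each source state the three possible products realize exactly one SBR,
one DBI and one HT, so a measured product distribution *is* a motion-type
distribution. Absolute R/S and P/M descriptors never enter any computation
and are not modelled. Only the abstract axis labels matter, and they are
fixed once so that the motion classification of every named transition is
consistent.

## Forward photokinetic model

Under continuous monochromatic irradiation with incident photon flux $F$
(einstein s$^{-1}$), each isomer $i$ absorbs photons at

$$ r_i = F \cdot \frac{A_i}{A_{tot}}\left(1 - 10^{-A_{tot}}\right),
   \qquad A_i = \varepsilon_i \, l \, c_{tot} \, x_i , $$

the standard partition of the absorbed photon stream among competing
absorbers, with $(1-10^{-A_{tot}})$ the photokinetic absorbed-fraction
factor. A transparent sample ($A_{tot}=0$) is a valid degenerate input and
absorbs nothing rather than raising an error. Moles then evolve as

$$ \frac{dn_i}{dt} \;=\; \sum_{j\neq i}\left[\Phi_{ji}\,r_j
   - \Phi_{ij}\,r_i\right], $$

where $\Phi_{ij}$ is the quantum yield of the $i\to j$ channel. Total moles
are conserved exactly by construction; the integrator is required to hold
the fraction sum within $10^{-8}$ and the test suite asserts it. Because
the channel yields of interest span roughly 0.01%–31%, the integration uses
a stiff-safe solver (`deSolve::lsoda`) with relative tolerance $10^{-8}$
and absolute tolerance $10^{-10}$. Times are minutes at every interface and
seconds internally. Tiny negative fractions from round-off (bounded at
$-10^{-12}$) are clamped to zero on output and rows renormalized.

The photostationary state is found by integrating over successively doubled
time chunks until the change per chunk falls below $10^{-10}$ (with an
iteration cap that raises a classed convergence error). For equal molar
absorptivities the kinetics are exactly linear, and the tests cross-check
the fixed point against the stationary distribution of the associated
continuous-time chain computed by eigendecomposition — an independent
route to the same quantity.

## Discrete-time Markov analysis

The central inference is the row-stochastic one-step (default
`dt = 1` minute) transition matrix $M$, estimated by a global least-squares
fit: the objective sums squared deviations between the observed mole
fractions of all series and $x_0 M^{t}$. Design choices that matter:

* **Exact constraints.** Each fitted row is parameterized by three
  unconstrained reals through a normalized-exponential (softmax) map with
  the diagonal pinned at logit zero, so every iterate is exactly
  row-stochastic; no penalties or projections are needed during
  optimization.
* **Multi-start.** Levenberg–Marquardt from a diagonal-dominant start plus
  seeded random restarts (8 by default, seed 20180628); the best objective
  wins. All series and time points are weighted equally.
* **Identifiability.** States whose fraction never rises above
  `populate_threshold` (default 1%) in any series cannot constrain their
  own outgoing row; those rows are returned as identity rows and flagged
  rather than fitted. With noisy data the threshold should sit above the
  noise floor (the validation studies use $5\sigma$); otherwise noise-level
  trace states can act as spurious fast relays (see below).
* **Parsimony ridge.** Composition data genuinely cannot distinguish a
  quiescent pair of states from a detailed-balance exchange between them,
  nor a direct channel from a fast two-step relay through a trace state:
  the least-squares surface has exactly flat valleys. A weak penalty
  (`ridge`, default $10^{-3}$) on the off-diagonal entries resolves every
  such tie toward the least-churn matrix. The penalty is orders of
  magnitude below the data curvature of identified entries — noise-free
  recoveries remain exact to about $10^{-6}$ per entry — while dominating
  the noise-induced tilt along the flat directions. Setting `ridge = 0`
  restores the plain objective.
* **Zero projection.** The softmax map cannot represent exact zeros;
  off-diagonal entries below $10^{-7}$ after optimization are projected to
  exact zero (renormalizing through the diagonal) whenever that does not
  worsen the fit.
* **Grid alignment.** Observation times that are not integer multiples of
  `dt` are linearly interpolated onto the step grid and the fit is flagged;
  matrix fractional powers are deliberately avoided.

Within one row, the off-diagonal entries of $M$ should stand in the same
ratios as the measured quantum yields, and `quantum_yield_ratio_check()`
quantifies the agreement. This mirroring is first-order: within a
one-minute step a weak channel (e.g. a $10^{-4}$ yield) picks up
second-order contributions from two-step paths through efficient channels,
so ratio deviations of tens of percent on the *weakest* channels are
expected and are not a fitting failure; the efficient channels agree to a
couple of percent in the shipped end-to-end test.

`propensity_shares()` converts a source row (of $M$ or of $\Phi$) into
motion-type fractions. Both reporting conventions in use are implemented:
`three_way` normalizes over all three channels, `pairwise` over two named
motions only — condition presets for which only a two-way ratio was ever
determined store a zero third share and are marked `partial`.

## Quantum-yield estimation

Two estimators are provided, mirroring the two experimental arguments:

* `full_ode_fit` (default) fits the full forward model to all series with
  the channel yields as free parameters (bounded to $[0,1]$,
  Levenberg–Marquardt, initialized from a one-interval slope estimate).
  Because the forward model repartitions photons as products accumulate,
  this estimator inherently corrects for photoproduct absorption.
* `early_slope` restricts each series to the maximal initial window in
  which the photoproducts' share of the total absorbance stays below a
  threshold (default 5%) — the regime in which product formation is
  attributable entirely to photons absorbed by the starting material — and
  regresses moles formed on cumulative einsteins absorbed. It
  systematically underestimates once back-reactions matter, which the test
  suite checks directionally.

Quantum yields are defined operationally as converted moles per einstein
absorbed by the reactant, with absorption attributed by the partition
formula above; both an inner-filter-corrected mode (`full_ode_fit`) and the
early-time mode are exposed, the former as default. Standard errors come
from the Gauss–Newton covariance of the fit. A seeded residual bootstrap is
available through `n_boot` (200 draws is a sensible request); it is off by
default because bootstrapping the ODE fit multiplies its cost by the number
of draws, and the Gauss–Newton errors are adequate for routine use.

## Thermal kinetics and barriers

Reversible first-order interconversion $X \rightleftharpoons Y$ starting
near-pure in $X$ follows
$x(t) = x_{eq} + (x_0 - x_{eq})\,e^{-(k_f+k_r)t}$ with
$x_{eq} = k_r/(k_f+k_r)$; the relaxation rate and plateau are fitted on
log/logit scales and decomposed into the two rate constants. Data starting
at (or never leaving) equilibrium are flagged unidentifiable rather than
silently fitted. Barriers use the Eyring relation
$\Delta G^\ddagger = RT\ln\!\left(k_B T / h k\right)$ with unit
transmission coefficient and pinned CODATA 2018 constants
($k_B = 1.380649\times10^{-23}$ J/K, $h = 6.62607015\times10^{-34}$ J s,
$R = 8.31446$ J/mol/K); the rate↔barrier conversion round-trips at
machine precision and both kJ/mol and kcal/mol (1 kcal = 4.184 kJ) are
reported.

Non-observation of a reaction after heating for $\tau$ bounds its rate by
$k_{max} = -\ln(1-f)/\tau$, where $f$ is the smallest conversion the assay
would have detected, and hence bounds the barrier from below. The default
$f = 0.05$ is a conservative NMR integration limit; the bound is
insensitive to this choice (any $f$ below ~50% keeps the 25 h / 100 °C
bound above 30 kcal/mol), increases by $RT\ln 2$ per doubling of the
heating time, and decreases monotonically as the detection limit loosens.
With rates at two or more temperatures, `eyring_regression()` separates
$\Delta H^\ddagger$ and $\Delta S^\ddagger$; otherwise extrapolation
assumes a temperature-independent $\Delta G^\ddagger$.

## Spectral diagnostics

For a clean two-state photoconversion every recorded spectrum is a convex
combination of two fixed component spectra, which has two observable
signatures. First, isosbestic points: wavelengths where the absorbance is
time-invariant. `isosbestic_points()` reports grid wavelengths whose
absorbance standard deviation across time is below `tol` while the mean
absorbance exceeds `tol` (excluding flat baseline), merging contiguous hits
at the minimum-deviation wavelength. The default `tol` of 0.002 absorbance
units is a typical spectrophotometer noise floor; note that a crossing
falling between grid points leaves a residual deviation at the nearest
grid point proportional to the offset, so `tol` should scale with the grid
step when the grid is coarse. If all spectra are identical, every
non-baseline wavelength qualifies — a documented degenerate behaviour.
Second, rank: after subtracting the per-wavelength mean, a two-component
series has rank one, so the ratio of the second to the first singular value
(`two_state_rank_test()`) measures the evidence for any additional species;
values below about 0.01 indicate effectively two-component behaviour. The
statistic is invariant under wavelength-independent baseline shifts and
global intensity rescaling, and a 5% third component pushes it above the
0.01 guideline.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the fitters consume, bit-reproducibly
under explicit seeds (master default 20180628):

* `generate_photokinetic_dataset()` — one composition series per pure
  starting isomer via the forward ODE model. The shipped quantum-yield
  preset encodes the benzene-solution measurement set (A→B 9%, A→C 31%,
  A→D 0.8%; B→A 0.9%, B→C 8%, B→D 9%; C→A 0.09%, C→B 0.1%, C→D 0.07%;
  D→A 0.3%, D→B 0.06%, D→C 0.01%). The irradiation preset is an
  NMR-tube-scale experiment: 405 nm, photon flux $10^{-9}$ einstein/s,
  1 cm path, 0.5 mL, 1 mM chromophore, equal molar absorptivities of
  5000 L/mol/cm. Flux and concentration were chosen once so that the
  efficient channels convert substantially within a 30-minute series while
  the weakest channel (0.3%) becomes identifiable by extending a series to
  200 minutes; the equal-absorptivity choice makes the kinetics exactly
  linear, which the tests exploit for independent oracles.
* `generate_share_dataset()` — single-source discrete Markov data built
  from a motion-share triple and an overall per-step loss probability
  (0.05/min in the validation studies). The preset library encodes the
  printed per-condition shares (e.g. B in cold liquid CD₂Cl₂: 76% HT vs
  24% DBI; A in CD₂Cl₂ ice: 99% DBI; B in MeOH: 70:30 HT:DBI; B in cold
  liquid EPA: 82% HT). Where only a two-way ratio was determined the third
  share is zero and flagged `partial`; where a single dominant share was
  determined (99% DBI for A in CD₂Cl₂ ice, 93% for B) the remainder is
  assigned to HT, matching the ordering observed in frozen toluene where
  all three shares were resolved (83/16/1 DBI/HT/SBR).
* `generate_thermal_dataset()` — closed-form reversible decays;
  `generate_spectra_dataset()` — Gaussian-band two-component mixtures with
  an optional third component.

Noise is additive Gaussian on mole fractions followed by clipping to
$[0,1]$ and renormalization — the simplest model consistent with reading
NMR integrals, with $\sigma = 0.01$ as the default magnitude (the true
experimental noise is not known; it is configurable). Two consequences of
this model are worth stating. Clipping at the simplex boundary biases
near-zero observed fractions upward by roughly $0.4\sigma$, so shares of
channels near 0% or 100% carry a small systematic error at finite noise.
And noise-level trace states can destabilize the Markov fit through the
relay degeneracy described above unless `populate_threshold` is set above
the noise floor. Passing tests on these synthetic data demonstrate correct
inference under the stated generative model — first-order kinetics, time-
invariant conditions, Gaussian integral noise — not robustness to
systematic NMR integration errors, baseline drifts, photon-flux drift, or
wavelength-dependent yields (treated as constant here, consistent with the
marginal 305–405 nm variation observed experimentally).

## Validation scale and reproduction

The shipped validation studies run at desk scale: quantum-yield recovery
uses four 31-point series (plus a 201-point D series for the weakest
channel), propensity round trips use 31-point series with 20 seeded noisy
replicates per condition, and the whole suite completes in about a minute.
`scripts/acceptance.R` re-derives the headline numbers — the four
recovered benzene quantum yields, the 25 h / 100 °C barrier bound in
kcal/mol, and the four condition propensity shares — from scratch through
the generate → fit pipelines and writes them as JSON.

## Known limitations

* The Markov fit estimates a discrete-time kernel; continuous-time
  generator estimation via the matrix logarithm is deliberately out of
  scope (the exact kernel of any linear photokinetic system is an
  admissible matrix, so nothing is lost at dt = 1 min).
* Ratio mirroring between $M$ and $\Phi$ degrades on channels weaker than
  ~1% per step (second-order paths), as quantified by
  `quantum_yield_ratio_check()`.
* Polychromatic sources, excited-state dynamics, fluorescence, spectral
  deconvolution into per-isomer absorptivities and chemical actinometer
  calibration are out of scope.
* The propensity analysis near share boundaries (0% or 100%) inherits the
  clip-noise bias discussed above; at $\sigma = 0.01$ it is within ~1
  percentage point once the populate threshold is noise-aware.
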