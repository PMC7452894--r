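---
title: "Models and methods behind scrunchFRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scrunchFRET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(scrunchFRET)
```

# The scientific problem

Single-subunit RNA polymerases initiate transcription by *scrunching*:
while the enzyme holds its upstream promoter contacts, downstream DNA is
pulled into the active site base by base as the nascent RNA grows, bending
the template more and more.  In the yeast mitochondrial system
(polymerase plus its initiation factor) a donor dye downstream and an
acceptor dye upstream of the promoter turn this geometry into a FRET
observable: closed promoter, open promoter, and progressively scrunched
initiation complexes appear as distinct FRET levels, and the transition to
elongation releases the bend in one abrupt step.  scrunchFRET implements
the full quantitative workflow for such experiments — from two-colour
photon-count traces to corrected FRET efficiencies, state assignments,
dwell-time kinetics, washout population decays and distances — together
with a simulator that generates realistic synthetic recordings from a
conformational kinetic scheme, so that every estimator in the package can
be validated by parameter recovery.

# The kinetic scheme and its simulation

A `kinetic_scheme()` is a labelled continuous-time Markov chain.  Each
state carries an *apparent* FRET efficiency (`fret_mean`) and a
conformational broadening (`fret_sd`); transitions carry first-order rate
constants, optionally tagged with an NTP species so that a `protocol()`
event (flow-in or washout) can switch them on or off mid-recording.
`simulate_ctmc()` samples trajectories with the Gillespie direct method;
rate changes at protocol events restart the exponential clocks, which is
exact for piecewise-constant generators because exponential waiting times
are memoryless.

The packaged fixtures (`fixtures()`) encode the published state levels of
this system: bare DNA at E = 0.138; closed/open promoter at 0.135/0.376;
scrunched complexes stalled at +2, +3, +5, +6, +7 at 0.563, 0.630, 0.665,
0.771, 0.811; the elongation complex on the alternative +11/−11 labelling
at 0.442 (closed/open 0.327/0.753 on that template); unscrunching rates
0.305 s⁻¹ (+2) and 0.0653 s⁻¹ (+7).  Quantities the source experiments do
not pin down numerically — promoter opening/closing rates, scrunching
rates, the unscrunching rates at +3/+5/+6 (0.25/0.18/0.10 s⁻¹ here), the
backtracked-state FRET level (open level minus 0.05), and the 2AP plateau
levels — were fixed once at field-plausible values and are marked as
non-printed choices in the fixture file.  The washout fixture realizes the
published 4.1 min scrunched-population half-life as an irreversible
scrunched→open exit at ln 2⁄246 s⁻¹; the branching fixture realizes the
published 30%/64%/6% transient/irreversible/no-drop split over a 110 s
observation via scrunched→backtracked 0.00816 s⁻¹, backtracked→scrunched
0.15 s⁻¹ and scrunched→open 0.01741 s⁻¹ (total high-state exit
0.026 s⁻¹, matching the published post-washout decay of the high state).

# Forward photophysics model

`render_trace()` converts a state trajectory into per-frame photon counts.
The per-frame *apparent* FRET efficiency is the occupancy-weighted mean of
the state levels over the 100 ms camera integration window (not a midpoint
snapshot — this reproduces the blurred intermediate values real cameras
record at transitions), plus Gaussian state noise.  Channel intensities
follow

* donor: `I_D = Q (1 − E_phys)`
* acceptor: `I_A = γ Q E_phys + β Q + d`

with `Q` the photon budget per frame, `γ` the acceptor/donor detection
asymmetry (default 1.51), `β` the donor leakage (default 0.08) and `d` the
acceptor direct excitation.  Two modelling choices matter:

* **Leakage is a constant fraction of the donor excitation budget**
  (`β Q` while the donor is alive) rather than of the instantaneous donor
  emission.  With this convention the two standard corrections are exact
  inverses of the generator: the apparent-E formula
  `(I_A − β I_D)/(I_D + I_A)` recovers each state's `fret_mean`
  identically in the noiseless limit, and the raw acceptor-drop /
  donor-rise ratio across an acceptor photobleach step equals `γ` exactly.
  With emission-proportional leakage neither identity holds and the
  calibrations the field actually uses would be biased by construction.
* **`E_phys` is obtained by inverting the apparent-E formula** through the
  γ/β model, so the state levels stored in fixtures are the apparent
  efficiencies the experiments print, not hidden physical transfer
  efficiencies.

Each dye photobleaches at most once (exponential times under
illumination; blinking is not modelled, as measurements of this kind use
oxygen-scavenging/triplet-quenching buffers).  After donor bleaching the
acceptor channel carries only direct excitation plus background — which is
exactly what the direct-excitation correction exploits — and after
acceptor bleaching the donor recovers the full budget.  Shot noise is
Poisson per channel; background is Gaussian (sd 15 photons/frame by
default).  The photon budget (1000 photons/frame) and background were
chosen to give block-averaged histogram peak widths (σ ≈ 0.04) comparable
to published FRET histograms of this system; the per-frame state noise
default is 0.08.

# Corrections

`subtract_direct_excitation()` estimates the per-trace acceptor offset
from the mean acceptor intensity after donor bleaching while the acceptor
is alive (≥ 10 frames by default), with a movie-median fallback for traces
whose donor outlives the recording or the acceptor.  `estimate_gamma()`
takes the median over acceptor-bleach step ratios (10-frame window means,
minimum step filter against no-FRET molecules), with a bootstrap standard
error; direct excitation must be subtracted first, otherwise its loss at
the bleach step inflates the ratio.  `estimate_beta()` uses donor-only
molecules, on which the acceptor channel is pure leakage: the per-frame
ratio `I_A/I_D` equals β; per-trace medians are aggregated as their kernel
density mode.  The uncorrected donor-only FRET peak sits at `β/(1+β)` —
a useful self-check.  `compute_fret_gamma()` implements the γ-corrected
efficiency with the denominator written exactly as the field's
distance-estimation formula, `γ(I_D + β I_D) + I_A − β I_D`; this term
differs from the more common `γ I_D` convention, so a `conventional`
switch is provided rather than silently "fixing" it.  At `γ = 1` both
reduce algebraically to the apparent-E formula.

# Histograms and mixtures

FRET histograms use five-frame non-overlapping block averages (one value
per block, so single events are not triple-counted as sliding windows
would), 60 half-open bins on [−0.1, 1.1] by default (the bin count is a
package choice; results are tested for robustness to doubling it).
`fit_mixture()` fits 1–3 Gaussian components to the bin counts by weighted
least squares with Poisson weights — mirroring how such histograms are
fitted in practice — with ten seeded starts whose candidate means
alternate between weighted quantiles and an even grid over the occupied
range (the grid finds rare, well-separated peaks that quantiles miss).
Component standard errors come from the fit covariance (a bootstrap would
also be defensible; covariance was chosen for determinism and speed).
`select_k()` compares k = 1..3 by BIC computed from the Poisson
log-likelihood of the binned fit, with ties resolved toward smaller k and
a low-power fallback to k = 1 below 200 values; a manual k override is
available wherever histograms are fitted, since the source analyses chose
k per condition by inspection.

# Hidden Markov modelling

`fit_hmm()` implements pooled maximum-likelihood Baum–Welch across traces
with shared Gaussian emissions and a shared per-frame transition matrix.
This deliberately replaces the empirical-Bayes variational treatment used
by ebFRET-style tools: for traces recorded under one condition the pooled
ML estimand is the same per-frame transition matrix, and the EM fit is
simpler, fast and deterministic given a seed.  Restarts matter more than
priors here: emission means are initialized from (1) a Gaussian
decomposition of the pooled FRET histogram, (2) k-means centres, (3) an
even grid over the pooled range, then jittered quantile grids.  The
histogram-based start is the important one when state occupancies are
very uneven (a 4% closed-state population at E = 0.135 under an 85%
scrunched population is invisible to quantile grids).  Convergence is
declared at a relative log-likelihood change below 1e-6 (capped at 300
iterations); restarts that starve a state below one expected frame are
discarded.  The forward–backward and Viterbi recursions are implemented
in C++ (Rcpp) with standard scaling; Viterbi ties break toward the lower
state index.

`rates_from_model()` converts per-frame transition probabilities to rates:
first-order `k = p/Δt` for all pairs, plus the exact embedded-chain
inversion for two-state models.  It serves as the cross-check; dwell-based
rates are the headline estimator, matching how unscrunching and
scrunching rates are defined in this field (inverse mean dwell times).

# Dwell times and the missed-event correction

`extract_dwells()` censors the first and last segment of every trace
(their start or end is unobserved) and flags dwells under two frames as
resolution-limited.  The plain inverse-mean estimator
(`rate_from_dwells()`) also reports an exponential ML fit and a
two-exponential likelihood-ratio flag for non-exponential dwell
distributions, which in this system indicate sub-states within the
scrunched conformation.

Camera-based recordings cannot resolve excursions much shorter than a few
frames, and a missed excursion silently concatenates two dwells.  For
rate recovery `dwell_rate_corrected()` therefore (i) imposes an explicit
resolution of 5 frames on the decoded paths, so the set of missed events
is a defined quantity instead of an accident of the decoder, and (ii)
inverts the alternating-renewal relation for the observed mean dwell,

`E[obs] = (1/k)/(1−q) + t_res + (q/(1−q)) m_short`,

where `q` is the probability that an excursion is sub-resolution *and*
returns, and `m_short` the mean sub-resolution excursion.  The `t_res`
term arises because an observed dwell must itself start with a visit
longer than the resolution (`E[S | S ≥ τ] = 1/k + τ` for exponentials).
`q` and `m_short` are obtained by *counting*, not by extrapolating a
parametric fit: the same decoded paths are re-segmented at a minimal
two-frame resolution, at which the excursions merged by the five-frame
dwell extraction are individually visible; only the small mass of
excursions below two frames is extrapolated, with an exponential rate
fitted to the short-excursion window by truncated moment matching.
(Parametric extrapolation of the full sub-resolution mass was evaluated
and rejected: a mis-fitted fast component can multiply the correction.)
This is the camera-era analogue of the classical missed-event
corrections of single-channel electrophysiology.  In recovery
simulations from the packaged +2 and +7
fixtures (20 and 40 traces × 1000 s, slow-bleach photophysics) the
corrected estimator recovers 0.305 s⁻¹ and 0.0653 s⁻¹ within a few
percent, whereas the uncorrected inverse mean is 15–25% low.

Rate-recovery simulations deliberately use extended recordings
(1000 s movies, bleach rates ≤ 5 × 10⁻⁴ s⁻¹): with ~50 s usable traces
the censoring of interior dwells alone biases an exponential inverse-mean
estimate by about `1.645/(k L)` relative (the integral of
`x e^{-x}/(1-e^{-x})` over the available window), which at `k L ≈ 3`
would dwarf the quantities being estimated.  This is a property of the
estimator, so the recovery study design removes it at the source.

# Washout kinetics, decays and branching

`simulate_washout_series()` emulates the post-washout imaging protocol:
the population evolves from the washout at t = 0, and each minute a set of
12 short (5 s) movies of fresh fields of view is recorded — fresh fields
because continuous illumination would bleach the sample long before the
12 min timecourse ends; bleaching clocks therefore start at each movie
start.  The movie length is a package assumption (the protocol's movie
duration is not pinned down numerically).  `washout_timecourse()` freezes
the mixture template (means and widths) and refits only the component
weights per minute by non-negative weighted least squares — with
~1-minute histograms a full mixture refit is unstable, and freezing the
template is what makes per-minute population fractions comparable.  The
template itself is best fitted on the pooled histogram of the
equilibrium run *and* the washout series: at equilibrium the closed
state holds only a few percent of the population, and a three-component
fit of the equilibrium alone can spend a component on transition-blur
mass instead, which then corrupts every per-minute attribution.  `fit_decay()` fits `a + b exp(−k t)` by Levenberg–Marquardt
least squares initialized from a log-linear regression of the
tail-subtracted values, reports `t½ = ln 2 / k` with delta-method errors,
and flags non-decaying series instead of fabricating rates.

`classify_post_washout()` works on the raw corrected FRET signal of
post-washout traces that start in the high-FRET state: a drop is a
non-high run of at least 3 frames (shorter flicker is merged away), a
trace is *transient* if the high state is re-entered afterwards,
*irreversible* if not, *no-drop* otherwise, with binomial errors on the
fractions.  The 3-frame guard is configurable; with the default noise
(state sd 0.08 against a 0.435 separation between open and scrunched
levels) spurious 3-frame runs are vanishingly rare.

`evolution_map()` synchronizes traces at the first *raw* frame reaching
the 0.5 threshold — raw rather than HMM-smoothed or block-averaged,
because the synchronization rule is defined on the signal itself — and
normalizes each column by the number of traces contributing at that
offset, so column sums conserve trace counts exactly.

# Geometry

`fret_to_distance()` applies the Förster relation `R = R₀(1/E − 1)^(1/6)`
to γ-corrected efficiencies.  R₀ defaults to 6.0 nm, a typical value for
a Cy3/Cy5-class pair — explicitly a configuration parameter, not a
measured one, so distance-level claims in the package are property-level
(ordering, monotonicity) rather than absolute.
`average_template_distances()` averages the two labelling geometries
(which place the downstream dye on opposite strands) to mitigate the DNA
twist contribution, combining half their difference with the propagated
input errors in quadrature.  `scrunch_model_distance()` realizes the
fixed-bend model used to interpret the distance series: two straight
B-DNA arms (0.34 nm/bp) meet at a fixed angle, only the downstream arm
shortens as bases are scrunched, and the label distance follows the law
of cosines.  The bend angle is calibrated so the unscrunched model
matches the measured open-complex distance
(`calibrate_bend_angle()`), replacing a coordinate-based calculation on a
reference crystal structure; whether position +n pulls in n or n − 1
bases is not settled, so `scrunched_bases` is an overridable function
defaulting to n − 1.

# Problem sizes, determinism and limitations

Every stochastic routine takes one integer seed and draws from a single
seeded Mersenne–Twister stream; identical seeds give bit-identical
trajectories, traces and fits.  The recovery studies in the test-suite
and acceptance script use desk-scale sizes chosen to keep each study in
the low minutes on one core while leaving estimator standard errors a few
times smaller than the tolerances being checked: 300 traces × 120 s for
histogram peak recovery (≥ 3 × 10⁴ block values per condition), 20-40
traces × 1000 s for rate recovery (≥ 10⁴ s aggregate), 200 traces for the β/γ
calibrations, 12 min × 12 movies × 17 traces for the washout timecourse,
and 300 traces for branching classification.

What passing these recoveries does *not* show about real data: the
generator draws Gaussian state noise and Gaussian background, models a
single donor–acceptor pair with a single leakage coefficient, and omits
blinking, spectral crosstalk beyond β, dye-linker dynamics, κ²
orientation effects and baseline drift.  Estimator behaviour under those
realities must be judged on real recordings; the synthetic suite
establishes correctness of the implementations, not completeness of the
physical model.
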