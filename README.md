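# scrunchFRET

Simulation and kinetic analysis of two-colour single-molecule FRET
recordings of transcription initiation.

Single-subunit RNA polymerases initiate transcription by *scrunching*:
downstream DNA is pulled into the active site base by base while upstream
promoter contacts are held, bending the template progressively until an
abrupt transition to elongation releases the bend.  With a donor dye
downstream and an acceptor upstream of the promoter, this appears as a
ladder of FRET states — closed promoter, open promoter, scrunched
initiation complexes, unbent elongation complex — with rich switching
kinetics between them.  scrunchFRET is aimed at experimentalists analysing
such recordings (and at anyone validating smFRET kinetic estimators): it
implements the complete workflow from raw donor/acceptor photon counts to
corrected FRET efficiencies, Gaussian-mixture state populations,
hidden-Markov state paths, dwell-time and washout kinetics, and
donor–acceptor distances, together with a forward simulator so every
estimator can be checked by parameter recovery.

## What is inside

* **Kinetic simulation** — `kinetic_scheme()`, `protocol()`,
  `simulate_ctmc()` (exact Gillespie sampling with time-varying NTP
  availability for flow-in/washout protocols), `render_trace()` (camera
  integration, detection asymmetry γ, donor leakage β, acceptor direct
  excitation, shot noise, photobleaching), `simulate_2ap_decay()`,
  `simulate_washout_series()`, and packaged `fixtures()` whose FRET levels
  and rates mirror the published values for the yeast mitochondrial
  system.
* **Trace correction** — `subtract_direct_excitation()`,
  `estimate_beta()`, `estimate_gamma()`, `compute_fret()`,
  `compute_fret_gamma()` (the efficiency formulas implemented exactly as
  used for this system, including the non-standard γ denominator),
  `filter_traces()`, `block_average()`.
* **Histogram decomposition** — `build_histogram()`, `fit_mixture()`
  (1–3 Gaussian peaks, Poisson-weighted least squares, multi-start),
  `select_k()` (BIC), `population_fractions()`.
* **Hidden Markov modelling** — `fit_hmm()` (pooled maximum-likelihood
  Baum–Welch with Gaussian emissions, C++ core), `viterbi()`,
  `transition_density()`, `rates_from_model()`.
* **Kinetics** — `extract_dwells()`, `rate_from_dwells()`,
  `dwell_rate_corrected()` (missed-event and resolution corrections),
  `evolution_map()`, `washout_timecourse()`, `fit_decay()`,
  `classify_post_washout()`.
* **Geometry** — `fret_to_distance()`, `average_template_distances()`,
  `scrunch_model_distance()` and `calibrate_bend_angle()` for the
  fixed-bend scrunching model.
* **Orchestration** — `run_pipeline()` chains
  simulate → correct → histogram → HMM → kinetics from a config list or
  YAML file, writing TSV/JSON artifacts and a hash manifest.

## Worked example

Simulate the stalled +2 initiation complex, recover its FRET states and
the unscrunching rate:

```r
library(scrunchFRET)

traces <- simulate_traces("IC2", n_traces = 50, seed = 1)
traces <- subtract_direct_excitation(traces)
fr     <- lapply(traces, compute_fret, params = correction_params(beta = 0.08))

h   <- build_histogram(unlist(lapply(fr, block_average)), condition = "IC2")
fit <- fit_mixture(h, k = 3, seed = 1)
fit$components[, c("weight", "mean", "sd")]
#>       weight      mean         sd
#> a1 0.1313762 0.1416263 0.04324333
#> a2 0.3682335 0.3812119 0.04449429
#> a3 0.5003903 0.5583192 0.03964324

# rate estimation wants long recordings with slow bleaching
long <- simulate_traces("IC2", n_traces = 20, seed = 2, duration = 1000,
                        phys_variant = "longmovie")
long <- subtract_direct_excitation(long)
frl  <- lapply(long, compute_fret, params = correction_params(beta = 0.08))
m     <- fit_hmm(frl, n_states = 3, seed = 1)
paths <- lapply(frl, function(f) viterbi(m, f))
dwell_rate_corrected(paths, state = 3, n_states = 3)$rate
#> [1] 0.3090735
```

The three mixture components sit at the closed (0.135), open (0.376) and
scrunched (0.563) promoter levels with roughly 13/37/50% of the
population, and the dwell-based unscrunching rate of the scrunched state
comes back at 0.309 s⁻¹ against the generative 0.305 s⁻¹ (from 1635
decoded dwells).  The `scrunchFRET-methods` vignette explains each model
and estimator in detail.

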