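# entrainkit

Input–output entrainment analysis for paired rhythmic event trains.

## What problem this solves

In closed-loop neurophysiology experiments a rhythm generator — e.g. the
respiratory central pattern generator read out as phrenic nerve bursts — is
driven by a weak periodic input, e.g. rhythmic vagal stimulus trains engaging
the Hering–Breuer reflex at a frequency matched to the intrinsic burst rate.
The scientific questions are per-trial: *is* the output phase-locked 1:1 to
the input, how strongly, how quickly does locking establish, and how long
does it persist? `entrainkit` answers these from the two event-onset trains
(plus, optionally, the continuous motor trace), for experimenters analyzing
such stimulation trials and for methodologists who want a validated,
simulator-backed reference implementation.

## What it computes

From event onsets the package builds the piecewise-linear instantaneous
phase, φ(t) = 2π (t − t_k)/(t_{k+1} − t_k) on each cycle, and derives:

* the relative phase φ_out − φ_in, its 21-bin histogram (maximum bin
  probability as a bounded coupling index) and the Rayleigh test;
* windowed phase coherence γ(t) = |mean over [t−3 s, t] of
  e^{iΔφ}|², with entrainment bouts (γ > 0.9), latency to first bout and
  phase-slip counts;
* the synchronization index (phase-locking value)
  γ_{n,m} = |⟨e^{i(nφ_out − mφ_in)}⟩|;
* the normalized cross-correlogram of the output burst envelope against the
  input square wave (min–max scaled, DC-removed, correlation convention);
* the mutual information of the instantaneous phases from a 50 × 50 joint
  histogram (nats), with an interval-shuffling bootstrap test: both trains'
  inter-event intervals are independently permuted (500 surrogates) and
  coupling is significant when observed MI exceeds the surrogates' 99th
  percentile.

Respiratory-pattern tools: threshold-crossing burst detection,
period/CV statistics, the apnea index (cycles > 1.5 × mean period, per
minute), inspiratory-time (Ti) reduction between conditions, and a 30%
frequency-drift QC.

A forced stochastic phase oscillator (`simulate_forced_trial()`, presets
`"wildtype"`, `"intermediate"`, `"severe"`) generates ground-truth trials —
matched-frequency forcing, tunable coupling gain, cycle-to-cycle period
noise and apneas — used throughout the test suite. See the vignette
(`vignettes/entrainment-analysis.Rmd`) for the model and all design
decisions.

## A worked example

```r
library(entrainkit)
report <- run_trial(trial_spec("wildtype", seed = 1))
print(report)
#> Coupling report 'wildtype' (wildtype):
#>   baseline: Ttot 0.497 s, CV 0.091, 0.00 apneas/min
#>   Ti: 0.199 -> 0.187 s (-5.9%)
#>   entrainment: sync 0.963, hist max 0.412, cc peak 0.643
#>   bouts: n 6, latency 3.3 s, mean duration 17.4 s, slips 0
#>   MI 1.7148 nats vs cutoff 0.5467 -> SIGNIFICANT
```

Reading: the simulated baseline breathes at ~0.5 s periods with CV 0.09 and
no apneas; stimulation shortens mean inspiratory time by 5.9% (the
off-switch reflex); the output locks to the input within ~3 s of trial
start (the coherence window itself is 3 s), stays locked in long bouts with
no phase slips, and the phase mutual information (1.71 nats) is far above
the 99th percentile of its interval-shuffled surrogate distribution
(0.55 nats), so the trial is significantly entrained. A `"severe"`-preset
trial (no coupling, high variability, ~3.7 apneas/min) yields sync ≈ 0.1
and a non-significant MI.

Step-by-step equivalents of `run_trial()` — `detect_bursts()`,
`instantaneous_phase()`, `relative_phase()`, `phase_coherence()`,
`detect_bouts()`, `synchronization_index()`,
`normalized_cross_correlogram()`, `mutual_information()`,
`bootstrap_mi()` — are all exported; `run_cohort()` aggregates trials into
group summaries and writes JSON/TSV reports.

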