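# tshrp — surface hopping with pump-generated coherences and repropagation

`tshrp` simulates the first femtoseconds of molecular dynamics after a
broadband ultrashort pump pulse, for people who model pump–probe experiments
with trajectory surface hopping (TSH). A spectrally broad pulse excites a
*coherent superposition* of electronic states; the resulting pump-generated
coherences (PGCs) oscillate at the interstate transition frequencies, decay
within a few femtoseconds, and leave visible fingerprints in observables such
as the molecular dipole. The package propagates them in two ways and lets you
check one against the other:

* **Full propagation (FP).** Every trajectory starts from the normalized
  first-order superposition the pump creates at its Wigner-sampled geometry,
  `c̃_k(0) = i d⃗_0k · E⃗(ω_k0)`, and electrons and nuclei are propagated
  together. Everything downstream depends on the pulse.
* **Repropagation (RP-AXE / RP-SXE).** Trajectories are first computed
  *without* initial coherences (delta-initialized per excited state — either
  all of them, AXE, or a subset selected with probability proportional to the
  oscillator strength, SXE) and are therefore pulse-independent. For any pump
  of interest, only the electronic Schrödinger equation is re-integrated
  along these frozen trajectories from the pump-generated amplitudes, and the
  ensemble is reweighted (`w ∝ |c̃_a(0)|²`, bias-corrected for SXE). Exact
  when no hops occur; cheap for every additional pulse.

Expectation values are weighted ensemble averages of quadratic forms
`A_j(t) = Σ c_i* c_i' ⟨ψ_i|Â|ψ_i'⟩` that split exactly into population and
coherence parts. The TSH engine uses velocity-Verlet nuclear steps,
local-diabatic electronic propagation (Löwdin-orthogonalized inter-step
overlaps, 51 unitary substeps), population-flux hopping with energy-conserving
momentum rescaling, and per-trajectory decoherence corrections (energy-based
EDC, or a frozen-Gaussian projected-forces-and-momenta surrogate, PFM).
Electronic structure comes from analytic diabatic models — a 1D avoided
crossing, general linear-vibronic-coupling (LVC) Hamiltonians, and a
"glycine-like" preset with two z-polarized and one bright in-plane transition
— so every result can be validated against closed forms and exact wave-packet
references.

## Worked example

Pulse-independent AXE trajectories on the glycine-like preset, repropagated
for a 0.64 fs broadband pump that coherently excites S1 and S2:

```r
library(tshrp)

gl   <- glycine_like_model()
pump <- gaussian_pulse(7.0, 2.83, polarization = c(0, 0, 1))
fwhm_duration(pump)                    # 0.64 fs

samples <- sample_wigner(gl$reference, 100, seed = 1)
cfg  <- propagator_config()            # 0.3 fs steps to 14.1 fs
dcfg <- decoherence_config("PFM")

axe   <- build_axe(samples, gl$model$n_states)          # 300 members
recs  <- propagate_ensemble(axe, gl$model, cfg, dcfg, base_seed = 7)
axe_b <- balance_ensemble(axe, vapply(recs, function(r) r$valid, TRUE))
rp    <- repropagate_ensemble(axe_b, recs[axe_b$kept], pump, gl$model, dcfg)

ser <- standard_series(rp$runs, rp$spec$members$weight,
                       records = recs[axe_b$kept])
```

Output of the summary lines:

```
S1/S2/S3 populations at t = 0:  0.353 / 0.646 / 0.001
Re S1-S2 coherence at t = 0:    0.435
Re S1-S2 coherence at t = 5 fs: -0.003
dipole x oscillation amplitude (first 5 fs): 0.864 a.u.
```

Reading: the z-polarized pump splits its population between S1 and S2 (S3 is
barely touched at this polarization), creating a large initial coherence of
0.435 — close to the theoretical two-state maximum of 0.5. The coherence
oscillates at the 1.2 eV S1–S2 gap (period ≈ 3.5 fs) and has decayed to zero
by 5 fs through single-trajectory decoherence plus ensemble dephasing; while
it lives, it drives ≈0.9 a.u. oscillations of the x dipole component via the
S1–S2 transition dipole. Repropagating the same records for a second pulse
costs only the electronic replay: `repropagate_ensemble(axe_b, recs, pulse2,
...)`.

A YAML-driven end-to-end pipeline (sample → propagate → repropagate per pulse
→ observables + manifest) is available as `run_pipeline()`; see
`inst/extdata/axe_two_pulse_example.yaml` and the thin CLI in
`inst/scripts/tshrp.R`. The methods vignette
(`vignettes/coherent-dynamics.Rmd`) documents the model, the ensemble
weights, the numerical choices and their limitations.

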