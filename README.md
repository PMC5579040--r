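# clsense

Analysis of ratiometric chloride-indicator imaging in brain slices.

Genetically encoded chloride indicators (a CFP donor fused to a
chloride-sensitive YFP) report intracellular chloride through the
fluorescence ratio **R = F₄₃₆/F₅₀₀**: chloride quenches the YFP emission,
so R rises with [Cl⁻]ᵢ. Experiments of this kind image dozens of neuronal
somata (ROIs) per acute slice, apply transporter blockers or GABA_A
agonists, and ask how chloride — and therefore the polarity of GABA
signalling — is regulated. `clsense` is for researchers analysing such
recordings; it implements the complete chain from raw two-channel ROI
intensities to clustered statistics and reversal-potential estimates:

- **Preprocessing** — per-wavelength background subtraction, ratio
  formation, single-exponential photoinactivation drift removal (gain
  correction, with dataset-level pooling of the time constant), and
  per-condition exposure normalisation to a 100 ms reference.
- **Calibration** — the four-parameter sigmoid
  `R(C) = Rmax + (Rmin − Rmax) / (1 + (C/Kd)^p)` and its exact inverse
  `C(R) = Kd·((Rmin − R)/(R − Rmax))^(1/p)`, fitted by multi-start
  nonlinear least squares; ratio changes convert to Δ[Cl⁻]ᵢ in mM.
- **Event quantification** — bath-drug effects as baseline/response window
  contrasts (ΔR per ROI); puff transients with amplitude, direction
  (influx/efflux), and recovery time.
- **Inference** — Gaussian GEE with exchangeable working correlation and
  Mancl–DeRouen bias-corrected cluster-robust SEs, slices as clusters;
  cross-solution z comparisons with Bonferroni adjustment; paired t-tests
  for electrophysiology.
- **E_GABA** — reversal potentials as x-intercepts of subtracted
  voltage-ramp I–V relations, plus Nernst/passive-distribution utilities.
- **Synthetic data** — a deterministic generator for clustered two-channel
  recordings with sensor photophysics, calibration point sets, and ramp
  pairs, all with ground-truth sidecars.

## Worked example

```r
library(clsense)

# Published calibration constants; refit your own with fit_calibration()
cal <- reference_calibration()
#> <calibration_fit> Kd = 108.8 mM, Rmin = 0.98, Rmax = 2.92, p = 2.91

inverse_model(cal, 1.0)        # resting R at the bottom of the operating band
#> 22.7  (mM — above 20 mM: chloride is actively accumulated)
delta_cl(cal, baseline_r = 1.05, delta_r = 0.27)
#> 28.7  (mM increase corresponding to a +0.27 ratio step)

# Simulate a two-condition experiment: KCC blocker bath-applied at 600 s
cfg <- sim_config(seed = 42, n_slices = 10, rois_per_slice = 4,
                  conditions = list(condition("AVP", "day"),
                                    condition("VIP", "day")))
sim <- simulate_dataset(cfg)

# Preprocess (background -> ratio -> drift -> exposure), quantify, infer
ratios  <- preprocess_dataset(sim$recordings)
effects <- build_effects_table(sim$recordings, ratios, "bath_VU")
attr(effects, "counts")
#>             condition n_slices n_rois   label
#> 1 AVP.day.bicarbonate       10     40 10 (40)
#> 2 VIP.day.bicarbonate       10     40 10 (40)

fit_gee(effects, terms = "neuron_type")
#> <gee_fit> delta_r outcome, exchangeable working correlation (rho = 0.985), 20 clusters / 80 obs
#>                estimate robust_se      z         p
#> (Intercept)      0.1602   0.01011 15.846 1.496e-56
#> neuron_typeVIP   0.1065   0.01313  8.107 5.185e-16
```

The intercept is the AVP-day drug effect in ratio units (truth 0.18, seen
through the analysis windows as ~0.177); the `neuron_typeVIP` term is the
VIP-vs-AVP contrast (truth 0.09). Both sit within two robust SEs of their
generating values — the property the acceptance suite verifies over 100
seeded replicates.

```r
# Reversal potential from a noisy simulated ramp pair (truth -47 mV)
p <- simulate_ramp(egaba_true_mV = -47, conductance_nS = 1.5,
                   noise_pA = 5, seed = 42)
estimate_egaba(subtract_ramp(p))
#> <egaba_estimate> E = -46.56 mV, g = 1.39 nS, R2 = 0.6056 (n = 67 in [-59.5477, -39.5477] mV)
```

## Command line

```sh
Rscript inst/exec/clsense simulate  --seed 7 --out data/
Rscript inst/exec/clsense calibrate --points points.csv --out fit.json
Rscript inst/exec/clsense analyze   --traces data/traces.csv \
    --manifest data/manifest.json --out results/
Rscript inst/exec/clsense egaba     --ramps ramps.csv --out egaba.json
Rscript inst/exec/clsense stats     --effects effects.csv --terms neuron_type,phase --out stats.json
```

Each command writes a run-log JSON (config hash, package version, seed)
next to its outputs. Exit codes: 0 success, 2 schema/validation error,
3 numerical failure.

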