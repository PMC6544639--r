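# guvepore

Quantitative analysis of electroporation experiments on giant unilamellar
vesicles (GUVs), for membrane biophysicists working with high-speed
bright-field and confocal imaging of vesicles under DC pulses.

When a pulse drives the induced transmembrane voltage
`Ψ_m = 1.5 R E (1 − exp(−t/τ_c))` past its critical value, an empty GUV
opens micrometre-scale macropores and reseals in milliseconds, while a
GUV carrying a membrane-bound actin shell stays macropore-free but
remains permeable for minutes — and at high fields the shell itself is
destroyed. This package implements the full measurement chain behind
those statements:

* **Contour tracking** (`track_sequence`): Canny-style edge detection,
  constrained conic (ellipse) fitting and a whole-image model polish
  give subpixel semi-axes `a` (along-field) and `b`, the deformation
  ratio `a/b` and projected area per frame, with macropore arcs bridged
  and flagged.
* **Kinetics** (`fit_relaxation`, `fit_uptake`, `classify_poration`):
  single/double exponential relaxation of `a/b` (τ₁ ~ 100 µs;
  τ₂ ~ 1 ms, the macropore closure time η_s r/2γ; τ₃ ~ 10 ms) with
  information-criterion model selection, and saturating-exponential
  dye-uptake fits `I(t) = I_∞ + (I_0 − I_∞) exp(−t/τ_uptake)`.
* **Per-pulse normalization** (`normalized_area`,
  `bleach_corrected_intensity`, `fit_field_sigmoid`):
  `A_norm(n) = (A_f/A_i)_n (A_f/A_i)_{n−1}`, photobleaching correction
  `I_norm = I_k/(I_0 I_ref,k)` against a no-pulse reference, and
  logistic fits of area/actin loss versus field strength.
* **Cortex force balance** (`force_report`): filament count
  `N_f = c_0 (4/3)πR³ d / l`, mesh size `ζ = √(A/N_f)`, the mesh
  stretch Δζ under the volume-conserving spheroid map
  `a = e^(2/3)R, b = e^(−1/3)R`, the mechanical force
  `f_m = k_stretch Δζ` and the electrophoretic force
  `f_ep = ξ_h μ_B (0.8E) l` on a filament once the membrane is porated.
* **Synthetic data** (`generate_deformation_trace`, `render_frame`,
  `generate_uptake_trace`, `generate_pulse_series`): seeded generators
  for image sequences and numeric traces with known ground truth, so
  every stage above is testable without microscope data.

## Worked example

The force balance for a 10 µm vesicle deformed to a/b = 1.18 under a
150 V/mm pulse:

```r
library(guvepore)
force_report(R_um = 10, e = 1.18)
#> Actin-cortex force balance
#>   R = 10.00 um, e = a/b = 1.180, E = 150 V/mm (porated: TRUE)
#>   filaments N_f         : 1.1e+04
#>   mesh size (sphere)    : 338.1 nm
#>   mesh size (spheroid)  : 338.9 nm
#>   mesh stretch dzeta    : 0.801 nm
#>   mechanical force      : 38.4 pN (below rupture range: insufficient alone)
#>   electrophoretic force : 163.2 pN (within rupture range: sufficient to disrupt the network)
```

The ~10⁴ filaments of the shell stretch by less than a nanometre during
the deformation, so mesh stretching (tens of pN) cannot break the
network — but the electrophoretic pull on a filament once the field
penetrates the porated membrane (~160 pN) reaches the 100–400 pN
rupture range.

Recovering relaxation times from a synthetic porated-vesicle trace, and
uptake kinetics from a synthetic resealing trace:

```r
sc <- deformation_scenario(ab_max = 1.2,
                           tau_list = list(c(1, 1e-3), c(0.5, 1e-2)),
                           duration_s = 0.1, noise_sigma = 0.01, seed = 42)
tr <- generate_deformation_trace(sc, optics_params(frame_rate = 10000))
fit_relaxation(tr, model = "auto")
#> double-exponential relaxation fit (n = 994)
#>   tau_fast = 0.0008406 s (amplitude 0.1417)
#>   tau_slow = 0.009432 s (amplitude 0.07009)

fit_uptake(generate_uptake_trace(uptake_scenario(seed = 42)))
#> uptake fit: I_inf = 0.3792, I0 = 0.0006192, tau = 146.5 s (n = 901)
```

The fitted 0.84 ms / 9.4 ms pair recovers the generative 1 ms / 10 ms
macropore and membrane relaxation scales, and the uptake fit returns
the slow actin-vesicle resealing regime (τ ≈ 146 s, I_∞ ≈ 0.38, i.e.
38% equilibration with the outside dye).

An end-to-end synthetic run (synthesize → track → fit → normalize →
force report) is one call:

```r
run_pipeline(list(seed = 7))
```

or, from a shell, `inst/scripts/guv-epore demo --seed 7`.

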