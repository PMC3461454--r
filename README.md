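# t1rhoMI

Quantification of chronic myocardial infarction from spin-lock (T1ρ)
cardiovascular MR — without contrast agents.

Late gadolinium enhancement (LGE) is the reference CMR method for imaging
myocardial scar, but it requires a gadolinium injection that is
contraindicated in renal failure. Chronic scar carries a markedly longer
rotating-frame relaxation time T1ρ than healthy myocardium (roughly 92 ms
vs 47 ms at 3 T with a 500 Hz spin-lock), so T1ρ-weighted imaging at long
spin-lock durations yields endogenous scar contrast. `t1rhoMI` implements
the full measurement chain for this contrast mechanism on synthetic
short-axis left-ventricle phantoms (or any user-supplied multi-TSL NIfTI
stack with matching metadata):

1. **Phantom simulation** — an annular LV myocardium with a sectoral infarct
   of configurable angular extent and transmural depth; partial volume by
   supersampled rasterization; mono-exponential spin-lock decay
   `S(TSL) = Σ_t frac_t · S0_t · exp(−TSL / T1ρ_t)` over the tissue
   compartments at TSL = 6, 18, 30, 42, 48 ms; Rician magnitude noise.
2. **Relaxometry** — pixelwise nonlinear least-squares T1ρ mapping
   (log-linear closed form as initializer), with validity masks and regional
   statistics.
3. **Chord segmentation** — 20 circumferential wedges × 5 radial sections
   about the cardiac centroid; normalized mid-myocardial (sections 2–4)
   signal.
4. **Infarct metrics** — threshold classification (default
   remote mean + 5 SD), infarct size as the ratio of infarct endocardial
   perimeter to total endocardial perimeter, chord-based transmurality,
   tissue mass at 1.06 g/mL, and contrast-to-noise ratio
   `(S_infarct − S_remote) / σ_noise`.
5. **Method agreement** — Bland–Altman limits of agreement, correlation, and
   two-way fixed-effects ANOVA between modalities.

## Worked example

```r
library(t1rhoMI)
cfg <- run_config(seed = 1L)   # default phantom: 192x192, 20 slices,
                               # 21.1% transmural infarct arc, SNR 50
report <- quantify_phantom(cfg)
print(report)
```

```
Infarct report (seed 1)
  infarct size        : 21.1 % of endocardial perimeter (truth 21.1)
  transmural wedges   : 100.0 %
  non-transmural      : 0.0 % of infarct volume
  infarct mass        : 17.15 g (LV 81.0 g, 21.2 %)
  CNR (longest TSL)   : 11.45
```

The infarct size is the endocardial-perimeter ratio after the noisy stack
has been fitted, classified against a remote reference region, and projected
onto the endocardial contour — here it recovers the phantom's true 21.1% arc
fraction. Masses follow from classified voxel counts at 1.06 g/mL; the CNR
uses the noise level re-estimated from the image background.

Regional relaxometry on the same stack
(`analysis/02_fit_t1rho_map.R`) prints:

```
infarct    T1rho =  92.30 +/-  6.71 ms (median  91.80, n = 14760)
remote     T1rho =  47.36 +/-  2.36 ms (median  47.24, n = 48600)
borderzone T1rho =  68.24 +/- 14.65 ms (median  67.62, n = 640)
delta T1rho (infarct - remote) = 44.94 ms
```

The `analysis/` directory holds the numbered workflow drivers
(`01_simulate_phantom.R` … `05_method_agreement.R`); each is a thin script
over the package functions that prints what it found and writes its tables
under `results/`.

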