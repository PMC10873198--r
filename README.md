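# idrfret

Correlative in-vitro / in-cell analysis of intrinsically disordered
protein (IDP) ensembles measured with FP–IDP–FP FRET "dumbbell"
constructs (mTurquoise2 donor, mNeonGreen acceptor).

Disordered regions do not fold; they are described by conformational
ensembles whose compaction and chemical sensitivity are encoded in
sequence. `idrfret` implements the quantitative chain that turns raw
measurements into ensemble statements:

- **Spectral FRET** — decompose a construct's emission spectrum into
  donor and sensitized-acceptor components by least squares against
  area-normalized basis spectra, and convert to the apparent efficiency
  `E = 1 − F_d / ((Q_d/Q_a)·F_s + F_d)` with `Q_d = 0.93`, `Q_a = 0.8`.
- **GS-repeat standard** — fit the linear efficiency-vs-length
  calibration of glycine–serine repeat constructs, interpolate a
  "GS-equivalent" baseline at any linker length with full error
  propagation, and classify constructs as compact/expanded relative to it.
- **Solution-space scanning** — per-condition ΔE against the buffer, each
  condition decomposed with its own basis spectra, with deviations from
  the GS response and sensitivity calls.
- **SAXS / SEC** — Guinier fits with self-consistent `q·Rg ≤ 1` range
  selection, Kratky transforms, Shannon-channel χ²_free goodness of fit,
  and chromatogram peak positions.
- **Coarse-grained ensemble model** — Metropolis Monte Carlo sampling of
  an FP–linker–FP dumbbell (1 bead/residue, square-well attraction scale
  `s`), Debye forward scattering, greedy χ²_free subensemble selection
  against a target SAXS curve, and Förster conversion
  `E = R₀⁶/(R₀⁶ + R_e⁶)` with `R₀ = 62 Å`.
- **Live-cell ratiometric FRET** — rigid registration, donor-channel
  segmentation (1,500–40,000 counts), particle filters (65–845 μm²,
  circularity 0.1–1.0), bleedthrough/cross-excitation correction from
  single-fluorophore controls, per-cell `E_f = F_A/(F_D+F_A)` before and
  after an osmotic challenge with the published exclusion rules, violin
  summaries and exact Mann–Whitney localization comparisons.
- **Sequence descriptors** — FCR, NCPR, windowed Kyte–Doolittle
  hydropathy and the charge-patterning parameter κ.
- **Synthetic data** — deterministic generators for every input class
  (spectra, SAXS profiles, chromatograms, multi-cell 3-channel image
  pairs) with machine-readable ground truth, so every stage is testable
  without downloads.

## Worked example

Plant an apparent efficiency, add noise, and recover it:

```r
library(idrfret)

cfg   <- fret_config()
basis <- make_basis_spectra(cfg)          # donor peak 474 nm, acceptor 517 nm
spec  <- synth_construct_spectrum(construct_spec("GS16", 32, true_ef = 0.42),
                                  basis,
                                  noise = spectrum_noise(relative_noise = 0.005),
                                  seed = 1)
fit <- spectral_fret(spec, basis)
fit
#> spectral decomposition: F_d = 674.735, F_s = 419.629, rms = 0.0673
#>   apparent FRET efficiency = 0.41961
```

`F_d` and `F_s` are the decoupled donor and sensitized-acceptor
contributions; the efficiency recovers the planted 0.42 to half a percent
at 0.5 % spectral noise.

Fit the GS standard and read off a 34-residue baseline:

```r
gs  <- fit_gs_standard(data.frame(residues = c(0, 16, 32, 48, 64, 96),
                                  ef       = 0.5 - 0.005 * c(0, 16, 32, 48, 64, 96)))
gs_equivalent(gs, 34)
#>   residues   ef se extrapolated
#> 1       34 0.33  0        FALSE
```

Sample a dumbbell ensemble and convert to FRET:

```r
ens <- sample_dumbbell_ensemble(dumbbell_params(48, attraction_scale = 0.45,
                                                n_conformers = 500, seed = 2))
ensemble_fret_summary(ens, r0 = 62)$mean_ef
#> [1] 0.7066067
```

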