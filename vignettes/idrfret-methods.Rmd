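---
title: "Models and methods behind idrfret"
author: "idrfret authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind idrfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idrfret)
```

# Scope

`idrfret` implements the analysis chain used to compare intrinsically
disordered protein (IDP) ensembles in vitro and in live cells with
FP--IDP--FP FRET "dumbbell" constructs (mTurquoise2 donor, mNeonGreen
acceptor): spectral unmixing of bulk emission spectra, the glycine--serine
(GS) repeat length standard, solution-space scanning, SAXS Guinier and
Kratky analysis with the chi-square-free statistic, a coarse-grained
ensemble model with SAXS-matched subensemble selection and Förster
conversion, a three-channel ratiometric live-cell image pipeline, and
sequence charge-patterning descriptors.  Every stage can be exercised on
synthetic inputs with planted ground truth, which is how the package
validates itself.

# Spectral unmixing and the apparent FRET efficiency

A construct's emission spectrum under donor-band excitation is modelled as
a linear mixture of the area-normalized free-donor and free-acceptor
emission spectra measured in the same solution condition,
$S(\lambda) \approx F_d\, f_d(\lambda) + F_s\, f_a(\lambda)$, solved by
unconstrained least squares over the full 450--600 nm grid.  The apparent
efficiency is

$$E_f^{app} = 1 - \frac{F_d}{\frac{Q_d\,\rho}{Q_a} F_s + F_d},$$

with quantum yields $Q_d = 0.93$ (mTurquoise2) and $Q_a = 0.8$
(mNeonGreen).  The factor involving the two basis curves is implemented as
the scalar area ratio $\rho$ of the curves as used in the regression; with
area-normalized bases $\rho = 1$ and the formula reduces to
$1 - F_d/((Q_d/Q_a)F_s + F_d)$.  This is the only reading under which the
expression is a scalar, and it makes the estimate invariant to the overall
amplitude of the measured spectrum (veriﬁed as a property test).

Two numerical choices matter.  The regression is unconstrained and
unweighted over the whole wavelength grid: negative coefficients raise a
quality flag instead of being clamped, because clamping biases $E$
estimates near 0 and 1.  And efficiencies outside $[-0.05, 1.05]$ flag
rather than error, since slightly out-of-range values are the expected
signature of noise at the boundaries.

The synthetic generator inverts the same equation: given a planted $E^*$
it emits $F_d \propto (Q_d\rho/Q_a)(1 - E^*)$ and $F_s \propto E^*$, so a
noiseless round trip must return $E^*$ to numerical precision (tested at
$10^{-9}$ over the whole $[0, 1]$ grid).  Basis shapes are smooth
single-peaked curves with maxima near 474 and 517 nm; the exact line
shapes are nuisance parameters, as only peak ordering, smoothness and area
normalization enter the analysis.

# The GS-repeat standard

GS repeats are treated as a bias-free length standard whose apparent
efficiency decreases linearly with residue count (2 residues per repeat).
The calibration line is fitted by ordinary least squares to per-length
averages; replicates at one length are averaged before fitting, so each
length carries equal weight.  Interpolation at an arbitrary length
propagates the full parameter covariance,
$\mathrm{Var}(E) = \mathrm{Var}(b) + x^2\mathrm{Var}(m) + 2x\,
\mathrm{Cov}(b, m)$, and lengths outside the fitted range are flagged as
extrapolations rather than refused.  A construct is called compact
(expanded) relative to its GS-equivalent when it exceeds (falls below) the
baseline by more than $k$ combined standard errors, $k = 1$ by default;
the margin is configurable because the underlying comparison in practice
is made by eye on non-overlapping error bars, and no universal numeric
criterion exists.  An absolute tolerance of $10^{-9}$ on the difference
prevents floating-point fuzz from flipping calls on error-free inputs.

With six fitted lengths the slope standard error carries 4 degrees of
freedom, so the calibrated 95% recovery interval in the simulation tests
uses the $t_4$ quantile (2.78 se), not 2 se; the plain 2-se band covers
only about 88% of seeds.

# Solution-space scanning

A scan measures $\Delta E_f^{app} = E_{solute} - E_{buffer}$ for a panel
of solutes, each condition decomposed with its own basis spectra (the free
fluorophores re-measured in the same solution, correcting solute effects
on emission).  The buffer row is fixed at exactly zero by construction.
When per-condition GS fits are supplied, the scan reports the deviation of
the construct's response from the GS-equivalent response at matched length
and classifies each condition as more sensitive, less sensitive, or
indistinguishable using the same $k$-combined-error margin.

# SAXS: Guinier, Kratky, chi-square-free

The Guinier fit is weighted least squares of $\ln I$ on $q^2$
($\sigma_{\ln I} = \sigma / I$), with a self-consistent upper bound: the
window shrinks or grows until $q_{max} R_g \le 1.0$ (the default limit;
1.3 is offered for flexible chains) and the fitted radius is stable to a
relative $10^{-4}$ between iterations, at most 50 iterations.
$R_g = \sqrt{-3m}$ and its error follows from the slope error by
$\sigma_{R_g} = \tfrac{3}{2R_g}\sigma_m$.  Log-space weighted fitting
matches the classical Guinier-plot procedure; a nonlinear fit in linear
space would weight the same data differently.  The number of leading
points to drop (beamstop proximity) is exposed as `q_min_index` because
real detectors corrupt the lowest channels; the synthetic profiles do not.
On the ideal Debye chain, whose Guinier law holds only asymptotically, the
fit at $qR_g \le 1$ recovers $R_g$ to within about 4%, which is the known
truncation bias of the expansion, not an implementation error.

The chi-square-free statistic guards against oversampled q grids: the
measured range is split into $\lceil q_{max} D_{max} / \pi \rceil$ Shannon
channels ($D_{max} \approx 3 R_g$ from an internal Guinier fit unless
supplied), one point is drawn per channel per round, the model is
optimally scaled to the data on the drawn points, and the median reduced
chi-square over 500 rounds is reported.  With scaling enabled the divisor
is $n - 1$; with scaling disabled it is $n$, which makes a uniform
one-sigma offset score exactly 1 — the statistic's second analytic anchor
besides 0 for a perfect model.

SEC peaks are located by parabolic interpolation through the apex and its
neighbours, requiring the apex to clear three times the trace's median
absolute deviation; the reported uncertainty is the half-width of the
region within 99% of apex height or one grid step, whichever is larger.

# The coarse-grained dumbbell model

The package replaces atomistic simulation with a deliberately minimal
dumbbell: one bead per linker residue (3.8 Å bonds, 1.9 Å hard radius) on
a freely jointed chain, flanked by two rigid 16 Å spheres standing in for
the FP beta barrels.  Non-adjacent linker beads attract through a square
well of depth $s \cdot \varepsilon_0$ ($\varepsilon_0 = 1\,k_BT$) within
6 Å; the FP spheres interact by excluded volume only, so attraction is
confined to intra-linker contacts, mirroring the published Hamiltonian
restriction.  Sampling is Metropolis Monte Carlo with bond-preserving
pivot and single-bead crankshaft moves.  The sweep convention for $s$ runs
from 0.30 (random coil) to 0.62 (compact globule), and the campaign
arithmetic on the published schedule (lengths {8, 16, 24, 32, 48} repeats,
$s$ in steps of 0.02, 1,000 simulations per combination, 100,000 steps
with 50,000 equilibration and sampling every 5,000) reproduces the three
printed counts: 10 samples per simulation, 10,000 conformers per
combination, 85,000 simulations in total.

Only the analysis logic of the published pipeline is reproduced — scale
sweep, forward scattering, chi-square-free subselection, Förster
conversion — not its energetics; all validation is planted-truth recovery
on the model's own terms.

Two observables are recorded per conformer.  `re` is the FP
center-to-center distance used for FRET conversion.  `re_linker` is the
first-to-last linker-bead distance: because the FP spheres add a
length-independent ~36 Å to `re`, excluded-volume (self-avoiding-walk)
scaling $\langle r \rangle \sim n^{\nu}$, $\nu \approx 0.588$, is visible
only in the linker extension (measured log--log slope ≈ 0.61 over
$n \in \{16, 48, 96\}$ at $s = 0$; the slope on `re` would be ≈ 0.33 for
purely geometric reasons).  The radius of gyration is mass-weighted with
the FP spheres as uniform spheres (parallel-axis $\tfrac{2}{5}R^2$ term,
mass 230 residues each), which makes it consistent with the scattering
definition below.

Forward scattering is the Debye double sum over scattering centers: each
bead a point scatterer of unit mass, each FP sphere its uniform-sphere
form factor with mass 230, cross-terms over center distances, normalized
so $I(0)$ equals the squared total mass.  A Guinier fit of the ensemble
curve therefore recovers the root-mean-square `rg` of the ensemble — the
consistency test that ties the two modules together.

Subensemble selection is greedy stochastic exchange on the
chi-square-free objective, evaluated on a draw set frozen from the seed so
that accepted swaps are monotone improvements and the whole search is
deterministic.  The published work states only the selection criterion,
not the search algorithm; greedy exchange is the simplest deterministic
choice and planted-truth tests (a compact subensemble hidden among
expanded decoys) verify that it recovers the planted mean $R_g$ to within
a few percent.  The reported statistic is recomputed on the final subset
with the full-round estimator.  The package reports the chi-square-free
value and leaves "matched/not matched" thresholds to the user, since no
published acceptance threshold exists.

Ensemble efficiencies use $E = R_0^6 / (R_0^6 + r_e^6)$ with $R_0 = 62$ Å
(mTurquoise2--mNeonGreen) applied per conformer and then averaged
($\langle E(r) \rangle$, the isotropic dynamic-averaging-free convention),
with the central 50% of per-conformer values as the spread.

# The live-cell ratiometric pipeline

Each acquisition is six images: donor, FRET (donor excitation, acceptor
emission) and direct-acceptor channels, before and after an osmotic
challenge (canonical conditions 100, 300, 750 mOsm).  The stages are:

1. **Rigid registration** of the after-frames to the before-frames:
   rotation by golden-section search over ±5° around FFT
   cross-correlation for translation, subpixel via parabolic peak
   interpolation.  Registration aborts when the normalized correlation
   peak is below 0.15, which rejects frames with no common content.
2. **Segmentation** on the donor channel before perturbation: fixed
   threshold keeping raw counts in [1,500, 40,000], 3×3 disc opening,
   distance-transform watershed, connected components.  The mask is frozen
   and reused on the registered after-frames.
3. **Particle filtering**: area within [65, 845] μm² and circularity
   $4\pi A / P^2$ within [0.1, 1.0], perimeter from the traced boundary
   contour.  Discretization can push an ideal disk's ratio slightly above
   1, so circularity is capped at 1 (the same convention ImageJ uses).
   Every region appears in an audit table with its metrics and its
   keep/drop reason, and the audit conserves counts by construction.
4. **Spectral-mixing correction**: bleedthrough $b$ and cross-excitation
   $c$ are slopes of regressions through the origin over single-
   fluorophore control cells (at least 10 each), with a purity check
   warning when a control population shows the other fluorophore's
   signal.  Corrections are applied to the FRET channel only
   ($F_A = \mathrm{fret} - b\,\mathrm{donor} - c\,\mathrm{direct}$);
   donor and direct channels are taken as pure, matching the
   two-control-construct design.  Noise can push a true-zero factor
   marginally negative; estimates are clamped at 0.
5. **Per-cell efficiencies**: $E_f^{cell} = F_A / (F_D + F_A)$ per
   timepoint and $\Delta E_f^{cell}$ as their exact difference.  Exclusion
   rules flag (never silently drop): donor mean above 10,000 counts;
   absolute direct-acceptor change above 2,000 counts; corrected
   $F_D/F_A$ negative or above 6.  The intensity cap is applied to the
   donor channel and the ratio filter to the before timepoint by default
   — the published description does not pin down either choice, so both
   are configuration options.  Background subtraction (median of
   non-cell pixels) is available but off by default so the absolute count
   thresholds apply to raw data.
6. **Summaries**: median with central 50% and 95% percentile intervals
   (linear-interpolation convention, stated because the interval values
   depend on it), over unflagged cells only.

Localization comparisons divide each compartment's efficiencies by the
median of an equivalent GS construct in that compartment and apply a
two-sided Mann--Whitney test: exact enumeration for tie-free pooled
samples of at most 12, normal approximation with tie correction
otherwise.

## What the image generator emulates, and what it does not

Synthetic pairs contain non-overlapping disk cells with per-cell
efficiencies from a Gaussian, brightness that splits between donor and
FRET channels as $(1-E)A$ and $EA$, configurable mixing factors, a small
rigid shift (≤5 px) and rotation (≤2°) of the after-frame, and
signal-proportional Gaussian noise (camera-like; Poisson statistics are
indistinguishable at the simulated counts).  Disk radii straddle the area
window so the particle filter is exercised in both directions, and
planted artifact cells each violate exactly one exclusion rule.  The
generator does not model point-spread functions, photobleaching,
cell migration or morphology change, phase-separated condensates, or the
decomposition of cell-to-cell variance into expression level, cell state
and composition — its single Gaussian spread knob lumps these together.
Passing pipeline tests therefore demonstrate correct bookkeeping,
registration, correction arithmetic and filter logic, not robustness to
every real-microscope pathology.

# Sequence descriptors

FCR and NCPR count D/E as negative and K/R as positive with histidine
neutral and termini uncharged, the convention of the descriptor tooling
used in this field.  Hydropathy is the Kyte--Doolittle value averaged
over a 5-residue centered window, truncated (not mirrored) at the
termini.

Kappa compares the mean squared deviation of windowed charge asymmetry
(blob sizes 5 and 6) from the global asymmetry against the same quantity
for the maximally segregated rearrangement of the composition —
positives, then neutrals, then negatives — and is clamped to [0, 1].  The
normalizing arrangement is that single canonical form (its mirror image
and charge swap are exactly equivalent): on sequences whose length is
close to the blob size, exotic permutations with charges at both extreme
ends can exceed the segregated arrangement's deviation, and normalizing
against a larger candidate set would break the defining property that the
segregated arrangement itself scores exactly 1.  The clamp absorbs those
short-sequence artifacts; exhaustive enumeration over every composition
of length 5--8 confirms that the segregated arrangement scores 1 and no
permutation exceeds it.  Kappa is undefined (NA) below length 5, where no
blob window fits, and for compositions with no possible asymmetry
variation.

# Problem sizes and determinism

Every stochastic operation takes an explicit integer seed and is
reproducible to the bit.  The validation suite uses desk-scale problem
sizes chosen to make each statistical check decisive: 100 noise seeds for
spectral bias, 200 for Guinier bias, 500 conformers per attraction scale,
a 2,000-conformer pool for subensemble recovery, 50-cell image pairs at
512×512 px, and exhaustive enumeration for kappa up to length 8.

# Known limitations

The dumbbell model is not an atomistic ensemble and its attraction scale
is not the Lennard-Jones scale of an implicit-solvent force field; only
the ordering (larger $s$, more compact) and the analysis chain transfer.
Spectral decomposition assumes the construct spectrum is exactly a
two-component mixture; chemical environments that reshape a fluorophore's
emission beyond what the per-condition bases capture will surface as
residual and flags, not corrected values.  The image pipeline assumes
rigid drift; cells that move independently violate the frozen-mask
assumption and are expected to be caught by the direct-acceptor-change
filter rather than re-segmented.
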