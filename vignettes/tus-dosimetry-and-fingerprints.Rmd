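---
title: "Modelling TUS dose and testing connectional fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TUS dose and testing connectional fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette explains the models behind `tusmod`, the choices made where
the design was genuinely open, and what the synthetic-data tests do and do
not establish about real data.

## 1. The acoustic model

The package estimates the *steady-state* focused pressure field of a
spherical-cap transducer rather than solving the full time-domain wave
equation. The quantities of interest for dosimetry — peak steady-state
pressure, pulse-average intensity, and the heat-production term of the
bioheat equation — are all functions of the monochromatic steady state, so
a Rayleigh surface integral over the cap

$$p(\mathbf{x}) = \frac{k}{2\pi}\left|\int_S a(\mathbf{x}')
  \frac{e^{ikR}}{R}\, dS'\right| \, p_0$$

suffices, with each voxel's amplitude further reduced by
$\exp(-\int \alpha\, dl)$ along the straight ray from the cap apex (a ray
approximation: refraction and reverberation in the skull are neglected).
What this misses relative to a full-wave solver — standing waves, shear
conversion in bone, focal shift from refraction — is partially absorbed by
the calibration step: as in experimental practice, the simulated free-water
maximum is rescaled to the hydrophone calibration of the transducer
(1.2 MPa at 130 V, linear in drive voltage), anchoring absolute amplitude.

Parameters and defaults:

* Transducer: 63 mm radius of curvature, 64 mm active diameter. The
  apodization parameter (r = 0.35) is interpreted as a radial Gaussian
  amplitude taper whose rim amplitude is 0.35 of the centre value; the
  underlying device specification does not define it further, so this is a
  package choice. Setting `apodization_r = 1` recovers a uniform cap, for
  which the classical on-axis closed form (`oneil_onaxis()`) applies; the
  discretised integral agrees with an independently coded brute-force
  quadrature within 2% at the focus.
* Medium maps: density and sound speed affine in Hounsfield units, HU 0 →
  (1000 kg/m³, 1500 m/s), `hu_ref` (default 2000, a configuration value
  because CT calibrations differ) → (2200 kg/m³, 3100 m/s). Porosity
  $\phi = (\rho_{max}-\rho)/(\rho_{max}-\rho_{water})$; attenuation
  $\alpha_0 f^b \phi^\beta$ with $\alpha_0 = 8$ dB/cm/MHz$^b$, $b = 1.1$,
  $\beta = 0.5$, converted to Np/m with the constant 8.6859 dB/Np.
  Soft tissue is acoustically water.
* One caveat on the on-axis geometry: for this moderate-gain cap the true
  axial pressure peak sits about one wavelength *proximal* of the geometric
  focus (the classical low-gain focal shift); tests assert the peak within
  8 mm of the focus and a focal amplitude within 15% of the peak.

Attenuation and absorption are kept distinct: attenuation (absorption +
scattering) shapes the pressure field; only absorption generates heat.
Tissue absorption is 0.21 dB/cm/MHz$^b$; skull absorption is proportional
to density with ceiling $\alpha_0/3 \approx 2.7$ dB/cm/MHz$^b$ at
compact-bone density.

## 2. The thermal model

`solve_pennes()` integrates
$\rho C\, \partial T/\partial t = \nabla\!\cdot\!(\kappa \nabla T) + q -
w\rho_b C_b (T - T_a)$
by explicit forward Euler with face-averaged conductivities, Dirichlet
boundaries fixed at their initial values, and the stability bound
$\Delta t \le 0.9\, \Delta x^2 / (6 \max \kappa/\rho C)$ (refused, with the
computed bound, if violated). The perfusion term is implemented as a
*cooling* term driving tissue toward arterial temperature — the standard
Pennes form — and applies in brain tissue only, since the perfusion
parameters are a brain-average description. The heat production
$q = \alpha_{abs} p^2 / (2\rho c)$ uses the sound speed in the
denominator, the dimensionally consistent reading under which $q$ equals
absorption times plane-wave intensity.

Pulsing (30 ms bursts every 100 ms) is handled by default as duty-averaged
heating ($q \times 0.3$ during the on-phase): thermal time constants here
(conduction across the 6 mm focal spot, perfusion τ ≈ 120.7 s) are three
orders of magnitude above the burst period, so the averaged form is
accurate and ~10³× cheaper. An explicit burst schedule (`burst_gate()`)
exists for verification.

Solver verification in the test suite: exact 37 °C equilibrium; the
perfusion-only exponential closed form
$\Delta T(t) = (q/w\rho_b C_b)(1 - e^{-t/\tau})$, τ = ρC/(wρ_bC_b) ≈
120.7 s, matched within 1%; the 1-D Gaussian heat kernel within 2% L∞;
a discrete maximum principle; first-order convergence in Δt.

`simulate_focal_heating()` packages the headline scenario: a homogeneous
soft-tissue grid carrying a focal spot peaking at 0.88 MPa with lateral
FWHM of one wavelength (6 mm at 250 kHz) and axial FWHM of three (the
typical elongation of a focused beam), run over 60 s pre / 40 s on / 300 s
post. At the default 0.5 mm grid the focal rise is ≈ 0.16 °C — comfortably
below the 0.5 °C level the protocol is designed to respect, and below the
perfusion-only ceiling of ≈ 0.39 °C because conduction across a 6 mm spot
is substantial over 40 s.

## 3. The preprocessing pipeline

Processing order is fixed: drop 5 volumes → high-pass (2000 s cutoff) →
dynamic band-stop → confound regression → low-pass (10 s) → volumetric
3 mm FWHM smoothing → demean.

**Filters.** The filters are zero-phase frequency-domain filters with
*ideal* (brick-wall) gains. The contracts this pipeline must satisfy —
unit passband within 5%, ≥ 20 dB stopband attenuation at twice the cutoff
distance, and near-idempotence under re-filtering — are jointly
unsatisfiable by low-order Butterworth-shaped responses (an order-2
forward-backward filter passes a tone at half the low-pass cutoff at 0.94,
and re-filtering keeps re-attenuating transition-band content), whereas
ideal gains satisfy all of them exactly. The cost is time-domain ringing
around sharp transients; resting-state data are ringing-benign, and the
band edges here (1/2000 Hz, 1/10 Hz) sit far from the signal band of
interest.

**Dynamic band-stop.** Cyclical noise (e.g. ventilation) is detected from
the amplitude spectra of the first three principal components: bins
exceeding 5× a 21-bin rolling median are flagged, widened by 2 bins and
merged into notch bands. The threshold, window and halfwidth are package
choices (the procedure is only described qualitatively in the field);
white-noise data yield no notches, and planted tones are detected and
removed ≥ 90% in tests.

**Confounds.** The nuisance basis is the mean and first five temporal
principal components (SVD, deterministic sign) of the combined WM +
meningeal compartment, plus a 27-term memoryless second-degree Volterra
expansion of the six motion ("B0-confound") parameters — 6 linear terms,
6 squares, 15 pairwise products, all demeaned (a lag-1 option exists).
Residuals are exact OLS residuals, orthogonal to every retained regressor;
rank-deficient columns are dropped with a warning. Setting
`include_meningeal = FALSE` reproduces the alternative pipeline that
removes WM components only, leaving meningeal-borne global signal in the
data — the contrast used to study non-neuronal signal changes.

**Smoothing** is volumetric separable Gaussian convolution
(σ = FWHM/2.3548) with replicate padding; surface-constrained smoothing is
out of scope, a stated approximation for cortical data.

## 4. Coupling, fingerprints and inference

Coupling is Pearson correlation, Fisher z-transformed and clipped to
[−2, 2] *per voxel pair before any averaging* (the clipping stage is a
package choice; clipping after averaging would give slightly different
values near the bound). Seed maps average the clipped z over the seed's
voxels and then across hemispheres; fingerprints average the seed map over
each bilateral target ROI (4 mm balls built in mm space and mirrored
across the mid-sagittal plane). Self-coupling averages within-ROI
pairwise z. The 98th-percentile coupling map (linear interpolation between
order statistics) summarises broad coupling inflation per voxel and is the
statistic used to demonstrate the effect of leaving meningeal signal in
the data.

**Group reduction.** Concatenated runs can be reduced to the top-k
singular components. The reduced series embeds $D_k V_k^\top$ into k+1
pseudo-volumes with exactly zero column means (a normalised Helmert
rotation), so Pearson-based operations on the reduced series equal those
on the stacked data exactly once k reaches the data rank. One property of
such reduction worth knowing: truncating *below* the rank removes mostly
noise variance, which inflates correlation magnitudes roughly uniformly
while preserving fingerprint shape almost exactly (cosine ≈ 0.9999 at
k = 200 on default synthetic data, values ×~1.75). Comparisons of reduced
and unreduced couplings should therefore be made on shape, not absolute z.

**Permutation test.** The observed statistic is the cosine similarity
between the two conditions' mean fingerprints — sensitive to fingerprint
*shape*, invariant to amplitude. The null relabels runs into two groups of
the original sizes; lower similarity means greater difference, so the test
is one-tailed toward dissimilarity (the field convention leaves the tail
implicit; this is the package's reading). Exhaustive mode enumerates all
distinct relabellings with complements identified — C(18,9)/2 − 1 = 24309
for 9-vs-9 runs, the only reading that reproduces that count — and reports
the exact proportion of null values at or below the observed one. That
proportion can be 0 when the observed similarity is strictly minimal;
report such results as p < 1/(N+1). Monte-Carlo mode uses the standard
(k+1)/(n+1) estimator. Treating the 18 run-level fingerprints as
exchangeable units is itself a modelling decision (runs nested in subjects
are not strictly exchangeable); with balanced designs the impact is
second-order, and the synthetic generator makes runs genuinely i.i.d.

## 5. The synthetic data generator

`make_bold_dataset()` is the testbed's ground truth. Three networks of
four bilateral ROIs each (named after the fingerprint regions of a
dorsomedial-frontal TUS study: SMA/M1/SPL/MCC; FPC/9m/9-46d/11m;
aSTG/midSTS/IPLc/PCC) live on a 16×16×10 grid of 2 mm voxels whose top two
slices form the meningeal compartment and whose unlabelled remainder is
WM. Latent network signals are an orthonormalised white basis mixed by the
Cholesky factor of the network coupling matrix, so their *sample*
correlation equals the requested matrix to machine precision — sampling
noise in the latent structure is removed by construction, which is what
lets tests assert coupling values exactly. ROI latents load on their
network signal (within-network coupling w = 0.45); voxels load on their
ROI latent (v = 0.5) plus unit white noise.

The stimulation condition modifies the *population* structure before
mixing: within-network coupling of the stimulated network is multiplied by
`local_gain` (default 1.3) and its coupling with other networks by
`distal_loss` (default 0.6) — applied as a congruence scaling plus a
rank-one diagonal restore, which is provably positive semidefinite, so the
nearest-PSD projection retained for user-supplied matrices never triggers
on the defaults. The planted magnitudes are package defaults chosen to
represent a clearly detectable sharpening; the underlying phenomenon has
no published effect size, so they are not empirical claims.

The global confound is a slow (< 0.05 Hz) standardized component added
with loading 1.0 on meningeal voxels and 0.3 on GM/WM voxels, scaled by
`global_confound_sd` (default 0; tests plant 1.0, the scale of the voxel
noise). Motion parameters are smoothed low-amplitude random walks.

What the generator does *not* emulate: haemodynamic response shapes,
spatial autocorrelation of noise, subject-level variance components,
scanner drifts beyond the planted tones, and real anatomy. Passing tests
therefore establish the correctness and calibration of the *methods* under
their stated assumptions, not performance on real macaque data.

## 6. Problem sizes used in the checks

The statistical acceptance checks run at sizes chosen to make their Monte
Carlo error small relative to the bands being asserted: null calibration
over 200 independent null datasets (3 subjects × 3 runs × 2 conditions,
160 volumes, 12×12×8 grid — the permutation test's calibration does not
depend on grid or run length); power over 50 replicates at the planted
defaults with 3×795 retained volumes per condition; confound removal on
single 400-volume runs. The dosimetry benchmark runs at 0.5 mm/64³ in the
acceptance script and 1 mm/40×40×48 in the test suite (the focal rise
changes by < 0.01 °C between the two).

## 7. Known limitations

* The acoustic model is linear, monochromatic and refraction-free; it is a
  dosimetry estimator, not a wave solver. Absolute in-skull pressures
  inherit the free-water calibration's assumptions.
* Skull maps here come from a geometric phantom; real CT calibration
  (`hu_ref`) varies by scanner and should be set by the user.
* Thermal dose summaries are peak temperature rises; cumulative dose
  integrals (CEM43) are out of scope.
* The fingerprint machinery works in volume space with mirror-symmetric
  bilateral ROIs; surface geometry and atlas-driven ROIs are the user's
  responsibility upstream.
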