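---
title: "Methods: quantifying apoptotic focus assembly and its protein neighborhood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying apoptotic focus assembly and its protein neighborhood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apopore)
```

## Scope

During intrinsic apoptosis the effector proteins BAX and BAK oligomerize into
discrete mitochondrial foci that permeabilize the outer membrane (MOMP) and
eventually release mitochondrial DNA into the cytosol. `apopore` implements
the quantitative readouts used to study this process:

1. **Proximity-proteomics candidate selection** — which proteins sit in the
   neighborhood of the pore-forming machinery, from dimethyl-labeling
   log~2~-ratio tables of APEX2 biotinylation experiments.
2. **Single-particle ratiometric stoichiometry** — how many GFP-tagged
   monomers each focus contains, calibrated against the nuclear pore protein
   NUP96 (exactly 32 copies per pore).
3. **MOMP-referenced kinetics** — when foci appear relative to mitochondrial
   depolarization (TMRE loss), per cell.
4. **mtDNA release** — delta-Ct and area-under-curve summaries of qPCR time
   courses.

A synthetic-data module generates every input class with known ground truth,
so the full pipeline is testable without raw microscopy or MS data.

## Candidate selection from proximity proteomics

Each labeling experiment yields, per protein, a log~2~(STS/CTRL) enrichment
ratio (apoptotic vs untreated), a log~2~(STS/STS) reference ratio between two
apoptotic baits, and a summed reporter intensity. Selection composes four
criteria:

* **C1** — log~2~(STS/CTRL) strictly above the 90th-percentile cutoff
  $t_{0.9} = \hat\mu + z_{0.9}\,\hat\sigma$ of the **fitted** normal
  distribution of the ratios ($\hat\mu$ the arithmetic mean, $\hat\sigma$ the
  $n-1$ sample s.d.). We use the fitted quantile rather than the empirical
  sample percentile because the selection rule is phrased in terms of the
  normal distribution of the ratios and the fitted form is robust to ties;
  `criterion1_select(..., method = "empirical")` exposes the alternative.
* **C2** — log~2~(STS/STS) within the arithmetic mean ± one sample s.d. of
  all reference ratios, bounds inclusive ("within"). On exactly normal data
  this keeps the central 68.27%.
* **C3/C4** — membership in the designated mitochondrial (GOCC-like) and
  apoptosis (GOBP-like) annotation sets. Annotations are flat membership
  tables; no ontology-graph traversal is performed.
* Bait (APEX2-fusion) proteins are excluded regardless, since their
  overexpression inflates their own ratios.

Both thresholds are strict inequalities (`>`), matching the ">" phrasing of
the rules; a protein sitting exactly at $t_{0.9}$, or at exactly 1.4-fold in
the Venn rule below, is *not* selected. Proteins missing a ratio fail the
criterion that needs it; nothing is imputed. Criterion statistics are fitted
on the proteins quantified in the relevant column.

The **Venn rule** (`venn_enriched()`) marks a protein enriched for a
construct iff its STS/CTRL ratio exceeds 1.4 on the linear scale
(log~2~ ratio > log~2~ 1.4 ≈ 0.485). The phrase "log~2~ ratios showing a
>1.4-fold increase" admits a second reading (log~2~ ratio > 1.4, i.e.
2.64-fold); we adopt the linear-scale reading, because "fold increase" is a
linear-scale notion, and expose `fold_scale = "log2"` for the other.

**Significance B** (`significance_b()`) is the intensity-binned robust
outlier test for ratio tables: proteins are ordered by summed intensity and
split into equal-count bins of at least `min_bin_size` (default 300, the
published description of the statistic gives no bin size; the last bin
absorbs the remainder). Within each bin, location is the median and scale is
$(q_{0.8413} - q_{0.1587})/2$ — half the central ≈68% spread, a robust sigma
— and each protein gets a two-sided normal tail p-value for its z-score.
Quantiles use R's default type-7 order-statistic interpolation. The default
flag threshold is p < 0.01.

**Term enrichment** (`hypergeom_enrich()`) is the one-sided upper-tail
hypergeometric test (equivalent to one-sided Fisher) with Benjamini–Hochberg
q-values over the tested terms; BH is the only multiple-testing procedure
offered (default FDR 0.05).

## Single-particle stoichiometry

Analysis runs on maximum-intensity z projections of photon-counting confocal
stacks (`max_project()` also records the per-pixel argmax plane, lowest index
on ties).

* **Detection** (`detect_foci()`): difference-of-Gaussian scale space over
  geometrically spaced widths, each layer scale-normalized by
  $s_i/(s_{i+1}-s_i)$; candidates are local maxima over space and scale above
  a threshold. The default threshold is 5× the MAD of the finest DoG layer —
  a matched-filter 5-sigma rule on the *response* map. (Band-pass filtering
  suppresses pixel shot noise, so thresholds scaled to raw-image noise are
  miscalibrated on the response scale.)
* **Fitting** (`fit_focus()`): isotropic 2D Gaussian plus offset,
  Levenberg–Marquardt least squares on a 5×5-pixel ROI. The single fitted
  width σ relates to FWHM by $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$; all
  filters in this package operate on σ and document the conversion rather
  than guessing which quantity the original software thresholded.
* **Background** (`subtract_background()`): offset re-estimated as the median
  of the square annulus of Chebyshev radius 3–6 px around the center (the
  ring just outside the 5×5 ROI; configurable); intensity = ROI photon sum −
  offset × ROI area, floored at 0.
* **Filters** (`filter_foci()`), in priority order with one recorded reason
  each: close pairs within `min_distance` (both members rejected by default —
  the procedure is defined to avoid overlap without naming a survivor;
  `keep_brighter = TRUE` keeps the brighter one), dim foci below
  `min_intensity` (default 5× the s.d. of a background ROI sum), σ outside
  `[0.5, 2] × psf_sigma`, and foci whose intensity maximum falls within
  `z_edge_margin` planes of either stack end, where depth information is
  lost.
* **Calibration and stoichiometry**: the standard is the mean
  background-subtracted intensity of accepted NUP96 foci *from the same
  acquisition day* (mixing days is an error unless overridden), processed
  with the identical detection/fit/filter chain for symmetry. Then
  $$S_\mathrm{foci} = 32\,\frac{I_\mathrm{foci}}{\langle I_\mathrm{NUP96}\rangle},$$
  reported continuous, linear in intensity, and invariant to any common
  rescaling of focus and standard intensities.

**PLA quantification** (`pla_mito_intensity()`): Otsu's threshold on the
mitochondrial channel defines the mask; the statistic is the mean PLA
intensity inside the mask divided by the mean outside.

All pixel, z and frame indices are 0-based; focus centers are sub-pixel.

### Accuracy of the ratiometric estimator

On synthetic fields (50 photons/monomer, 2 background photons/pixel,
molecularities 8–64) the pipeline recovers molecularity with a median
relative error below 10%, and the ensemble mean recovered molecularity is
unbiased within sampling error (tested at 2 SE over 100 simulated fields).
Two intrinsic properties of the max-projection method are worth knowing:

* the estimator applied to the *noiseless* expected image is exactly linear
  in molecularity (verified: intensity ratios 0.25/0.5/1/2 for 8/16/32/64);
* on noisy data, taking per-pixel maxima over z inflates photon counts by an
  amount that grows with brightness, and the NUP96 division cancels this
  inflation exactly at the standard's brightness (32-mers). Foci much dimmer
  than the standard are therefore underestimated by a few percent (≈6% at
  8-mers under the conditions above). This is a property of the published
  max-projection ratiometric approach itself, not of the implementation.

## MOMP-referenced kinetics

* **Depolarization** (`call_depolarization()`): first frame whose TMRE
  signal drops strictly more than 30% below the time-zero value
  (`tmre < tmre[0] × 0.70`); a drop of exactly 30% does not trigger. The
  baseline is strictly frame 0 by default; `baseline_frames > 1` averages the
  first k frames as a robust option for noisy traces. The call is invariant
  to rescaling the trace.
* **GFP dispersion** (`gfp_dispersion_traces()`): per-frame s.d. and maximum
  of GFP pixel intensities within a cell mask. Whether the original analyses
  used a whole-field or mask-based statistic is not specified; we adopt
  mask-based (a supplied mask, or Otsu on the frame-0 TMRE channel) and flag
  the choice here. `normalize_to_reference()` divides each cell's series by
  the mean frame-0 value of the reference condition (e.g. wild type).
* **Onset and lag**: onset is the first frame with ≥1 accepted focus; lag =
  onset time − depolarization time, signed (0 = concurrent, negative = foci
  first), and *missing* — never imputed — when either event is absent.
* **Cumulative fraction** (`cumulative_foci_fraction()`): at each time after
  TMRE loss, the fraction of depolarized cells with lag ≤ τ; cells that never
  form foci stay in the denominator, so the curve plateaus at the
  ever-forming fraction.
* **Oligomerized amount** (`oligomerized_amount()`): monomers per focus ×
  number of foci, defined as 0 in focus-free frames.

Times are minutes throughout; the frame interval (default 10 min) comes from
the acquisition manifest.

## mtDNA release from qPCR

Technical replicates are averaged per (primer, time) as the arithmetic mean
of Ct. The sign convention is
$$\Delta C_t(t) = \overline{C_t}(0) - \overline{C_t}(t),$$
so template release (lower Ct) gives positive values and one cycle ≈ a
two-fold template change; the reference phrasing ("with respect to time
zero") does not fix the sign, so we state it prominently. The per-primer AUC
is the trapezoidal integral of ΔCt over the observed, possibly irregular,
time grid — no interpolation, smoothing, efficiency correction or absolute
quantification.

## The synthetic-data generators

Every generator is a pure function of its spec, including an explicit,
mandatory integer seed; there is no global random state. Defaults mirror the
acquisition geometry of the imaging experiments: 8 z-planes at 0.3 µm,
0.045 µm pixels, 10-min frames, qPCR in technical triplicates.

* **Ratio tables**: background log~2~(STS/CTRL) ratios ~ N(µ, σ²) with a
  spiked subpopulation shifted by `spike_shift`; reference ratios centered at
  0; log-uniform intensities; Bernoulli annotation membership with different
  rates for background and spiked proteins.
* **Focus stacks**: each focus is a 3D Gaussian photon-rate field — isotropic
  lateral width `psf_sigma` (pixels) and independent axial width
  `psf_sigma_z` (z-planes, default 1.2 ≈ 0.36 µm at the 0.3 µm step, the
  confocal axial PSF at NA 1.4 — much wider than the lateral width in
  physical units) — whose integral is molecularity × `photons_per_monomer`,
  plus a uniform background rate, Poisson-sampled per voxel. Voxel values are
  rate-field point samples at voxel centers (not analytic integrals); the
  error is negligible for `psf_sigma` ≥ 1 px. Single-plane stacks render as
  plain 2D images (all photons in the plane). The instrument does not fix
  photons per GFP monomer, so it is a free parameter (default 50).
* **NUP96 fields**: identical machinery with every ground-truth molecularity
  fixed at 32.
* **Time lapses**: a step TMRE drop of `depol_depth` at `depol_frame`
  (optional Gaussian noise), one focus nucleating at the onset frame,
  further foci as Poisson counts at `nucleation_rate`/frame, all growing
  linearly at `growth_rate` monomers/frame from molecularity 1.
* **qPCR**: relative template amount $2^{t/\texttt{release\_halflife}}$
  (the field is the template *doubling time* in hours; `Inf` gives a flat
  no-release curve), mean Ct = `ct0` − log~2~(amount), Gaussian replicate
  noise.

What the generators deliberately do **not** model: detector gain or read
noise (photon-counting detection is assumed), cell-to-cell heterogeneity and
segmentation (a single-cell field), mitochondrial network texture under the
foci, chromatic or drift artifacts, MS peptide-level effects (ratio tables
are generated at the protein level), and qPCR efficiency differences between
primers. Passing tests on synthetic data therefore validate the estimators
under the stated noise model, not robustness to those real-data features.

## Numerical and interface choices

* Degenerate inputs fail loudly: zero-variance ratio fits, constant Otsu
  images, zero-spread significance-B bins, missing qPCR time zero, empty
  masks, and non-positive TMRE baselines are errors, not silent NAs.
* DoG ties and plateau maxima resolve to all plateau members before
  non-maximum suppression; max-projection ties resolve to the lowest z.
* Negative net intensities after background subtraction clamp to 0.
* Image stacks travel as uncompressed 16-bit multi-page TIFF plus a CSV
  manifest (file, channel, frame, z-planes, pixel size, frame interval,
  day); photon counts are integers, so the round trip is voxel-exact.
* `run_pipeline()` writes every table with a header comment carrying the
  package version, config MD5 and seed, and a JSON run manifest; outputs
  contain no timestamps, so runs with identical config and seed are
  byte-identical. All per-stage seeds derive from the single top-level seed.
* Configuration is one YAML file validated against the full default tree:
  unknown keys and out-of-range values are rejected by name
  (`load_config()`).

The test suite exercises the stochastic claims at desk scale: 10⁵-draw
checks for the criterion-1/2 pass fractions, 100 simulated 64×64×8 fields
for molecularity recovery, 200 seeds for photon conservation on a tiny
image, and a 3-frame 32×32 end-to-end determinism run — sizes chosen so the
whole suite completes in well under a minute while keeping Monte-Carlo
standard errors far below the asserted tolerances.
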