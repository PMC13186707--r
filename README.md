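# apopore

Quantitative analysis of apoptotic BAX/BAK focus assembly and its protein
neighborhood.

During intrinsic apoptosis, BAX and BAK oligomerize into discrete
mitochondrial foci that permeabilize the outer membrane (MOMP, observable as
TMRE fluorescence loss) and ultimately release mitochondrial DNA. `apopore`
is an R implementation of the quantitative pipeline behind this biology, for
researchers analyzing proximity-proteomics screens and photon-counting
confocal time lapses of focus formation:

* **Proximity-proteomics candidate selection** from dimethyl-labeling
  log2-ratio tables: cutoff at the 90th percentile of the fitted normal of
  log2(STS/CTRL) (strict `>`), a mean ± s.d. window on the log2(STS/STS)
  reference ratio, mitochondrial and apoptosis annotation filters, bait
  exclusion; plus the intensity-binned **significance-B** outlier statistic
  (median-centered, scale `(q0.8413 − q0.1587)/2`, two-sided normal tails)
  and **hypergeometric term enrichment** with Benjamini–Hochberg q-values,
  and the `>1.4`-fold Venn rule across constructs.
* **Single-particle ratiometric stoichiometry**: difference-of-Gaussian spot
  detection on maximum-intensity z projections, isotropic 2D Gaussian PSF
  fits on 5×5 ROIs, annulus background subtraction, distance/dimness/width/
  z-edge quality filters, and conversion of focus intensities to monomer
  counts against the 32-copy NUP96 nuclear-pore standard:

  S_foci = 32 · I_foci / ⟨I_NUP96⟩  (day-matched calibration)

* **MOMP-referenced kinetics**: depolarization at a strict >30% TMRE drop
  from the time-zero value, GFP dispersion traces, focus-onset lag,
  cumulative focus-positive fractions, and oligomerized amount
  (monomers per focus × focus count).
* **mtDNA release**: replicate-averaged ΔCt = Ct(0) − Ct(t) per primer and
  trapezoidal AUC.
* A **synthetic-data generator** for every input class (ratio tables,
  Poisson photon-counting z-stacks, NUP96 fields, TMRE/GFP time lapses,
  qPCR Ct tables) with known ground truth and explicit seeds.

See `vignettes/apopore-methods.Rmd` for the full model descriptions,
parameter conventions and design decisions.

## Worked example

Simulate a field with foci of 8, 16, 32 and 64 monomers, quantify it, and
calibrate stoichiometries against a simulated NUP96 field:

```r
library(apopore)

field <- gen_focus_stack(focus_sim_spec(
  image_shape = c(64, 64), molecularities = c(8, 16, 32, 64),
  positions = cbind(c(15, 15, 45, 45), c(15, 45, 15, 45)),
  photons_per_monomer = 50, background_rate = 2, seed = 1))

foci <- quantify_foci(field$stack)
nup  <- gen_nup96_stack(n_pores = 10, photons_per_monomer = 50, seed = 2)
cal  <- calibrate(quantify_foci(nup$stack))

accepted <- foci[foci$accepted, ]
accepted$stoichiometry <- stoichiometry(accepted, cal)
accepted[, c("x0", "y0", "sigma", "intensity", "stoichiometry")]
#>     x0    y0 sigma intensity stoichiometry
#>  45.07 45.08  1.24       850         60.91
#>  14.92 44.94  1.96       445         31.89
#>  45.02 14.92  1.21       195         13.97
#>  14.74 15.22  1.08        98          7.02
```

The four foci are recovered at sub-pixel positions with stoichiometries
7.0/14.0/31.9/60.9 monomers against ground truth 8/16/32/64: the
background-subtracted intensity of each focus (photons) divided by the mean
accepted NUP96 intensity (here ⟨I⟩ = 446.6) and multiplied by the standard's
32 copies.

Kinetics on a simulated single-cell time lapse (10-min frames, TMRE step
drop at frame 1, first focus at frame 3 growing by 6 monomers/frame):

```r
tl <- gen_timelapse(timelapse_sim_spec(n_frames = 6, depol_frame = 1,
  focus_onset_frame = 3, growth_rate = 6, seed = 3))
counts <- vapply(tl$stacks, function(s) sum(quantify_foci(s)$accepted), numeric(1))
ks <- summarize_kinetics(cell_trace("cell1", "wt", tl$time_min, tl$tmre,
                                    foci_count = counts))
c(ks$depol_time, ks$onset_time, ks$lag_min)
#> [1] 10 40 30
```

Depolarization is called exactly at the simulated frame (10 min). The
detected onset (40 min) trails the ground-truth nucleation (30 min) by one
frame because the newborn single-monomer focus is below the detection limit
— lags are measured from *detectable* foci, exactly as in a real experiment.

mtDNA release from a simulated doubling-per-hour qPCR experiment:

```r
qp <- gen_qpcr(qpcr_sim_spec(primers = c("Dloop", "16S"),
  timepoints_h = 0:3, release_halflife = 1, noise_sd = 0.1, seed = 4))
curve <- delta_ct(qp$table)
release_auc(curve)
#>  primer      auc
#>     16S 4.403443
#>   Dloop 4.397030
```

ΔCt climbs by ≈1 cycle/hour (one template doubling), giving an AUC near the
noise-free closed form of 4.5 cycle·hours.

`run_pipeline(load_config("my.yaml"), seed = 1, out_dir = "run")` chains
simulate → foci → kinetics (plus proteomics and qPCR) into an artifact
directory with seed-deterministic, byte-identical outputs; a thin CLI
wrapper lives at `inst/cli/apopore.R`.

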