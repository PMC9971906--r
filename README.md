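# curtaintrack

Single-molecule DNA-curtain tracking and resection kinetics in R.

## The problem

In a DNA-curtain assay, thousands of 48.5 kb DNA molecules (lambda phage
substrate) are tethered by one end inside a microfluidic flow cell and
stretched by buffer flow. Quantum-dot-labeled motor proteins — DNA-end
resection machines such as BLM–TOP3A–RMI1/2 (BTRR) with the DNA2 nuclease,
plus MRN and RPA — are imaged as diffraction-limited spots while they
translocate along the DNA. Quantifying their behavior means turning raw
two-channel EMCCD movies (0.2 s exposure every 2 s; 1800 frames/h) into:

* subpixel localizations — each spot's point spread function fit to a 2D
  Gaussian, giving (x, y) to a few hundredths of a pixel;
* drift-corrected, base-pair-calibrated trajectories (≈485 bp/px);
* per-molecule kinetics — velocity *v* from the OLS slope of position vs
  time, processivity *P* as the distance traveled (kb), pauses (≥30 s with
  no net motion beyond the ~500 bp resolution), bound lifetimes with a
  single-exponential survival fit S(t) = exp(−k t);
* cohort statistics — initiation / pause / dissociation / colocalization
  fractions with bootstrap SDs, Welch t tests, fold changes, and
  GC-content association of pause sites.

Raw curtain movies are rarely deposited, so the package also ships a
ground-truthed synthetic-imaging simulator (blinking QD emitters, Poisson +
read noise, stage drift, flow-stop recoil, piecewise motor paths) that
makes every pipeline stage testable. It is aimed at single-molecule
biophysicists who want a scriptable, reproducible version of this analysis,
and at method developers who need a oracle-backed testbed.

## Worked example

Simulate a small imaged cohort at the reference resection kinetics
(velocity 18 ± 11 bp/s, processivity 18 ± 6 kb), then recover it through
the full localize → drift-correct → link → calibrate → analyze pipeline:

```r
library(curtaintrack)
acq <- acquisition_config(n_frames = 450)        # 15 min movie at 2 s
sim <- simulate_cohort(12, acq, velocity_mean = 18, velocity_sd = 11,
                       processivity_mean_kb = 18, processivity_sd_kb = 6,
                       seed = 42)
rec  <- recover_cohort(sim)
summ <- cohort_summary(rec$kinetics, condition = "MRN-BTRR-DNA2 (synthetic)",
                       seed = 42)
summ[, c("n_molecules", "velocity_mean", "velocity_sd",
         "processivity_mean", "processivity_sd")]
#>  n_molecules velocity_mean velocity_sd processivity_mean processivity_sd
#>           12       14.4579     10.5594           11.2702        7.189764

cohort_truth(sim)  # ground truth for this seed: v = 14.3 bp/s, P = 11.2 kb
```

The recovered cohort mean velocity (14.46 bp/s) and processivity
(11.27 kb) match this seed's simulation ground truth (14.3 bp/s, 11.2 kb)
to ~1%; the short 15-min movie truncates the longest runs, which is why
the realized processivity sits below the 18 kb generative mean.

Count-derived statistics work directly from published molecule counts:

```r
fraction_from_counts(97, 112, percent = TRUE, seed = 1)
#> $fraction 86.6  -> 87% of DNA2 molecules colocalized with MRN
#> $sd        3.1  (bootstrap SD, 1000 molecule-level resamples)
fold_change(18, 9)
#> 2.0-fold       (velocity decrease when MRN or TOP3A-RMI1/2 is omitted)
```

## Command line

```sh
Rscript -e 'curtaintrack::curtain_cli()' simulate --out sim/ --seed 7
Rscript -e 'curtaintrack::curtain_cli()' localize --stack sim/stack_01_c0.tif \
    --fiducial-roi 0,0,112,12 --out det.csv
Rscript -e 'curtaintrack::curtain_cli()' track --detections det.csv \
    --calibration cal.json --out traj.csv
Rscript -e 'curtaintrack::curtain_cli()' analyze --traj traj.csv --out kinetics/
Rscript -e 'curtaintrack::curtain_cli()' stats --kinetics kinetics/kinetics.csv \
    --out summary/
```

or `run` with a single JSON config (`run_pipeline()`), which writes a
manifest with seeds and file hashes for provenance.

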