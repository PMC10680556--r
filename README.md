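# slimcount

Single-molecule stoichiometry, assembly periodicity and photophysiology
analysis for Slimfield fluorescence microscopy.

## What it does, and for whom

Slimfield microscopy images live cells at millisecond exposures with
single-molecule sensitivity.  A fluorescently tagged protein complex
appears as a diffraction-limited spot whose integrated intensity is
proportional to the number of tagged molecules it carries, and every
fluorophore bleaches in discrete steps.  `slimcount` is for microscopists
and quantitative cell biologists who want to turn such image stacks into:

* a **single-molecule brightness calibration** from terminal
  photobleaching steps (the modal step height, e.g. ~56 photoelectrons per
  frame per molecule for mScarlet-I);
* a **stoichiometry** per tracked complex: the track's summed intensity,
  background-corrected over a 5 px disc minus a 5–8 px annulus, linearly
  extrapolated backwards over the first 4 frames to illumination onset,
  divided by the single-molecule brightness,

  `S = I(0) / b`,  `I(0)` from OLS through frames 0–3 at frame-centre times;
* an **assembly periodicity**: per-acquisition Gaussian kernel densities
  (fixed 0.7-molecule bandwidth) of the stoichiometry samples are peak-
  located; all pairwise peak intervals, weighted `d^(-1/2)`, feed a second
  weighted kernel density with bandwidth `0.7 * sqrt(mean(S)/n_intervals)`
  whose mode (with a bootstrap 95% CI over acquisitions) is the repeat
  unit — a pentameric channel population shows peaks at 5, 10, 15 and a
  periodicity of 5.

It also implements the photophysiology formula set used alongside such
experiments: NPQ = (Fm−Fm′)/Fm′, Y(II) = (Fm′−F)/Fm′, Fv/Fm, fast-relaxing
NPQ (qE), the electrochromic-shift signal ΔA520−ΔA545 with PMF size,
gH⁺ = 1/τ (single-exponential fit over the first 100 ms after light-off)
and vH⁺ = PMF × gH⁺, total chlorophyll = 22.12·A652 + 2.71·A665 (µg/mL),
and specific growth rate µ = ln(N2/N1)/t.

Because raw Slimfield data are rarely shareable, the package ships a
ground-truthed synthetic generator (`simulate_image_stack`,
`simulate_bleach_traces`, `simulate_pam_trace`, `simulate_ecs_trace`) whose
defaults mirror the stated acquisition conditions (53 nm/pixel, 10 ms
frames, brightness 56, Poisson + read noise), so the entire chain is
testable end to end.

## Worked example

```r
library(slimcount)

all_tracks <- NULL
for (a in 1:25) {
  sim <- simulate_image_stack(slimfield_config(seed = derive_seed(42, a)))
  tr <- track_stack(sim$stack, sim$mask)
  tr$acquisition_id <- a
  all_tracks <- rbind(all_tracks, tr)
}
counted <- count_tracks(all_tracks, frame_interval = 0.01)
counted$calibration
#> <brightness_calibration> 56.4 +/- 36.5 photoelectrons/frame/molecule (n = 633 steps)
result <- estimate_periodicity(counted$samples, seed = 1)
result$periodicity
#> <periodicity_result> 5.08 molecules (95% CI 4.46-5.50, 78 intervals)
head(result$population_peaks)
#>    position    height
#> 1  4.952451 0.2045924
#> 2  9.855009 0.1225475
#> 3 15.040793 0.0740223
```

The calibration recovers the configured 56 photoelectrons/frame/molecule;
the population stoichiometry density peaks at ~5, ~10 and ~15 molecules
(pentamers and groups of pentamers); and the weighted interval-density
mode reports the pentameric repeat unit, 5 molecules, with its bootstrap
CI.

A single-command pipeline (simulate → track → count → periodicity, with
on-disk TIFF/CSV/JSON artifacts and a manifest) is available as
`run_pipeline(config, out_dir)` or from the shell via the installed
launcher:

```sh
DEMO=$(Rscript -e 'cat(system.file("extdata", "demo_pipeline.json", package = "slimcount"))')
Rscript $(Rscript -e 'cat(system.file("cli", "slimcount", package = "slimcount"))') \
    pipeline --config "$DEMO" --out results/demo
```

## Layout

* `R/` — configs & JSON I/O, baseline TIFF reader/writer, synthetic
  generators, tracking, counting, periodicity, photophysiology, pipeline,
  CLI.
* `src/` — Rcpp kernels (integrated-Gaussian PSF rendering, local maxima,
  disc/annulus photometry, Chung–Kennedy filter); each has a brute-force R
  oracle in the test suite.
* `tests/testthat/` — unit, property and acceptance suites.
* `vignettes/slimfield-stoichiometry.Rmd` — the methods vignette: model,
  assumptions, parameter rationale, numerical choices, limitations.
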