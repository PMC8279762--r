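# smctools

Quantitative analysis of two-color single-molecule coincidence (SMC)
experiments and the companion cell-biology assays used to characterize a
protein–protein interaction: PLA puncta and DNA-damage foci, comet-assay
damage metrics, plate-based viability/survival formulas, and SAM-style
permutation-FDR statistics for label-free proteomics. Every input the
analyses consume can also be simulated with known ground truth, so each
method is testable end to end.

It is written for groups doing single-molecule spectroscopy of tagged
protein pairs (e.g. a GFP-tagged protein coexpressed with an
mCherry-tagged partner) who need the downstream numbers — associated
fraction, complex stoichiometry, per-cell puncta, tail moments, survival
fractions, differential-abundance calls — computed reproducibly from raw
observables.

## The core method

A dilute (~1 nM) mixture of GFP- and mCherry-tagged proteins diffuses
through a confocal volume; photon counts in both channels are recorded in
1 ms bins. Bursts are maximal runs of bins with ≥ 50 photons/ms (channel
sum by default). After subtracting the 6% leakage of GFP signal into the
red channel, each burst's coincidence ratio is

    C = mCherry / (GFP + mCherry)

with C ≈ 0 for GFP-only, C ≈ 1 for mCherry-only and intermediate values
for co-diffusing complexes. Events with 0.25 ≤ C ≤ 0.75 are coincident;
the associated fraction of the GFP species is
coincident / (GFP-only + coincident), reported alongside a
three-Gaussian fit of the normalized C histogram. Burst brightness,
calibrated against a monomeric control, estimates copies of the labeled
protein per complex.

## Worked example

Simulate a two-color experiment in which 60% of the GFP-tagged protein is
in a 2:1 complex with the mCherry-tagged partner, then analyze it:

```r
library(smctools)

sim <- simulate_mixture(f_assoc = 0.6, n_events = 2000,
                        acquisition_model(seed = 7))
res <- coincidence_pipeline(sim$trace)
summary(res)
#> Two-color single-molecule coincidence analysis
#>   events: 2745
#>   classes: GFP-only 804, coincident 1144, mCherry-only 797 (0 dropped)
#>   associated fraction (window):  58.7%
#>   associated fraction (mixture): 57.4%
#> Three-Gaussian coincidence fit
#>   GFP-only     weight 0.302  mean 0.012  sd 0.006
#>   coincident   weight 0.407  mean 0.349  sd 0.010
#>   mCherry-only weight 0.291  mean 0.991  sd 0.002
```

The window estimator recovers the simulated 60% association within
sampling error; the coincident component sits at C ≈ 0.35, as expected
for a 2 GFP : 1 mCherry complex. Calibrating burst brightness against a
monomeric GFP control calls the stoichiometry of the green-labeled
protein:

```r
ctrl <- detect_bursts(simulate_trace(species_model("gfp", 1, 0, 10),
                        acquisition_model(duration = 60, seed = 8))$trace)
cal  <- calibrate_monomer(ctrl$green_counts, seed = 9)
est  <- estimate_copy_number(
          res$bursts$green_counts[res$bursts$klass == "coincident"],
          cal, seed = 10)
est
#> Copy-number estimate: 2 copies per complex
#>   median brightness ratio 2.09 (95% CI 2.09-2.10)
```

i.e. the complexes carry a GFP-tagged dimer. The same package quantifies
the companion assays, for example:

```r
comet <- simulate_comet_image(tail_fraction = 0.3, seed = 2)
seg   <- segment_comet(comet$image)
comet_metrics(seg$head_intensity, seg$tail_intensity, seg$tail_length)
# Tail DNA% ~ 30, Extent Tail Moment = Tail DNA% x tail length

prot <- simulate_proteome(1000, effects = rep(c(2, -2), 25), seed = 3)
diff_proteome(prot$table, prot$truth$groups)   # permutation FDR 5%, S0 = 1
```

A command-line wrapper over the same functions is installed at
`inst/cli/smctools.R` (`Rscript smctools.R coincidence trace.tsv --out res`);
every stochastic subcommand takes `--seed` and writes a provenance JSON.

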