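---
title: "Methods: two-color coincidence analysis and companion assays"
author: "smctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-color coincidence analysis and companion assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`smctools` quantifies four kinds of measurement that together characterize a
protein–protein interaction and its cellular consequences:

1. **Two-color single-molecule coincidence (SMC)**: burst detection in
   simultaneous GFP/mCherry photon-count traces, spectral leakage
   correction, coincidence-ratio classification, a three-Gaussian histogram
   fit, and brightness-based stoichiometry calibration.
2. **Image-based assays**: proximity-ligation (PLA) puncta per cell with a
   nuclear/cytosolic split, DNA-damage focus positivity, and comet-assay
   tail metrics.
3. **Plate-based formulas**: resazurin-dye (PrestoBlue) percent reduction,
   clonogenic plating efficiency and survival fraction, relative LDH
   release, percent-positive counts.
4. **Label-free differential proteomics**: MaxQuant-dialect filtering, a
   SAM-style moderated difference statistic with additive fudge constant
   S0, and permutation-based FDR calls for a 3 vs 3 design.

Every input can be produced by the package's own generators with known
ground truth, so each analysis is testable against the truth that produced
its data.

# The coincidence model

A fluorescent particle diffusing through a confocal volume produces a
photon burst in each spectral channel. With counts binned at 1 ms, a bin is
*positive* when its photon count reaches a threshold of 50 photons/ms
(inclusive), applied by default to the green+red sum so that events of
either color are admitted; maximal runs of positive bins are bursts, and
per-burst channel counts are sums over the run.

GFP emission leaks partially into the red detection channel. For a leakage
fraction $\ell$ (default 0.06) the corrected red count of a burst is
$R' = \max(0, R - \ell G)$, and the coincidence ratio is

$$C = \frac{R'}{G + R'} \in [0, 1].$$

GFP-only bursts give $C \approx 0$, mCherry-only bursts $C \approx 1$, and
co-diffusing complexes intermediate values. Events with
$0.25 \le C \le 0.75$ are classified *coincident* (boundaries inclusive:
boundary membership is measure-zero in practice, so the choice is a
documented convention, not a result driver). The package reports two
estimators of the associated fraction:

* `f_assoc_window` $= \dfrac{\#\text{coincident}}{\#\text{GFP-only} +
  \#\text{coincident}}$ — the associated fraction *of the GFP-bearing
  species*. This is the default summary, because the biological claim of
  interest ("X% of the GFP-tagged protein is associated") conditions on the
  GFP species, not on all events including free red label.
* `f_assoc_mixture` — the analogous ratio of fitted mixture weights, from a
  bounded nonlinear least-squares fit of three Gaussians to the normalized
  $C$ histogram (component means constrained to $[0,0.2]$, $[0.2,0.8]$,
  $[0.8,1]$). Component contributions are integrated over each histogram
  bin rather than evaluated at bin centers, so clusters narrower than one
  bin — common in bright, low-background data — are weighted correctly.

The histogram is normalized to total events; analyses with fewer than 1000
events carry an `under_sampled` flag, following the convention that a
reliable coincidence histogram needs >1000 events.

## Stoichiometry calibration

Burst brightness (total photons per burst) scales with the number of
fluorophores on the particle. A monomeric single-label control calibrates
the per-fluorophore yield; the copy number of the labeled protein in a
complex is the sample/control ratio of median burst brightness, rounded to
the nearest integer, with a bootstrap percentile interval and an ambiguity
flag when the interval spans two integers. The median (not the mean) is
used because transit trajectories through the focus skew brightness to the
right; the calibration statistic itself is this package's explicit choice —
the calibration literature this emulates describes the procedure only as
matching against the monomer brightness profile.

Burst integration only covers above-threshold bins, which truncates a
larger fraction of a dim monomer's photons than of a bright k-mer's. The
measured ratio for a k-mer therefore slightly exceeds k (about +4% for a
dimer, +7% for a 4-mer at the default optics). Rounding absorbs this bias
for small k; it is the main reason a full brightness-distribution
deconvolution would be needed for k beyond ~5.

# The trace generator

`simulate_trace()` draws event centers as a Poisson process, gives every
transit a Gaussian temporal profile (width `transit_sigma`, default 1.5 ms)
and integrates that profile over bins to get expected counts; observed
counts are Poisson. Each emitted green photon is independently rerouted to
the red channel with probability `crosstalk` (default 0.06), which makes
the expected leakage exactly the crosstalk parameter and the standard 6%
subtraction an exact correction in expectation. Defaults: 180 s
acquisition, 1 ms bins, 250 detected photons per fluorophore per ms at
focus, 1 photon/ms background per channel. A transit then yields
$250\,\sigma\sqrt{2\pi} \approx 940$ photons per fluorophore, putting even
a monomer's peak (~245 photons/ms) far above the 50 photons/ms detection
threshold — the regime in which burst counting, not photon statistics,
limits accuracy. The default single-species rate of ~10 transits/s over
180 s satisfies the >1000-event convention with margin.

A full 3-D diffusion simulation is deliberately out of scope: downstream
analysis uses only per-burst aggregate counts, so the marginal burst
brightness and duration distributions are what matter, and the Gaussian
transit profile reproduces those.

## Mixture runs and pile-up

`simulate_mixture(f_assoc, n_events)` generates `n_events` GFP-bearing
transits of which a binomial fraction `f_assoc` are complexes (default
2 GFP : 1 mCherry — the canonical dimer-bound-to-monomer preset) and the
rest GFP-only; an equal number of mCherry-only singletons is appended so
all three event classes occur, as in a coexpression lysate with free red
label. Defined this way, `f_assoc` is exactly the quantity the window
estimator targets.

Overlapping transits are allowed and recorded. Pile-up of a GFP-only and a
mCherry-only transit within one burst mimics coincidence, with expected
rate approximately $n_\text{red}\, w / n_\text{bins}$, where
$w \approx 12$ bins is the merge window at the default optics. To keep
this artifact at the few-percent level — the "sparse, mostly
non-overlapping" single-molecule regime the method assumes — the mixture
generator fixes the *total transit rate* (default 5/s) and derives the
acquisition length from the requested event count, exactly as a real
experiment acquires longer rather than denser. At 2000 GFP events and
`f_assoc = 0.6` this leaves a residual positive bias of about +1 to +2
percentage points in the window estimator, well inside the ±5-point
tolerance used in validation; at the default optics the bias grows roughly
linearly with event density, which the pile-up expression above makes easy
to budget.

# Image assays

**Maximum-entropy threshold.** Puncta and comets are binarized at the
Kapur–Sahoo–Wong threshold: the gray level maximizing the summed Shannon
entropies of the normalized foreground and background histograms (the
"Maximum Entropy" option of ImageJ's particle analysis). The
implementation is an exhaustive scan over candidate levels via cumulative
sums; tests verify it against an independent brute-force evaluation of the
two-class entropy criterion. Pixels strictly above the level are
foreground; a constant image has no threshold and is an error.

**Puncta counting.** Connected components use 8-connectivity (via a pixel
adjacency graph). Particles with area outside [2, 200] px are discarded —
limits chosen to exclude single-pixel noise and merged clusters, and
config-exposed because the reference workflow does not report its particle
settings. A punctum belongs to the cell containing its centroid and is
nuclear iff the centroid lies in the nucleus mask, so the
nuclear/cytosolic split always partitions the total. Cell and nucleus
masks are inputs (or come from the generator); segmentation of cells from
raw fluorescence is a non-goal.

**Focus positivity** uses a strict cutoff: a nucleus is positive with more
than 5 foci, matching the usual ">5 foci/nucleus" scoring wording.

**Comet assay.** `segment_comet()` assumes one comet per image migrating
along +x. After subtracting the median border intensity, the
maximum-entropy threshold locates the comet as the largest component, but
intensities are then measured on the signed background-subtracted image
over the comet's row band extended to the image's right edge — the faint
tail must not be clipped by the threshold. The head is estimated by
mirroring the leading (left) flank of the 1-D x-profile about its peak
(a standard comet-scoring convention the reference protocol leaves
unspecified), the tail is the remaining right-side mass, and

$$\text{Tail DNA\%} = 100 \cdot \frac{\text{tail}}{\text{head}+\text{tail}},
\qquad
\text{Extent Tail Moment} = \text{Tail DNA\%} \times \text{tail length},$$

with the tail length the head-to-tail centroid distance. The generator
builds a Gaussian head disc plus an exponential tail streak with an exact
intensity split, and round-trip tests recover Tail DNA% within ±3 points.
The mirror convention assumes an approximately symmetric head; heavily
damaged comets whose peak lies in the tail would violate it.

# Plate formulas

The PrestoBlue percent reduction is implemented in two modes. `as_printed`
is the published two-wavelength equation
$100\,(117216\,A_1 - 80586\,A_2)/(155677\,A_1 - 14652\,A_2)$ on the
test-well absorbances; the constants are the vendor's extinction
coefficients for the reduced/oxidized dye at 570/600 nm. The protocol also
defines media-only absorbances $N_1, N_2$ that the printed equation never
uses — most likely a transcription slip of the vendor formula — so a
`vendor_control` mode with $(155677\,N_1 - 14652\,N_2)$ in the denominator
is provided rather than guessing intent; media-only replicates are
averaged first. The two modes coincide when test equals blank.

In the clonogenic survival fraction the plating efficiency enters as a
fraction (PE/100): read literally with "× PE × 100%" the self-test of an
untreated plate would give 10,000%, so the fraction reading is the only
self-consistent one, and the package's invariant test pins SF(untreated) =
100%.

# Differential proteomics

Rows flagged "Only identified by site", "Reverse" or "Potential
contaminant", rows with fewer than 2 unique peptides, and rows lacking at
least 2 observed values in either group are removed; LFQ intensities of 0
on disk are treated as missing, never as measured zeros, and nothing is
imputed anywhere — every statistic uses observed values only (proteins
failing the valid-values filter are excluded instead, and constant rows
are z-scored to zeros with a degeneracy flag rather than dropped, so
heatmap matrices keep their shape).

The test statistic is a SAM-style moderated difference

$$d = \frac{\bar{x}_{KO} - \bar{x}_{WT}}
{s_p \sqrt{1/n_1 + 1/n_2} + S_0}, \qquad S_0 = 1 \text{ by default},$$

with $s_p$ the pooled standard deviation. The additive $S_0$ damps the
significance of low-variance proteins. The exact internals of the
reference desktop software's S0 treatment are not published; the fixed
additive form above, taken directly from the printed "S0 = 1", is this
package's declared definition. Raw p-values come from the pooled-variance
two-sample two-sided t-test on the same observed values.

Significance is by permutation FDR: for each group relabeling the |d|
statistics are recomputed, and for a cutoff $t$,

$$\widehat{FDR}(t) = \frac{\text{mean}_\pi \#\{|d_\pi| \ge t\}}
{\max(1, \#\{|d_{obs}| \ge t\})},$$

with the significance threshold the smallest observed cutoff with
$\widehat{FDR} \le$ the target (5% default). For a 3 vs 3 design all
$\binom{6}{3} = 20$ relabelings exist; the identity and its complement are
excluded because a full group swap leaves |d| unchanged — keeping them
would floor the FDR estimate at 1/20 and make the 5% target unattainable
by construction — leaving 18 informative relabelings. Larger designs are
subsampled to 1000 relabelings under the run seed. With so few
permutations the FDR is coarse (a warning is attached below 10 distinct
relabelings); validation shows the global-null false-positive proportion
stays below 0.07 over 20 generator seeds and recall of |log2FC| = 2 spikes
exceeds 0.9 at replicate noise SD 0.3.

The proteome generator draws per-protein base log2 abundances
$\mathcal{N}(25, 2^2)$ (typical log2 LFQ scale), adds the spiked effects to
the knockout group, replicate noise of SD 0.3, and missing-at-random
dropout (default rate 0.1, roughly the label-free dropout rate after
match-between-runs). It emulates intensity-independent dropout only;
real LFQ missingness is left-censored (low-abundance proteins drop out
more), so passing tests here do not certify behavior under
abundance-dependent missingness — with no imputation, left-censoring
mainly costs detections near the filter boundary.

# Numerical and interface choices

* Tie-breaks: the first maximizer is taken in the entropy scan; burst
  threshold comparisons are inclusive (`>=`); window boundaries classify
  as coincident.
* Bursts with zero counts after leakage correction have no defined C; they
  are dropped and counted in `n_dropped`.
* The three-Gaussian fit falls back from Levenberg–Marquardt to L-BFGS-B
  on failure, flags non-convergence, and skips the fit entirely (window
  estimate only) for degenerate single-bin histograms. Spike components
  pinned at the width lower bound can stall the LM convergence test at a
  negligible residual; such fits are accepted.
* All file I/O is UTF-8 with "." as the decimal point regardless of
  locale; traces round-trip byte-exactly through their canonical form.
* Every stochastic entry point takes a seed; identical parameters and seed
  give bit-identical outputs.

# Problem sizes used in validation

The shipped tests validate at sizes a laptop handles in well under a
minute each: coincidence runs at 2000 GFP events (the >1000-event regime),
crosstalk calibration at ~100,000 transits, burst-caller equivalence on
1000 random traces, proteome runs at 400–1000 proteins with 3 vs 3
replicates, and image assays at single- to few-cell frames. These sizes
were chosen so the binomial/Poisson error bars are small against the
stated tolerances, not because the methods are size-limited; all
generators scale by parameters.

# Known limitations

* The window estimator inherits a positive pile-up bias at high event
  density (quantified above); the mixture-weight estimator shares it.
* No photophysics (blinking, bleaching, triplet states) and no direct
  excitation of mCherry by the 488 nm line; leakage is one-directional
  green→red.
* Copy-number calibration assumes identical acquisition settings for
  control and sample and small k.
* Comet scoring assumes a single comet per frame and +x migration.
* The permutation FDR at 3 vs 3 is coarse by construction; reported
  achieved FDR values are plug-in estimates, not guarantees.
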