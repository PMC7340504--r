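# burstFISH

Quantification of single-molecule FISH (smFISH) image stacks in developing
tissue, and stochastic modelling of the transcriptional bursting that
underlies them.

smFISH renders individual mRNAs in fixed tissue as ~600 nm
diffraction-limited spots, and active transcription sites as brighter
nuclear spots. Counting both — mature mRNAs per cell and nascent RNA per
site, as functions of position along a morphogen gradient — lets one ask
whether a gradient tunes transcription through the *size* of
transcriptional bursts or their *frequency*. burstFISH provides both
halves of that analysis for R users working with 3D confocal stacks
(76 nm x-y pixels, 345 nm z-spacing, 12-bit):

* **Imaging**: plateau-based segmentation-threshold selection, 2D→3D spot
  linking, fixed-radius intensity measurement, transcription-site calling
  normalized to nascent-RNA units, classical nucleus segmentation with 3D
  "pancake" stacking, virtual cells by bounded 3D Voronoi tessellation,
  and spatially binned statistics (median mRNAs/cell, site fraction, Fano
  factor) with BCa bootstrap confidence intervals.
* **Modelling**: exact Gillespie simulation of the two-state telegraph
  promoter — OFF→ON at `kon`, ON→OFF at `koff`, initiation at `kini`
  while ON, decay at `kdeg` — with burst size `kini/koff`, burst
  frequency `1/(1/kon + 1/koff)`, probe-weighted nascent-signal read-out,
  random allele pairing, and parameter sweeps that discriminate
  size-modulated from frequency-modulated control.
* **Synthetic scenes**: a ground-truthed generator of two-channel stacks
  (spots, sites, nuclei, noise) so the whole pipeline is testable without
  any external imaging data.

## A worked example

Render a synthetic stack, segment it, and compare a telegraph-model
prediction:

```r
library(burstFISH)

## a 192 x 192 x 14 stack with 120 mRNAs, 4 transcription sites, 4 nuclei
spec <- SceneSpec(dims = c(192, 192, 14), nSpots = 120, nSites = 4,
                  nNuclei = 4, siteMultiplierRange = c(4, 8), seed = 7)
scene <- renderScene(spec)

seg <- segmentSpots(scene$fish)
seg$scan
#> ThresholdScan: 60 cutoffs in [102, 443]
#>   plateau: cutoffs 211.814..269.61 (11 steps), selected 240.712
nrow(seg$spots)
#> [1] 120

sites <- segmentSites(scene$fish, seg$spots)
round(sites$units, 2)
#> [1] 3.68 4.49 4.39 4.86     # nascent units; true multipliers 4.5-6.1
```

120 of 120 rendered mRNAs are recovered at the plateau-selected cutoff,
and all four sites are called, with normalized nascent units tracking
their true intensity multipliers (units = site intensity / median mature
intensity; only candidates with >= 2 units — twice a single mRNA — are
reported).

On the model side, sweeping initiation rate (burst size) versus ON-rate
(burst frequency) leaves distinct signatures in the same two observables
the imaging measures:

```r
tm <- nascentTiming("dad")       # tau_elong = 2.05 min at 1100 nt/min
sweepParameter("kini", c(2, 8, 32), TelegraphParams(kon = 0.4, koff = 2,
               kini = 1), tm, nPairs = 1000, seed = 101)[,
               c("burstSize", "fractionDetected", "medianNascent")]
#>   burstSize fractionDetected medianNascent
#> 1         1            0.197           2.5
#> 2         4            0.601           4.5
#> 3        16            0.795          14.0
```

Under size modulation the nascent signal per detected site climbs with
the detection fraction; under frequency modulation (sweeping `kon` at
fixed burst size) it stays at the level set by the burst size. That
contrast is the model-side discriminator for how a morphogen controls
its targets.

## Documentation

The methods vignette (`vignettes/burstFISH-methods.Rmd`) describes the
segmentation and tessellation algorithms, the telegraph model and its
stationary theory, the nascent-weighting scheme, all tunable parameters
with defaults and rationale, what the synthetic scenes do and do not
emulate, and known limitations.
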