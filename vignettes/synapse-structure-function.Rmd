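---
title: "Correlating presynaptic function with nanoscale structure: models and methods"
author: "SynapseCorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlating presynaptic function with nanoscale structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SynapseCorr)
```

## The problem

Individual synapses differ widely in how reliably they release
neurotransmitter for a given calcium influx, and part of that variability is
thought to come from the nanoscale organisation of active-zone proteins such
as Bassoon and the P/Q-type calcium channel Cav2.1, which form compact
subsynaptic domains (SSDs) within each bouton. Relating the two requires a
correlative experiment: first functional imaging of a dual reporter
(SypHy-RGECO: a pH-sensitive green fluorescent protein on the synaptic
vesicle reports release, a red calcium indicator on the same protein reports
calcium influx), then 3D single-molecule localisation microscopy (dSTORM) of
the same boutons after fixation, with the two modalities registered so that
each functional bouton can be paired with its segmented protein clusters.

SynapseCorr implements the analysis side of this workflow as a tested
package: trace analysis of the dual-reporter movies, spectral demixing and
drift correction of the localisation tables, Voronoi-based two-colour
cluster segmentation, landmark affine registration, and the per-synapse
correlation statistics — plus a synthetic-data generator that produces every
input with ground truth, so each stage can be validated quantitatively
without access to microscope data.

## Functional side: trace analysis

Movies are acquired at 4x4 binning (433 nm pixels) with the two channels
interleaved at 12.5 Hz each. For each bouton a 5x5-pixel ROI mean is
computed per frame and channel, and one 15x15-pixel background ROI per field
is subtracted frame by frame. Traces are smoothed with a 4-frame sliding
window; we use a *trailing* (causal) window: a centred 4-frame window is
ill-defined, and a trailing window cannot leak post-stimulus signal into the
baseline. Baselines G0 and R0 are means of the 15 frames ending one frame
before the stimulus; the peak responses dG and dR are the maxima of the
baseline-subtracted smoothed trace within the 15 frames starting at the
stimulus frame (inclusive). A bouton is a *calcium responder* when dR
exceeds 3x its baseline SD — strictly, so a perfectly flat trace never
classifies as responding — and *release* is detected by the same rule on the
G channel. The two flags are independent; downstream correlation includes
only calcium responders, mirroring the experimental inclusion rule. Both dG
and dR are normalised to R0, the baseline reporter level, and dG/dR
(the optical estimate of the calcium dependence of release) is reported for
calcium responders with dR > 0.

Two details are genuinely open in the protocol and are settable:

* whether the baseline SD is taken on the smoothed or the raw trace. We
  default to the raw trace: a 3 SD rule is only calibrated against the
  unsmoothed noise scale, whereas thresholding the *maximum* of the
  smoothed trace over a 15-frame window at 3 x the smoothed-baseline SD —
  a quantity with a quarter of the variance, estimated from 15 strongly
  autocorrelated samples — misclassifies roughly 10-15% of non-responding
  boutons in simulation. `baselineSdOn = "smoothed"` switches to the
  smoothed trace for sensitivity analysis.
* the placement of the background ROI. By default the minimum-mean
  background-sized window of the time-averaged G channel is used; an
  explicit centre can be supplied.

## Structure side: spectral demixing, drift, rendering

Spectral demixing dSTORM images two spectrally close far-red fluorophores
with one laser and splits their emission onto two cameras with a long-pass
dichroic. Each emitter's photon ratio rho = I_cam1 / (I_cam1 + I_cam2) is
then bimodal across detections. We pair detections across cameras (mutual
nearest neighbours on the same frame, tolerance one camera pixel = 97 nm),
fit a two-component Gaussian mixture to the ratio histogram, and assign a
fluorophore only when its posterior probability reaches 0.99; everything
else is rejected. The posterior band, rather than a fixed ratio cut, bounds
the crosstalk explicitly. Two degeneracy guards protect against unimodal
input: component means closer than one pooled SD, and the absence of a
density dip between the component means (an EM fit on unimodal data can
converge to a spurious "split" solution that passes a separation test
alone).

Lateral drift is estimated by redundant cross-correlation: localisations are
split into 2,000-frame bins (30 bins of a typical 60,000-frame stack),
each bin is rendered as a 20 nm 2D histogram, and each bin is
cross-correlated against the first with 10x-upsampled sub-pixel refinement,
giving 2 nm granularity. The cross-power spectrum is Gaussian low-pass
filtered (sigma 1.5 histogram pixels) before peak finding: sparse
localisation histograms otherwise give a jagged correlation peak whose
sub-pixel refinement is biased by several nm. The per-bin shifts, linearly
interpolated at each record's frame, are subtracted from x and y; the end
segments are extrapolated linearly, so a steady drift is corrected without
an endpoint residual (constant end extrapolation would leave a sawtooth of
half a bin's drift at both ends of the stack). Only lateral drift is
corrected; z is untouched. Super-resolved images are 2D count histograms at
10 nm pixels; rendering conserves counts exactly.

## Voronoi segmentation and colocalisation

For each colour separately, a 3D Voronoi tessellation is computed over the
localisation coordinates and each point's density is defined as the inverse
volume of its cell, delta_i = 1 / V_i. Cell volumes are computed exactly by
half-space clipping: each cell starts as a small cube around its point and
is clipped by the bisector planes of its neighbours (with a security-radius
bound: a neighbour farther than twice the current maximum vertex distance
cannot cut the cell). Unbounded cells — their points lie on the boundary of
the dataset convex hull, a rigid-motion-invariant classification — carry
delta_i = 0, and the mean-density summary uses only bounded cells lying
fully inside the dataset bounding box (bulging boundary cells would bias it
upward).

The density that segmentation thresholds is not the raw inverse cell
volume but the *first-rank* density: the median inverse cell volume over
a cell and its Voronoi neighbours. The raw inverse volume honestly
reports a near-zero density for the outward-facing shell of every cluster
— such cells legitimately bulge into empty space — so thresholding it
cuts a band off every cluster and can push small SSDs below the
20-molecule minimum. The neighbourhood median measures the local
environment instead of the single cell, and it is robust in both
directions: a shell point surrounded by dense core cells scores high,
while one enormous cell cannot drag down the density of the points
around it, and a genuinely sparse neighbourhood stays sparse. On a
regular grid the median equals 1/V exactly, which keeps the analytic
exactness checks meaningful. Both quantities are stored on the
[VoronoiDensityMap-class].

Segmentation keeps points with delta_i >= 1 x the dataset average density,
links kept points within a maximum neighbour distance of 200 nm (colour 1)
or 100 nm (colour 2), and accepts connected components with at least 200
(colour 1) or 20 (colour 2) molecules as clusters. The *average density of
the dataset* is implemented as the global density — detections per dataset
extent — which is the convention of the Voronoi-segmentation tools this
analysis follows (the SR-Tesseler / PoCA lineage). The alternative reading,
the mean of the per-point Voronoi densities over finite cells, is exposed
as `densityReference = "mean"` but is not the default: because points
sample density in proportion to density itself, that mean sits *inside* the
range of cluster densities and cuts roughly half the points of every
Gaussian-shaped cluster, which empties small SSDs below the 20-molecule
minimum and contradicts the published behaviour of the threshold (complete
clusters survive segmentation). The extent that defines the global density
is the acquisition volume (e.g. a 512 x 512 pixel field at 97 nm with a
1 um axial range) and should be supplied via `voronoiDensity(extent = ...)`
whenever the localisations occupy only part of the imaged field; the
default, the dataset convex-hull volume, is the conservative data-driven
choice and is invariant under rigid motions. One consequence worth knowing:
in empty surroundings the Voronoi cells of a cluster's outward-facing shell
are legitimately enormous (their density honestly low), so a reference
density computed over the points' own footprint — rather than the field —
cuts into every cluster's shell.

Cluster volume is the 3D convex hull of the member points (deterministic and
cheap; an alpha-shape would be tighter for strongly non-convex clusters but
introduces a free parameter), and cluster density is detections per hull
volume. Clusters with fewer than 4 non-coplanar points are flagged
degenerate.

Colocalisation declares an SSD to overlap a synapse when any SSD point lies
inside the colour-1 hull. SSDs that overlap nothing are assigned to the
nearest colour-1 centroid within 500 nm and tagged "orphan-assigned" — a
deterministic, recorded replacement for the manual correction of missed
colocalisations that the original workflow required (active-zone SSDs often
sit at the edge of, or just outside, the vesicle-cloud cluster). SSDs
farther than 500 nm stay unassigned; synapses with no SSD are retained with
`n_ssd = 0` and excluded only by downstream group statistics.

## Registration and matching

Registration is 2D: a maximum z-projection of the live green channel
against the rendered dSTORM image plane (dSTORM z is used for clustering,
not matching). The live-to-dSTORM map x -> A x + t is fitted by least
squares from at least 3 non-collinear landmark pairs, and the landmark RMSE
is reported so users can judge the alignment, as the original workflow did
visually. The package-wide coordinate convention is physical nm with
pixel-centre mapping nm = (index - 0.5) x pixelSize for 1-based indices,
which avoids a half-pixel registration bias.

Responder ROI centres are mapped through the transform and matched greedily,
one-to-one and nearest-first, to colour-1 centroids within 500 nm. A
responder with a second candidate within 10% of its best distance is
excluded and logged: reproducibility over curation, replacing the manual
selection of well-aligned synapses.

## Statistics

The analysis battery over matched synapses reports (i) Spearman
correlations of dG/R vs dR/R overall and within single- and multiple-SSD
groups, (ii) a two-sample Kolmogorov-Smirnov comparison of dG/dR between
single- and multiple-SSD synapses, and (iii) KS comparisons of total SSD
detections and mean SSD density between synapses with and without
detectable release, plus the SSD-count distribution. Spearman uses
mid-ranks; its two-sided p-value is computed by exhaustive enumeration of
the permutation distribution for n <= 10 (ties handled exactly) and by the
t-approximation above that. KS reports the exact supremum distance with the
asymptotic two-sided p-value. No multiple-testing correction is applied —
p-values are per comparison, as in the original analysis — and the report
footer says so.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth:

* **Functional movies.** Each bouton is a Gaussian spot (sigma 1.5 px)
  whose 5x5-ROI mean is normalised to 1, on baselines G0 = 10 (dim,
  quenched pHluorin) and R0 = 100 (bright calcium indicator baseline). At
  the stimulus both channels step by their programmed amplitude, hold a
  plateau as long as the smoothing window, and decay exponentially (tau = 40
  frames for G — slow vesicle re-acidification; tau = 8 frames for R —
  calcium extrusion). The plateau guarantees that trailing-window smoothing
  of a noiseless response recovers the programmed amplitude exactly, which
  is what makes the exactness checks meaningful. Noise is i.i.d. Gaussian
  per pixel.
* **Two-camera emitters.** Total photons are lognormal (mean 3,000,
  log-SD 0.5); the photon ratio is Normal per fluorophore (means 0.75 and
  0.30, SD 0.05), truncated to [0, 1] — chosen to mimic the published
  bimodal ratio histogram of an AF647/CF680 pair, not a physical spectral
  model.
* **Point-cloud scenes.** Each synapse is a diffuse colour-1 Gaussian
  cluster (sigma 150 nm, 200-2,000 detections) with 1-6 colour-2 SSDs
  (sigma 40 nm, 20-200 detections) on its periphery, over uniform Poisson
  background (default 5 points/um^3 in both colours) in a box whose z span
  is 1,000 nm — the usable axial range of astigmatic 3D localisation. SSD
  centres are drawn at radii between 1x and 3x the nominal 150 nm offset
  and keep at least 400 nm mutual separation. That separation floor is a
  deliberate identifiability choice: the ground-truth SSD count is defined
  as the number of *link-separable* domains, exactly as in the real
  analysis, where SSD counts are themselves segmentation outputs. Domains
  whose 40 nm-SD clouds sit closer than roughly the linking distance plus
  their tails would merge into one segmented cluster with near-certainty,
  and a "truth" that cannot be observed even in principle would make
  recovery rates meaningless.
* **Correlative datasets.** Bouton centres in live pixel space are pushed
  through a randomly drawn invertible affine (scale near the 433 nm pixel
  size, rotation up to 5 degrees, shear up to 3%) into nm space, where the
  scene is placed; six exact landmark pairs are emitted. Per-point camera
  intensities follow the two-camera ratio model with colour 1 as the high-
  ratio fluorophore. Under positive coupling dG = c x (total SSD
  detections) x exp(eps) with eps Normal, SD 0.3, centred so the factor has
  mean 1; under null coupling dG is drawn independently of structure. dR is
  uniform on [20, 60] over an R0 of 100, spanning the realistic range of
  evoked calcium transients.

What the generator does *not* emulate: optical PSFs and camera noise
physics, fluorophore blinking and repeat localisations, bleaching, z-drift,
chromatic offsets, and non-Gaussian cluster shapes. Passing tests therefore
demonstrate the correctness of the analysis chain on data satisfying its
stated model, not robustness to every artefact of real acquisitions.

## Numerical choices and problem sizes

The Voronoi engine is exact (half-space clipping with an absolute plane
tolerance of 1e-12 of the scene diagonal); hulls use an incremental
algorithm with a scale-relative tolerance. The drift estimator's granularity
is grid/upsample = 2 nm at the defaults. Validation workloads were sized to
make every check statistically meaningful while staying desk-scale: 20
boutons for exactness, 500 boutons for responder operating characteristics,
20,000 emitters for demixing error rates, 9,000 localisations over 6,000
frames for drift, three 8-synapse scenes for SSD recovery, and an n = 100
correlative dataset plus 200 null replicates (n = 15 each) for the
correlation statistics.

## Known limitations

* Convex-hull volumes overestimate strongly non-convex clusters.
* The photon-ratio mixture assumes two Gaussian components; heavy-tailed
  ratio distributions would inflate the rejection fraction.
* Drift correction assumes drift is well-approximated as piecewise linear
  across 2,000-frame bins.
* The orphan-assignment rule is distance-based only; it cannot use the
  axonal-morphology context a human curator would.
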