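---
title: "Methods: simulated photon-counting cardiac phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated photon-counting cardiac phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices and numerical decisions. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## Spectral physics

Attenuation is the two-basis photoelectric/Compton decomposition

$$\mu(E) = \left[\,p\,(30/E)^3 + c\,\mathrm{KN}(E)\,\right]\cdot s(E),$$

with $\mathrm{KN}$ the Klein–Nishina total cross-section normalized at
30 keV, and $s(E)$ a multiplicative step equal to 1 below a material's
K-edge and to the edge jump at and above it. Two deliberate choices:

* **Coefficients are calibration parameters, not table lookups.** The
  pipeline's conclusions depend only on self-consistent, linear-in-
  concentration, K-edge-bearing physics. Magnitudes are set near tabulated
  values — water $0.375\,\mathrm{cm^{-1}}$ at 30 keV; iodine
  $\approx 0.011\,\mathrm{cm^{-1}}$ per mg/mL below its 33.2 keV edge with
  a jump of 3.1; calcium $\approx 0.003\,\mathrm{cm^{-1}}$ per mg/mL — so
  simulated Hounsfield values and contrasts are plausible, but no claim of
  NIST fidelity is made.
* **The K-edge step multiplies the total attenuation**, not only the
  photoelectric term, so the across-edge ratio equals the configured jump
  exactly. With the Compton weight of iodine two orders of magnitude below
  its photoelectric weight, the difference from an edge on the PE term
  alone is far below the calibration uncertainty, and the exact-ratio
  property is worth having.

Mixtures are concentration-weighted sums of per-material attenuations —
the linearity that image-domain material decomposition inverts.

## Phantoms

Geometry is one axial slice (2D) with a slab thickness converting mask
areas to volumes; every algorithm is dimension-agnostic, and desk-scale 2D
keeps the whole pipeline runnable in minutes on one CPU. The default
cardiac phantom is a 96² grid at 0.25 mm with a 1 mm slab.

The LV is a disk whose area follows a raised cosine between end-diastole
(phase 0) and end-systole (phase 0.5) at a configurable heart rate in the
murine 300–600 bpm range. Only the volume extrema enter the cardiac
metrics, so the smooth waveform is a modeling convenience, not a claim
about murine ventricular mechanics. Rendering uses an area-fraction
(linear edge) model, which makes ROI means and mask areas analytically
predictable; the stored ground truth (DLVV, SLVV, and derived SV/EF) is
measured from the rendered 0.5-coverage masks, so truth and rendering can
never disagree. Blood-pool iodine defaults to 20 mg/mL — mid-range for a
liposomal blood-pool agent, about +580 HU in the lowest energy bin; the
in-vivo concentration after dosing is not a published quantity, so it is
an explicit configuration parameter.

The detectability phantom embeds calcium cylinders (diameters 0.5–2.5 mm;
10, 20, 40 mg/mL) and one iodine row in a 10 mg/mL iodinated background
disk: the "calcium against iodine" task. Cylinder interiors displace the
background iodine. Layout pitch (2.5 mm columns, 2.7 mm rows) is the
tightest non-overlapping arrangement that keeps every background annulus
inside the iodinated region.

## Acquisition

The source is filtered bremsstrahlung (Kramers shape with an $E^{-3}$
filtration factor) at 80 kVp, normalized to `photons_per_ray` expected air
counts per detector pixel per view — tube current is folded into this
single number. Detector thresholds default to 25/34/50/60 keV, chosen to
straddle the iodine K-edge; bins are ideal (sharp thresholds, no charge
sharing or pile-up). Views are 10 ms (100 Hz view rate), which the
simulator checks against the cardiac Nyquist limit (a 600 bpm heart is
10 Hz; 100 Hz sampling is comfortably sufficient). The geometry is
parallel-beam: a pixel-driven sparse system matrix whose entries carry the
voxel path length, built per angle and cached; the backprojector is the
exact matrix transpose, so adjointness holds to machine precision by
construction. Counting noise is Poisson on the expected per-bin counts,
fully seeded. Log-normalization clamps zero counts to 0.5 (with a warning
counter) before the log.

The default scan for gated studies is 1000 views over 5 rotations (10 s);
the paper-scale 7000-view protocol is configuration, not code.

## Intrinsic gating

The difference between measured projections and reprojections of an
ungated single-channel reconstruction cancels static anatomy and keeps
motion. The per-view reduction of this residual is the **signed detector
mean** rather than an RMS: for a volume waveform symmetric about its mean,
any even (sign-free) reduction concentrates spectral power at twice the
heart rate, while the signed mean is a direct LV-volume proxy at the
fundamental. `rms` and center-of-mass reductions remain available via the
`reduction` argument.

The heart rate is the dominant amplitude-spectrum peak inside the
300–600 bpm band, refined by quadratic interpolation of the Hann-windowed
log-amplitude around the peak — this beats the 6 bpm FFT resolution of a
10 s scan by more than an order of magnitude. A peak below four times the
median in-band amplitude raises a `no_cardiac_signal` condition (the
expected outcome for a motionless subject). Phases come from signal peaks
(minimum separation 0.8 cycles) delimiting the R-R intervals; cycles are
anchored half a bin before each peak so that bin 0 is *centered* on
end-diastole and bin `n/2` on end-systole. With edge-aligned bins the
systolic bin would average the rising and falling flanks and overestimate
SLVV by ~25% structurally; centering removes that bias. Respiratory-band
signal is simply outside the filter band and discarded.

## Reconstruction

FBP is ramp-filtered (optionally Hann-apodized) backprojection through the
transpose system matrix. The iterative method solves, per cardiac phase
$t$ and energy bin $e$,

$$\hat X = \arg\min_X \sum_{t,e}\left[\tfrac12\|R\,X(t,e) - Y(t,e)\|_2^2
  + \lambda(t,e)\,\mathrm{TV}(X(t,e))\right]$$

by split Bregman (anisotropic TV, shrinkage on the splitting variable,
conjugate-gradient x-updates with 10 inner iterations, 5 outer loops,
convergence at $10^{-4}$ relative objective change) with the
add-residual-back strategy re-injecting the data residual each outer loop.
After each outer loop the multi-channel regularization is applied:
temporal bilateral filtration across the (circular) phase axis and a
rank-sparse filter across energy bins. $\lambda$ defaults to a
noise-proportional rule — `lambda_scale` times the median absolute
deviation of the FBP seed's horizontal differences — because no universal
weight exists across photon budgets; `lambda_scale = 8` was fixed once on
the water-phantom study.

The rank-sparse energy filter is a simplified re-implementation: the
(pixel × bin) matrix is split by SVD into its leading rank-1 component
(kept intact, so spectrally proportional stacks are exact fixed points)
and a residual whose singular values are soft-thresholded at a fraction of
the leading one and which is smoothed with bilateral weights computed from
the bin-averaged image. It shares the fixed points of the full
rank-sparse kernel regression it stands in for, at a fraction of the
code.

Inside the cardiac pipeline the filter strengths default to gentle
settings (bilateral window 1, domain sigma 0.6; rank threshold 0.03,
spatial sigma 1) — at 10 phases the LV boundary moves little between
neighbouring phases, and stronger temporal mixing measurably dilates the
systolic blood pool ("temporal ghosting") and biases SLVV upward.

The recorded objective uses the original data and must be non-increasing
within 0.1% per outer iteration; three consecutive violations raise a
divergence error with diagnostics.

## Material decomposition

Vials of known composition give the sensitivity matrix by least squares of
per-bin ROI means against concentrations; its condition number is
reported, and a warning fires above $10^3$. Per voxel, $X = C M$ is
solved by (optionally inverse-variance-weighted) least squares over the
4 bins; any voxel with a negative component is re-solved with the most
negative basis removed, repeated until feasible — the standard active-set
realization of orthogonal subspace projection, which is idempotent and
leaves non-negative voxels untouched (for those, $CM$ reproduces $X$ to
solver precision). Each cardiac phase is decomposed independently.

## Detectability

`CNR = (mean(signal) − mean(background)) / sd(background)` with the signal
ROI eroded one voxel from the cylinder boundary and the background an
annulus of three times the signal area in the surrounding iodine,
excluding neighbouring cylinders. The "single-energy" image is the
reconstruction of the *summed* four-bin counts — a counting detector's
lowest-threshold image is cumulative — in which iodine out-attenuates
calcium and CNR is negative. The Monte-Carlo study (default 10 seeded
repetitions at `photons_per_ray = 2e5`, Hann-apodized FBP,
inverse-variance decomposition weights estimated from a cylinder-free
iodine region) reports mean CNR with its standard error.

## Segmentation

The U-Net is implemented directly in R: im2col 3×3 convolutions as single
BLAS products (offset-fastest weight layout; the input gradient is a
convolution with the flipped kernel), ReLU, 2×2 max pooling,
nearest-neighbour upsampling with a 1×1 channel projection and skip
concatenation, and a sigmoid head whose bias starts at −2 (a ~12%
foreground prior, avoiding the early all-background stall of imbalanced
Dice+BCE training). Backpropagation is exact and verified against
numerical gradients in the test suite. The default is 3 levels and 8 base
channels on 64² inputs — a desk-scale budget (about 12 s per epoch on one
CPU at batch 16) that the synthetic task does not outgrow; depth, width
and size are configurable.

Training follows the protocol: Adam at $5\times10^{-4}$, up to 50 epochs
by default with the validation-plateau rule (patience 5, factor 0.1), and
the best-validation checkpoint is returned. The training loss sums binary
cross entropy and one minus the *soft* Dice coefficient (smoothing
constant 1) — the printed form of the Dice loss term carries a sign that
would reward empty masks and its binarized form is non-differentiable, so
training uses the standard soft form while *evaluation* Dice uses the
binarized definition. The decision threshold minimizes
|precision − recall| on the training data over a 0.01-step grid, ties to
the lowest threshold. For a near-perfect network this rule deliberately
returns a very small threshold (all thresholds tie); the *pipeline*
therefore binarizes at 0.5, which is bias-neutral for a calibrated
network, and keeps the precision-recall rule for the benchmark protocol.
The validation and benchmark runs in this package train for 15 epochs;
on the synthetic task the validation loss is flat well before that.

The synthetic slice generator emulates a center-cropped, contrast-enhanced
cardiac slice: a thorax filling ~80% of the frame, lung-like hypodense
regions, an elliptical LV at 1.3–1.8× the body pool intensity, blurring by
the *measured point-spread of the package's own FBP operator* (ramp-filter
side lobes included) plus a small random Gaussian, and white noise, then
z-normalization. It does not emulate papillary muscles, myocardial
texture, respiratory motion or streak artifacts, so benchmark Dice values
speak to the pipeline's geometry handling, not to real-animal
performance. For use *inside* the pipeline the training set is augmented
with samples generated through the actual acquisition + FBP operator
(`make_lv_recon_samples`): a purely synthetic-trained model shows a
systematic ~1.5-pixel outward boundary bias on reconstructed images (its
probability 0.5 contour sits outside the true edge at every threshold),
and domain-matched training removes it. The pipeline's segmentation input
is the gated FBP of the cumulative lowest-threshold channel -- the same
operator family the domain-matched samples are generated with -- and the
validation set used for best-checkpoint selection mixes three domains
(synthetic slices, static reconstructions, and gated phase slices
harvested from the pipeline's own imaging chain, labeled at the
bin-averaged effective area), so a checkpoint cannot drift away from the
pipeline's domain while looking good on purely synthetic slices; a
trained candidate whose volume calibration on the gated validation
slices is off by more than 6% is retrained once with a fresh
initialization. At inference the pipeline averages probabilities over
the four exact lattice flips: single-slice boundary errors driven by a
particular noise realization are close to independent across flips, and
the averaging collapses the heavy tail of per-slice volume errors. Labels for the iodine-map
input variant are the same CT-derived masks.

## Cardiac metrics and statistics

Record-wise identities: `SV = DLVV − SLVV`, `EF = 100·SV/DLVV`,
`CO = SV·HR` (mL/min), `CI = CO/weight` (mL/(min·g)) — body weight
replaces body surface area in the cardiac index, as is common in murine
work. DLVV and SLVV are the maximum and minimum segmented phase volumes;
because bins are centered on the extremes, the bin-averaging bias on both
is second-order.

Age outliers are removed by the 1.5 IQR rule within each of the eight
genotype × sex groups, with type-7 (linear interpolation) quantiles —
the convention choice is explicit since conventions differ; groups under
4 records pass through with a warning. The factorial model
`response ~ Sex*Age*Weight*HN*Genotype` is fitted by OLS with
`singular.ok`: the HN-within-knockout columns are structurally aliased
(HN is identically 0 for KO) and are dropped and reported. The ANOVA is
**type II by model comparison** — each term tested against the model
containing everything except itself and its higher-order relatives —
implemented directly because the usual type-II routine refuses aliased
fits; on single-factor designs it reduces to the classical F, which the
tests pin to the squared pooled t-statistic. Post hocs are estimated
marginal means (covariates at their means, the emmeans default) with
Tukey adjustment within each contrast family. Cohen's
$f = \sqrt{\eta^2/(1-\eta^2)}$ uses
$\eta^2 = SS_{\mathrm{term}}/(SS_{\mathrm{term}} + SS_{\mathrm{res}})$.
The diet–weight association is the point-biserial correlation with the
exact t transformation. The synthetic cohort generator reproduces the
packaged 123-animal group structure with ages near 12 months (the
high-fat-diet timeline) and configurable injected effects for power
studies.

## Problem sizes and seeds

Defaults throughout are desk-scale choices: 96² grids (160² for the
detectability phantom at 0.125 mm), 1000-view gated scans, 240–360-view
static scans, 10 phase bins × 4 energy bins, 200-slice segmentation
benchmarks, 500-repetition power simulations. Every stochastic operation
takes an explicit seed; the pipeline fans a single global seed out to
named per-stage sub-seeds so adding a stage never perturbs another
stage's randomness, and reruns are bit-identical.

## Known limitations

Parallel-beam 2D geometry (no cone-beam weighting); ideal detector
response; no scatter, pile-up or dose model; respiratory motion is not
rendered (the gating band simply excludes it); the rank-sparse energy
filter is a simplified stand-in sharing fixed points with the full
algorithm; segmentation benchmarks are synthetic and say nothing about
real-animal Dice; the statistics layer reproduces the analysis machinery,
not any real cohort's values.
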