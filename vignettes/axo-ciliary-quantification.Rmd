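---
title: "Quantifying axo-ciliary contacts: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axo-ciliary contacts: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliaxis)
```

`ciliaxis` turns multichannel 3D fluorescence volumes, lifetime stacks and
sensor time series into the quantities that establish contacts between
serotonergic axons and neuronal primary cilia. This vignette explains the
models behind each stage, the parameters that matter, what the synthetic
data generator does and does not emulate, and the design decisions taken
where the procedure left genuine freedom.

## Volumes, grids and conventions

Every volume is a 3D array in `(z, y, x)` order with a physical voxel size
per axis in micrometres; physical coordinates are voxel-centre positions.
Distance mapping and skeletonization require isotropic voxels, so
anisotropic acquisitions (e.g. 41 x 41 x 189 nm) are first resampled with
`resample_isotropic()` — trilinear interpolation for intensities, nearest
neighbour for masks (to avoid label bleeding), with physical extent
preserved to within one voxel per axis. Spectral unmixing solves the linear
mixing model per voxel by least squares; because abundances are physical
intensities, voxels with negative solutions are re-solved under a
non-negativity constraint (active-set least squares) and their count is
reported. Lifetime-gated channel separation (`flim_split()`) assigns each
voxel's photon counts to signal or background according to whether its mean
arrival time reaches the gate; the default gate of 1.0 ns sits between the
autofluorescence population (peak near 0.3 ns) and the dye population (peak
near 2.3 ns), which are the only two anchors the protocol provides, and the
gate is exposed as a parameter. Gating is per voxel; per-photon gating
would need raw photon streams, which the exported count/lifetime pairs do
not contain.

Volumes travel as plain multi-page TIFF plus a JSON sidecar carrying the
voxel spacing, channel label and intensity scale. The sidecar is
authoritative on read and a missing one is a hard error: silently assuming
a default voxel size corrupts every micrometre-valued result downstream.

## Segmentation

Foreground extraction uses Otsu's threshold over a 256-bin histogram; the
implementation accumulates exact per-bin value sums so the maximizer agrees
with an exhaustive search over all candidate thresholds on any input. The
*restricted* variant computes the threshold only from values at or below a
percentile cap (90th by default) — the right gate for DNA stains whose
bright tail would otherwise drag the threshold up — and then applies it to
all voxels. Yen's threshold is provided for dim stacks where Otsu
over-segments. Masks are cleaned by morphological closing with a Euclidean
ball (default radius 0.4 um; 0.3 um for cilia and 0.5 um for axons in the
bundled pipeline defaults) followed by removal of components below a
physical volume cutoff (default 0.05 um^3, raised per structure). Kernel
shapes and size cutoffs are not dictated by the protocol, so they are
configuration with documented defaults rather than constants.

The pyramidal cell layer is recovered by dilating the nuclei mask until the
densely packed somata merge and keeping the largest connected component
(ties broken deterministically toward the lowest label and reported).
Nucleus centres come from erosion, a Euclidean distance transform, and a
per-component threshold at a fraction (default 0.5) of the component's
maximum interior depth — enough to separate touching nuclei whose necks are
shallower than their cores.

2D orientation analysis computes the structure tensor from Gaussian
gradients (default scale 2 px) smoothed with the analysis window (default
20 px), after maximum-intensity projection along z. The orientation
histogram over (-90, 90] degrees is weighted by tensor energy (trace), with
coherence available as an alternative since the reference plugin's exact
weighting is unspecified. A single circular Gaussian is fitted to the
histogram; the result is flagged low-confidence unless the peak rises above
the baseline, is narrower than a quarter period, and carries at least 20%
of the histogram mass — an isotropic image fails at least one of these.

## Skeletons, lengths and distances

Masks are reduced to one-voxel central axes by distance-ordered homotopic
thinning with a (26, 6) simple-point test. Two implementation details
matter for quantitative use. First, plain endpoint-preserving thinning can
retreat off the ends of a tube by far more than one radius before a curve
endpoint forms; each component's geodesically farthest voxel pair (its cap
tips) is therefore protected during thinning, anchoring the skeleton to the
full tube span. Second, the digital skeleton both zigzags (overestimating
oblique curves by up to ~10%) and runs from cap tip to cap tip
(overestimating by about one tube radius per end). `cilium_length()`
compensates by re-centring each path vertex on the tube's cross-section
centroid (sub-voxel, perpendicular to the local tangent), smoothing with a
symmetric moving average that pins the endpoints, and measuring each cap's
overshoot directly — walking outward along the end tangent to the mask
boundary, which lies one tube radius beyond the true axis end. For branched
skeletons, length is the longest geodesic path; side branches shorter than
3 voxels are pruned as thinning artefacts.

Distance encoding follows the distance-transform formulation: the Euclidean
distance transform of the target is sampled at every cilium skeleton voxel,
and the per-cilium minimum feeds classification. At 0.2-um voxels the
digital skeleton carries up to half a voxel of jitter and its anchored tips
sit on the blur-elongated mask surface, which biases minima low by up to
~0.7 um; `distance_on_skeleton(refine = TRUE)` therefore also computes a
sub-voxel estimate — both skeletons re-centred voxel-wise, graph-neighbour
smoothed, with the cap/tip neighbourhoods excluded — whose error stays
within about +/- 0.45 um on the bundled scenes. Contact classification is
inclusive (`d_min <= 2 um`, "within" read as at-most), and the cutoff is
exposed in `contact_params()`. Cilia are excluded from analysis when any
skeleton voxel lies within one voxel of a volume face or when their nearest
nucleus (to the skeleton point closest to any nucleus centre — the base)
falls outside the selected layer; the nucleus-assignment rule is a design
choice, since "associated nuclei" is otherwise undefined.

Puncta are detected as 26-neighbourhood local maxima of the scale-normalized
3D Laplacian-of-Gaussian response, with centroids refined by local centre of
mass. The filter scale defaults to 0.2 um (a diffraction-limited punctum at
typical Airyscan sampling) and the threshold defaults to 5 robust (MAD)
standard deviations of the response, both exposed; neither value is stated
by the protocol.

## Photophysics

dF/F0 uses the mean background-subtracted intensity over the baseline
window as F0 (ten pre-stimulation frames for optogenetic protocols, the
first five for ligand application). The low-pass filter is a hard cutoff in
the Fourier domain (0.2 Hz for sensor traces, 1 Hz for FRET at 4 Hz
digitization), which preserves the mean exactly and is idempotent. Hill
fits run against log10 concentration with the slope free (the original
fitting software's default is unknown) and an optional zero lower
asymptote; exponential kinetics fit a single component and warn when the
trace covers fewer than three fitted time constants. Perfectly noiseless
inputs can place the optimizer's start exactly at the optimum, which the
underlying least-squares machinery rejects; the fits retry from small
deterministic start perturbations.

FRET ratio series are computed frame-wise from maximum-projected stacks:
the donor projection is background-flattened by a grayscale disk opening
(radius configurable, default 50 px — standing in for paraboloid
background subtraction), Otsu-masked, both channels are offset by the mean
of a caller-supplied acellular region, and the ratio is the summed
sensitized emission over summed donor emission within the mask (summed and
mean intensities give identical ratios for a shared mask; summed is
implemented). Temporal averaging by 2 and baselining over the stated early
frames (1-25 for direct ligand application, 1-30 for uncaging) are options.

FLIM decays are fitted with both lifetimes fixed (1.3/2.7 ns) and only the
amplitudes free — a tail fit; instrument-response reconvolution is
deliberately omitted, a documented simplification of the vendor fitting.
The representative ciliary lifetime is the analytic mode of a
maximum-likelihood three-parameter alpha-distribution fit to voxel
lifetimes with at least 50 photon counts. The alpha family is taken as
given (it was selected upstream among many candidates; that selection is
not reproduced). The fit initializes by the method of moments on reciprocal
lifetimes — if `1/Z` is unit-variance normal with mean `a`, `Z` is standard
alpha with shape `a` — and runs a deterministic Nelder-Mead on
log-transformed parameters, so no random seed is involved. Fewer than 10
usable voxels is a refusal, and a zero-variance sample returns its common
value directly.

## Ratiometric mapping

The z flat-field vector is exactly the stated projection sequence: mean
projection through y, per-channel max normalization, averaging across
channels, a 2D Gaussian (sigma 2 px), averaging through x, and max
normalization. The estimate is meaningful only when the staining it is
computed from is dense (content-homogeneous in z at the projection scale),
as antibody staining of packed tissue is; the synthetic ratio scene
therefore carries a dense reference-stain channel with the same planted
attenuation. Marker channels are corrected; the DNA channel is not (only
antibody channels suffer penetration loss). Ratios are computed where the
DNA signal reaches the restricted-Otsu gate and summarized by the mode of a
Gaussian-kernel density estimate with Scott's-rule bandwidth evaluated on a
2048-point grid; the bandwidth is logged and overridable since the original
choice is unspecified. Percent changes are reported relative to the
reference (control) mode — the convention is fixed here because published
legends are not internally consistent about the denominator.

## Estimation statistics

Effect sizes are mean differences with a percentile bootstrap interval
(5000 within-group resamples, 95% by default; the percentile rather than
BCa interval is a documented, overridable choice). The permutation test is
two-sided on the mean difference with the +1 correction, so p is never
exactly zero — published "p = 0" values correspond to the minimum
attainable `1/(n_perm + 1)` here — and it switches to exhaustive
enumeration whenever the number of distinct group assignments is at most
`n_perm`. Two-group resampling is independent; a paired design would need
its own resampling scheme and is out of scope. Rank-sum tests are delegated
to `stats::wilcox.test()`.

## The synthetic scenes

`make_contact_scene()` emulates a stained tissue volume: two rows of
pyramidal-layer nuclei densely infilled so the layer is one connected
band after modest dilation, scattered out-of-band nuclei, tubular cilia
(lognormal arc length, median 7 um, truncated to 3-12 um), axons with
varicosities every 2 um, synaptophysin-like puncta planted on and away from
axons, a receptor channel with a planted in/out intensity split, Gaussian
PSF blur (0.1 um lateral, 0.3 um axial) and Poisson-plus-read-noise photon
statistics at a peak of 200 photons. The load-bearing construction is the
planted distance: each cilium is a planar constant-z arc and its paired
axon is the same arc translated by a pure z offset and extended along its
end tangents, so the true minimum centre-axis distance equals the planted
offset exactly, for curved paths as well as straight ones; placement is
verified against all other axons and retried within bounds so the planted
distance is always the global minimum. Default planted distances alternate
between 0.5-1.5 um (contacting) and 2.5-3.5 um (non-contacting), all at
least 0.5 um from the 2-um cutoff. One global seed feeds fixed
per-structure substreams, so identical parameters and seed reproduce scenes
bit-exactly.

What the scenes do not emulate: real point-spread functions (the PSF is a
Gaussian, not an Airyscan model), spectral bleed-through, axial refractive
aberrations, cilia that bend out of a constant-z plane, axons that branch,
or biological covariation between cilium length and contact state. Passing
tests therefore demonstrate that the measurement chain recovers known
geometry and photometry under realistic sampling and noise — not that any
biological effect size would be reproduced from real tissue, whose raw
volumes are not distributed with the package.

`make_ratiometric_scene()` plants per-nucleus marker/DNA ratios (lognormal
around 1.1 by default) and a multiplicative exponential z attenuation
(e-folding depth 8 um by default where enabled — a moderate antibody
penetration loss over a 6-um stack). `make_flim_scene()` draws ciliary
lifetimes from a chosen alpha distribution (defaults a = 3, location 1.2 ns,
scale 1.5 ns, mode ~1.62 ns, inside the physical 1.3-2.7 ns range) or from
a two-population 1.3/2.7 ns mixture, with ~20% of voxels planted below the
50-count filter to exercise it, optionally with adversarial lifetimes.
`make_traces()` synthesizes stimulus-locked traces with exponential
kinetics (tau_on 0.19 s, tau_off 8.46 s), a 0.15 peak dF/F amplitude, and
Hill titration sets at EC50 84 nM and 28 nM — the sensors' published
scales, used here as generator constants whose recovery the tests force.

## Numerical choices and problem sizes

Distance transforms use the exact separable squared-distance algorithm, so
sampled distances agree with exhaustive all-pairs scans to machine
precision. Otsu ties break toward the lowest threshold; the layer-component
tie breaks toward the lowest label; both are logged. Inclusive comparisons
at planted cutoffs carry a 1e-9 tolerance so exact-boundary cases are
stable under floating-point arithmetic. The default test and demonstration
problem sizes — contact scenes of 48 x 200 x 600 voxels at 0.2 um with 20
cilia, ratio scenes of 40 x 96 x 96 voxels at 0.15 um, lifetime samples of
10^5 draws, 500 bootstrap-coverage replicates and 2000 permutation null
simulations — were chosen as the smallest sizes at which the planted
effects are comfortably resolved, and run end to end in a few minutes on a
single CPU.

## Known limitations

Skeleton-based distances are accurate to roughly a quarter voxel after
refinement but are not sub-voxel-exact at tube junctions; FLIM fitting
ignores the instrument response and will bias quenched fractions when the
true decay is heavily convolved; flat-field estimation requires a dense
staining channel and will chase content structure if given a sparse one;
and the CLI is a thin convenience wrapper — programmatic use through the
package functions is the primary interface.
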