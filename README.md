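# ciliaxis

Quantitative mapping of axo-ciliary contacts in 3D fluorescence microscopy.

Most central neurons carry a single primary cilium. Serotonergic axons form
synapse-like contacts onto these cilia ("axo-ciliary synapses"), and
establishing them quantitatively requires a chain of image- and
signal-analysis steps: segmenting nuclei, cilia and axons in multichannel
volumes, reducing tubular structures to their central axes, encoding
distances between those axes, classifying contacts, detecting synaptic
puncta, measuring ciliary receptor enrichment, analysing fluorescent-sensor
traces and FRET/FLIM read-outs, mapping chromatin-marker-to-DNA ratios with
depth correction, and reporting effect sizes with estimation statistics.
`ciliaxis` implements that chain as a tested R package for image analysts
and neurobiologists who want each stage reproducible and verifiable against
planted ground truth.

## The quantities at the core

* **Contact classification.** Cilia and axon masks (Otsu threshold,
  morphological closing, small-object removal) are thinned to one-voxel
  central axes; the Euclidean distance transform of the axon skeleton is
  sampled along each cilium skeleton. A cilium is *axon-contacting* when its
  minimum centre-axis distance `d_min <= 2 um` (serotonergic varicosities
  are 1-3 um across); synaptophysin puncta within 1 um of an axon axis are
  axon-associated. Headline rates are reported as rounded percentages,
  e.g. `percent_of(426, 1209) = 35`.
* **Ciliary receptor fraction.** Integrated receptor intensity inside the
  1-voxel-dilated ciliary mask divided by integrated intensity over all
  voxels with >= 20 photon counts.
* **Sensor analytics.** dF/F0 = (F − F0)/F0 with a pre-stimulus baseline
  window after background subtraction; hard Fourier low-pass; Hill fits
  `resp = bottom + (top − bottom) / (1 + (EC50/c)^h)`; single-exponential
  on/off kinetics.
* **FLIM.** Two-component decays with lifetimes fixed at 1.3 ns (quenched)
  and 2.7 ns (unquenched); per-cilium representative lifetime = analytic
  mode `loc + scale (sqrt(a^2+8) − a)/4` of a maximum-likelihood
  three-parameter alpha-distribution fit to ciliary voxel lifetimes with
  >= 50 photon counts.
* **Ratiometrics.** Voxel-wise marker/DNA ratios gated by a restricted
  (90th-percentile-capped) Otsu threshold on the DNA channel, after
  dividing each z plane by a flat-field correction vector estimated from
  mean-projected, Gaussian-smoothed (sigma 2 px) stain profiles; condition
  summaries are kernel-density-estimate modes.
* **Estimation statistics.** Mean difference with a percentile bootstrap
  interval (5000 resamples, 95% by default) and a two-sided permutation
  test with the +1 correction.

A synthetic-scene generator (`make_contact_scene()`,
`make_ratiometric_scene()`, `make_flim_scene()`, `make_traces()`) plants
every one of these quantities with known truth and is the package's data
source for tests and demonstrations.

## Worked example

```r
library(ciliaxis)

sc <- make_contact_scene(scene_params(seed = 1), channels = c("cilia", "axons"))
cil <- close_and_filter(otsu_mask(sc$volume$channels$cilia), 0.3, 0.2)
axo <- close_and_filter(otsu_mask(sc$volume$channels$axons), 0.5, 0.2)
sk_c <- skeletonize_instances(cil)
sk_a <- skeletonize_instances(axo)
tab <- data.frame(id = seq_along(sk_c$instances), excluded = FALSE,
                  min_axon_distance = distance_on_skeleton(sk_c, sk_a,
                                                           refine = TRUE)$minima,
                  contacting = NA)
class(tab) <- c("cilium_table", "data.frame")
print(classify_contacts(tab))
#> cilium_table: 24 cilia (0 excluded); 10/24 contacting (42%)
```

The scene plants 20 cilia, half with centre-axis distances below the 2-um
cutoff, plus 3 cilia attached to out-of-band nuclei and 1 touching the
volume face (those four are excluded once the nuclei channel and
`filter_cilia()` enter the pipeline, giving 10/20 = 50% contacting). The
printed minimum distances match the planted ones to well under half a
micrometre.

```r
mt <- make_traces(seed = 1)
hill_fit(mt$dose_sets[[1]]$conc, mt$dose_sets[[1]]$resp)
#> dose_response: EC50 = 8.4e-08 M (84 nM), hill = 1, range [0, 0.3]

fs <- make_flim_scene(seed = 1)
flim_cilium_mode(fs$flim, fs$mask)
#> lifetime_summary: mode 1.624 ns from 259 voxel(s) (>= 50 counts)
```

The fitted EC50 (84 nM) and ciliary lifetime mode (1.624 ns against a
planted closed-form mode of 1.621 ns) are recovered from the generated
inputs, not read from them.

A command-line interface wraps the same functions:

```sh
Rscript inst/exec/ciliaxis simulate --preset contact --seed 1 --out scene/
Rscript inst/exec/ciliaxis contacts --cilia scene/cilia.tif --axon scene/axons.tif \
    --cutoff-um 2.0 --out-prefix results/contact
```

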