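---
title: "Query-based probabilistic synapse detection: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Query-based probabilistic synapse detection: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsequery)
```

## The problem

Synapses appear in multiplex immunofluorescence volumes (array tomography in
particular) as small bright puncta of antibody signal: a presynaptic marker
punctum (synapsin, VGluT1, vGAT, ...) closely apposed to a postsynaptic
marker punctum (PSD-95, gephyrin, NR1, ...). An expert finds synapses by
judging, channel by channel, whether a bright spot is real signal, whether
it is punctum-shaped, whether it persists across physical sections, and
whether a matching partner punctum sits next door in the other channels.
`synapsequery` implements that reasoning as an unsupervised probabilistic
pipeline: no training data, no classifier — the user's **query** (which
markers, how large their puncta) is the model, and the output is a per-voxel
probability map rather than a hard detection mask.

## The model, stage by stage

Let $v(x, y, z)$ be the intensity of a voxel in one channel.

**1. Foreground probability.** Stained volumes are sparse (on the order of
2% foreground), so each slice's intensity distribution essentially *is* its
background. We fit a Gaussian $(\mu_B, \sigma_B)$ per slice — all voxels
included, no masking; the sparse foreground is accepted as negligible
contamination — and score each voxel by the probability that its intensity
is not background:
$$p_F(x,y,z) = 1 - p_B(x,y,z) = \Phi\!\left(\frac{v - \mu_B}{\sigma_B}\right),$$
where $p_B$ is the upper-tail Gaussian integral from $v$. Per-slice fitting
absorbs section-to-section staining and imaging drift. By construction
$p_B + p_F = 1$, a voxel at the slice mean scores exactly $1/2$, and $p_F$
is monotone in intensity within a slice.

**2. 2D punctum probability.** Photons from a single pixel usually reflect
noise; genuine puncta light up a neighbourhood. Each voxel's foreground
probability is multiplied by that of its in-plane neighbours in a
$(2W{+}1)\times(2W{+}1)$ window:
$$p_P(x,y,z) = \prod_{i=x-W}^{x+W}\ \prod_{j=y-W}^{y+W} p_F(i,j,z).$$
$W$ comes from the query's in-plane punctum size — the *smallest* punctum
the user expects, slightly larger than the PSF — so the product demands
punctum-wide support.

**3. Slice-span attenuation.** Puncta that persist across physical sections
are more trustworthy than single-section flashes. With slice offsets
determined by the query's axial size,
$$f(x,y,z) = \exp\left(-\sum_j \left[p_P(x,y,z) - p_P(x,y,z{+}j)\right]^2\right),
\qquad p_{3DP} = p_P \cdot f.$$
A punctum holding its probability across the compared slices keeps
$f \approx 1$; a single-section flash against empty neighbours is cut by
$e^{-2} \approx 0.135$ per unit disagreement squared, per compared slice.

**4. Pre/post adjacency.** For every voxel — anchored on the postsynaptic
grid — a rectangular grid is laid over each presynaptic channel's
$p_{3DP}$, subdivided into $K \times K$ punctum-sized in-plane cells
spanning $K$ slices ($K{=}3$ presynaptically; postsynaptic markers
co-localize tightly, so $K{=}1$ voxelwise). Each cell is scored by its
geometric-mean probability and the best cell wins:
$$p_{pres} = \exp\left(\max_k \frac{1}{|G_k|}\sum_{G_k} \log p_{3DP}\right),
\qquad p_{synap} = p_{pres} \cdot p_{post}.$$
The grid is what makes the detector robust to slight channel misalignment
and to imperfect pre/post apposition. Multi-marker queries combine their
channels by elementwise product — a probabilistic AND under independence;
a synapse of the queried subtype must express every listed marker.

### Why the geometric mean in stage 4

The natural alternative readings of the grid score are a raw *sum* of
$\log p_{3DP}$ over a cell and an arithmetic *average* of $p_{3DP}$. A raw
log-sum over dozens of voxels collapses to $\sim 0$ after exponentiation and
breaks the $[0,1]$ contract that stage 4's final product relies on. The
mean-of-logs (geometric mean) keeps every intermediate a probability,
reduces to "the average value of the box" in spirit, and — being the
log-sum divided by a constant cell size — ranks subregions *identically* to
the raw sum. This is the largest single inference in the package and is
pinned by an exhaustive-enumeration oracle test.

### Probability scale at native resolution

Because stage 2 multiplies $(2W{+}1)^2$ probabilities and stage 4 takes
punctum-sized geometric means, the absolute scale of $p_{synap}$ depends
strongly on how far puncta exceed the query's minimum size. On data where
probability plateaus span whole windows (e.g. heavily upsampled volumes),
peaks approach 1 and operating thresholds of 0.55–0.7 are natural. At
native array-tomography resolution, where a typical punctum only slightly
exceeds the window, genuine synapse peaks land around 0.1–0.4 while the
background floor sits many orders of magnitude lower. The *ranking* is
unaffected, which is why thresholds here are chosen by density matching
(below) rather than fixed a priori.

## From map to detections

Voxels at or above a threshold are grouped into 26-connected components
("adjacent" read permissively — faces, edges, corners; the convention is
pinned by a test against 6-connectivity). Components below `min_voxels`
(default 2) are dropped, echoing the single-pixel-is-noise rationale.
Detections report voxel count, peak probability, and unweighted centroids
in voxels and micrometres.

The operating threshold is picked from a density-versus-threshold curve:
detection density (per µm³) falls monotonically as the threshold rises, and
the threshold whose density best matches the expected synaptic density
(about 0.9/µm³ for cortical excitatory, 0.1/µm³ for inhibitory synapses;
ties resolve to the higher threshold) is taken. The default candidate
ladder spans 0.02–0.9 in steps of 0.02, covering the native-resolution
operating range discussed above.

Evaluation against ground truth uses greedy nearest-neighbour one-to-one
matching of centroids within a tolerance (default 0.3 µm, about one punctum
diameter; the tolerance is explicit configuration, since no matching rule
is canonical). Precision and recall carry Agresti–Coull 95% intervals, with
the normal quantile computed from the requested level so other levels work
too. Greedy matching is verified against exhaustive optimal assignment on
small scenes.

## The synthetic-data generator

Real annotated volumes (EM-verified array tomography) are large, scarce,
and not shippable; the simulator provides the statistical regime the
detector assumes, with exact ground truth:

* i.i.d. Gaussian background per voxel per channel (default $\mu = 100$,
  $\sigma = 20$ in 16-bit counts), clipped at zero, fitted per slice by the
  detector exactly as on real data;
* puncta as anisotropic Gaussian blobs: in-plane sigma 0.15 µm (FWHM
  ≈ 0.35 µm — typical puncta modestly exceed the 0.2 µm *minimum* that the
  query window encodes), truncated at 3σ; Gaussian axial weights with FWHM
  equal to the slice span (default 3 sections of 70 nm);
* synapses as pre/post blob pairs, the presynaptic centroid drawn uniformly
  in an in-plane disc of radius 0.15 µm around the postsynaptic one —
  inside one grid subregion, so the adjacency search is exercised without
  perfect apposition;
* amplitude expressed as SNR × background sigma (default SNR 5);
* two distractor classes mirroring the failure modes stages 3 and 4 exist
  to suppress: *single-slice* pre/post pairs (span violation) and
  *single-channel* full-span puncta (conjunction violation);
* rejection sampling keeps planted anchors ≥ 0.6 µm apart (a realistic
  spacing at ~1 synapse/µm³ densities, and comfortably above the 0.3 µm
  matching tolerance), with a 10,000-attempt cap that fails loudly;
* integer-rounded 16-bit export, so a given spec and seed reproduce
  volumes bit-identically.

What the simulator does **not** model: optics. No PSF convolution, no shot
noise, no deconvolution ringing (the dark-ring artifact of real processed
AT data), no log-normal punctum size distribution, no spatially varying
background. Passing the end-to-end benchmark therefore shows the pipeline
recovers adjacently-paired multi-slice puncta from Gaussian clutter at
realistic sparsity — it does not certify performance on any real dataset.

**The frozen benchmark** (`default_benchmark_scene()`): 256 × 256 × 20
voxels at 100 nm / 70 nm, two channels (synapsin-like, PSD-95-like), 50
synapses at SNR 5, 25 single-channel distractors per channel, 25
single-slice pairs, seed 1337, paired with the matching excitatory query
(0.2 µm in-plane, 0.21 µm ≈ 3 sections axial, $K_{pre} = 3$,
$K_{post} = 1$). At the density-chosen threshold the detector recovers the
planted synapses with precision and recall ≥ 0.9 — the synthetic analogue
of the published human-level (~90%) accuracy — while picking up ≤ 10% of
span-violating and ≤ 5% of conjunction-violating distractors. The
mixed-population check plants excitatory and inhibitory synapses 10:1 in a
shared-presynaptic three-channel scene and recovers the ratio within
binomial sampling bounds by running both query families. These problem
sizes (≈ 918 µm³ and 516 µm³ per scene) keep a full run in seconds while
leaving every planted object statistically resolvable.

## Numerical choices and edge cases

* **Index layout.** Arrays are `[row, column, slice]` = (y, x, z), the
  native R image convention; slice $k$ is the $k$-th physical section. An
  asymmetric-ramp round-trip test pins the layout.
* **Log clamp.** Probabilities are clamped to $[10^{-12}, 1]$ before
  logarithms; the floor is far below any meaningful probability and keeps
  $\log 0$ out of the box filter.
* **Degenerate slices.** A constant slice gets $\sigma_B = 10^{-6}$ and
  hence $p_F \equiv 0.5$: a slice with no variation carries no evidence
  either way.
* **Population SD** (1/N) rather than sample SD — immaterial at ≥ 10⁴
  voxels per slice, fixed for reproducibility.
* **Borders.** Replicate (nearest) padding everywhere: in-plane for the
  punctum window, axially for the span comparison (edge slices contribute
  zero difference), and for grid cells reaching outside the volume — so
  there is no detection dead zone and no spurious border attenuation.
* **Window parity.** The punctum window is forced symmetric (odd width);
  sizes mapping to an even pixel count round up. 0.2 µm at 100 nm/px spans
  2 px and becomes a 3 × 3 window.
* **Even slice spans** put the extra comparison before the slice
  ($j_{before} \ge j_{after}$); the published queries use odd spans (1 or
  3), so this only matters for unusual axial sizes such as 0.14 µm at
  70 nm.
* **Ties in threshold choice** resolve to the higher threshold, and the
  comparison carries a $10^{-12}$ guard against floating-point asymmetry
  in the distance-to-target.
* **CDF evaluation** uses `pnorm()` (erfc-based, tail-stable); numerical
  quadrature of the defining integral appears only in tests as the oracle.

## Design choices where the method is genuinely open

* **Multi-marker combination** is an elementwise product per side
  (probabilistic AND); presynaptic markers are grid-searched each with
  their own punctum-sized cells and then combined, rather than sharing one
  joint search.
* **$K_{post} > 1$** is accepted and reuses the presynaptic grid machinery,
  for data whose postsynaptic markers co-localize loosely.
* **Grid axial extent** equals $K$ slices, one slice per cell —
  a $3\times3$ grid spanning 3 sections for the default $K_{pre} = 3$.
* **I/O** is multi-page TIFF (32-bit float for probabilities, 16-bit
  integer for intensities — both round-trip losslessly) plus a JSON channel
  manifest; channel names are case-sensitive exact keys so that, e.g.,
  VGluT1 and VGluT2 can never silently alias.
* **Detection reporting** anchors on the postsynaptic side: the reported
  position of a synapse is its postsynaptic punctum.

## Known limitations

* Operates at native acquisition resolution; no resampling to a partner
  modality's grid.
* No registration, flat-fielding, or deconvolution — inputs are assumed
  co-registered, as in published multiplexed AT datasets.
* The per-slice single-Gaussian background cannot express bimodal or
  spatially structured backgrounds; heavy foreground (≫ 5%) would bias it.
* Absolute probability values are resolution- and punctum-size-dependent
  (see above); compare maps across datasets via density-matched thresholds,
  not raw values.
* Evaluation matching is centroid-distance based with an explicit
  tolerance; it is a declared substitute for expert annotation-overlap
  protocols, not a reconstruction of one.
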