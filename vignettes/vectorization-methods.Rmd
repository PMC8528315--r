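---
title: "Methods: segmentation-free vascular vectorization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-free vascular vectorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselvec)
```

This vignette documents the model behind `vesselvec`, the choices made
where the design was genuinely open, the numerical behaviour a user
should expect, and what the synthetic studies do and do not demonstrate.

## The matched-filter model

A vessel segment of radius $R$ is modelled as the convolution of an
*ideal kernel* of radius $r$ — a unit-mass solid sphere for lumen-filling
(plasma) contrast, a unit-mass spherical shell for wall-bound
(endothelial) contrast, mixed by the spherical fraction $f_S \in [0,1]$ —
with an isotropic Gaussian of standard deviation $\sigma$, where

$$R^2 = \sigma^2 + r^2, \qquad f_G = \frac{\sigma}{\sigma + r}.$$

The Gaussian fraction $f_G$ is the main tuning knob: at $f_G \to 1$ the
filter degenerates to a pure Laplacian-of-Gaussian (robust to noise,
blind to the top-hat profile); at $f_G \to 0$ it is a bare geometric
template (sharp but brittle). The microscope point-spread function is
modelled as an anisotropic Gaussian whose per-axis standard deviations
(µm) are user configuration — the analytic dependence on numerical
aperture and wavelength is deliberately not built in, because in practice
the effective PSF of an in vivo session is better measured than derived —
and is combined with the scale Gaussian by variance addition,
$\sigma_{\mathrm{eff},a}^2 = \sigma^2 + \sigma_{\mathrm{PSF},a}^2$.

Everything is assembled analytically in the spatial-frequency domain.
The spectrum of one scale is the product of three real factors:

$$\hat K(\mathbf k) \;=\;
  -\Big(\textstyle\sum_a \sigma_{\mathrm{eff},a}^2 k_a^2\Big)\;
  \exp\!\Big(-\tfrac12 \textstyle\sum_a \sigma_{\mathrm{eff},a}^2 k_a^2\Big)\;
  \Big[f_S\,\hat S(kr) + (1-f_S)\,\hat A(kr)\Big],$$

with $\hat S(u) = 3(\sin u - u\cos u)/u^3$ and $\hat A(u) = \sin(u)/u$
the unit-mass sphere and shell transforms (both $\to 1$ as $u \to 0$).
The first factor is the variance-weighted Laplacian: weighting each
second derivative by the Gaussian variance on that axis compensates the
derivative attenuation caused by blurring, making responses comparable
across scales and across anisotropic axes. The sign convention makes
bright structure on a dark background give *negative* response
("energy"); voxels that are nowhere negative across scale are ignored.

Scale space is sampled geometrically: one octave is a doubling of matched
filter volume (radius factor $2^{1/3}$), sampled at `scales_per_octave`
points, anchored at `r_min_um` and spanning
$\lceil 3\log_2(r_{\max}/r_{\min})\rceil$ octaves. The reference
configuration (radii 1.5–60 µm at 6 per octave) yields 96 scales.

### Scale projection and the size estimate

Per voxel, the shell-matched ("annular") size estimate is the radius of
the least-energy scale, because the shell template tolerates almost no
size mismatch; the sphere-matched estimate is the energy-magnitude-
weighted mean radius over all scales with negative response; the two are
mixed by $f_S$. The reported energy is the response at the bank scale
nearest the estimate in log-radius (ties toward the smaller scale). If
the response at that looked-up scale happens to be positive the voxel's
energy is clamped to zero, so the energy field is non-positive by
construction.

Two properties of this estimator are worth knowing, both verified
against an independent continuous-domain quadrature oracle in the test
suite:

* For **spheres** the weighted-mean estimate is nearly unbiased (ratio
  ≈ 1.01 to the true radius) *provided the bank extends well past the
  object on both sides*; near the bank edges the negative-response tail
  is censored and the estimate is pulled toward the bank interior. The
  scale-recovery tests therefore probe radii in the interior of the
  bank, and users should choose `r_min`/`r_max` with margin around the
  vessel calibre of interest.
* For **tubes** the estimate runs high by a factor that converges to
  roughly 1.18–1.26 for every $f_G \in [0.5, 1)$, because an elongated
  structure keeps producing negative response at coarse scales. The
  bias propagates quadratically into volume estimates. This is
  consistent with the observation that larger Gaussian fractions
  under-estimate volume relative to mid-range ones only through their
  effect on which vectors survive classification — the size readout
  itself is structurally optimistic for tubes. We deliberately did not
  re-calibrate the estimator (e.g. by an empirical tube factor): the
  definition above is the method, and the evaluation reports the bias
  honestly. Voxel-by-voxel classification accuracy is only mildly
  affected because the over-rendered sleeve is thin relative to the
  image volume.

Relatedly, the *location* of the global energy minimum across scales
sits below the geometric radius (at $a/\sqrt3$ in the pure-Gaussian
sphere limit) — the classic behaviour of variance-normalized Laplacian
scale selection. The filter tests assert agreement with the continuous
oracle rather than with the geometric radius.

## Vertex and edge extraction

Vertex centres are strict 26-neighborhood minima of the energy field;
exact plateau ties are broken toward the lexicographically earlier voxel
so extraction is deterministic. Candidates are processed from lowest to
highest energy and accepted only if their centre is not inside the
physical ball (anisotropy-aware ellipsoid in voxel space) of an earlier
vertex — a greedy maximum-probability packing. An accepted vertex takes
its radius from the size field at its centre.

Edge tracing is a per-origin best-first exploration: pop the
lowest-energy frontier voxel, expand its unvisited 26-neighbors with
write-once back-pointers, stop at non-negative energy. Reaching another
vertex back-traces the pointer chain into a centerline. Three guards
bound the search: at most `max_edges_per_vertex` (default 4) edges per
origin; a trace-length cap of `max_trace_factor` (default 30, sensibly
20–100) times the seed radius; and a facing-plane constraint — once a
terminal is found, exploration never crosses the half-space behind it —
which prevents re-tracing the same vessel direction. Centerline
stretches shared between two traces from one origin are kept only in the
first-extracted (more probable) edge. Note the interaction between cap
and geometry: a long unbranched vessel whose interior produces no
vertices (its axis is an energy plateau, so only the ends seed) needs
`max_trace_factor` large enough for the ends to reach each other.

Cleanup is graph-theoretic: reciprocal discoveries keep the
lower-max-energy trace; "small cycles" are removed by computing the
adjacency of vertices reachable from each other in both one and two
edges (i.e. triangle co-membership), deleting the highest-max-energy
triangle edge per connected component, and iterating until no triangle
remains — each round deletes at least one edge, so termination is
guaranteed.

Strand smoothing applies, in one pass along each strand's unsmoothed arc
length, Gaussian kernels with standard deviation equal to the local
radius (truncated at three standard deviations — the truncation length
is not prescribed anywhere, three keeps >99 % of kernel mass), with
weights multiplied by $|E|$ so more probable locations dominate; the two
strand end points are returned untouched. A consequence of truncation is
that interior points within one kernel width of a strand end can slide
*along* the strand (their support is one-sided); they never leave it.

## Simulator and phantom

The phantom generator grows tortuous vessel trees by a random walk with
momentum inside a rectangular domain: tips advance in 2 µm steps with a
direction perturbation of amplitude 0.25, are steered away from walls,
branch exactly `n_branches` times (each event spawning two tips at an
0.8-tapered radius), and may close anastomotic loops between nearby
terminals with probability 0.2. Defaults emulate the superficial mouse
cortical microvasculature the method targets: radii 2–8 µm, ~30 strands
in a (128 µm)³ domain, giving a length density of ~0.9 m/mm³ and a
volume fraction of ~4 % — inside the range reported for murine cortex.
What the phantom does *not* emulate: depth-dependent attenuation and
scattering, uneven illumination, motion artifacts, diving arterioles'
systematic orientation, or the empirical radius distribution; passing
the synthetic studies therefore demonstrates correctness of the
algorithmic chain under the stated noise model, not performance on any
particular in vivo dataset.

Images are simulated by rendering the network as a binary capsule fill
at `supersample`× resolution (block-averaged back to the target grid —
detector integration), blurring with the Gaussian PSF model, mapping
occupancy linearly onto $[I_B, I_F]$, and adding a Gaussian variate per
voxel with variance equal to the noise-free intensity (the Poisson
surrogate), clamped at zero. Image quality is summarized by
$\mathrm{CNR} = (I_F - I_B)/\sqrt{I_F + I_B}$.

## Evaluation protocol and study sizes

The automated evaluation mirrors the vectorize-then-threshold protocol:
extract vertices, sweep a global vertex-energy threshold, render each
retained set and compare voxel-by-voxel with the rendered ground truth,
pass the maximal-accuracy vertex set to edge extraction, sweep the edge
maximum-energy threshold the same way, and compute bulk statistics from
the best edge set. Sweeps enumerate every distinct feature value plus
$-\infty$, accumulate the confusion table incrementally in one rendering
pass, and break accuracy ties toward the stricter threshold. The
intensity-thresholding benchmark sweeps (a ≤512-point quantile subsample
of) the distinct voxel values. Because vertex classification happens
before edge extraction, the vertex stage acts as a learned seed filter;
the ROC curves of vector features do not reach sensitivity 1 — voxels
outside every rendered vector have no support.

The shipped quality study uses a (128 µm)³ phantom at 1 µm voxels with
31 strands, CNR ∈ {1, 2, 4, 8} at $I_B = 25$, filtering at $f_G = 0.6$,
$f_S = 1$, radii 2–8 µm, 3 scales per octave, PSF std (1.5, 0.7, 0.7) µm
— sizes chosen so the full four-quality sweep completes in a few minutes
on one CPU while the phantom remains dense enough (~4 % foreground) that
accuracy is not trivially dominated by background. Peak edge-set
accuracy stays above 97–98 % at every quality and exceeds the intensity
benchmark in the poor-quality regime (CNR ≤ 2), while the benchmark wins
at high CNR — as expected, since intensity thresholding is perfect in
the noise-free limit whereas the vector route pays the tube-radius
rendering bias everywhere.

## Numerical notes

* FFT filtering is circular. `filter_multiscale()` documents this and
  the chunked driver `filter_chunked()` mirror-pads every chunk by the
  kernel support (Gaussian tails at five standard deviations) before
  transforming, so no wrap-around crosses real data; with sufficient
  overlap the chunk layout is irrelevant to ~1e-7 relative error.
* Per-scale downsampling triggers when a matched radius spans more than
  `max_voxels_per_radius` (default 10) voxels on an axis; the coarse
  pass block-averages, compensates the box pre-filter in the spectrum,
  and upsamples with Catmull-Rom interpolation, keeping the field within
  ~0.5 % of the full-resolution result at the default trigger.
* Scale-too-large errors fire when the ideal radius plus two effective
  Gaussian standard deviations exceeds half the grid extent.
* Energies at voxels with near-zero response can flip sign under 1e-7
  perturbations (e.g. a different chunk layout); the projected *size*
  at such voxels is correspondingly unstable, which is why equivalence
  checks gate on decisive energies.
* All voxel indices are 1-based `(z, y, x)` inside R and exported
  0-based in CSV; physical positions are `(index - 1) * spacing +
  origin` µm. Block-averaged grids carry the half-voxel origin shift
  explicitly.
* Determinism: phantom generation and simulation consume a seed and
  restore the caller's RNG state; vertex extraction, tracing and sweeps
  are deterministic given their inputs (ties broken lexicographically
  or toward stricter thresholds).

## Known limitations

* The tube-radius bias discussed above (~+20 % under plasma-label
  settings); derived areas/volumes inherit it.
* Vessels thinner than `r_min` or thicker than `r_max` are censored
  toward the bank, silently.
* Long unbranched vessels seed vertices only at their ends (energy
  plateaus produce no interior minima); the trace cap must span them.
* The simulator's noise is an independent Gaussian surrogate; real
  photon-counting noise is correlated by the detector and scan pattern.
* Strand smoothing is a single pass; it shortens zig-zags but does not
  re-estimate radii from the image.
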