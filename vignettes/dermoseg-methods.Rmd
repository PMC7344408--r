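---
title: "Bit-plane lesion segmentation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bit-plane lesion segmentation: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermoseg)
```

## The problem and the model

Pigmented skin lesions are darker than the surrounding skin in dermoscopic
images, and the first step of any computer-aided melanoma workup is to find
the lesion's border. `dermoseg` implements a deliberately simple, training-free
segmentation built entirely from Boolean image operations.

Each 8-bit channel value decomposes into bit planes,
$V(x,y) = \sum_{i=0}^{7} v_i(x,y)\,2^i$, and only the most significant plane
($i = 7$, equivalent to thresholding at 128) is retained per channel. Healthy
skin is bright enough that all three channels typically carry the MSB; a
pigmented lesion loses it in one or more channels. The three binary planes
are individually smoothed with a 7×7 Hanning-window kernel and re-quantized
to one bit, then summed into a four-level map:

* level 3 — MSB present in R, G and B: bright skin;
* levels 1–2 — transition tissue, lesion periphery;
* level 0 — MSB absent everywhere: lesion core, or the dark field outside
  the dermoscope's circular inspection area.

The lesion mask is the postprocessed set of pixels with level ≤ 2, and the
border is the ordered outer boundary of that mask. Per-level RGB histograms
are computed for presentation to the clinician, and predicted masks can be
scored against expert ground truth by pixel accuracy,
$\mathrm{Acc} = (TP + TN)/(TP + FP + TN + FN)$.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `bit_index` | 7 | bit position | The MSB carries the skin/lesion contrast; lower planes are exposed only as an exploratory hook and are not part of the validated pipeline. |
| kernel size | 7 | pixels | A 7×7 Hann window; its zero endpoints make the effective support 5×5. |
| `quantize_threshold` | 0.5 | fraction of unit DC gain | Majority vote on a unit-sum kernel; ties map to 1. |
| `lesion_level_max` | 2 | level | A pixel lacking the MSB in *any* channel is a lesion candidate; can be tightened to ≤ 1 or = 0 for darker cores only. |
| postprocessing flags | all on | — | Corner-component exclusion, largest-component selection, hole filling (see below). |

## Numerical and design choices

**Hann window form.** The kernel is the separable outer product of the 1D
raised cosine $w[n] = 0.5\,(1-\cos(2\pi n/6))$, $n = 0..6$, normalized to
unit sum; its center weight is exactly 1/9. A rotationally symmetric window
would be an alternative reading of "Hanning shaped"; the separable form was
chosen as the standard construction of 2D window filters.

**Quantization threshold.** 0.5 of the unit-DC filtered value is the natural
majority rule; ties (exactly 0.5) map to 1. With this kernel a single
isolated pixel contributes at most the center weight 1/9 < 0.5, so isolated
spurious pixels of either polarity are always removed, while pixels at
Chebyshev distance ≥ 3 inside a solid block are always kept.

**Border handling.** Convolution uses edge-inclusive reflect (mirror)
padding. Zero padding would darken the frame of an all-bright image and
manufacture spurious level drops along the borders; reflection is neutral
for locally uniform regions (an all-ones plane maps to all ones).

**Filtering happens once, per channel plane, before summation.** Smoothing
the 4-level sum instead would mix levels across the skin/lesion boundary;
smoothing binary planes keeps every stage Boolean.

**Which levels are "lesion".** The four levels by themselves do not say
which side is lesion. Because dermoscopic lesions are darker than skin,
level 3 is taken as skin and levels ≤ 2 as lesion candidates. The dark
corners outside the dermoscope's circular field are also low-level; they are
separated from the lesion by discarding 8-connected candidate components
that touch any image corner, then keeping the largest surviving component
and filling its interior holes. Each step can be switched off independently.

**Connectivity and contours.** Foreground uses 8-connectivity, the
background complement 4-connectivity (the standard duality, so hole filling
is well defined). The border is traced by walking the crack boundary — the
polyline of pixel edges separating mask from background — and collecting the
adjacent mask pixels. This guarantees that the contour is a closed
8-connected cycle visiting exactly the mask pixels that have a background
4-neighbor. The path starts at the topmost-then-leftmost border pixel and
runs counterclockwise as displayed; diagonal saddles are crossed so that an
8-connected region yields a single closed path. Coordinates are 1-based
`(row, col)` with row 1 at the top, matching R's matrix indexing.

**Degenerate inputs.** A uniformly bright image yields an all-3 level map
and an empty mask; a uniformly dark image yields an all-0 map whose single
component touches the corners and is excluded, also giving an empty mask.
Empty masks produce empty contours and are a warning, not an error, in the
CLI.

**Histograms: levels or regions?** "Each segmented region" can mean the four
level classes or spatially distinct components. Histograms are computed over
the level classes by default, and `region_color_histograms()` accepts any
integer labelling (a lesion mask, component labels) for the per-region
variant, so both readings are available.

**Dataset averaging.** The dataset-level score is the unweighted mean of
per-image accuracies, the common convention for segmentation benchmarks;
pooling pixels would let large images dominate. Dice, Jaccard, sensitivity
and specificity are reported alongside as standard companions.

## The synthetic fixture generator

Real dermoscopy benchmarks (such as PH2, 200 expert-annotated images) are
external downloads, so the package ships a generator that produces paired
image/ground-truth fixtures with the statistical structure the algorithm
exploits:

* a star-shaped lesion with boundary
  $r(\theta) = r_0\,(1 + a \sum_{k=1}^{K} c_k \cos(k\theta + \varphi_k))$,
  $c_k \sim U(-1,1)/k$, $\varphi_k \sim U(0, 2\pi)$ — irregular but never
  self-intersecting for $a < 1/\sum 1/k$;
* a smoothstep blend between lesion core color (90, 60, 50) and skin color
  (200, 160, 140) over a 4 px transition band. These defaults put skin above
  128 and lesion core below 128 in all channels — the contrast regime in
  which MSB slicing is meaningful — and are fixture choices, not measured
  dermatological values;
* additive Gaussian noise (sd 10) applied after blending and clipped, never
  wrapped, so noise cannot flip an MSB by wrap-around; dark 1 px hair
  strokes (3 by default) exercising the spurious-structure suppression of
  the 7×7 filter; an optional corner vignette emulating the dermoscope
  field edge (off by default);
* truth mask = pixels strictly inside the analytic boundary, so ground truth
  is exact by construction; everything is driven by a single seed and is
  bit-reproducible.

Default geometry: 256×256 px, base radius 60 px, $K = 5$ harmonics,
amplitude scale 0.15. The standard test suite is 20 such fixtures with
per-image randomized center (±10 px), radius (0.8–1.1×), irregularity
(0.08–0.18) and harmonic count (3–6).

What the generator does **not** emulate: pigment networks, globules,
blue-white veils, specular reflections, air bubbles, multi-lesion fields,
low-contrast lesions whose core straddles 128. Passing the synthetic
recovery tests therefore shows that the implementation is faithful to the
algorithm and that the algorithm works in its intended contrast regime; it
does not certify performance on real clinical images, which depends on how
often that regime holds.

## Problem sizes used in tests

Unit oracles run on 8–64 px rasters (nested-loop brute-force convolution,
histogram and confusion tallies, flood-fill component labelling); the
end-to-end recovery check uses the default 20-image 256×256 suite, which
segments in a few seconds. On the default suite the pipeline recovers the
generator's truth with mean pixel accuracy ≈ 0.993, and ≈ 0.994 on a
noiseless, artifact-free fixture — the residual error is the ~1 px outward
bias where the blue channel (the first to drop below 128) crosses the
transition band, times the perimeter.

## Known limitations

* The method presumes the MSB contrast regime; lesions on dark skin, or
  overexposed/underexposed images, violate it and will segment poorly. No
  enhancement step compensates, by design.
* Exactly one lesion is reported (largest component); multi-lesion images
  yield only the dominant one.
* The contour is pixel-resolution; no sub-pixel smoothing is attempted.
* Hair wider than ~1 px survives the 7×7 majority filter and, when it
  crosses the lesion, locally perturbs the border.
* Images whose lesion touches an image corner lose it to the
  corner-exclusion rule unless that flag is disabled.

## A worked example

```{r example, eval = FALSE}
fx <- generate_fixture(synthetic_spec(seed = 0L))
seg <- segment_lesion(fx$image)
glance(seg)
accuracy(confusion_counts(seg$mask, fx$truth))

ev <- evaluate_dataset(generate_suite(20, synthetic_spec(), master_seed = 0L))
glance(ev)
autoplot(seg)
```
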