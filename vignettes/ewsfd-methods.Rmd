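---
title: "Entropy-weighted spectral fractal dimension: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-weighted spectral fractal dimension: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewsfd)
```

## The measurement problem

Ultraweak photon emission from living tissue is recorded as a
time-lapse stack of long-integration frames (one minute per frame is
typical) from a cooled, single-photon-sensitive sensor in complete
darkness. The counts are tiny — a 16-bit container often holds only 6
or 8 bits of actual data — and the biological signal differs from the
dark signal less in mean intensity than in *how the values are
organised*. This package therefore measures the value distribution of
each region of interest (ROI) per frame with four quantities: Shannon
entropy, two spectral box-counting fractal dimensions, and an
entropy-weighted combination of the two ideas.

## Spectral boxes and the metrics

A frame of `n` bands at analysis depth `S` maps each pixel to an
n-tuple in `[0, 2^S)^n` — a point in *spectral space*. Cutting every
axis into `2^j` equal cells tiles spectral space with `(2^j)^n`
spectral boxes at level `j`; quantization to level `j` keeps the top
`j` bits of each value (`v %/% 2^(S-j)`), which halves the box edge per
level — the standard box-counting refinement, and the reason occupied
counts `SBM_j` are non-decreasing in `j`.

For levels `j = 1 .. S-1`:

* `SFD_ESR = n Σ_j log(SBM_j) / log((2^S)^n) / (S-1)` — the averaging
  form with a constant full-depth denominator. It is kept exactly as
  published because it is in practical use as an image metric.
* `SFD_DSR = n Σ_j log(SBM_j) / log((2^j)^n) / (S-1)` — the measurable
  box-counting form whose denominator shrinks with the box grid. This
  is the genuinely dimension-like variant: it is 1 (per band) when
  every box is occupied at every level and 0 for a constant frame.
* `f_j = H_j / (j n)` with `H_j` the Shannon entropy of the level-`j`
  joint histogram; `EW-SFD` replaces `SBM_j` by `f_j · SBM_j` in the
  DSR ratio.

Two points in the published formulation were genuinely open and are
resolved here as follows:

1. **The possible-box total "for bit j".** The printed total is the
   constant `(2^S)^n` at every level, yet it is *named* per level, and
   a box-counting dimension needs the grid to refine with the level.
   Both readings are implemented: the constant total is the ESR
   variant, the level-dependent `(2^j)^n` is the DSR variant, and
   `possible_boxes(mode =)` exposes each. EW-SFD uses the DSR total.
2. **Which histogram feeds `f_j`.** The weighting entropy is
   normalized by the *maximum entropy for j-bit pixels*, `j` bits
   (generalized to `j·n` for n bands). That maximum belongs to the
   distribution of level-`j` symbols over the whole sample, so `H_j`
   is computed from one histogram of all ROI pixels per level, not per
   individual box — a per-box entropy would not have `j` as its bound.

Other numerical conventions: `p log2(1/p) → 0` as `p → 0`; base-2 logs
for entropies, natural logs for the (base-invariant) box-count ratios;
when `f_j · SBM_j < 1` the EW term is floored to 0 rather than letting
a structureless level contribute a negative or infinite value — the
number of floored levels is reported in every result so the rule is
auditable. Every pixel inside the (corrected) ROI counts, including
zeros; excluding zeros would leave the background ROI's own metrics
undefined on quiet frames, so zero-exclusion exists only as an
explicit option.

## Pipeline

The analysis path is: optional per-pixel dark correction (subtract the
temporal mean of a dark stack, clamp at 0 — counts are non-negative,
so clamping beats recentering), ROI extraction (0-based half-open
windows, 21 × 21 default — the sampling-area size used for embryo
work), pixel-by-pixel background correction (positional pairing within
same-size, disjoint windows; a scalar per-frame-mean mode is available
but off by default), optional integration-time rebinning (groups of
`k` frames summed exactly, trailing partial group dropped so all
output frames integrate equally), then the four metrics per frame.

The analysis depth defaults to the *effective data depth* of the
corrected ROI sub-stack — the smallest `S` with all values below
`2^S` — because low-light data fill far less than their container and
the level sum should not average over structurally empty levels; a
fixed `S` can be forced. The background ROI is its own reference and
is only dark-corrected. The frame interval (default 60 s) is metadata
only.

## What the generator emulates — and what it does not

`generate_stack()` draws every pixel as
`Poisson(dark + profile(t) · source + texture)`: Poisson shot noise
with an additive dark rate is the minimal model for a photon-counting
sensor with amplification disabled. Defaults, chosen once as a
realistic desk-scale stand-in for an embryo recording and not
revisited: 60 one-minute frames of 64 × 64 pixels (a cropped field
around one specimen), dark rate 3 counts/frame/pixel (a few spurious
counts per minute), one Gaussian-footprint source of peak 12
counts/frame/pixel with 6-pixel radius sitting inside a 21 × 21
window — a weak but resolvable emitter, a handful of counts above
dark. The `degenerate` profile holds the source until the changepoint
`t* = T/2` and then decays with a 3-frame e-folding time, emulating an
embryo whose emission collapses to the noise floor; `live` sustains
it. Per-frame child seeds are derived from the root seed by counter,
so the stack is bit-exact regardless of generation order.

Not modelled: optics (no point-spread function), read noise, gain or
pixel-to-pixel sensitivity variation, cosmic events, drift, or any
biology beyond a smooth rate profile. Passing tests on these stacks
shows the *algorithmic* chain is correct and that the metrics separate
structured emission from shot noise under known conditions; it does
not certify separation on real recordings, whose noise is richer.

`generate_structured_frame(S, q)` is different in kind: its pixel
values cycle through `0 .. ⌈q·2^S⌉ − 1`, so by the nested-ceiling
identity the level-`j` occupied count is exactly `⌈q·2^j⌉`, giving a
closed-form SFD_DSR surface that the box-counting code must hit to
floating-point accuracy — an analytic oracle, not a realism claim.

## Verification strategy and problem sizes

The test suite checks the metrics against an independent brute-force
enumerator that materializes every spectral box and scans every pixel:
exhaustively on all 256 single-band 2 × 2 frames at `S = 2`, and on
1,000 seeded random 8 × 8 frames at `S = 4`. Property tests cover the
entropy bounds and extremes (10,000 random frames), the
`EW-SFD ≤ SFD_DSR ≤ n` ordering (10,000 frames), permutation
invariance, box-count monotonicity, level nesting across depths,
lossless TIFF round trips, rebinning composition, and changepoint
detectability. The discrimination property — live vs degenerate
post-changepoint EW-SFD, and embryo vs background entropy — is run on
100 seeded replicate pairs at the generator defaults. These sizes keep
the whole suite near a minute on one core while the exhaustive and
10,000-draw sweeps leave no realistic room for coincidental passes.

## Known limitations

* ESR and DSR values are only comparable at a common analysis depth;
  the auto-depth default trades that comparability for per-ROI
  sensitivity, which is why the chosen `S` is part of every output row.
* The EW floor rule makes EW-SFD non-smooth where `f_j · SBM_j`
  crosses 1; curves from near-constant regions can sit exactly at 0.
* Multi-band file I/O is limited to 4 bands (TIFF channel model);
  in-memory metrics accept any `n`.
* The package produces metric curves, not a viability decision rule;
  thresholding or classification on the curves is out of scope.
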