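# ewsfd

Entropy-weighted spectral fractal dimension analysis of ultraweak
photon emission (UPE) time-lapse recordings.

Living cells emit spontaneous, extremely faint photon fluxes tied to
their metabolism. Recorded with a cooled single-photon-sensitive CMOS
sensor in complete darkness — one frame per minute of integration over
hours — these emissions are barely above the sensor's dark signal, and
plain intensity statistics separate the biological signal from noise
poorly. This package quantifies the *structure* of the emission
instead: the information content and self-similar (fractal)
organisation of the pixel-value distribution, which differ between
living embryos, degenerated embryos, fresh and frozen specimens, and
empty background. It is aimed at researchers analysing low-light image
stacks of embryos or similar weakly emitting samples.

## The metrics

All metrics act on the *spectral* (pixel-value) space of a frame, not
the image plane. For an `n`-band frame at analysis depth `S` bits,
dividing each value axis into `2^j` cells partitions spectral space
into `(2^j)^n` *spectral boxes* at resolution level `j`; `SBM_j` is the
number of boxes containing at least one pixel.

- **Shannon entropy** `H = Σ_i p_i log2(1/p_i)` over the occupied value
  symbols, with `0 ≤ H ≤ S·n` bits.
- **SFD_ESR** (equal spectral resolution):
  `n · Σ_{j=1}^{S−1} log(SBM_j) / log((2^S)^n) / (S−1)` — the
  constant-denominator averaging form.
- **SFD_DSR** (different spectral resolution):
  `n · Σ_{j=1}^{S−1} log(SBM_j) / log((2^j)^n) / (S−1)` — the
  measurable box-counting form, in `[0, n]`.
- **EW-SFD**: each level's occupied-box count is weighted by the
  normalized level entropy `f_j = H_j / (j·n) ∈ [0,1]` before the DSR
  ratio: `term_j = log(f_j · SBM_j) / log((2^j)^n)` (0 when
  `f_j · SBM_j < 1`). It couples structure and information content and
  satisfies `0 ≤ EW-SFD ≤ SFD_DSR ≤ n`.

Around the metrics sits a full analysis pipeline: lossless multi-page
TIFF stack I/O (`.btf` batch-lossless recordings are a multi-page TIFF
dialect), rectangular ROI extraction (21 × 21 pixel default windows),
per-pixel dark-frame and background-ROI correction with clamping at
zero, integration-time rebinning, effective data-depth estimation, and
per-frame metric time series. A seeded Poisson generator produces
synthetic background / live / degenerating scenarios so the whole chain
is testable without raw recordings.

## Worked example

```r
library(ewsfd)

stk <- generate_stack(scenario_config("live", seed = 42))
stk
#> FrameStack: 60 frame(s) of 64 x 64, 1 band(s), 16-bit container, 60 s/frame

emb <- roi(8, 8,  role = "embryo",     name = "embryo")
bg  <- roi(8, 36, role = "background", name = "background")
ser <- metric_time_series(stk, list(emb, bg),
                          corrections = correction_spec(background_roi = bg))
tab <- bind_series(ser)
head(tab[tab$roi == "embryo", ], 3)
#>   time_s    roi entropy_bits sfd_esr sfd_dsr ew_sfd S n floored_levels
#> 1      0 embryo        3.829  0.4315  0.8797 0.4104 5 1              1
#> 2     60 embryo        3.772  0.4315  0.8797 0.4045 5 1              1
#> 3    120 embryo        3.854  0.4522  0.9316 0.4716 5 1              1

aggregate(cbind(entropy_bits, sfd_dsr, ew_sfd) ~ roi, tab, mean)
#>          roi entropy_bits sfd_dsr ew_sfd
#> 1 background         2.77   0.870  0.295
#> 2     embryo         3.84   0.876  0.409
```

Each row is one ROI in one one-minute frame. The embryo window (after
pixel-by-pixel background subtraction) carries about one bit more
entropy and a clearly higher EW-SFD than the pure-noise background
window: the emission adds informative spectral structure that the
entropy weighting amplifies, while the unweighted SFD_DSR of Poisson
noise is already high and barely separates the two. `S = 5` is the
effective data depth chosen automatically — the corrected counts only
fill 5 bits of the 16-bit container.

The same analysis runs from a shell:

```sh
Rscript inst/cli/ewsfd.R synth --scenario live --seed 42 --out stack.tif
Rscript inst/cli/ewsfd.R run --stack stack.tif --rois rois.yaml --out series.csv
Rscript inst/cli/ewsfd.R depth --stack stack.tif
Rscript inst/cli/ewsfd.R selfcheck
```

(after installation the launcher is at
`system.file("cli", "ewsfd.R", package = "ewsfd")`).

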