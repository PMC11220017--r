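#' Synthetic photon-emission scenario
#'
#' Describes a seeded synthetic time-lapse stack: Poisson photon counts
#' with an additive dark rate (the minimal model for a single-photon
#' sensitive sensor), optional localized emission sources with a
#' Gaussian footprint, a temporal profile, and an optional static
#' multiscale texture that tunes spectral occupancy.
#'
#' Defaults model a desk-scale recording: 60 one-minute frames of
#' 64 x 64 pixels in a 16-bit container, a dark rate of 3
#' counts/frame/pixel, and (for the embryo scenarios) one source of
#' peak rate 12 counts/frame/pixel with a 6-pixel Gaussian radius
#' centred at (18, 18), i.e. inside a 21 x 21 window at offset (8, 8).
#'
#' @param scenario preset: `"background"` (dark only), `"live"`
#'   (sustained emission) or `"degenerate"` (emission decays to the
#'   noise floor after frame `t_star`).
#' @param seed root seed; fixes the stack bit-exactly. Per-frame child
#'   seeds are derived from it by counter, so generation order cannot
#'   change the result.
#' @param shape `c(T, H, W)`.
#' @param container_bits container depth (default 16).
#' @param dark_mean dark rate, counts/frame/pixel.
#' @param sources list of `list(row, col, radius)` (1-based centres);
#'   default one centred source for the embryo scenarios, none for
#'   background.
#' @param source_rate peak source rate, counts/frame/pixel.
#' @param t_star changepoint frame for `"degenerate"` (default `T/2`).
#' @param decay_frames e-folding time of the post-changepoint decay.
#' @param texture `"none"` or `"multiscale"` (static octave-mixed field
#'   added to the rate).
#' @param texture_amplitude peak amplitude of the texture field.
#' @param frame_interval seconds per frame (default 60).
#' @return a list of class `ScenarioConfig`.
#' @export
scenario_config <- function(scenario = c("background", "live", "degenerate"),
                            seed = 1L,
                            shape = c(60L, 64L, 64L),
                            container_bits = 16L,
                            dark_mean = 3,
                            sources = NULL,
                            source_rate = 12,
                            t_star = NULL,
                            decay_frames = 3,
                            texture = c("none", "multiscale"),
                            texture_amplitude = 4,
                            frame_interval = 60) {
  scenario <- match.arg(scenario)
  texture <- match.arg(texture)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L))
    stop("shape must be c(T, H, W) with all dimensions >= 1", call. = FALSE)
  if (dark_mean < 0 || source_rate < 0 || texture_amplitude < 0)
    stop("all rates must be >= 0", call. = FALSE)
  if (is.null(sources)) {
    sources <- if (scenario == "background") list()
               else list(list(row = 18, col = 18, radius = 6))
  }
  if (is.null(t_star)) t_star <- shape[1] %/% 2L
  if (scenario == "degenerate" && t_star >= shape[1])
    stop("changepoint t_star must be < T", call. = FALSE)
  structure(list(scenario = scenario, seed = as.integer(seed), shape = shape,
                 container_bits = as.integer(container_bits),
                 dark_mean = dark_mean, sources = sources,
                 source_rate = source_rate, t_star = as.integer(t_star),
                 decay_frames = decay_frames, texture = texture,
                 texture_amplitude = texture_amplitude,
                 frame_interval = frame_interval),
            class = "ScenarioConfig")
}

# child seed for frame t (counter-derived, < 2^31)
child_seed <- function(seed, t) {
  as.integer((as.numeric(seed) * 7919 + t * 104729) %% 2147483647)
}

# Gaussian-footprint source rate map, H x W
source_rate_map <- function(cfg) {
  H <- cfg$shape[2]; W <- cfg$shape[3]
  m <- matrix(0, H, W)
  for (s in cfg$sources) {
    r2 <- outer((seq_len(H) - s$row)^2, (seq_len(W) - s$col)^2, "+")
    m <- m + cfg$source_rate * exp(-r2 / (2 * s$radius^2))
  }
  m
}

# static octave-mixed texture field, H x W, in [0, amplitude]
texture_field <- function(cfg) {
  H <- cfg$shape[2]; W <- cfg$shape[3]
  set.seed(child_seed(cfg$seed, 0L))
  field <- matrix(0, H, W)
  octave <- 1L
  while (2^octave <= min(H, W)) {
    hc <- max(1L, H %/% 2^octave); wc <- max(1L, W %/% 2^octave)
    coarse <- matrix(stats::runif(hc * wc), hc, wc)
    up <- kronecker(coarse, matrix(1, ceiling(H / hc), ceiling(W / wc)))
    field <- field + up[seq_len(H), seq_len(W)] / 2^(octave - 1L)
    octave <- octave + 1L
  }
  cfg$texture_amplitude * field / max(field)
}

temporal_factor <- function(cfg, t) {
  switch(cfg$scenario,
         background = 1,
         live = 1,
         degenerate = if (t <= cfg$t_star) 1
                      else exp(-(t - cfg$t_star) / cfg$decay_frames))
}

#' Generate a synthetic photon-emission stack
#'
#' Each pixel of frame `t` is drawn as
#' `Poisson(dark_mean + profile(t) * source(p) + texture(p))`, clipped
#' to the container range. Deterministic given `cfg$seed`.
#'
#' @param cfg a [scenario_config()].
#' @return a `FrameStack`; if systematic clipping touched more than 1\%
#'   of pixels the attribute `clip_warning` is set on the result.
#' @export
generate_stack <- function(cfg) {
  stopifnot(inherits(cfg, "ScenarioConfig"))
  d <- cfg$shape
  src <- source_rate_map(cfg)
  tex <- if (cfg$texture == "multiscale") texture_field(cfg) else 0
  vmax <- 2^cfg$container_bits - 1
  out <- array(0L, dim = d)
  clipped <- 0
  for (t in seq_len(d[1])) {
    set.seed(child_seed(cfg$seed, t))
    lambda <- cfg$dark_mean + temporal_factor(cfg, t) * src + tex
    vals <- stats::rpois(d[2] * d[3], as.vector(lambda))
    clipped <- clipped + sum(vals > vmax)
    out[t, , ] <- matrix(pmin(vals, vmax), d[2], d[3])
  }
  fs <- frame_stack(out, container_bits = cfg$container_bits,
                    frame_interval = cfg$frame_interval)
  frac <- clipped / prod(d)
  if (frac > 0.01) {
    warning(sprintf("%.1f%% of pixels clipped at container maximum", 100 * frac))
    attr(fs, "clip_warning") <- frac
  }
  fs
}

#' Frame with analytically known spectral occupancy
#'
#' Builds a single-band frame whose occupied-box count at every level
#' `j` equals `ceiling(q * 2^j)` by construction: the pixel values
#' cycle through `0 .. ceiling(q * 2^S) - 1`, so the level-`j`
#' quantization occupies exactly the first `ceiling(q * 2^j)` boxes
#' (nested-ceiling identity). This gives the closed form
#' `SFD_DSR = sum_j log(ceiling(q * 2^j)) / log(2^j) / (S - 1)`
#' as an exact analytic surface for the box-counting code.
#'
#' @param S analysis depth, `>= 2`.
#' @param q occupancy fraction per level, `0 < q <= 1`.
#' @param shape `c(H, W)`; default the smallest square holding
#'   `2^S` pixels.
#' @return an `H x W` integer matrix with values `< 2^S`.
#' @export
generate_structured_frame <- function(S, q, shape = NULL) {
  if (S < 2L) stop("S must be >= 2", call. = FALSE)
  if (q <= 0 || q > 1) stop("occupancy q must be in (0, 1]", call. = FALSE)
  M <- ceiling(q * 2^S)
  if (is.null(shape)) {
    side <- 2^ceiling(S / 2)
    shape <- c(side, side)
  }
  npix <- prod(shape)
  if (npix < M)
    stop(sprintf("pixel budget %d cannot realize %d occupied boxes", npix, M),
         call. = FALSE)
  matrix(rep(seq_len(M) - 1L, length.out = npix), shape[1], shape[2])
}

#' Closed-form SFD_DSR of a structured frame
#'
#' @inheritParams generate_structured_frame
#' @export
structured_sfd_dsr <- function(S, q) {
  js <- 1:(S - 1L)
  sum(log(ceiling(q * 2^js)) / log(2^js)) / (S - 1)
}
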