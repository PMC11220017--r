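#' @title Spectral structure metrics
#' @description
#' The metrics in this file act on the *spectral* (pixel-value) space of
#' a frame, not on the image plane. A frame of `n` bands at analysis
#' depth `S` assigns each pixel an n-tuple of values in `[0, 2^S)`;
#' dividing each value axis into `2^j` equal cells partitions spectral
#' space into `(2^j)^n` spectral boxes at resolution level `j`. The
#' occupied-box counts `SBM_j` across levels `j = 1..S-1` carry the
#' box-counting (fractal) structure of the value distribution, and the
#' per-level Shannon entropies weight that structure by information
#' content.
#' @name spectral-metrics
NULL

# frame as an npix x n matrix of band values
as_band_matrix <- function(frame) {
  d <- dim(frame)
  if (is.null(d)) return(matrix(frame, ncol = 1L))
  if (length(d) == 2L) return(matrix(frame, ncol = 1L))
  if (length(d) == 3L) return(matrix(frame, nrow = d[1] * d[2], ncol = d[3]))
  stop("frame must be H x W or H x W x n", call. = FALSE)
}

check_frame_depth <- function(vals, S) {
  if (S < 1L || S > 53L) stop("analysis depth S out of range", call. = FALSE)
  if (any(vals < 0) || any(vals != floor(vals)))
    stop("frame values must be non-negative integers", call. = FALSE)
  if (max(vals) >= 2^S)
    stop(sprintf("frame values exceed %d-bit analysis depth", S), call. = FALSE)
  invisible(TRUE)
}

#' Quantize a frame to a coarser spectral level
#'
#' Keeps the top `j` bits of each `S`-bit band value:
#' `v -> floor(v / 2^(S - j))`. This halves the spectral box edge per
#' level, the standard box-counting refinement.
#'
#' @param frame `H x W` matrix or `H x W x n` array of values `< 2^S`.
#' @param S analysis bit depth.
#' @param j target level, `1 <= j <= S`.
#' @return the frame with values `< 2^j`, same shape.
#' @export
quantize_to_level <- function(frame, S, j) {
  if (j < 1L || j > S) stop("level j must satisfy 1 <= j <= S", call. = FALSE)
  check_frame_depth(frame, S)
  frame %/% 2^(S - j)
}

# joint level-j histogram over all pixels: counts per occupied n-tuple
level_counts <- function(bands, S, j, exclude_zero = FALSE) {
  if (exclude_zero) {
    keep <- rowSums(bands) > 0
    bands <- bands[keep, , drop = FALSE]
  }
  if (nrow(bands) == 0L)
    stop("no pixels left to histogram", call. = FALSE)
  q <- bands %/% 2^(S - j)
  n <- ncol(q)
  key <- q[, 1]
  if (n > 1L) for (b in 2:n) key <- key * 2^j + q[, b]
  as.vector(table(key))
}

#' Joint spectral histogram of a frame at level j
#'
#' Counts the pixels falling in each occupied spectral box after
#' quantization to level `j`; for multi-band frames the symbol is the
#' joint n-tuple of quantized band values.
#'
#' @inheritParams quantize_to_level
#' @param exclude_zero drop pixels whose band values are all zero before
#'   histogramming (off by default: every corrected pixel counts).
#' @return an object of class `SpectralHistogram`: `level_bits`,
#'   `counts` (occupied boxes only), `total_pixels`, `n`.
#' @export
spectral_histogram <- function(frame, S, j, exclude_zero = FALSE) {
  if (j < 1L || j > S) stop("level j must satisfy 1 <= j <= S", call. = FALSE)
  bands <- as_band_matrix(frame)
  check_frame_depth(bands, S)
  counts <- level_counts(bands, S, j, exclude_zero)
  structure(list(level_bits = as.integer(j), counts = counts,
                 total_pixels = sum(counts), n = ncol(bands)),
            class = "SpectralHistogram")
}

#' Shannon entropy of a histogram, in bits
#'
#' `H = sum_i p_i * log2(1 / p_i)` over the occupied symbols, with
#' `p_i` the relative frequency; zero-count symbols contribute nothing
#' (`p * log2(1/p) -> 0` as `p -> 0`). For a level-`j` histogram of an
#' `n`-band frame, `0 <= H <= j * n`: zero iff a single symbol occurs,
#' maximal iff all `(2^j)^n` boxes are equally frequent.
#'
#' @param hist a `SpectralHistogram`, or a bare vector of non-negative
#'   counts.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(hist) {
  counts <- if (inherits(hist, "SpectralHistogram")) hist$counts else hist
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("empty histogram", call. = FALSE)
  total <- sum(counts)
  p <- counts / total
  -sum(p * log2(p))
}

#' Number of occupied spectral boxes at level j
#'
#' `SBM_j`: the count of distinct quantized n-tuples, i.e. spectral
#' boxes containing at least one pixel. Always in `[1, (2^j)^n]`, and
#' non-decreasing in `j` (refining the grid never merges boxes).
#'
#' @inheritParams spectral_histogram
#' @export
count_spectral_boxes <- function(frame, S, j, exclude_zero = FALSE) {
  length(spectral_histogram(frame, S, j, exclude_zero)$counts)
}

#' Total possible spectral boxes at level j
#'
#' Two conventions are in use. `"esr"` (equal spectral resolution) uses
#' the constant full-depth grid `(2^S)^n` at every level; `"dsr"`
#' (different spectral resolution) uses the level-`j` grid `(2^j)^n`,
#' which varies with the box size as box-counting dimensions require.
#'
#' @param S analysis bit depth.
#' @param n band count.
#' @param j level (only used in `"dsr"` mode).
#' @param mode `"esr"` or `"dsr"`.
#' @export
possible_boxes <- function(S, n = 1L, j = NULL, mode = c("dsr", "esr")) {
  mode <- match.arg(mode)
  if (S < 1L || n < 1L) stop("invalid S or n", call. = FALSE)
  if (mode == "esr") return((2^S)^n)
  if (is.null(j) || j < 1L || j > S) stop("dsr mode needs 1 <= j <= S", call. = FALSE)
  (2^j)^n
}

n_levels_check <- function(S) {
  if (S < 2L) stop("analysis depth S must be >= 2", call. = FALSE)
  1:(S - 1L)
}

#' Spectral fractal dimension, equal-spectral-resolution form
#'
#' `SFD_ESR = n * sum_{j=1}^{S-1} log(SBM_j) / log((2^S)^n) / (S - 1)`.
#' The denominator is the constant full-depth box total; the log-ratio
#' is base-invariant. Zero for a constant frame.
#'
#' @inheritParams spectral_histogram
#' @param S analysis bit depth, `>= 2`.
#' @export
sfd_esr <- function(frame, S, exclude_zero = FALSE) {
  js <- n_levels_check(S)
  bands <- as_band_matrix(frame)
  check_frame_depth(bands, S)
  n <- ncol(bands)
  sbm <- vapply(js, function(j) length(level_counts(bands, S, j, exclude_zero)),
                numeric(1))
  n * sum(log(sbm) / log((2^S)^n)) / (S - 1)
}

#' Spectral fractal dimension, different-spectral-resolution form
#'
#' `SFD_DSR = n * sum_{j=1}^{S-1} log(SBM_j) / log((2^j)^n) / (S - 1)`,
#' the measurable box-counting form in which the possible-box total
#' shrinks with the level. Ranges over `[0, n]`: 0 for a constant
#' frame, exactly `n` when every box is occupied at every level.
#'
#' @inheritParams sfd_esr
#' @export
sfd_dsr <- function(frame, S, exclude_zero = FALSE) {
  js <- n_levels_check(S)
  bands <- as_band_matrix(frame)
  check_frame_depth(bands, S)
  n <- ncol(bands)
  sbm <- vapply(js, function(j) length(level_counts(bands, S, j, exclude_zero)),
                numeric(1))
  n * sum(log(sbm) / log((2^js)^n)) / (S - 1)
}

#' Entropy weighting factor f_j
#'
#' `f_j = H_j / (j * n)`, clipped to `[0, 1]`, where `H_j` is the
#' Shannon entropy of the level-`j` joint histogram over all pixels and
#' `j * n` bits is its maximum. Zero for a constant frame, one when the
#' level-`j` boxes are uniformly occupied.
#'
#' @inheritParams sfd_esr
#' @param j level, `1 <= j <= S - 1`.
#' @export
entropy_weight <- function(frame, S, j, exclude_zero = FALSE) {
  if (j < 1L || j > S - 1L) stop("level j must satisfy 1 <= j <= S - 1", call. = FALSE)
  h <- spectral_histogram(frame, S, j, exclude_zero)
  min(1, max(0, shannon_entropy(h) / (j * h$n)))
}

#' Entropy-weighted spectral fractal dimension
#'
#' Weights each level's occupied-box count by the entropy factor `f_j`
#' before taking the DSR box-counting ratio:
#' `EW-SFD = n * sum_j term_j / (S - 1)` with
#' `term_j = log(f_j * SBM_j) / log((2^j)^n)` when `f_j * SBM_j >= 1`
#' and 0 otherwise. The floor rule makes structureless levels (a
#' sub-unit weighted count) contribute nothing instead of a negative or
#' infinite term. Always `0 <= EW-SFD <= SFD_DSR`, with equality when
#' every level histogram is uniform.
#'
#' @inheritParams sfd_esr
#' @export
ew_sfd <- function(frame, S, exclude_zero = FALSE) {
  ew_sfd_terms(frame, S, exclude_zero)$value
}

# shared worker: returns value and number of floored levels
ew_sfd_terms <- function(frame, S, exclude_zero = FALSE) {
  js <- n_levels_check(S)
  bands <- as_band_matrix(frame)
  check_frame_depth(bands, S)
  n <- ncol(bands)
  terms <- vapply(js, function(j) {
    counts <- level_counts(bands, S, j, exclude_zero)
    sbm <- length(counts)
    fj <- min(1, max(0, shannon_entropy(counts) / (j * n)))
    w <- fj * sbm
    if (w >= 1) log(w) / log((2^j)^n) else NA_real_
  }, numeric(1))
  floored <- sum(is.na(terms))
  terms[is.na(terms)] <- 0
  list(value = n * sum(terms) / (S - 1), floored_levels = floored)
}

#' Per-level box-count profile of a frame
#'
#' One row per level `j = 1..S-1` with the occupied-box count `SBM_j`,
#' the possible-box totals in both conventions, and the entropy weight
#' `f_j`.
#'
#' @inheritParams sfd_esr
#' @return a data frame of class `BoxCountProfile` with attributes `S`
#'   and `n`.
#' @export
box_count_profile <- function(frame, S, exclude_zero = FALSE) {
  js <- n_levels_check(S)
  bands <- as_band_matrix(frame)
  check_frame_depth(bands, S)
  n <- ncol(bands)
  rows <- lapply(js, function(j) {
    counts <- level_counts(bands, S, j, exclude_zero)
    data.frame(j = j,
               sbm = length(counts),
               sbt_dsr = (2^j)^n,
               sbt_esr = (2^S)^n,
               f = min(1, max(0, shannon_entropy(counts) / (j * n))))
  })
  out <- do.call(rbind, rows)
  attr(out, "S") <- as.integer(S)
  attr(out, "n") <- n
  class(out) <- c("BoxCountProfile", class(out))
  out
}

#' All four metrics of one frame
#'
#' Computes the full-depth joint entropy (bits), `SFD_ESR`, `SFD_DSR`
#' and `EW-SFD` of a single frame at analysis depth `S`, sharing the
#' per-level histograms.
#'
#' @inheritParams sfd_esr
#' @param S analysis bit depth; `NULL` uses the frame's effective data
#'   depth (raised to 2 if necessary, since the level sums need
#'   `S >= 2`).
#' @return a list of class `MetricResult`: `entropy_bits`, `sfd_esr`,
#'   `sfd_dsr`, `ew_sfd`, `S`, `n`, `floored_levels`.
#' @export
frame_metrics <- function(frame, S = NULL, exclude_zero = FALSE) {
  bands <- as_band_matrix(frame)
  if (is.null(S)) S <- max(2L, bit_depth_of(max(bands)))
  check_frame_depth(bands, S)
  js <- n_levels_check(S)
  n <- ncol(bands)
  sbm <- numeric(length(js))
  ent <- numeric(length(js))
  for (j in js) {
    counts <- level_counts(bands, S, j, exclude_zero)
    sbm[j] <- length(counts)
    ent[j] <- shannon_entropy(counts)
  }
  fj <- pmin(1, pmax(0, ent / (js * n)))
  w <- fj * sbm
  ew_terms <- ifelse(w >= 1, log(pmax(w, 1)) / log((2^js)^n), 0)
  structure(list(
    entropy_bits = shannon_entropy(level_counts(bands, S, S, exclude_zero)),
    sfd_esr = n * sum(log(sbm) / log((2^S)^n)) / (S - 1),
    sfd_dsr = n * sum(log(sbm) / log((2^js)^n)) / (S - 1),
    ew_sfd = n * sum(ew_terms) / (S - 1),
    S = as.integer(S), n = n,
    floored_levels = sum(w < 1)),
    class = "MetricResult")
}

#' @export
print.MetricResult <- function(x, ...) {
  cat(sprintf("MetricResult (S=%d, n=%d): H=%.4f bits, SFD_ESR=%.4f, SFD_DSR=%.4f, EW-SFD=%.4f (%d floored level(s))\n",
              x$S, x$n, x$entropy_bits, x$sfd_esr, x$sfd_dsr, x$ew_sfd,
              x$floored_levels))
  invisible(x)
}
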