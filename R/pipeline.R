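#' Pixel-wise dark correction
#'
#' Subtracts a per-pixel dark reference (e.g. the mean of frames
#' recorded with the cooled sensor in the dark) from every frame,
#' clamping at zero: photon counts are non-negative.
#'
#' @param stack a `FrameStack`.
#' @param dark an `H x W` (or `H x W x n`) per-pixel reference frame, or
#'   a `FrameStack` whose per-pixel temporal mean is used.
#' @return the corrected `FrameStack`; container depth unchanged.
#' @export
dark_correct <- function(stack, dark) {
  stopifnot(inherits(stack, "FrameStack"))
  if (inherits(dark, "FrameStack")) dark <- dark_reference(dark)
  d <- dim(stack$frames)
  dd <- dim(dark) %||% length(dark)
  if (!identical(as.integer(dd), as.integer(d[-1])))
    stop("dark reference shape does not match frames", call. = FALSE)
  out <- stack$frames
  T <- d[1]
  # recycle dark across the time axis
  ref <- aperm(array(dark, dim = c(d[-1], T)), c(length(d), seq_len(length(d) - 1L)))
  out <- floor(pmax(out - ref, 0))
  frame_stack(out, container_bits = stack$container_bits,
              frame_interval = stack$frame_interval)
}

#' Per-pixel temporal mean of a dark stack
#'
#' @param dark_stack a `FrameStack` of dark acquisitions.
#' @return an `H x W` (or `H x W x n`) matrix of per-pixel means.
#' @export
dark_reference <- function(dark_stack) {
  stopifnot(inherits(dark_stack, "FrameStack"))
  apply(dark_stack$frames, seq_along(dim(dark_stack$frames))[-1], mean)
}

#' Pixel-by-pixel background correction
#'
#' Subtracts the background ROI from the embryo ROI frame by frame,
#' pairing pixels by position within each (same-size) window and
#' clamping at zero. An alternative scalar mode subtracts the
#' background ROI's per-frame mean instead.
#'
#' @param stack a `FrameStack` (full frames).
#' @param embryo_roi,background_roi same-size, non-overlapping
#'   `RegionOfInterest`s.
#' @param scalar use the per-frame background mean rather than
#'   positional pairing (default `FALSE`).
#' @return the corrected embryo sub-stack (`T x height x width`).
#' @export
background_correct <- function(stack, embryo_roi, background_roi,
                               scalar = FALSE) {
  stopifnot(inherits(stack, "FrameStack"))
  if (embryo_roi$height != background_roi$height ||
      embryo_roi$width != background_roi$width)
    stop("embryo and background ROIs must have identical size", call. = FALSE)
  if (rois_overlap(embryo_roi, background_roi))
    stop("embryo and background ROIs overlap", call. = FALSE)
  emb <- extract_roi(stack, embryo_roi)
  bg <- extract_roi(stack, background_roi)
  sub <- if (scalar) {
    means <- apply(bg$frames, 1, mean)
    sweep(emb$frames, 1, means, "-")
  } else {
    emb$frames - bg$frames
  }
  frame_stack(floor(pmax(sub, 0)), container_bits = stack$container_bits,
              frame_interval = stack$frame_interval)
}

rois_overlap <- function(a, b) {
  (a$row0 < b$row0 + b$height) && (b$row0 < a$row0 + a$height) &&
    (a$col0 < b$col0 + b$width) && (b$col0 < a$col0 + a$width)
}

#' Rebin frames to a longer integration time
#'
#' Sums consecutive groups of `k` frames elementwise, emulating a
#' `k`-times longer sensor integration. A trailing partial group is
#' dropped so every output frame integrates the same duration.
#' Accumulation is exact (doubles hold the <= 2^53 sums involved); the
#' output container depth is the smallest depth holding the new
#' maximum, capped at `accumulator_bits`.
#'
#' @param stack a `FrameStack` with at least `k` frames.
#' @param k frames per bin, `>= 1`.
#' @param accumulator_bits cap on the output container depth
#'   (default 32).
#' @return a `FrameStack` of `floor(T / k)` frames with
#'   `frame_interval` scaled by `k`.
#' @export
rebin_integration_time <- function(stack, k, accumulator_bits = 32L) {
  stopifnot(inherits(stack, "FrameStack"))
  k <- as.integer(k)
  if (k < 1L) stop("rebin factor k must be >= 1", call. = FALSE)
  d <- dim(stack$frames)
  if (k > d[1]) stop("rebin factor k exceeds frame count", call. = FALSE)
  if (k == 1L) return(stack)
  nb <- d[1] %/% k
  out <- array(0, dim = c(nb, d[-1]))
  for (b in seq_len(nb)) {
    idx <- ((b - 1L) * k + 1L):(b * k)
    chunk <- if (length(d) == 3L) stack$frames[idx, , , drop = FALSE]
             else stack$frames[idx, , , , drop = FALSE]
    summed <- apply(chunk, seq_along(d)[-1], sum)
    if (length(d) == 3L) out[b, , ] <- summed else out[b, , , ] <- summed
  }
  bits <- min(as.integer(accumulator_bits), max(1L, bit_depth_of(max(out))))
  frame_stack(out, container_bits = bits,
              frame_interval = stack$frame_interval * k)
}

#' Effective data depth of a stack
#'
#' The smallest bit depth `S_eff >= 1` with every pixel `< 2^S_eff`.
#' Low-light recordings typically fill far less than their 16-bit
#' container: a stack whose maximum is 63 has depth 6, one reaching 255
#' has depth 8. Metrics computed at the effective depth avoid summing
#' structurally empty levels.
#'
#' @param stack a `FrameStack` (or a bare array/matrix of values).
#' @return integer `S_eff`.
#' @export
effective_data_depth <- function(stack) {
  vals <- if (inherits(stack, "FrameStack")) stack$frames else stack
  if (length(vals) == 0L) stop("empty stack", call. = FALSE)
  bit_depth_of(max(vals))
}

#' Correction specification
#'
#' Bundles the optional per-pixel dark reference and the background ROI
#' used for pixel-wise background subtraction.
#'
#' @param dark optional `FrameStack` or per-pixel reference frame.
#' @param background_roi optional `RegionOfInterest` with role
#'   `"background"`.
#' @param scalar_background use scalar (per-frame mean) background mode.
#' @export
correction_spec <- function(dark = NULL, background_roi = NULL,
                            scalar_background = FALSE) {
  if (!is.null(background_roi)) {
    stopifnot(inherits(background_roi, "RegionOfInterest"))
    if (background_roi$role != "background")
      stop("background_roi must have role 'background'", call. = FALSE)
  }
  structure(list(dark = dark, background_roi = background_roi,
                 scalar_background = scalar_background),
            class = "CorrectionSpec")
}

#' Metric time series for a set of ROIs
#'
#' The full analysis path behind the per-ROI metric curves: apply dark
#' correction (if a reference is given), extract each ROI, apply
#' pixel-wise background correction to non-background ROIs (the
#' background ROI is its own reference and is only dark-corrected),
#' optionally rebin the integration time, and compute the four metrics
#' per frame.
#'
#' @param stack a `FrameStack`.
#' @param rois a list of `RegionOfInterest` (or a single ROI).
#' @param corrections a [correction_spec()]; default none.
#' @param S analysis bit depth, or `"auto"` (default) for the effective
#'   data depth of each corrected ROI sub-stack (minimum 2).
#' @param rebin integration-time rebin factor (default 1).
#' @param exclude_zero passed to the metric functions (default `FALSE`).
#' @param verbose log corrections and chosen depths to standard error.
#' @return a list of `MetricSeries`, one per ROI, each a data frame with
#'   columns `time_s`, `roi`, `entropy_bits`, `sfd_esr`, `sfd_dsr`,
#'   `ew_sfd`, `S`, `n`, `floored_levels`.
#' @export
metric_time_series <- function(stack, rois, corrections = correction_spec(),
                               S = "auto", rebin = 1L, exclude_zero = FALSE,
                               verbose = FALSE) {
  stopifnot(inherits(stack, "FrameStack"))
  if (inherits(rois, "RegionOfInterest")) rois <- list(rois)
  stopifnot(inherits(corrections, "CorrectionSpec"))
  if (!is.null(corrections$dark)) {
    stack <- dark_correct(stack, corrections$dark)
    if (verbose) message("applied per-pixel dark correction")
  }
  bg <- corrections$background_roi
  lapply(rois, function(r) {
    sub <- if (r$role != "background" && !is.null(bg) &&
               !identical(r, bg)) {
      background_correct(stack, r, bg, scalar = corrections$scalar_background)
    } else {
      extract_roi(stack, r)
    }
    if (rebin > 1L) sub <- rebin_integration_time(sub, rebin)
    depth <- if (identical(S, "auto")) {
      max(2L, effective_data_depth(sub))
    } else {
      as.integer(S)
    }
    if (verbose)
      message(sprintf("ROI '%s': analysis depth S = %d", r$name, depth))
    res <- lapply(seq_len(n_frames(sub)), function(t)
      frame_metrics(get_frame(sub, t), S = depth, exclude_zero = exclude_zero))
    out <- data.frame(
      time_s = (seq_len(n_frames(sub)) - 1) * sub$frame_interval,
      roi = r$name,
      entropy_bits = vapply(res, `[[`, numeric(1), "entropy_bits"),
      sfd_esr = vapply(res, `[[`, numeric(1), "sfd_esr"),
      sfd_dsr = vapply(res, `[[`, numeric(1), "sfd_dsr"),
      ew_sfd = vapply(res, `[[`, numeric(1), "ew_sfd"),
      S = vapply(res, `[[`, integer(1), "S"),
      n = vapply(res, function(x) as.integer(x$n), integer(1)),
      floored_levels = vapply(res, function(x) as.integer(x$floored_levels),
                              integer(1)),
      stringsAsFactors = FALSE)
    attr(out, "provenance") <- list(
      dark_corrected = !is.null(corrections$dark),
      background_roi = if (!is.null(bg)) bg$name else NULL,
      rebin = as.integer(rebin), depth = depth,
      exclude_zero = exclude_zero)
    class(out) <- c("MetricSeries", class(out))
    out
  })
}

#' Bind metric series into one table
#'
#' @param series a list of `MetricSeries` (as returned by
#'   [metric_time_series()]).
#' @return a single data frame, one row per ROI per frame.
#' @export
bind_series <- function(series) {
  out <- do.call(rbind, lapply(series, function(s) {
    attr(s, "provenance") <- NULL
    class(s) <- "data.frame"
    s
  }))
  rownames(out) <- NULL
  out
}
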