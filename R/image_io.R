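#' Read a multi-page TIFF stack
#'
#' Reads a lossless multi-page TIFF (or BigTIFF) of unsigned-integer
#' samples into a [frame_stack()]. Page order is taken as acquisition
#' order; `container_bits` is taken from the file's sample depth. The
#' `.btf` batch-lossless files produced by 16-bit time-lapse recorders
#' are multi-page TIFF dialects and are read the same way.
#'
#' @param path path to a readable TIFF/BigTIFF file.
#' @param frame_interval seconds per frame to record as metadata
#'   (default 60).
#' @return a `FrameStack`.
#' @export
read_stack <- function(path, frame_interval = 60) {
  if (!file.exists(path)) stop(sprintf("cannot read stack: %s", path), call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
                    error = function(e) stop(sprintf("unreadable TIFF '%s': %s",
                                                     path, conditionMessage(e)),
                                             call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  bits <- vapply(pages, function(p) as.integer(attr(p, "bits.per.sample") %||% NA_integer_),
                 integer(1))
  if (anyNA(bits) || any(bits > 16L))
    stop("unsupported format: samples deeper than 16 bits", call. = FALSE)
  # as.is applies only to single-channel pages; multi-channel data come
  # back normalized to [0,1] and are rescaled to their integer codes
  pages <- lapply(seq_along(pages), function(i) {
    p <- pages[[i]]
    if (!is.double(p)) return(p)
    v <- p * (2^bits[i] - 1)
    if (any(abs(v - round(v)) > 1e-6))
      stop("unsupported format: floating-point samples", call. = FALSE)
    structure(round(v), dim = dim(p))
  })
  shapes <- lapply(pages, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("inconsistent page shapes in stack", call. = FALSE)
  pages <- lapply(pages, function(p) { attributes(p) <- list(dim = dim(p)); p })
  frame_stack(pages, container_bits = max(bits), frame_interval = frame_interval)
}

#' Write a stack as a lossless multi-page TIFF
#'
#' Pixel values round-trip bit-exactly through [read_stack()]. Data are
#' stored uncompressed at the smallest standard sample depth (8 or 16
#' bits) that holds `container_bits`; shallower logical depths (e.g.
#' 6-bit data) therefore come back with the file's container depth but
#' identical pixel values.
#'
#' @param stack a `FrameStack` with `container_bits` <= 16 and at most
#'   4 bands (the TIFF channel limit).
#' @param path output path.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "FrameStack"))
  if (stack$container_bits > 16L)
    stop("cannot write stacks deeper than 16 bits", call. = FALSE)
  if (stack$band_count > 4L)
    stop("TIFF output supports at most 4 bands", call. = FALSE)
  bits <- if (stack$container_bits <= 8L) 8L else 16L
  scale <- 2^bits - 1
  pages <- lapply(seq_len(n_frames(stack)),
                  function(t) get_frame(stack, t) / scale)
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = bits,
                                 compression = "none"),
                 error = function(e) stop(sprintf("cannot write '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  invisible(path)
}
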