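#' Frame stack container
#'
#' A `FrameStack` holds an ordered sequence of same-shape non-negative
#' integer frames: the raw time-lapse measurement, one frame per
#' integration interval. Single-band stacks are stored as a `T x H x W`
#' array, multi-band stacks as `T x H x W x n`.
#'
#' @param frames a `T x H x W` or `T x H x W x n` array of non-negative
#'   integers, or a list of `H x W` matrices (or `H x W x n` arrays) in
#'   time order.
#' @param container_bits declared container bit depth `S_c` in 1..16 (or
#'   larger for rebinned accumulator stacks). Defaults to the smallest
#'   depth holding the data, with a floor of 8.
#' @param frame_interval seconds per frame (metadata only; default 60,
#'   one-minute integration).
#' @return an object of class `FrameStack`.
#' @examples
#' fs <- frame_stack(array(0L, c(3, 4, 4)), container_bits = 8)
#' n_frames(fs)
#' @export
frame_stack <- function(frames, container_bits = NULL, frame_interval = 60) {
  if (is.list(frames)) {
    shapes <- lapply(frames, function(f) dim(f) %||% length(f))
    if (length(frames) == 0L) stop("frame list is empty", call. = FALSE)
    if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
      stop("all frames must share an identical shape", call. = FALSE)
    d <- dim(frames[[1]])
    if (is.null(d)) stop("frames must be matrices or arrays", call. = FALSE)
    arr <- array(0, dim = c(length(frames), d))
    for (t in seq_along(frames)) {
      if (length(d) == 2L) arr[t, , ] <- frames[[t]] else arr[t, , , ] <- frames[[t]]
    }
    frames <- arr
  }
  d <- dim(frames)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("frames must be a T x H x W or T x H x W x n array", call. = FALSE)
  if (any(d < 1L)) stop("all stack dimensions must be >= 1", call. = FALSE)
  if (anyNA(frames)) stop("frames contain NA values", call. = FALSE)
  if (any(frames < 0)) stop("frames must be non-negative", call. = FALSE)
  if (any(frames != floor(frames)))
    stop("frames must contain integer values", call. = FALSE)
  mx <- max(frames)
  need <- bit_depth_of(mx)
  if (is.null(container_bits)) container_bits <- max(8L, need)
  container_bits <- as.integer(container_bits)
  if (container_bits < 1L)
    stop("container_bits must be >= 1", call. = FALSE)
  if (mx >= 2^container_bits)
    stop(sprintf("pixel value %s exceeds %d-bit container", format(mx), container_bits),
         call. = FALSE)
  structure(
    list(frames = frames,
         container_bits = container_bits,
         band_count = if (length(d) == 4L) d[4] else 1L,
         frame_interval = as.numeric(frame_interval)),
    class = "FrameStack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# smallest S >= 1 with x < 2^S
bit_depth_of <- function(x) {
  x <- max(0, x)
  s <- 1L
  while (x >= 2^s) s <- s + 1L
  s
}

#' @export
print.FrameStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("FrameStack: %d frame(s) of %d x %d, %d band(s), %d-bit container, %g s/frame\n",
              d[1], d[2], d[3], x$band_count, x$container_bits, x$frame_interval))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `FrameStack`.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "FrameStack"))
  dim(stack$frames)[1]
}

#' Extract a single frame
#'
#' @param stack a `FrameStack`.
#' @param t 1-based frame index.
#' @return an `H x W` matrix (single band) or `H x W x n` array.
#' @export
get_frame <- function(stack, t) {
  stopifnot(inherits(stack, "FrameStack"))
  d <- dim(stack$frames)
  if (t < 1L || t > d[1]) stop("frame index out of range", call. = FALSE)
  if (length(d) == 3L) {
    matrix(stack$frames[t, , ], d[2], d[3])
  } else {
    array(stack$frames[t, , , ], d[-1])
  }
}

#' @export
dim.FrameStack <- function(x) dim(x$frames)
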