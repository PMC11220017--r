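#' Rectangular region of interest
#'
#' Coordinates are 0-based and half-open: the window covers rows
#' `[row0, row0 + height)` and columns `[col0, col0 + width)`. The
#' default window is 21 x 21 pixels, the sampling-area size used for
#' embryo and background regions.
#'
#' @param row0,col0 0-based offsets of the top-left corner.
#' @param height,width window extents in pixels (default 21).
#' @param role one of `"background"`, `"embryo"`, `"reference"`.
#' @param name label used in metric output (defaults to the role).
#' @return an object of class `RegionOfInterest`.
#' @export
roi <- function(row0, col0, height = 21L, width = 21L,
                role = c("embryo", "background", "reference"),
                name = NULL) {
  role <- match.arg(role)
  row0 <- as.integer(row0); col0 <- as.integer(col0)
  height <- as.integer(height); width <- as.integer(width)
  if (row0 < 0L || col0 < 0L) stop("ROI offsets must be >= 0", call. = FALSE)
  if (height < 1L || width < 1L) stop("ROI extents must be >= 1", call. = FALSE)
  structure(
    list(row0 = row0, col0 = col0, height = height, width = width,
         role = role, name = name %||% role),
    class = "RegionOfInterest")
}

#' @export
print.RegionOfInterest <- function(x, ...) {
  cat(sprintf("ROI '%s' (%s): rows [%d,%d) x cols [%d,%d)\n",
              x$name, x$role, x$row0, x$row0 + x$height, x$col0, x$col0 + x$width))
  invisible(x)
}

check_roi_bounds <- function(r, H, W) {
  if (r$row0 + r$height > H || r$col0 + r$width > W)
    stop(sprintf("ROI '%s' [%d,%d)x[%d,%d) exceeds frame bounds %d x %d",
                 r$name, r$row0, r$row0 + r$height, r$col0, r$col0 + r$width,
                 H, W), call. = FALSE)
  invisible(TRUE)
}

#' Extract an ROI sub-stack
#'
#' Returns the `T x height x width` (times bands) sub-stack covered by
#' the ROI window. Out-of-bounds ROIs are an error; there is no silent
#' clipping.
#'
#' @param stack a `FrameStack`.
#' @param r a `RegionOfInterest`.
#' @return a `FrameStack` with unchanged container depth and frame order.
#' @export
extract_roi <- function(stack, r) {
  stopifnot(inherits(stack, "FrameStack"), inherits(r, "RegionOfInterest"))
  d <- dim(stack$frames)
  check_roi_bounds(r, d[2], d[3])
  rows <- (r$row0 + 1L):(r$row0 + r$height)
  cols <- (r$col0 + 1L):(r$col0 + r$width)
  sub <- if (length(d) == 3L) {
    stack$frames[, rows, cols, drop = FALSE]
  } else {
    stack$frames[, rows, cols, , drop = FALSE]
  }
  frame_stack(sub, container_bits = stack$container_bits,
              frame_interval = stack$frame_interval)
}

#' Read ROI definitions from a YAML or JSON file
#'
#' The file holds a list of records with fields `name`, `role`, `row0`,
#' `col0`, `height`, `width` (extents optional, default 21).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a list of `RegionOfInterest` objects.
#' @export
read_roi_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("ROI file not found: %s", path), call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(raw) == 0L) stop("ROI file defines no regions", call. = FALSE)
  lapply(raw, function(rec) {
    roi(row0 = rec$row0, col0 = rec$col0,
        height = rec$height %||% 21L, width = rec$width %||% 21L,
        role = rec$role %||% "embryo", name = rec$name)
  })
}
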