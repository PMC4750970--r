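# Image-stack data model, window extraction, plane/channel selection and
# raster file I/O.  A "slide" is an ordered z-stack of 8-bit planes.

#' Construct an image stack (one slide)
#'
#' An image stack is the unit of a slide: an ordered list of z-planes, each a
#' `height x width x channels` integer array of intensities in
#' `[0, max_intensity]`.  All planes must share identical dimensions;
#' z-plane order is preserved throughout the package.
#'
#' @param planes list of 2-D matrices (single channel) or 3-D arrays
#'   (`height x width x channels`); matrices are promoted to
#'   single-channel arrays.
#' @param bit_depth integer bit depth of the source imagery (default 8).
#' @param max_intensity maximum representable intensity (default 255).
#' @param pixel_pitch_um physical pixel pitch in micrometers (informational;
#'   default 0.23, the pitch of a 400x slide scan).
#' @param slide_id identifier for the slide.
#' @param slide_label optional class label or known mixture ratio.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(planes, bit_depth = 8L, max_intensity = 255L,
                        pixel_pitch_um = 0.23, slide_id = "slide",
                        slide_label = NULL) {
  if (!is.list(planes) || length(planes) == 0L)
    stopf("`planes` must be a non-empty list of matrices or 3-D arrays")
  planes <- lapply(planes, as_plane)
  dims <- vapply(planes, dim, integer(3))
  if (length(planes) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stopf("all planes must share identical height, width and channel count")
  for (p in planes) {
    if (anyNA(p) || min(p) < 0L || max(p) > max_intensity)
      stopf("plane intensities must lie in [0, %d]", max_intensity)
  }
  structure(list(planes = planes, bit_depth = as.integer(bit_depth),
                 max_intensity = as.integer(max_intensity),
                 pixel_pitch_um = pixel_pitch_um,
                 slide_id = slide_id, slide_label = slide_label),
            class = "image_stack")
}

# Promote a matrix to a height x width x 1 integer array.
as_plane <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stopf("each plane must be a matrix or a 3-D array")
  storage.mode(x) <- "integer"
  x
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("<image_stack '%s': %d z-plane(s), %d x %d px, %d channel(s)%s>\n",
              x$slide_id, length(x$planes), d[1], d[2], d[3],
              if (is.null(x$slide_label)) "" else
                sprintf(", label=%s", format(x$slide_label))))
  invisible(x)
}

#' Extract a rectangular window from one z-plane
#'
#' Coordinates are 0-based and the rectangle is half-open:
#' rows `[row0, row0 + height)`, columns `[col0, col0 + width)`.
#'
#' @param stack an [image_stack()].
#' @param z 0-based z-plane index.
#' @param row0,col0 0-based top-left corner.
#' @param height,width window size in pixels.
#' @return a `gh_window`: list with `pixels` (h x w x ch array), `origin`
#'   (`c(z, row0, col0)`) and `mask` (`NULL`; attach one with
#'   [set_window_mask()]).
#' @export
extract_window <- function(stack, z, row0, col0, height, width) {
  stopifnot(inherits(stack, "image_stack"))
  nz <- length(stack$planes)
  if (!is_count(z, min = 0L) || z >= nz)
    stopf("z-plane index %s out of bounds [0, %d)", format(z), nz)
  plane <- stack$planes[[z + 1L]]
  d <- dim(plane)
  if (!is_count(height) || !is_count(width))
    stopf("height and width must be positive counts")
  if (!is_count(row0, min = 0L) || row0 + height > d[1])
    stopf("row range [%s, %s) out of bounds for plane height %d",
          format(row0), format(row0 + height), d[1])
  if (!is_count(col0, min = 0L) || col0 + width > d[2])
    stopf("col range [%s, %s) out of bounds for plane width %d",
          format(col0), format(col0 + width), d[2])
  px <- plane[row0 + seq_len(height), col0 + seq_len(width), , drop = FALSE]
  gh_window(px, origin = c(z, row0, col0))
}

#' Construct a window object
#'
#' @param pixels matrix or `h x w x ch` array of intensities.
#' @param origin 0-based `c(z, row0, col0)` in the parent stack.
#' @param mask optional binary matrix (1 = pollen) matching `pixels`.
#' @export
gh_window <- function(pixels, origin = c(0L, 0L, 0L), mask = NULL) {
  pixels <- as_plane(pixels)
  w <- structure(list(pixels = pixels, origin = as.integer(origin),
                      mask = NULL),
                 class = "gh_window")
  if (!is.null(mask)) w <- set_window_mask(w, mask)
  w
}

#' Attach a binary pixel-label mask to a window
#'
#' @param window a `gh_window`.
#' @param mask binary matrix (values 0/1) whose dimensions equal the window's.
#' @export
set_window_mask <- function(window, mask) {
  stopifnot(inherits(window, "gh_window"))
  mask <- as.matrix(mask)
  d <- dim(window$pixels)
  if (!identical(dim(mask), d[1:2]))
    stopf("mask dimensions %d x %d do not match window %d x %d",
          nrow(mask), ncol(mask), d[1], d[2])
  if (!all(mask %in% c(0, 1))) stopf("mask must be binary (0/1)")
  storage.mode(mask) <- "integer"
  window$mask <- mask
  window
}

#' Keep every k-th z-plane of a stack
#'
#' Retains planes whose 0-based index is divisible by `step`, preserving
#' order — the sub-sampling used to cut species-classification run time
#' (every 5th focal plane of a 61-plane scan leaves 13).
#'
#' @param stack an [image_stack()].
#' @param step positive plane step.
#' @export
select_planes <- function(stack, step) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is_count(step)) stopf("`step` must be a positive integer")
  keep <- seq_along(stack$planes)[(seq_along(stack$planes) - 1L) %% step == 0L]
  stack$planes <- stack$planes[keep]
  stack
}

#' Restrict a window to a single channel
#'
#' @param window a `gh_window`.
#' @param channel 0-based channel index (0 = red for RGB imagery).
#' @export
select_channel <- function(window, channel) {
  stopifnot(inherits(window, "gh_window"))
  nch <- dim(window$pixels)[3]
  if (!is_count(channel, min = 0L) || channel >= nch)
    stopf("channel %s invalid for a %d-channel window", format(channel), nch)
  window$pixels <- window$pixels[, , channel + 1L, drop = FALSE]
  window
}

#' Paste a window back into a stack (inverse of [extract_window()])
#'
#' @param stack an [image_stack()].
#' @param window a `gh_window` with origin metadata.
#' @export
paste_window <- function(stack, window) {
  stopifnot(inherits(stack, "image_stack"), inherits(window, "gh_window"))
  o <- window$origin
  d <- dim(window$pixels)
  stack$planes[[o[1] + 1L]][o[2] + seq_len(d[1]), o[3] + seq_len(d[2]), ] <-
    window$pixels
  stack
}

plane_to_raster <- function(plane, max_intensity) {
  arr <- plane / max_intensity
  if (dim(arr)[3] == 1L) arr <- arr[, , 1] # writers expect a matrix for grey
  arr
}

raster_to_plane <- function(arr, max_intensity) {
  if (length(dim(arr)) == 3L && dim(arr)[3] == 4L)
    arr <- arr[, , 1:3, drop = FALSE]  # drop alpha
  as_plane(array(as.integer(round(arr * max_intensity)),
                 dim = if (is.matrix(arr)) c(dim(arr), 1L) else dim(arr)))
}

read_raster_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return(png::readPNG(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF requires the 'tiff' package")
    return(tiff::readTIFF(path))
  }
  stopf("unsupported raster format '%s' (PNG or TIFF expected): %s", ext, path)
}

#' Read an image stack from plane files or a manifest
#'
#' Accepts either an ordered vector of 8-bit PNG/TIFF plane files (z order),
#' or the path of a JSON manifest written by [write_stack()] listing plane
#' files plus slide metadata.
#'
#' @param paths character vector of plane files, or one manifest path.
#' @param max_intensity intensity ceiling used to decode (default 255).
#' @export
read_stack <- function(paths, max_intensity = 255L) {
  meta <- list(slide_id = "slide", slide_label = NULL, pixel_pitch_um = 0.23)
  if (length(paths) == 1L && tolower(tools::file_ext(paths)) == "json") {
    man <- jsonlite::read_json(paths, simplifyVector = TRUE)
    dir <- dirname(paths)
    meta$slide_id <- man$slide_id %||% "slide"
    meta$slide_label <- man$slide_label
    meta$pixel_pitch_um <- man$pixel_pitch_um %||% 0.23
    paths <- file.path(dir, man$planes)
  }
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) stopf("cannot read plane file(s): %s",
                                  paste(missing, collapse = ", "))
  planes <- lapply(paths, function(p)
    raster_to_plane(read_raster_file(p), max_intensity))
  dims <- vapply(planes, dim, integer(3))
  if (length(planes) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stopf("plane files have mixed dimensions; a stack must be homogeneous")
  image_stack(planes, max_intensity = max_intensity,
              pixel_pitch_um = meta$pixel_pitch_um,
              slide_id = meta$slide_id, slide_label = meta$slide_label)
}

#' Write an image stack as one PNG per z-plane plus a JSON manifest
#'
#' The round trip `read_stack(write_stack(s))` is lossless for pixel data
#' and plane order.
#'
#' @param stack an [image_stack()].
#' @param directory output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_stack <- function(stack, directory) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("plane_%03d.png", seq_along(stack$planes) - 1L)
  for (i in seq_along(stack$planes)) {
    png::writePNG(plane_to_raster(stack$planes[[i]], stack$max_intensity),
                  file.path(directory, files[i]))
  }
  manifest <- file.path(directory, "manifest.json")
  jsonlite::write_json(
    list(slide_id = stack$slide_id, slide_label = stack$slide_label,
         pixel_pitch_um = stack$pixel_pitch_um, planes = files),
    manifest, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
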