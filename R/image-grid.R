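#' Image lattice with physical metadata
#'
#' Container for 2-D images, 3-D multi-channel stacks and time-lapse movies,
#' carrying per-axis physical pixel sizes in micrometres and, for movies, the
#' frame interval in minutes. Pixel centers sit at integer 0-based indices;
#' the physical position of index i is `i * pixel_size`.
#'
#' @param data numeric array: a matrix `[y, x]` for a 2-D image, a 3-D array
#'   `[z, y, x]` (single-channel stack) or `[t, y, x]` (movie, when
#'   `frame_interval` is given), or a 4-D array `[z, y, x, channel]`.
#' @param pixel_size numeric vector of per-axis sizes in micrometres:
#'   `c(y, x)` for 2-D, `c(z, y, x)` for stacks, `c(y, x)` for movie frames.
#' @param channel_names optional character vector naming the channel axis.
#' @param frame_interval optional frame interval in minutes (movies only).
#' @param kind one of `"image2d"`, `"stack3d"`, `"movie"`; inferred when `NULL`.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(data, pixel_size, channel_names = NULL,
                       frame_interval = NULL, kind = NULL) {
  if (!is.array(data) && !is.matrix(data)) stop("`data` must be an array")
  if (any(!is.finite(data))) stop("intensities must be finite")
  if (any(data < 0)) stop("intensities must be >= 0")
  nd <- length(dim(data))
  if (is.null(kind)) {
    kind <- if (nd == 2L) "image2d"
      else if (nd == 3L && !is.null(frame_interval)) "movie"
      else if (nd %in% c(3L, 4L)) "stack3d"
      else stop("unsupported dimensionality: ", nd)
  }
  expected_ps <- switch(kind, image2d = 2L, movie = 2L, stack3d = 3L)
  if (length(pixel_size) != expected_ps) {
    stop("pixel_size must have length ", expected_ps, " for kind '", kind, "'")
  }
  if (any(pixel_size <= 0)) stop("pixel sizes must be > 0")
  names(pixel_size) <- switch(kind, image2d = c("y", "x"), movie = c("y", "x"),
                              stack3d = c("z", "y", "x"))
  if (!is.null(channel_names)) {
    nch <- if (nd == 4L) dim(data)[4L] else 1L
    if (length(channel_names) != nch) stop("channel_names length mismatch")
  }
  if (!is.null(frame_interval) && frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  structure(list(data = data, pixel_size = pixel_size,
                 channel_names = channel_names,
                 frame_interval = frame_interval, kind = kind),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> kind:", x$kind, " dim:", paste(dim(x$data), collapse = "x"),
      " pixel_size:", paste(signif(x$pixel_size, 4), collapse = "/"), "um\n")
  invisible(x)
}

#' Binary mask with physical metadata and provenance
#'
#' @param mask logical array with the same geometry as its source image.
#' @param pixel_size per-axis physical size in micrometres.
#' @param provenance list recording the method and parameters that produced
#'   the mask (threshold value, cleaning steps, overrides, degenerate flags).
#' @return an object of class `labeled_mask`.
#' @export
labeled_mask <- function(mask, pixel_size, provenance = list()) {
  if (!is.logical(mask)) storage.mode(mask) <- "logical"
  if (any(pixel_size <= 0)) stop("pixel sizes must be > 0")
  structure(list(mask = mask, pixel_size = pixel_size, provenance = provenance),
            class = "labeled_mask")
}

#' @export
print.labeled_mask <- function(x, ...) {
  cat("<labeled_mask> dim:", paste(dim(x$mask), collapse = "x"),
      " foreground:", sum(x$mask), "px\n")
  invisible(x)
}

#' Resample a 2-D image to an isotropic pixel size
#'
#' Bilinear resampling of a single-channel 2-D image to a target isotropic
#' pixel size (the morphometry pipeline operates at 1 um/px, the resolution
#' at which its pixel-denominated cleaning thresholds are defined). An image
#' already at the target size is returned unchanged.
#'
#' @param image an [image_grid] of kind `"image2d"`.
#' @param target_px target pixel size in micrometres (> 0).
#' @return an [image_grid] at `target_px` on both axes.
#' @export
resample_isotropic <- function(image, target_px = 1) {
  stopifnot(inherits(image, "image_grid"))
  if (image$kind != "image2d") stop("resample_isotropic expects a 2-D image")
  if (target_px <= 0) stop("target_px must be > 0")
  ps <- image$pixel_size
  if (isTRUE(all.equal(unname(ps), rep(target_px, 2L)))) return(image)
  d <- dim(image$data)
  new_ny <- max(2L, round(d[1L] * ps[["y"]] / target_px))
  new_nx <- max(2L, round(d[2L] * ps[["x"]] / target_px))
  eb <- EBImage::resize(.as_eb(image$data), w = new_nx, h = new_ny)
  out <- .from_eb(eb)
  out[out < 0] <- 0
  image_grid(out, c(target_px, target_px),
             channel_names = image$channel_names)
}
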