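# Histogram thresholding -------------------------------------------------

# 256-bin histogram shared by the three algorithms
.intensity_hist <- function(x, levels = 256L) {
  r <- range(x)
  if (r[1L] == r[2L]) return(NULL)
  breaks <- seq(r[1L], r[2L], length.out = levels + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = levels)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  list(counts = counts, mids = mids, breaks = breaks)
}

.otsu_idx <- function(counts) {
  n <- length(counts)
  p <- counts / sum(counts)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(n))
  mu_t <- mu[n]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  which.max(sigma_b[-n])
}

.triangle_idx <- function(counts) {
  nz <- which(counts > 0)
  first <- nz[1L]; last <- nz[length(nz)]
  peak <- which.max(counts)
  flipped <- (peak - first) >= (last - peak)
  if (flipped) {
    counts <- rev(counts)
    nz <- which(counts > 0)
    first <- nz[1L]; last <- nz[length(nz)]
    peak <- which.max(counts)
  }
  if (peak >= last) {
    idx <- peak
  } else {
    xs <- (peak + 1L):last
    # vertical distance to the peak->tail chord has the same argmax as the
    # perpendicular distance
    chord <- counts[peak] * (last - xs) / (last - peak)
    idx <- xs[which.max(chord - counts[xs])]
  }
  if (flipped) length(counts) - idx + 1L else idx
}

.yen_idx <- function(counts) {
  p <- counts / sum(counts)
  n <- length(p)
  P1 <- cumsum(p)
  P1sq <- cumsum(p^2)
  P2sq <- sum(p^2) - P1sq
  crit <- rep(-Inf, n)
  ok <- P1 > 0 & P1 < 1 & P1sq > 0 & P2sq > 0
  crit[ok] <- 2 * log(P1[ok] * (1 - P1[ok])) - log(P1sq[ok] * P2sq[ok])
  which.max(crit)
}

#' Compute an intensity threshold
#'
#' Histogram-based global threshold on a 256-bin histogram. `"otsu"`
#' maximizes between-class variance, `"triangle"` maximizes the distance to
#' the peak-to-tail chord (suited to heavy-tailed unimodal histograms), and
#' `"yen"` maximizes Yen's entropic correlation criterion. Foreground is
#' defined as intensities strictly greater than the returned value.
#'
#' @param x numeric vector or array of intensities.
#' @param method one of `"otsu"`, `"triangle"`, `"yen"`.
#' @param levels number of histogram bins.
#' @return threshold value, or `NA` for a constant input.
#' @export
threshold_value <- function(x, method = c("otsu", "triangle", "yen"),
                            levels = 256L) {
  method <- match.arg(method)
  h <- .intensity_hist(as.numeric(x), levels)
  if (is.null(h)) return(NA_real_)
  idx <- switch(method,
                otsu = .otsu_idx(h$counts),
                triangle = .triangle_idx(h$counts),
                yen = .yen_idx(h$counts))
  # threshold at the upper edge of the selected bin: mask = x > t
  h$breaks[idx + 1L]
}

#' Binarize an image by global thresholding
#'
#' Applies [threshold_value()] and keeps pixels strictly above the threshold
#' (ties at the threshold go to background). A constant image yields an empty
#' mask flagged as degenerate, with a warning, rather than an error.
#'
#' @param image an [image_grid] (single channel; 2-D or 3-D).
#' @param method thresholding algorithm, see [threshold_value()].
#' @return a [labeled_mask] whose provenance records method and threshold.
#' @export
binarize <- function(image, method = c("otsu", "triangle", "yen")) {
  stopifnot(inherits(image, "image_grid"))
  method <- match.arg(method)
  dat <- image$data
  if (length(dim(dat)) == 4L && dim(dat)[4L] == 1L) dat <- dat[, , , 1L]
  thr <- threshold_value(dat, method)
  if (is.na(thr)) {
    warning("constant image: returning empty mask (degenerate)")
    return(labeled_mask(array(FALSE, dim(dat)), image$pixel_size,
                        provenance = list(method = method, threshold = NA_real_,
                                          degenerate = TRUE)))
  }
  labeled_mask(dat > thr, image$pixel_size,
               provenance = list(method = method, threshold = thr,
                                 degenerate = FALSE))
}

#' Recommend a thresholding algorithm for an image
#'
#' Candidate-comparison heuristic: each of the three algorithms is applied
#' and the method whose mask has the smallest boundary-length-to-area ratio
#' wins (clean segmentations have compact boundaries; over- or
#' under-thresholding produces ragged, high-ratio masks). The choice is
#' deterministic given the image; callers can always override it.
#'
#' @param image an [image_grid], single-channel 2-D.
#' @return the recommended method name, with attributes `scores` (named
#'   boundary/area ratios) and `degenerate` (TRUE for a constant image, for
#'   which the default `"otsu"` is returned).
#' @export
select_threshold_method <- function(image) {
  stopifnot(inherits(image, "image_grid"))
  methods <- c("otsu", "triangle", "yen")
  if (diff(range(image$data)) == 0) {
    out <- "otsu"
    attr(out, "degenerate") <- TRUE
    attr(out, "scores") <- stats::setNames(rep(NA_real_, 3L), methods)
    return(out)
  }
  scores <- vapply(methods, function(m) {
    msk <- suppressWarnings(binarize(image, m))$mask
    a <- sum(msk)
    if (a == 0) return(Inf)
    .crofton_perimeter(msk) / a
  }, numeric(1L))
  out <- methods[which.min(scores)]
  attr(out, "scores") <- scores
  attr(out, "degenerate") <- FALSE
  out
}

# Connected-component labeling of a logical matrix, returning integer labels
.label2d <- function(m) {
  .from_eb(EBImage::bwlabel(.as_eb(m)))
}

#' Clean a binary body mask
#'
#' Mask-cleaning recipe for somitoid morphometry, applied in fixed order:
#' interior holes smaller than `min_size` pixels are filled, foreground
#' components smaller than `min_size` pixels are removed, then the mask is
#' smoothed by morphological opening with a disk-shaped structuring element.
#' Thresholds are pixel-denominated and assume a 1 um/px mask; a warning is
#' issued otherwise.
#'
#' @param mask a [labeled_mask] (2-D).
#' @param min_size minimum hole/component size in pixels (default 10000).
#' @param opening_radius disk radius of the opening footprint in pixels
#'   (default 5).
#' @return a cleaned [labeled_mask]; an empty mask passes through unchanged.
#' @export
clean_mask <- function(mask, min_size = 10000, opening_radius = 5) {
  stopifnot(inherits(mask, "labeled_mask"))
  m <- mask$mask
  if (length(dim(m)) != 2L) stop("clean_mask expects a 2-D mask")
  if (any(abs(mask$pixel_size - 1) > 1e-9)) {
    warning("clean_mask thresholds are pixel-denominated; mask is not at 1 um/px")
  }
  if (any(m)) {
    # 1. fill holes smaller than min_size (background components not touching
    #    the image border)
    bg_lab <- .label2d(!m)
    if (max(bg_lab) > 0) {
      border_labs <- unique(c(bg_lab[1L, ], bg_lab[nrow(bg_lab), ],
                              bg_lab[, 1L], bg_lab[, ncol(bg_lab)]))
      sizes <- tabulate(bg_lab, nbins = max(bg_lab))
      fill <- setdiff(which(sizes > 0 & sizes < min_size), border_labs)
      if (length(fill)) m[bg_lab %in% fill] <- TRUE
    }
    # 2. remove foreground components smaller than min_size
    fg_lab <- .label2d(m)
    if (max(fg_lab) > 0) {
      sizes <- tabulate(fg_lab, nbins = max(fg_lab))
      drop <- which(sizes > 0 & sizes < min_size)
      if (length(drop)) m[fg_lab %in% drop] <- FALSE
    }
    # 3. morphological opening with a disk footprint
    if (opening_radius > 0 && any(m)) {
      brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
      m <- .from_eb(EBImage::opening(.as_eb(m), brush)) > 0
    }
  }
  labeled_mask(m, mask$pixel_size,
               provenance = c(mask$provenance,
                              list(cleaned = list(min_size = min_size,
                                                  opening_radius = opening_radius))))
}

#' Generic region morphometrics of a binary mask
#'
#' Area, perimeter, principal axes and circularity of a single connected
#' region. The perimeter uses a two-direction Crofton estimate (asymptotically
#' exact for smooth round shapes; it underestimates polygonal boundaries, so
#' circularity of a square exceeds 1). Axis lengths derive from second
#' central moments as for an ellipse with the same moments.
#'
#' @param mask a [labeled_mask], 2-D, isotropic pixels, exactly one connected
#'   component.
#' @return named list: `area_um2`, `perimeter_um`, `major_axis_um`,
#'   `minor_axis_um`, `circularity`.
#' @export
region_morphometrics <- function(mask) {
  stopifnot(inherits(mask, "labeled_mask"))
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  ps <- mask$pixel_size
  if (abs(ps[1L] - ps[2L]) > 1e-9) stop("region_morphometrics requires isotropic pixels")
  px <- unname(ps[1L])
  lab <- .label2d(m)
  if (max(lab) != 1L) stop("mask must contain exactly one connected region, found ", max(lab))
  area <- sum(m) * px^2
  perim <- .crofton_perimeter(m, px)
  idx <- which(m, arr.ind = TRUE)
  ys <- (idx[, 1L] - 1) * px
  xs <- (idx[, 2L] - 1) * px
  cxx <- stats::var(xs) * (length(xs) - 1) / length(xs)
  cyy <- stats::var(ys) * (length(ys) - 1) / length(ys)
  cxy <- stats::cov(xs, ys) * (length(xs) - 1) / length(xs)
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2L), symmetric = TRUE)$values
  list(area_um2 = area,
       perimeter_um = perim,
       major_axis_um = 4 * sqrt(max(ev[1L], 0)),
       minor_axis_um = 4 * sqrt(max(ev[2L], 0)),
       circularity = 4 * pi * area / perim^2)
}
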