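# shared fixtures (cached so expensive generations run once per test session)
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

default_somitoid <- function() {
  cached("somitoid0", generate_somitoid(somitoid_spec(seed = 0)))
}

# full morphometry run on the default somitoid
default_morph <- function() {
  cached("morph0", {
    gen <- default_somitoid()
    mask <- clean_mask(binarize(gen$image, "yen"))
    pts <- midline_ridge_points(mask)
    ord <- order_midline_points(pts, gen$truth$anchors$posterior,
                                gen$truth$anchors$anterior)
    mid <- fit_midline_spline(ord$points)
    prof <- compute_width_profile(mask, mid)
    calls <- call_somites(prof, find_profile_extrema(prof))
    list(gen = gen, mask = mask, midline = mid, profile = prof, calls = calls)
  })
}

run_morphometry <- function(gen) {
  mask <- clean_mask(binarize(gen$image, "yen"))
  pts <- midline_ridge_points(mask)
  ord <- order_midline_points(pts, gen$truth$anchors$posterior,
                              gen$truth$anchors$anterior)
  mid <- fit_midline_spline(ord$points)
  prof <- compute_width_profile(mask, mid)
  calls <- call_somites(prof, find_profile_extrema(prof))
  list(mask = mask, midline = mid, profile = prof, calls = calls)
}

# rasterize a disc: logical matrix at the given pixel size
raster_disc <- function(r_um, px, margin_um = 10) {
  half <- r_um + margin_um
  n <- ceiling(2 * half / px) + 1L
  cc <- (n - 1) * px / 2
  g <- ((seq_len(n)) - 1) * px
  outer((g - cc)^2, (g - cc)^2, `+`) <= r_um^2
}

# independent width oracle: exhaustive fine-step scan along the normal with
# an interpolated half-level boundary crossing (brute force, no coarse
# bracketing, written independently of the implementation under test)
oracle_width <- function(mask_mat, px, point, normal, step = 0.1,
                         max_range = 300) {
  tv <- seq(0, max_range, by = step)
  interp <- function(xs, ys) {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    val <- function(ix, iy) {
      v <- numeric(length(ix))
      ok <- ix >= 0 & iy >= 0 & ix <= ncol(mask_mat) - 1 & iy <= nrow(mask_mat) - 1
      v[ok] <- mask_mat[cbind(iy[ok] + 1L, ix[ok] + 1L)]
      v
    }
    (1 - fx) * (1 - fy) * val(x0, y0) + fx * (1 - fy) * val(x0 + 1, y0) +
      (1 - fx) * fy * val(x0, y0 + 1) + fx * fy * val(x0 + 1, y0 + 1)
  }
  one_side <- function(dir) {
    v <- interp((point[1L] + dir[1L] * tv) / px, (point[2L] + dir[2L] * tv) / px)
    out <- which(v < 0.5)
    if (!length(out)) return(max_range)
    k <- out[1L]
    if (k == 1L) return(0)
    tv[k - 1L] + step * (v[k - 1L] - 0.5) / (v[k - 1L] - v[k])
  }
  one_side(normal) + one_side(-normal)
}

# independent bilinear interpolation (for kymograph line-sampling checks)
oracle_bilinear <- function(m, x_px, y_px) {
  vapply(seq_along(x_px), function(i) {
    x <- x_px[i]; y <- y_px[i]
    x0 <- floor(x); y0 <- floor(y)
    fx <- x - x0; fy <- y - y0
    g <- function(ix, iy) {
      if (ix < 0 || iy < 0 || ix > ncol(m) - 1 || iy > nrow(m) - 1) return(0)
      m[iy + 1L, ix + 1L]
    }
    (1 - fx) * (1 - fy) * g(x0, y0) + fx * (1 - fy) * g(x0 + 1, y0) +
      (1 - fx) * fy * g(x0, y0 + 1) + fx * fy * g(x0 + 1, y0 + 1)
  }, numeric(1L))
}

# brute-force morphological opening: erosion then dilation by explicit
# structuring-element sweep
brute_opening <- function(m, brush) {
  ny <- nrow(m); nx <- ncol(m)
  off <- which(brush > 0, arr.ind = TRUE)
  cy <- (nrow(brush) + 1L) / 2; cx <- (ncol(brush) + 1L) / 2
  dys <- off[, 1L] - cy; dxs <- off[, 2L] - cx
  shift <- function(mm, dy, dx, fill) {
    out <- matrix(fill, ny, nx)
    ys <- seq_len(ny) + dy; xs <- seq_len(nx) + dx
    oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
    out[which(oky), which(okx)] <- mm[ys[oky], xs[okx]]
    out
  }
  er <- matrix(TRUE, ny, nx)
  for (i in seq_along(dys)) er <- er & shift(m, dys[i], dxs[i], FALSE)
  di <- matrix(FALSE, ny, nx)
  for (i in seq_along(dys)) di <- di | shift(er, -dys[i], -dxs[i], FALSE)
  di
}

# straight midline along y = y0 from x = 0 to x = len (built from >= 4
# collinear points so the spline path is exercised)
straight_midline <- function(len, y0 = 0) {
  pts <- cbind(x = seq(0, len, length.out = 9L), y = rep(y0, 9L))
  fit_midline_spline(pts)
}

n_components <- function(m) {
  max(EBImage::bwlabel(EBImage::Image(t(m))))
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
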