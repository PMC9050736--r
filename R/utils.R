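`%||%` <- function(a, b) if (is.null(a)) b else a

# matrix [y, x] <-> EBImage layout [x, y]
.as_eb <- function(m) EBImage::Image(t(m))
.from_eb <- function(img) t(EBImage::imageData(img))

#' Bilinear interpolation of a 2-D lattice
#'
#' Samples a matrix at fractional 0-based pixel coordinates (pixel centers at
#' integer coordinates). Coordinates outside the lattice return 0, so a mask
#' sampled beyond the image border reads as background.
#'
#' @param m numeric matrix indexed `[y, x]`.
#' @param x_px,y_px numeric vectors of 0-based pixel coordinates.
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(m, x_px, y_px) {
  ny <- nrow(m)
  nx <- ncol(m)
  x0 <- floor(x_px)
  y0 <- floor(y_px)
  fx <- x_px - x0
  fy <- y_px - y0
  get <- function(ix, iy) {
    v <- numeric(length(ix))
    ok <- ix >= 0 & ix <= nx - 1 & iy >= 0 & iy <= ny - 1
    if (any(ok)) v[ok] <- m[cbind(iy[ok] + 1L, ix[ok] + 1L)]
    v
  }
  (1 - fx) * (1 - fy) * get(x0, y0) +
    fx * (1 - fy) * get(x0 + 1, y0) +
    (1 - fx) * fy * get(x0, y0 + 1) +
    fx * fy * get(x0 + 1, y0 + 1)
}

# 8-neighborhood maximum of a matrix (excluding the center pixel)
.neighborhood_max <- function(m) {
  ny <- nrow(m)
  nx <- ncol(m)
  pad <- matrix(-Inf, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- m
  res <- matrix(-Inf, ny, nx)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      res <- pmax(res, pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx])
    }
  }
  res
}

# mean fraction of foreground 8-neighbors over foreground pixels: ~1 for a
# compact blob, ~foreground fraction for structureless noise
.foreground_coherence <- function(fg) {
  if (!any(fg)) return(0)
  ny <- nrow(fg); nx <- ncol(fg)
  pad <- matrix(0, ny + 2L, nx + 2L)
  pad[2:(ny + 1L), 2:(nx + 1L)] <- fg
  cnt <- matrix(0, ny, nx)
  for (dy in -1:1) {
    for (dx in -1:1) {
      if (dy == 0L && dx == 0L) next
      cnt <- cnt + pad[(2:(ny + 1L)) + dy, (2:(nx + 1L)) + dx]
    }
  }
  mean(cnt[fg]) / 8
}

# Two-direction Crofton perimeter estimate (exact for discs in the limit).
.crofton_perimeter <- function(m, px = 1) {
  m <- m != 0
  mp <- rbind(FALSE, cbind(FALSE, m, FALSE), FALSE)
  nx_trans <- sum(mp[, -1L] != mp[, -ncol(mp)])
  ny_trans <- sum(mp[-1L, ] != mp[-nrow(mp), ])
  (pi / 4) * (nx_trans + ny_trans) * px
}

#' Unwrap a phase series
#'
#' Removes 2*pi jumps from a wrapped phase sequence by accumulating wrapped
#' first differences.
#'
#' @param p numeric vector of phases in radians.
#' @return unwrapped phase vector of the same length.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1L], p[1L] + cumsum(dp))
}

# Analytic signal via FFT (one-sided spectrum doubling).
.analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    if (n > 2) h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each query point to a polyline given as an
#' ordered matrix of vertices. Used to score fitted midlines against a known
#' centerline.
#'
#' @param points n x 2 matrix of query points.
#' @param poly m x 2 matrix of polyline vertices (m >= 2).
#' @return numeric vector of n distances.
#' @export
polyline_distance <- function(points, poly) {
  points <- rbind(points)
  stopifnot(ncol(points) == 2L, ncol(poly) == 2L, nrow(poly) >= 2L)
  ax <- poly[-nrow(poly), 1L]; ay <- poly[-nrow(poly), 2L]
  bx <- poly[-1L, 1L]; by <- poly[-1L, 2L]
  dx <- bx - ax; dy <- by - ay
  len2 <- dx^2 + dy^2
  len2[len2 == 0] <- .Machine$double.eps
  vapply(seq_len(nrow(points)), function(i) {
    px <- points[i, 1L]; py <- points[i, 2L]
    t <- ((px - ax) * dx + (py - ay) * dy) / len2
    t <- pmin(pmax(t, 0), 1)
    min(sqrt((ax + t * dx - px)^2 + (ay + t * dy - py)^2))
  }, numeric(1L))
}

# shared 1-D extrema finder with prominence and minimum-separation filters;
# plateaus are resolved to their midpoint.  Returns fractional indices.
.find_extrema_1d <- function(w, min_prominence = 0, min_separation = 0,
                             discard_ends = FALSE) {
  find_max <- function(v) {
    r <- rle(v)
    k <- length(r$values)
    if (k < 3L) return(list(idx = numeric(0), height = numeric(0)))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    is_max <- logical(k)
    for (j in 2:(k - 1L)) {
      is_max[j] <- r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]
    }
    j <- which(is_max)
    idx <- (starts[j] + ends[j]) / 2
    height <- r$values[j]
    # prominence: on each side, min value until a strictly higher point (or end)
    prom <- vapply(seq_along(j), function(q) {
      i0 <- starts[j[q]]; h <- height[q]
      left <- v[seq_len(i0 - 1L)]
      higher <- which(left > h)
      lmin <- if (length(higher)) min(left[(max(higher) + 1L):(i0 - 1L)]) else min(left)
      i1 <- ends[j[q]]
      right <- v[(i1 + 1L):length(v)]
      higher <- which(right > h)
      rmin <- if (length(higher)) min(right[seq_len(min(higher) - 1L)]) else min(right)
      h - max(lmin, rmin)
    }, numeric(1L))
    keep <- prom >= min_prominence
    idx <- idx[keep]; height <- height[keep]
    # separation filter: keep tallest first
    if (min_separation > 0 && length(idx) > 1L) {
      ord <- order(height, decreasing = TRUE)
      kept <- numeric(0)
      for (q in ord) {
        if (!length(kept) || all(abs(idx[q] - kept) >= min_separation)) {
          kept <- c(kept, idx[q])
        }
      }
      sel <- idx %in% kept
      idx <- idx[sel]; height <- height[sel]
    }
    o <- order(idx)
    list(idx = idx[o], height = height[o])
  }
  mx <- find_max(w)
  mn <- find_max(-w)
  mn$height <- -mn$height
  if (discard_ends && min_separation > 0) {
    n <- length(w)
    keep_range <- function(e) {
      sel <- e$idx > min_separation & e$idx < n + 1 - min_separation
      list(idx = e$idx[sel], height = e$height[sel])
    }
    mx <- keep_range(mx)
    mn <- keep_range(mn)
  }
  # enforce alternation: between two maxima keep the higher, between two
  # minima keep the lower
  if (length(mx$idx) + length(mn$idx) > 1L) {
    typ <- c(rep(1L, length(mx$idx)), rep(-1L, length(mn$idx)))
    pos <- c(mx$idx, mn$idx)
    hei <- c(mx$height, mn$height)
    o <- order(pos)
    typ <- typ[o]; pos <- pos[o]; hei <- hei[o]
    keep <- rep(TRUE, length(pos))
    i <- 1L
    while (i < length(pos)) {
      nxt <- which(keep & seq_along(pos) > i)
      if (!length(nxt)) break
      j <- nxt[1L]
      if (typ[i] == typ[j]) {
        if (typ[i] == 1L) {
          if (hei[i] >= hei[j]) keep[j] <- FALSE else { keep[i] <- FALSE; i <- j }
        } else {
          if (hei[i] <= hei[j]) keep[j] <- FALSE else { keep[i] <- FALSE; i <- j }
        }
      } else {
        i <- j
      }
    }
    typ <- typ[keep]; pos <- pos[keep]
    mx <- list(idx = pos[typ == 1L])
    mn <- list(idx = pos[typ == -1L])
  }
  list(maxima = mx$idx, minima = mn$idx)
}
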