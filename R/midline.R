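# Midline extraction -----------------------------------------------------

#' Ridge points of a body mask
#'
#' Computes the Euclidean distance transform of the mask and returns its
#' local maxima (8-neighborhood, plateaus included): a disordered cloud of
#' points lying along the medial axis of the body. Shallow maxima closer to
#' the boundary than `min_radius` are discarded, which suppresses the spur
#' branches that ragged boundaries contribute to the medial axis; if that
#' filter removes everything the unfiltered maxima are returned instead so
#' thin shapes remain usable.
#'
#' Along a tapering body the EDT grows slowly toward the wide end, so exact
#' maxima are sparse; a point qualifies when its EDT is within `ridge_tol`
#' pixels of its 8-neighborhood maximum, which keeps points within half a
#' pixel of the medial ridge (where the EDT gradient vanishes) while
#' excluding off-ridge points, whose EDT drops by about one pixel per pixel.
#'
#' @param mask a cleaned 2-D [labeled_mask] with a single main component.
#' @param min_radius minimum EDT value (micrometres) for a ridge point.
#' @param ridge_tol ridge tolerance in pixels.
#' @return n x 2 matrix of point coordinates `(x, y)` in micrometres, with
#'   attribute `degenerate = TRUE` when the mask has no interior (1 px wide).
#' @export
midline_ridge_points <- function(mask, min_radius = 5, ridge_tol = 0.5) {
  stopifnot(inherits(mask, "labeled_mask"))
  m <- mask$mask
  if (length(dim(m)) != 2L) stop("midline_ridge_points expects a 2-D mask")
  if (!any(m)) stop("empty mask")
  ps <- mask$pixel_size
  if (abs(ps[1L] - ps[2L]) > 1e-9) stop("midline extraction requires isotropic pixels")
  px <- unname(ps[1L])
  edt <- .from_eb(EBImage::distmap(.as_eb(m))) * px
  nbr <- .neighborhood_max(edt)
  cand <- m & edt >= nbr - ridge_tol * px & edt > 0
  sel <- cand & edt >= min_radius
  if (!any(sel)) sel <- cand
  degenerate <- max(edt) <= px
  idx <- which(sel, arr.ind = TRUE)
  pts <- cbind(x = (idx[, 2L] - 1) * px, y = (idx[, 1L] - 1) * px)
  attr(pts, "degenerate") <- degenerate
  pts
}

#' Order midline points from posterior to anterior
#'
#' Greedy nearest-neighbor chaining seeded at the ridge point closest to the
#' posterior anchor and walked until no unvisited point lies within the
#' capture radius; points never reached (outliers off the midline) are
#' dropped. The anchors themselves are prepended/appended so the chain spans
#' tip to tip. The capture radius defaults to 3x the median nearest-neighbor
#' distance of the cloud, floored at 80 um: the EDT ridge is dense along a
#' tapering body but sparse across somite interiors (essentially one point
#' cluster per somite center), so the chain must bridge gaps up to about
#' half a somite diameter (up to ~70 um for the largest somites). `anchor_capture` bounds how far an anchor may sit
#' from the nearest ridge point (ridge points end roughly one local
#' half-width short of the tissue tips).
#'
#' @param points n x 2 matrix `(x, y)` in micrometres.
#' @param posterior_anchor,anterior_anchor length-2 numeric `(x, y)` in
#'   micrometres.
#' @param capture chaining capture radius (um); `NULL` for the default.
#' @param anchor_capture maximum anchor-to-cloud distance (um).
#' @param include_anchors prepend/append the anchors to the returned chain.
#' @return list with `points` (ordered matrix), `order` (chain order as row
#'   indices into `points`), and `dropped` (indices of discarded outliers).
#' @export
order_midline_points <- function(points, posterior_anchor, anterior_anchor,
                                 capture = NULL, anchor_capture = 100,
                                 include_anchors = TRUE) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < 2L) stop("need at least 2 points")
  d_post <- sqrt((points[, 1L] - posterior_anchor[1L])^2 +
                 (points[, 2L] - posterior_anchor[2L])^2)
  d_ant <- sqrt((points[, 1L] - anterior_anchor[1L])^2 +
                (points[, 2L] - anterior_anchor[2L])^2)
  if (min(d_post) > anchor_capture) {
    stop("posterior anchor is ", round(min(d_post), 1),
         " um from the nearest point (capture ", anchor_capture, " um)")
  }
  if (min(d_ant) > anchor_capture) {
    stop("anterior anchor is ", round(min(d_ant), 1),
         " um from the nearest point (capture ", anchor_capture, " um)")
  }
  D <- as.matrix(stats::dist(points))
  diag(D) <- Inf
  if (is.null(capture)) {
    nn <- apply(D, 1L, min)
    capture <- max(3 * stats::median(nn), 80)
  }
  ord <- integer(n)
  visited <- logical(n)
  cur <- which.min(d_post)
  ord[1L] <- cur
  visited[cur] <- TRUE
  k <- 1L
  repeat {
    d <- D[cur, ]
    d[visited] <- Inf
    nxt <- which.min(d)
    if (!is.finite(d[nxt]) || d[nxt] > capture) break
    k <- k + 1L
    ord[k] <- nxt
    visited[nxt] <- TRUE
    cur <- nxt
  }
  ord <- ord[seq_len(k)]
  chain <- points[ord, , drop = FALSE]
  if (include_anchors) {
    chain <- rbind(matrix(posterior_anchor, 1L), chain,
                   matrix(anterior_anchor, 1L))
  }
  colnames(chain) <- c("x", "y")
  list(points = chain, order = ord, dropped = which(!visited),
       capture = capture)
}

# evaluate a fitted per-coordinate smoothing-spline pair
.eval_curve <- function(fx, fy, t) {
  cbind(x = stats::predict(fx, t)$y, y = stats::predict(fy, t)$y)
}

#' Fit a smoothed midline curve through ordered points
#'
#' Cubic smoothing spline per coordinate against a chord-length parameter.
#' The ordered chain is first resampled to a fixed 0.5 um spacing so the
#' smoothing budget has a sampling-independent meaning; the penalty is then
#' chosen by bisection as the largest value whose total squared residual
#' stays within `smoothing` (i.e. the smoothest curve consistent with the
#' budget). The fit is trimmed in two robust passes: samples farther than
#' `pretrim` from a maximally smoothed reference curve are discarded first
#' (the medial axis of a bilaterally paired string branches to the two
#' off-axis somite centers, and because those branches are mirror-symmetric
#' the smooth reference stays on the central axis), then samples deviating
#' from the budget fit by more than `outlier_threshold` are dropped and the
#' spline refitted once. Fewer than 4 points fall back to the raw polyline
#' with a warning. The returned curve is resampled uniformly in arc length.
#'
#' @param ordered_points n x 2 matrix `(x, y)` in micrometres, posterior
#'   first.
#' @param smoothing residual budget in um^2 (default 10000).
#' @param resample_step arc-length sampling step of the returned curve (um).
#' @param pretrim residual (um) against the smooth reference beyond which a
#'   sample is discarded before fitting (about half the smallest somite
#'   radius; must exceed the expected midline curvature amplitude).
#' @param outlier_threshold residual (um) beyond which a sample is dropped
#'   in the single refit pass.
#' @return an object of class `midline_curve` with `points`, `arc_length`
#'   (cumulative, from the posterior end), `tangents`, `normals`,
#'   `total_length`, `step` and the smoothing parameters used.
#' @export
fit_midline_spline <- function(ordered_points, smoothing = 10000,
                               resample_step = 0.5, pretrim = 25,
                               outlier_threshold = 10) {
  pts <- rbind(ordered_points)
  n <- nrow(pts)
  if (n < 2L) stop("need at least 2 points")
  seg <- sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)
  keep <- c(TRUE, seg > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  n <- nrow(pts)
  tt <- c(0, cumsum(sqrt(diff(pts[, 1L])^2 + diff(pts[, 2L])^2)))
  if (n < 4L) {
    warning("fewer than 4 points: falling back to a polyline midline")
    dense_t <- sort(unique(c(seq(0, tt[n], by = resample_step), tt[n])))
    dense <- cbind(x = stats::approx(tt, pts[, 1L], dense_t)$y,
                   y = stats::approx(tt, pts[, 2L], dense_t)$y)
    return(.midline_from_dense(dense, resample_step, smoothing, NA_real_))
  }
  # standardize sampling density before fitting
  ut <- seq(0, tt[n], by = resample_step)
  ux <- stats::approx(tt, pts[, 1L], ut)$y
  uy <- stats::approx(tt, pts[, 2L], ut)$y
  budget_fit <- function(tt_f, xx_f, yy_f) {
    fit_at <- function(spar) {
      fx <- stats::smooth.spline(tt_f, xx_f, spar = spar, cv = FALSE,
                                 keep.data = FALSE)
      fy <- stats::smooth.spline(tt_f, yy_f, spar = spar, cv = FALSE,
                                 keep.data = FALSE)
      rss <- sum((stats::predict(fx, tt_f)$y - xx_f)^2) +
             sum((stats::predict(fy, tt_f)$y - yy_f)^2)
      list(fx = fx, fy = fy, rss = rss)
    }
    lo <- -1.5; hi <- 1.5
    f_hi <- fit_at(hi)
    if (f_hi$rss <= smoothing) return(c(f_hi, spar = hi))
    while (hi - lo > 0.01) {
      mid <- (lo + hi) / 2
      f <- fit_at(mid)
      if (f$rss <= smoothing) lo <- mid else hi <- mid
    }
    c(fit_at(lo), spar = lo)
  }
  # pass 1: trim against a maximally smooth reference
  rfx <- stats::smooth.spline(ut, ux, spar = 1.5, cv = FALSE, keep.data = FALSE)
  rfy <- stats::smooth.spline(ut, uy, spar = 1.5, cv = FALSE, keep.data = FALSE)
  r0 <- sqrt((stats::predict(rfx, ut)$y - ux)^2 +
             (stats::predict(rfy, ut)$y - uy)^2)
  keep1 <- r0 <= pretrim
  if (sum(keep1) < 10L) keep1 <- rep(TRUE, length(ut))
  best <- budget_fit(ut[keep1], ux[keep1], uy[keep1])
  # pass 2: fine rejection against the budget fit
  resid <- sqrt((stats::predict(best$fx, ut[keep1])$y - ux[keep1])^2 +
                (stats::predict(best$fy, ut[keep1])$y - uy[keep1])^2)
  keep2 <- resid <= outlier_threshold
  if (any(!keep2) && sum(keep2) >= 10L) {
    best <- budget_fit(ut[keep1][keep2], ux[keep1][keep2], uy[keep1][keep2])
  }
  dense <- .eval_curve(best$fx, best$fy, ut)
  .midline_from_dense(dense, resample_step, smoothing, best$spar)
}

# build the arc-length-parameterized curve object from dense samples
.midline_from_dense <- function(dense, step, smoothing, spar) {
  seg <- sqrt(diff(dense[, 1L])^2 + diff(dense[, 2L])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  su <- seq(0, total, by = step)
  if (su[length(su)] < total) su <- c(su, total)
  px <- stats::approx(s, dense[, 1L], su)$y
  py <- stats::approx(s, dense[, 2L], su)$y
  pts <- cbind(x = px, y = py)
  m <- nrow(pts)
  tx <- numeric(m); ty <- numeric(m)
  tx[2:(m - 1L)] <- pts[3:m, 1L] - pts[1:(m - 2L), 1L]
  ty[2:(m - 1L)] <- pts[3:m, 2L] - pts[1:(m - 2L), 2L]
  tx[1L] <- pts[2L, 1L] - pts[1L, 1L]; ty[1L] <- pts[2L, 2L] - pts[1L, 2L]
  tx[m] <- pts[m, 1L] - pts[m - 1L, 1L]; ty[m] <- pts[m, 2L] - pts[m - 1L, 2L]
  nrm <- sqrt(tx^2 + ty^2)
  nrm[nrm == 0] <- 1
  tx <- tx / nrm; ty <- ty / nrm
  structure(list(points = pts, arc_length = su,
                 tangents = cbind(x = tx, y = ty),
                 normals = cbind(x = -ty, y = tx),
                 total_length = total, step = step,
                 smoothing = smoothing, spar = spar),
            class = "midline_curve")
}

#' @export
print.midline_curve <- function(x, ...) {
  cat("<midline_curve> length:", round(x$total_length, 1), "um,",
      nrow(x$points), "samples at", x$step, "um\n")
  invisible(x)
}

#' Evaluate a midline curve at given arc lengths
#'
#' Linear interpolation of position, tangent and normal at arbitrary arc
#' lengths along the curve.
#'
#' @param curve a `midline_curve`.
#' @param s numeric vector of arc lengths in `[0, total_length]` (um).
#' @return list of matrices `point`, `tangent`, `normal` (one row per `s`).
#' @export
midline_eval <- function(curve, s) {
  stopifnot(inherits(curve, "midline_curve"))
  s <- pmin(pmax(s, 0), curve$total_length)
  interp <- function(mat) {
    cbind(x = stats::approx(curve$arc_length, mat[, 1L], s)$y,
          y = stats::approx(curve$arc_length, mat[, 2L], s)$y)
  }
  tan <- interp(curve$tangents)
  nrm <- sqrt(tan[, 1L]^2 + tan[, 2L]^2)
  tan <- tan / nrm
  list(point = interp(curve$points), tangent = tan,
       normal = cbind(x = -tan[, 2L], y = tan[, 1L]))
}
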