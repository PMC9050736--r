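# Width profile and somite calling ---------------------------------------

# march rays from points along dirs until the bilinearly interpolated mask
# drops below 0.5; two-stage (coarse then refined) search.
.ray_exit_distance <- function(m, px, points, dirs, coarse = 1, fine = 0.1,
                               max_range = NULL) {
  n <- nrow(points)
  if (is.null(max_range)) {
    max_range <- sqrt((nrow(m) * px)^2 + (ncol(m) * px)^2)
  }
  tcoarse <- seq(0, max_range, by = coarse)
  nc <- length(tcoarse)
  dist <- numeric(n)
  border <- logical(n)
  block <- 256L
  for (b in seq(1L, n, by = block)) {
    rows <- b:min(b + block - 1L, n)
    X <- points[rows, 1L] + outer(dirs[rows, 1L], tcoarse)
    Y <- points[rows, 2L] + outer(dirs[rows, 2L], tcoarse)
    V <- matrix(bilinear_sample(m, as.vector(X) / px, as.vector(Y) / px),
                nrow = length(rows))
    inside <- V >= 0.5
    first_out <- apply(inside, 1L, function(z) {
      w <- which(!z)
      if (length(w)) w[1L] else NA_integer_
    })
    for (q in seq_along(rows)) {
      i <- rows[q]
      fo <- first_out[q]
      if (is.na(fo)) {
        dist[i] <- max_range
        border[i] <- TRUE
        next
      }
      # refine from three coarse steps back: a grazing boundary can dip
      # below the half level briefly and re-enter before the definitive
      # exit, and the first crossing may precede the first coarse-outside
      # sample by more than one coarse interval
      t0 <- max(0, tcoarse[fo] - 3 * coarse)
      tf <- seq(t0, tcoarse[fo], by = fine)
      xv <- points[i, 1L] + dirs[i, 1L] * tf
      yv <- points[i, 2L] + dirs[i, 2L] * tf
      vv <- bilinear_sample(m, xv / px, yv / px)
      k <- which(vv < 0.5)
      if (!length(k)) {
        dist[i] <- tcoarse[fo]
        next
      }
      k <- k[1L]
      if (k == 1L) {
        dist[i] <- tf[1L]
      } else {
        v1 <- vv[k - 1L]; v0 <- vv[k]
        frac <- if (v1 > v0) (v1 - 0.5) / (v1 - v0) else 0
        dist[i] <- tf[k - 1L] + frac * fine
      }
      # flag rays whose exit point lies at the image border
      ex <- c(points[i, 1L] + dirs[i, 1L] * dist[i],
              points[i, 2L] + dirs[i, 2L] * dist[i]) / px
      if (ex[1L] <= 0.5 || ex[2L] <= 0.5 ||
          ex[1L] >= ncol(m) - 1.5 || ex[2L] >= nrow(m) - 1.5) {
        border[i] <- TRUE
      }
    }
  }
  list(dist = dist, border = border)
}

#' Perpendicular width profile along a midline
#'
#' At uniformly spaced arc-length samples along the midline, rays are cast
#' along the positive and negative local normal until they exit the mask
#' (sub-pixel boundary by linear interpolation of the bilinearly sampled
#' mask edge); the width is the sum of the two ray lengths. Rays that never
#' exit inside the image are truncated at the border and flagged.
#'
#' @param mask a 2-D [labeled_mask].
#' @param midline a `midline_curve` lying inside the mask.
#' @param step arc-length sampling step in micrometres.
#' @return an object of class `width_profile`: list with `s` (arc length,
#'   um), `w` (width, um), `step` and logical `flagged` per sample.
#' @export
compute_width_profile <- function(mask, midline, step = 1) {
  stopifnot(inherits(mask, "labeled_mask"), inherits(midline, "midline_curve"))
  ps <- mask$pixel_size
  if (abs(ps[1L] - ps[2L]) > 1e-9) stop("width profile requires isotropic pixels")
  px <- unname(ps[1L])
  s <- seq(0, midline$total_length, by = step)
  ev <- midline_eval(midline, s)
  m <- mask$mask * 1
  plus <- .ray_exit_distance(m, px, ev$point, ev$normal)
  minus <- .ray_exit_distance(m, px, ev$point, -ev$normal)
  structure(list(s = s, w = plus$dist + minus$dist, step = step,
                 flagged = plus$border | minus$border),
            class = "width_profile")
}

#' @export
print.width_profile <- function(x, ...) {
  cat("<width_profile>", length(x$s), "samples over",
      round(max(x$s), 1), "um; width", round(min(x$w), 1), "-",
      round(max(x$w), 1), "um\n")
  invisible(x)
}

#' Extrema of a width profile
#'
#' Finds alternating minima and maxima of the width profile: somite-to-somite
#' edges (minima) and somite widths (maxima). Candidate extrema must clear a
#' prominence threshold and a minimum mutual separation; plateaus resolve to
#' their midpoint and extrema within `min_separation` of the profile ends
#' are discarded. Defaults reflect the somitoid scale (somite widths start
#' around 104 um, so a 40 um separation is about one third of a somite).
#'
#' Each extremum position is then refined to the midpoint of the contiguous
#' near-plateau region within `plateau_tol` of its extreme value: somite
#' necks are flat over tens of micrometres, and measurement roughness of a
#' micrometre or two would otherwise place the minimum anywhere on the
#' plateau.
#'
#' @param profile a `width_profile`.
#' @param min_prominence minimum prominence in micrometres.
#' @param min_separation minimum extrema separation in micrometres.
#' @param plateau_tol width tolerance (um) for the plateau-midpoint
#'   refinement.
#' @return list with numeric vectors `minima` and `maxima` of arc-length
#'   positions (um); either may be empty.
#' @export
find_profile_extrema <- function(profile, min_prominence = 10,
                                 min_separation = 40, plateau_tol = 2) {
  stopifnot(inherits(profile, "width_profile"))
  if (max(profile$s) <= 2 * min_separation) {
    stop("profile shorter than twice the minimum separation")
  }
  sep_samples <- min_separation / profile$step
  ex <- .find_extrema_1d(profile$w, min_prominence, sep_samples,
                         discard_ends = TRUE)
  w <- profile$w
  n <- length(w)
  refine <- function(idx, sign) {
    vapply(idx, function(i0) {
      i <- as.integer(round(i0))
      v0 <- w[i]
      near <- sign * (w - v0) >= -plateau_tol
      a <- i
      while (a > 1L && near[a - 1L]) a <- a - 1L
      b <- i
      while (b < n && near[b + 1L]) b <- b + 1L
      (a + b) / 2
    }, numeric(1L))
  }
  to_s <- function(idx) profile$s[1L] + (idx - 1) * profile$step
  list(minima = to_s(refine(ex$minima, -1)),
       maxima = to_s(refine(ex$maxima, 1)))
}

#' Ellipse-model somite shape statistics
#'
#' Somite area and circularity from the inter-somite distance (length) and
#' the somite width, modeling the somite outline as an ellipse with those
#' axes: area = pi * L * W / 4; circularity = 4 * pi * area / perimeter^2
#' with the perimeter from Ramanujan's approximation. Circularity is 1
#' exactly when length equals width.
#'
#' @param length,width somite length and width in micrometres (> 0).
#' @return named list `area_um2`, `circularity`.
#' @export
somite_shape_stats <- function(length, width) {
  if (any(length <= 0) || any(width <= 0)) stop("length and width must be > 0")
  a <- length / 2
  b <- width / 2
  area <- pi * a * b
  h <- ((a - b) / (a + b))^2
  perim <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  list(area_um2 = area, circularity = 4 * pi * area / perim^2)
}

#' Call somites from width-profile extrema
#'
#' One somite per width maximum bracketed by two minima, indexed from the
#' posterior end (index 1 = newest somite). The posterior-most body region
#' (NMP + PSM) is never called: its width maximum lacks a posterior bounding
#' minimum. The anterior-most somite often lacks an anterior minimum because
#' the profile simply ends; when `end_cap` is enabled a virtual boundary is
#' placed where the profile first drops below `end_cap_frac` of that
#' maximum (or at the profile end), and the call is flagged `end_capped`.
#'
#' @param profile a `width_profile`.
#' @param extrema output of [find_profile_extrema()].
#' @param end_cap recover the anterior-most somite with a virtual boundary.
#' @param end_cap_frac drop fraction defining the virtual boundary.
#' @return data.frame with one row per somite: `index`, `s_start`, `s_peak`,
#'   `s_end`, `length_um`, `width_um`, `area_um2`, `circularity`,
#'   `end_capped`.
#' @export
call_somites <- function(profile, extrema, end_cap = TRUE,
                         end_cap_frac = 0.25) {
  stopifnot(inherits(profile, "width_profile"))
  maxima <- sort(extrema$maxima)
  minima <- sort(extrema$minima)
  rows <- list()
  w_at <- function(s) stats::approx(profile$s, profile$w, s, rule = 2)$y
  for (pk in maxima) {
    before <- minima[minima < pk]
    after <- minima[minima > pk]
    s_start <- if (length(before)) max(before) else NA_real_
    s_end <- if (length(after)) min(after) else NA_real_
    capped <- FALSE
    if (is.na(s_start)) next  # the body region: no posterior boundary
    if (is.na(s_end)) {
      if (!end_cap || pk < max(maxima)) next
      wp <- w_at(pk)
      beyond <- profile$s > pk & profile$w < end_cap_frac * wp
      s_end <- if (any(beyond)) profile$s[which(beyond)[1L]] else max(profile$s)
      capped <- TRUE
    }
    sel <- profile$s >= s_start & profile$s <= s_end
    width <- max(profile$w[sel])
    shape <- somite_shape_stats(s_end - s_start, width)
    rows[[length(rows) + 1L]] <- data.frame(
      s_start = s_start, s_peak = pk, s_end = s_end,
      length_um = s_end - s_start, width_um = width,
      area_um2 = shape$area_um2, circularity = shape$circularity,
      end_capped = capped)
  }
  if (!length(rows)) {
    return(data.frame(index = integer(0), s_start = numeric(0),
                      s_peak = numeric(0), s_end = numeric(0),
                      length_um = numeric(0), width_um = numeric(0),
                      area_um2 = numeric(0), circularity = numeric(0),
                      end_capped = logical(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$s_peak), , drop = FALSE]
  out <- cbind(index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Number of somite rows
#'
#' Counts somite calls. A left-right pair contributes a single row: the 2-D
#' projection of a paired string yields one width maximum per pair.
#'
#' @param calls data.frame from [call_somites()].
#' @return integer count.
#' @export
count_somite_rows <- function(calls) {
  nrow(calls)
}

#' First-somite geometry at the midline
#'
#' Intersects the annotated left-right (LR) segment with the midline. The
#' intersection point P gives the relative position (fraction of total arc
#' length from the posterior end); the formation angle is the unsigned angle
#' between the normal of the LR segment and the midline tangent at P,
#' computed as `acos(|n . t|)` so it lies in [0, 90] degrees. If the segment
#' does not cross the midline, the closest approach is used when within
#' `tol`, flagged; otherwise an error reports the distance.
#'
#' @param midline a `midline_curve`.
#' @param lr_segment 2 x 2 matrix: the two LR endpoints `(x, y)` in um.
#' @param tol closest-approach tolerance in micrometres.
#' @param frame,time optional annotation metadata passed through.
#' @return list: `relative_position`, `angle_deg`, `point`, `s`, `flagged`,
#'   `frame`, `time`.
#' @export
first_somite_metrics <- function(midline, lr_segment, tol = 5,
                                 frame = NA_integer_, time = NA_real_) {
  stopifnot(inherits(midline, "midline_curve"))
  lr <- rbind(lr_segment)
  if (nrow(lr) != 2L) stop("lr_segment must be two points")
  a <- lr[1L, ]; b <- lr[2L, ]
  pts <- midline$points
  s <- midline$arc_length
  # segment-segment crossings against each midline segment
  p1x <- pts[-nrow(pts), 1L]; p1y <- pts[-nrow(pts), 2L]
  p2x <- pts[-1L, 1L]; p2y <- pts[-1L, 2L]
  rx <- p2x - p1x; ry <- p2y - p1y
  qx <- b[1L] - a[1L]; qy <- b[2L] - a[2L]
  denom <- rx * qy - ry * qx
  t_num <- (a[1L] - p1x) * qy - (a[2L] - p1y) * qx
  u_num <- (a[1L] - p1x) * ry - (a[2L] - p1y) * rx
  with_tol <- abs(denom) > 1e-12
  t_par <- ifelse(with_tol, t_num / denom, NA_real_)
  u_par <- ifelse(with_tol, u_num / denom, NA_real_)
  hit <- which(!is.na(t_par) & t_par >= 0 & t_par <= 1 &
                 u_par >= 0 & u_par <= 1)
  flagged <- FALSE
  if (length(hit) > 1L) {
    stop("LR segment crosses the midline ", length(hit), " times; expected one")
  } else if (length(hit) == 1L) {
    i <- hit
    s_p <- s[i] + t_par[i] * (s[i + 1L] - s[i])
    p_pt <- c(p1x[i] + t_par[i] * rx[i], p1y[i] + t_par[i] * ry[i])
  } else {
    d <- polyline_distance(pts, lr)
    i <- which.min(d)
    if (d[i] > tol) {
      stop("LR segment does not cross the midline; closest approach ",
           round(d[i], 2), " um exceeds tolerance ", tol, " um")
    }
    s_p <- s[i]
    p_pt <- pts[i, ]
    flagged <- TRUE
  }
  tn <- midline_eval(midline, s_p)$tangent[1L, ]
  u <- c(qx, qy) / sqrt(qx^2 + qy^2)
  n_lr <- c(-u[2L], u[1L])
  ang <- acos(pmin(1, abs(sum(n_lr * tn)))) * 180 / pi
  list(relative_position = s_p / midline$total_length,
       angle_deg = ang, point = p_pt, s = s_p, flagged = flagged,
       frame = frame, time = time)
}
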