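# Segmentation-clock analysis --------------------------------------------

#' Translation registration of a reporter movie
#'
#' Keeps the tissue at the same position across frames by aligning the
#' centroid of the Otsu-thresholded foreground of every frame to that of the
#' first frame (integer-pixel translation; background fill is the frame's
#' sub-threshold median). Confidence is the spatial coherence of the
#' thresholded foreground (mean fraction of foreground 8-neighbors over
#' foreground pixels): near 1 for a compact tissue, near the foreground
#' fraction for structureless noise; frames below 0.6 are flagged
#' low-confidence.
#'
#' @param movie an [image_grid] of kind `"movie"` with at least 2 frames.
#' @return list: `movie` (registered), `shifts` data.frame with per-frame
#'   `dx_px`, `dy_px`, `confidence`, `low_confidence`.
#' @export
register_frames <- function(movie) {
  stopifnot(inherits(movie, "image_grid"))
  if (movie$kind != "movie") stop("register_frames expects a movie")
  nt <- dim(movie$data)[1L]
  if (nt < 2L) stop("need at least 2 frames")
  cents <- matrix(NA_real_, nt, 2L)
  confs <- numeric(nt)
  for (t in seq_len(nt)) {
    fr <- movie$data[t, , ]
    if (diff(range(fr)) == 0) stop("frame ", t, " is empty (constant)")
    thr <- threshold_value(fr, "otsu")
    fg <- fr > thr
    confs[t] <- .foreground_coherence(fg)
    idx <- which(fg, arr.ind = TRUE)
    cents[t, ] <- c(mean(idx[, 2L]), mean(idx[, 1L]))  # (x, y) in px
  }
  shifts <- round(sweep(cents, 2L, cents[1L, ]))
  out <- movie$data
  for (t in seq_len(nt)) {
    dx <- shifts[t, 1L]; dy <- shifts[t, 2L]
    if (dx == 0 && dy == 0) next
    fr <- movie$data[t, , ]
    fill <- stats::median(fr[fr <= threshold_value(fr, "otsu")])
    ny <- nrow(fr); nx <- ncol(fr)
    new <- matrix(fill, ny, nx)
    src_y <- seq_len(ny) + dy
    src_x <- seq_len(nx) + dx
    ok_y <- src_y >= 1 & src_y <= ny
    ok_x <- src_x >= 1 & src_x <= nx
    new[which(ok_y), which(ok_x)] <- fr[src_y[ok_y], src_x[ok_x]]
    out[t, , ] <- new
  }
  reg <- image_grid(out, movie$pixel_size, frame_interval = movie$frame_interval,
                    kind = "movie")
  list(movie = reg,
       shifts = data.frame(frame = seq_len(nt),
                           dx_px = shifts[, 1L], dy_px = shifts[, 2L],
                           confidence = confs,
                           low_confidence = confs < 0.6))
}

#' Build a kymograph along a posterior-anterior axis
#'
#' Each frame is median-filtered, then sampled along the axis polyline with
#' transverse averaging over +/- `half_width` along the local normal; one
#' kymograph row per frame, in temporal order (top row = first frame).
#'
#' @param movie an [image_grid] movie (registered).
#' @param axis k x 2 matrix of polyline points `(x, y)` in micrometres,
#'   posterior first.
#' @param half_width transverse averaging half-width in micrometres
#'   (0 = pure line sampling).
#' @param median_radius median filter radius in pixels (0 disables).
#' @param spatial_step sampling step along the axis (um); defaults to the
#'   pixel size.
#' @return object of class `kymograph_data`: `mat` (time x position),
#'   `frame_interval` (min), `spatial_step` (um), `positions` (um along the
#'   axis), `axis`, `half_width`.
#' @export
build_kymograph <- function(movie, axis, half_width = 20, median_radius = 3,
                            spatial_step = NULL) {
  stopifnot(inherits(movie, "image_grid"))
  if (movie$kind != "movie") stop("build_kymograph expects a movie")
  px <- unname(movie$pixel_size[["x"]])
  if (abs(px - movie$pixel_size[["y"]]) > 1e-9) stop("frames must be isotropic")
  spatial_step <- spatial_step %||% px
  axis <- rbind(axis)
  nt <- dim(movie$data)[1L]
  ny <- dim(movie$data)[2L]; nx <- dim(movie$data)[3L]
  if (any(axis[, 1L] < 0 | axis[, 1L] > (nx - 1) * px |
          axis[, 2L] < 0 | axis[, 2L] > (ny - 1) * px)) {
    stop("axis exits the image")
  }
  # resample the axis polyline at spatial_step
  seg <- sqrt(diff(axis[, 1L])^2 + diff(axis[, 2L])^2)
  cs <- c(0, cumsum(seg))
  pos <- seq(0, cs[length(cs)], by = spatial_step)
  ax <- stats::approx(cs, axis[, 1L], pos)$y
  ay <- stats::approx(cs, axis[, 2L], pos)$y
  # tangents / normals along the axis
  tx <- c(diff(ax), ax[length(ax)] - ax[length(ax) - 1L])
  ty <- c(diff(ay), ay[length(ay)] - ay[length(ay) - 1L])
  nn <- sqrt(tx^2 + ty^2); nn[nn == 0] <- 1
  nxv <- -ty / nn; nyv <- tx / nn
  offs <- if (half_width > 0) seq(-half_width, half_width, by = px) else 0
  XS <- outer(ax, rep(1, length(offs))) + outer(nxv, offs)
  YS <- outer(ay, rep(1, length(offs))) + outer(nyv, offs)
  mat <- matrix(NA_real_, nt, length(pos))
  for (t in seq_len(nt)) {
    fr <- movie$data[t, , ]
    if (median_radius > 0) {
      mx <- max(fr)
      if (mx > 0) {
        eb <- EBImage::medianFilter(.as_eb(fr / mx), as.integer(median_radius))
        fr <- .from_eb(eb) * mx
      }
    }
    v <- matrix(bilinear_sample(fr, as.vector(XS) / px, as.vector(YS) / px),
                nrow = length(pos))
    mat[t, ] <- rowMeans(v)
  }
  structure(list(mat = mat, frame_interval = movie$frame_interval,
                 spatial_step = spatial_step, positions = pos,
                 axis = axis, half_width = half_width),
            class = "kymograph_data")
}

#' @export
print.kymograph_data <- function(x, ...) {
  cat("<kymograph_data>", nrow(x$mat), "frames x", ncol(x$mat),
      "positions; dt =", x$frame_interval, "min\n")
  invisible(x)
}

#' Detrend an oscillation trace
#'
#' Subtracts a centered moving average (default 50-frame window); at the
#' edges the window shrinks symmetrically. Gaps (NA runs) up to `max_gap`
#' frames are linearly interpolated first; longer gaps raise an error
#' advising a segment split (see [trace_segments()]). The moving-average
#' filter passes a fraction of oscillations slower than the window, so
#' periods much longer than `window` frames are strongly attenuated.
#'
#' @param raw numeric intensity series.
#' @param window moving-average window in frames.
#' @param max_gap longest NA run to interpolate across.
#' @return detrended numeric series.
#' @export
detrend_trace <- function(raw, window = 50, max_gap = 3) {
  n <- length(raw)
  if (n <= window) stop("series length must exceed the detrending window")
  if (anyNA(raw)) {
    r <- rle(is.na(raw))
    if (any(r$values & r$lengths > max_gap)) {
      stop("gap longer than ", max_gap,
           " frames; split the trace into segments (trace_segments)")
    }
    ok <- which(!is.na(raw))
    raw <- stats::approx(ok, raw[ok], seq_len(n), rule = 2)$y
  }
  half <- floor(window / 2)
  cs <- cumsum(c(0, raw))
  trend <- vapply(seq_len(n), function(i) {
    k <- min(half, i - 1L, n - i)
    (cs[i + k + 1L] - cs[i - k]) / (2 * k + 1)
  }, numeric(1L))
  raw - trend
}

#' Split a gappy trace into analyzable segments
#'
#' Returns index ranges of contiguous runs separated by NA gaps longer than
#' `max_gap` frames; gaps within a run are short enough for interpolation.
#'
#' @param raw numeric series with NA gaps.
#' @param max_gap longest NA run to tolerate within a segment.
#' @return list of integer index vectors, one per segment.
#' @export
trace_segments <- function(raw, max_gap = 3) {
  n <- length(raw)
  isna <- is.na(raw)
  r <- rle(isna)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  brk <- which(r$values & r$lengths > max_gap)
  cuts <- c(0L, as.vector(rbind(starts[brk] - 1L, ends[brk])), n)
  segs <- list()
  for (i in seq(1L, length(cuts) - 1L, by = 2L)) {
    a <- cuts[i] + 1L; b <- cuts[i + 1L]
    if (b >= a) segs[[length(segs) + 1L]] <- a:b
  }
  Filter(function(ix) any(!isna[ix]), segs)
}

#' Instantaneous phase of a detrended trace
#'
#' Analytic-signal (Hilbert) phase of a zero-mean oscillation, unwrapped so
#' clean oscillations yield a monotonically increasing phase.
#'
#' @param detrended zero-mean numeric series.
#' @return unwrapped phase in radians.
#' @export
instantaneous_phase <- function(detrended) {
  if (all(detrended == 0)) stop("all-zero series has no phase")
  unwrap_phase(Arg(.analytic_signal(detrended)))
}

#' Peak-to-peak oscillation period
#'
#' Detects peaks and troughs of the detrended trace under prominence and
#' minimum-distance constraints and reports the mean successive peak-to-peak
#' interval in hours with its SD and count. Defaults: minimum distance half
#' the coarse period guess from the dominant FFT bin; minimum prominence
#' 0.3 x the SD of the trace. For detection the trace is first smoothed with
#' a short centered moving average (about a sixth of the coarse period) so
#' frame-to-frame noise does not jitter the located peak positions; a
#' symmetric smoother leaves the peaks of a clean oscillation in place.
#'
#' @param detrended zero-mean numeric series.
#' @param frame_interval minutes per frame.
#' @param min_prominence,min_distance overrides (intensity units / frames).
#' @param smooth_frames detection smoothing window in frames (1 disables);
#'   `NULL` for the period-scaled default.
#' @return object of class `oscillation_trace`: `period_h`, `period_sd_h`,
#'   `n_peaks`, `peak_times`, `trough_times` (minutes).
#' @export
peak_to_peak_period <- function(detrended, frame_interval,
                                min_prominence = NULL, min_distance = NULL,
                                smooth_frames = NULL) {
  n <- length(detrended)
  sp <- Mod(stats::fft(detrended - mean(detrended)))[2:floor(n / 2 + 1)]
  coarse_period <- n / which.max(sp)
  if (is.null(min_distance)) min_distance <- 0.5 * coarse_period
  if (is.null(smooth_frames)) {
    smooth_frames <- max(1L, round(coarse_period / 6))
  }
  x <- detrended
  if (smooth_frames > 1L) {
    half <- floor(smooth_frames / 2)
    cs <- cumsum(c(0, x))
    x <- vapply(seq_len(n), function(i) {
      k <- min(half, i - 1L, n - i)
      (cs[i + k + 1L] - cs[i - k]) / (2 * k + 1)
    }, numeric(1L))
  }
  if (is.null(min_prominence)) min_prominence <- 0.3 * stats::sd(x)
  ex <- .find_extrema_1d(x, min_prominence, min_distance,
                         discard_ends = FALSE)
  if (length(ex$maxima) < 2L) {
    stop("fewer than 2 peaks detected (", length(ex$maxima),
         " peak(s) at prominence ", signif(min_prominence, 3),
         ", distance ", signif(min_distance, 3), " frames)")
  }
  peak_times <- (ex$maxima - 1) * frame_interval
  trough_times <- (ex$minima - 1) * frame_interval
  intervals <- diff(peak_times)
  structure(list(period_h = mean(intervals) / 60,
                 period_sd_h = if (length(intervals) > 1L) stats::sd(intervals) / 60 else 0,
                 n_peaks = length(peak_times),
                 peak_times = peak_times, trough_times = trough_times),
            class = "oscillation_trace")
}

#' @export
print.oscillation_trace <- function(x, ...) {
  cat(sprintf("<oscillation_trace> period %.2f h (SD %.2f, %d peaks)\n",
              x$period_h, x$period_sd_h, x$n_peaks))
  invisible(x)
}

#' Posterior-anterior phase lag of a traveling wave
#'
#' Averages the kymograph over a posterior and an anterior region of
#' interest, detrends both traces, and reports the circular mean phase
#' difference converted to minutes through the posterior period estimate.
#' Positive lag means the posterior oscillation leads (a posterior-to-
#' anterior traveling wave). The phase difference is only defined modulo one
#' cycle, so the two regions should sit within half a spatial wavelength of
#' each other (as when comparing adjacent posterior and anterior PSM
#' regions); larger separations alias.
#'
#' @param kymo a `kymograph_data`.
#' @param posterior_roi,anterior_roi length-2 numeric ranges (um along the
#'   axis) defining the two regions.
#' @param window detrending window in frames.
#' @return list: `lag_min`, `phase_diff_rad`, `period_h`.
#' @export
phase_lag <- function(kymo, posterior_roi, anterior_roi, window = 50) {
  stopifnot(inherits(kymo, "kymograph_data"))
  roi_cols <- function(r) {
    sel <- which(kymo$positions >= min(r) & kymo$positions <= max(r))
    if (!length(sel)) stop("ROI [", min(r), ", ", max(r), "] um is outside the kymograph")
    sel
  }
  n <- nrow(kymo$mat)
  win <- min(window, n - 1L)
  tr_p <- detrend_trace(rowMeans(kymo$mat[, roi_cols(posterior_roi), drop = FALSE]), win)
  tr_a <- detrend_trace(rowMeans(kymo$mat[, roi_cols(anterior_roi), drop = FALSE]), win)
  per <- peak_to_peak_period(tr_p, kymo$frame_interval)  # errors if non-oscillatory
  ph_p <- instantaneous_phase(tr_p)
  ph_a <- instantaneous_phase(tr_a)
  interior <- seq(max(2L, ceiling(n * 0.1)), min(n - 1L, floor(n * 0.9)))
  dphi <- Arg(mean(exp(1i * (ph_p[interior] - ph_a[interior]))))
  list(lag_min = dphi / (2 * pi) * per$period_h * 60,
       phase_diff_rad = dphi, period_h = per$period_h)
}

#' Somite-formation period from annotated event times
#'
#' Mean successive interval of a strictly increasing series of somite
#' formation times, in hours, with SD and count.
#'
#' @param events numeric vector of event times in minutes, strictly
#'   increasing, length >= 2.
#' @return list: `period_h`, `period_sd_h`, `n_intervals`.
#' @export
event_period <- function(events) {
  if (length(events) < 2L) stop("need at least 2 events")
  if (any(diff(events) <= 0)) stop("event times must be strictly increasing")
  iv <- diff(events)
  list(period_h = mean(iv) / 60,
       period_sd_h = if (length(iv) > 1L) stats::sd(iv) / 60 else 0,
       n_intervals = length(iv))
}
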