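# Synthetic ground-truthed data ------------------------------------------

#' Specification of a synthetic somitoid
#'
#' Geometry and imaging parameters of a synthetic somitoid: an elongated
#' tapered body (posterior) continued by a string of ball-like somites
#' joined by a narrow neck, optionally as two mirrored rows (paired
#' somites), on a straight or sinusoidal midline. Defaults sit in the
#' measured somitoid regime: somite diameter 110 um with 10 um gaps
#' (center spacing = diameter + gap), a 300 x 150 um tapered body, imaged
#' at 1 um/px with additive Gaussian noise.
#'
#' @param n_somites number of somites (>= 0).
#' @param somite_diameter somite diameter in um; either a scalar or a vector
#'   of length `n_somites` (posterior first) for graded strings.
#' @param gap surface-to-surface gap between somites (um).
#' @param spacing center-to-center spacing (um) used when `somite_diameter`
#'   is a scalar; default `diameter + gap`. With vector diameters the
#'   spacing follows from consecutive radii plus the gap.
#' @param body_length,body_width body dimensions in um.
#' @param taper posterior tip width as a fraction of `body_width`.
#' @param neck_width width of the connecting neck (um); must stay below the
#'   somite diameter and the body width so profile minima are well defined.
#' @param paired mirror the somite row across the midline.
#' @param midline_shape `"straight"` or `"sinusoidal"`.
#' @param sin_amplitude,sin_wavelength sinusoidal midline parameters (um).
#' @param foreground,background,noise_sd intensity model (additive Gaussian).
#' @param pixel_size pixel size in um (isotropic).
#' @param margin canvas margin around the tissue (um).
#' @param seed RNG seed fixing all randomness.
#' @return object of class `somitoid_spec`.
#' @export
somitoid_spec <- function(n_somites = 8, somite_diameter = 110, gap = 10,
                          spacing = somite_diameter + gap,
                          body_length = 300, body_width = 150, taper = 0.5,
                          neck_width = 60, paired = FALSE,
                          midline_shape = c("straight", "sinusoidal"),
                          sin_amplitude = 15, sin_wavelength = 700,
                          foreground = 200, background = 20, noise_sd = 30,
                          pixel_size = 1, margin = 40, seed = 0) {
  midline_shape <- match.arg(midline_shape)
  stopifnot(n_somites >= 0, all(somite_diameter > 0), all(spacing > 0),
            body_length > 0, body_width > 0, taper > 0, taper <= 1,
            neck_width > 0, pixel_size > 0)
  if (n_somites > 0 && !length(somite_diameter) %in% c(1L, n_somites)) {
    stop("somite_diameter must be a scalar or one value per somite")
  }
  if (any(neck_width >= somite_diameter) || neck_width >= body_width) {
    stop("neck_width must be smaller than the somite diameter and body width")
  }
  if (n_somites > 0 && length(somite_diameter) == 1L &&
      spacing < somite_diameter) {
    stop("somites overlap: spacing < diameter")
  }
  structure(list(n_somites = n_somites, somite_diameter = somite_diameter,
                 gap = gap, spacing = spacing, body_length = body_length,
                 body_width = body_width, taper = taper,
                 neck_width = neck_width, paired = paired,
                 midline_shape = midline_shape,
                 sin_amplitude = sin_amplitude,
                 sin_wavelength = sin_wavelength,
                 foreground = foreground, background = background,
                 noise_sd = noise_sd, pixel_size = pixel_size,
                 margin = margin, seed = seed),
            class = "somitoid_spec")
}

# arc-length-parameterized centerline: returns a function s -> (x, y) and
# unit tangent, plus total reach needed
.make_centerline <- function(spec, s_max) {
  if (spec$midline_shape == "straight") {
    pos <- function(s) cbind(x = s, y = rep(0, length(s)))
    tan <- function(s) cbind(x = rep(1, length(s)), y = rep(0, length(s)))
    return(list(pos = pos, tan = tan))
  }
  A <- spec$sin_amplitude
  lam <- spec$sin_wavelength
  # arc length along y = A sin(2 pi x / lam): tabulate and invert
  xs <- seq(0, s_max * 1.2 + lam, by = 0.5)
  dy <- A * 2 * pi / lam * cos(2 * pi * xs / lam)
  ds <- sqrt(1 + dy^2)
  s_tab <- c(0, cumsum((ds[-1L] + ds[-length(ds)]) / 2 * diff(xs)))
  pos <- function(s) {
    x <- stats::approx(s_tab, xs, s, rule = 2)$y
    cbind(x = x, y = A * sin(2 * pi * x / lam))
  }
  tan <- function(s) {
    x <- stats::approx(s_tab, xs, s, rule = 2)$y
    d <- A * 2 * pi / lam * cos(2 * pi * x / lam)
    n <- sqrt(1 + d^2)
    cbind(x = 1 / n, y = d / n)
  }
  list(pos = pos, tan = tan)
}

# stamp a filled disc into a logical matrix (1-based indices, 0-based coords)
.stamp_disc <- function(mask, cx, cy, r, px) {
  ny <- nrow(mask); nx <- ncol(mask)
  i0 <- max(1L, floor((cy - r) / px) + 1L)
  i1 <- min(ny, ceiling((cy + r) / px) + 1L)
  j0 <- max(1L, floor((cx - r) / px) + 1L)
  j1 <- min(nx, ceiling((cx + r) / px) + 1L)
  if (i0 > i1 || j0 > j1) return(mask)
  yy <- ((i0:i1) - 1) * px
  xx <- ((j0:j1) - 1) * px
  d2 <- outer((yy - cy)^2, (xx - cx)^2, `+`)
  sub <- mask[i0:i1, j0:j1]
  sub[d2 <= r^2] <- TRUE
  mask[i0:i1, j0:j1] <- sub
  mask
}

#' Generate a synthetic somitoid image with ground truth
#'
#' Rasterizes the tissue described by a [somitoid_spec()] as a union of
#' discs stamped along the midline: a tapered capsule body, a neck band, and
#' the somite discs (mirrored across the midline when `paired`). Intensities
#' are foreground/background levels plus seeded additive Gaussian noise.
#'
#' @param spec a [somitoid_spec()].
#' @return list with `image` (an [image_grid]), `truth` (ground-truth
#'   record: `mask`, `centerline` (s, x, y in canvas coordinates),
#'   `somites` data.frame, `anchors`, `total_midline_length`, `spec`).
#' @export
generate_somitoid <- function(spec) {
  stopifnot(inherits(spec, "somitoid_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_size
  W2 <- spec$body_width / 2
  diam <- rep(spec$somite_diameter, length.out = max(spec$n_somites, 1L))
  d2v <- diam / 2
  Lb <- spec$body_length
  # somite centers along the centerline arc: consecutive surfaces `gap` apart
  body_tip_r <- spec$taper * W2       # posterior cap radius
  chain_start <- Lb + W2              # anterior edge of the body cap
  centers_s <- if (spec$n_somites > 0) {
    if (length(spec$somite_diameter) == 1L) {
      chain_start + spec$gap + d2v[1L] +
        (seq_len(spec$n_somites) - 1L) * spec$spacing
    } else {
      cs <- chain_start + spec$gap + d2v[1L]
      for (k in seq_len(spec$n_somites - 1L)) {
        cs <- c(cs, cs[k] + d2v[k] + spec$gap + d2v[k + 1L])
      }
      cs
    }
  } else numeric(0)
  s_end <- if (spec$n_somites > 0) max(centers_s) + d2v[spec$n_somites] else chain_start
  cl <- .make_centerline(spec, s_end)
  # canvas extent
  s_dense <- seq(0, s_end, by = 2)
  p_dense <- cl$pos(s_dense)
  max_r <- max(W2, max(d2v) * if (spec$paired) 2 else 1)
  xr <- range(p_dense[, 1L]) + c(-1, 1) * (max_r + spec$margin)
  yr <- range(p_dense[, 2L]) + c(-1, 1) * (max_r + spec$margin)
  offset <- c(xr[1L], yr[1L])
  nx <- ceiling((xr[2L] - xr[1L]) / px) + 1L
  ny <- ceiling((yr[2L] - yr[1L]) / px) + 1L
  to_canvas <- function(p) sweep(rbind(p), 2L, offset)
  mask <- matrix(FALSE, ny, nx)
  # body: tapered capsule (disc radius grows linearly along the body)
  body_s <- seq(0, Lb, by = 2)
  body_r <- W2 * (spec$taper + (1 - spec$taper) * body_s / Lb)
  bp <- to_canvas(cl$pos(body_s))
  for (i in seq_along(body_s)) {
    mask <- .stamp_disc(mask, bp[i, 1L], bp[i, 2L], body_r[i], px)
  }
  # neck band connecting the somite chain
  if (spec$n_somites > 0) {
    neck_s <- seq(Lb, max(centers_s), by = 2)
    np <- to_canvas(cl$pos(neck_s))
    for (i in seq_along(neck_s)) {
      mask <- .stamp_disc(mask, np[i, 1L], np[i, 2L], spec$neck_width / 2, px)
    }
    # somite discs
    cp <- to_canvas(cl$pos(centers_s))
    nv <- cl$tan(centers_s)
    nv <- cbind(-nv[, 2L], nv[, 1L])  # unit normal
    for (i in seq_along(centers_s)) {
      if (spec$paired) {
        off <- d2v[i]
        mask <- .stamp_disc(mask, cp[i, 1L] + off * nv[i, 1L],
                            cp[i, 2L] + off * nv[i, 2L], d2v[i], px)
        mask <- .stamp_disc(mask, cp[i, 1L] - off * nv[i, 1L],
                            cp[i, 2L] - off * nv[i, 2L], d2v[i], px)
      } else {
        mask <- .stamp_disc(mask, cp[i, 1L], cp[i, 2L], d2v[i], px)
      }
    }
  }
  img <- spec$background + (spec$foreground - spec$background) * mask +
    matrix(stats::rnorm(ny * nx, 0, spec$noise_sd), ny, nx)
  img[img < 0] <- 0
  # ground-truth midline spans tissue tip to tissue tip
  s_mid <- unique(c(seq(-body_tip_r, s_end, by = 1), s_end))
  mid <- to_canvas(.extend_centerline(cl, s_mid))
  anchors <- list(posterior = mid[1L, ], anterior = mid[nrow(mid), ])
  total_len <- s_end + body_tip_r
  somites <- if (spec$n_somites > 0) {
    s_from_tip <- centers_s + body_tip_r
    # boundaries: midpoints between consecutive centers; the string ends at
    # the anterior tip of the last somite
    gaps_half <- if (spec$n_somites > 1L) diff(s_from_tip) / 2 else numeric(0)
    s_start <- s_from_tip - c(d2v[1L] + spec$gap / 2, gaps_half)
    s_end <- s_from_tip + c(gaps_half, d2v[spec$n_somites])
    data.frame(index = seq_len(spec$n_somites),
               center_s = s_from_tip,
               s_start = s_start,
               s_end = s_end,
               diameter = diam,
               spacing = c(d2v[1L] + spec$gap / 2 + if (spec$n_somites > 1L)
                 gaps_half[1L] else d2v[1L],
                 s_end[-1L] - s_start[-1L]),
               width = diam * if (spec$paired) 2 else 1)
  } else {
    data.frame(index = integer(0), center_s = numeric(0), s_start = numeric(0),
               s_end = numeric(0), diameter = numeric(0), spacing = numeric(0),
               width = numeric(0))
  }
  truth <- list(mask = mask,
                centerline = cbind(s = s_mid + body_tip_r,
                                   x = mid[, 1L], y = mid[, 2L]),
                somites = somites, anchors = anchors,
                total_midline_length = total_len,
                spec = spec)
  list(image = image_grid(img, c(px, px)), truth = truth)
}

# evaluate the centerline at arc positions, extending linearly along the
# tangent for s < 0 (into the posterior cap)
.extend_centerline <- function(cl, s) {
  p <- cl$pos(pmax(s, 0))
  neg <- s < 0
  if (any(neg)) {
    t0 <- cl$tan(0)[1L, ]
    p0 <- cl$pos(0)[1L, ]
    p[neg, 1L] <- p0[1L] + s[neg] * t0[1L]
    p[neg, 2L] <- p0[2L] + s[neg] * t0[2L]
  }
  p
}

#' Place a left-right annotation segment on a synthetic somitoid
#'
#' Returns a two-point LR segment crossing the true midline at a given arc
#' fraction, optionally tilted away from the perpendicular, for testing
#' first-somite geometry.
#'
#' @param truth ground-truth record from [generate_somitoid()].
#' @param fraction arc fraction (0-1) from the posterior tip.
#' @param tilt_deg tilt from the perpendicular in degrees.
#' @param half_length half-length of the segment in um.
#' @return 2 x 2 matrix of `(x, y)` endpoints.
#' @export
generate_lr_segment <- function(truth, fraction, tilt_deg = 0,
                                half_length = 120) {
  cl <- truth$centerline
  s_target <- fraction * truth$total_midline_length
  x0 <- stats::approx(cl[, "s"], cl[, "x"], s_target)$y
  y0 <- stats::approx(cl[, "s"], cl[, "y"], s_target)$y
  eps <- 1
  x1 <- stats::approx(cl[, "s"], cl[, "x"], s_target + eps, rule = 2)$y
  y1 <- stats::approx(cl[, "s"], cl[, "y"], s_target + eps, rule = 2)$y
  tv <- c(x1 - x0, y1 - y0)
  tv <- tv / sqrt(sum(tv^2))
  nv <- c(-tv[2L], tv[1L])
  th <- tilt_deg * pi / 180
  dirv <- cos(th) * nv + sin(th) * tv
  rbind(c(x0, y0) - half_length * dirv,
        c(x0, y0) + half_length * dirv)
}

#' Specification of a synthetic segmentation-clock movie
#'
#' Traveling-wave reporter dynamics in the measured regime: a ~5 h (300 min)
#' period, posterior-to-anterior waves, 5-10 min frame intervals, with
#' optional somite events locked to successive oscillation peaks at the
#' anterior position.
#'
#' @param period oscillation period in minutes.
#' @param wavelength spatial wavelength in um (sign sets wave direction;
#'   positive travels posterior -> anterior).
#' @param amplitude,baseline,drift intensity model: `baseline + drift * t`
#'   plus the oscillation of the given amplitude.
#' @param noise_sd additive Gaussian noise SD.
#' @param n_frames,frame_interval movie length and cadence (frames, min).
#' @param body_length,body_width,pixel_size geometry of the rectangular
#'   tissue band (um).
#' @param events_on emit somite event times locked to oscillation peaks.
#' @param anterior_frac position (fraction of body length) where events are
#'   read out.
#' @param seed RNG seed.
#' @return object of class `clock_spec`.
#' @export
clock_spec <- function(period = 300, wavelength = 400, amplitude = 50,
                       baseline = 100, drift = 0.05, noise_sd = 0,
                       n_frames = 60, frame_interval = 10,
                       body_length = 500, body_width = 100, pixel_size = 2,
                       events_on = TRUE, anterior_frac = 0.8, seed = 0) {
  stopifnot(period > 2 * frame_interval, n_frames >= 2, amplitude > 0,
            wavelength != 0)
  structure(list(period = period, wavelength = wavelength,
                 amplitude = amplitude, baseline = baseline, drift = drift,
                 noise_sd = noise_sd, n_frames = n_frames,
                 frame_interval = frame_interval, body_length = body_length,
                 body_width = body_width, pixel_size = pixel_size,
                 events_on = events_on, anterior_frac = anterior_frac,
                 seed = seed),
            class = "clock_spec")
}

#' Generate a synthetic clock-reporter movie with ground truth
#'
#' Inside a rectangular tissue band, intensity follows
#' `baseline + drift * t + A * cos(2 pi (t / period - x / wavelength))` plus
#' seeded Gaussian noise; positive wavelength yields a wave traveling from
#' the posterior (x = 0 end of the band) to the anterior. With event
#' coupling on, somite event times are emitted at successive oscillation
#' peaks at the anterior read-out position (one somite per cycle).
#'
#' @param spec a [clock_spec()].
#' @return list with `movie` (an [image_grid] of kind `"movie"`), `truth`
#'   (`period`, `wavelength`, `velocity`, `lag_fun(x_post, x_ant)` in
#'   minutes, `events` (min), `body_x` band limits (um), `spec`).
#' @export
generate_clock_movie <- function(spec) {
  stopifnot(inherits(spec, "clock_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_size
  margin <- 40
  nx <- ceiling((spec$body_length + 2 * margin) / px)
  ny <- ceiling((spec$body_width + 2 * margin) / px)
  x_um <- ((seq_len(nx)) - 1) * px
  y_um <- ((seq_len(ny)) - 1) * px
  x0 <- margin
  x1 <- margin + spec$body_length
  in_x <- x_um >= x0 & x_um <= x1
  in_y <- y_um >= margin & y_um <= margin + spec$body_width
  body <- outer(in_y, in_x, `&`)
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  dat <- array(0, c(spec$n_frames, ny, nx))
  phase_x <- outer(rep(1, ny), (x_um - x0) / spec$wavelength)
  for (k in seq_len(spec$n_frames)) {
    t <- times[k]
    osc <- spec$baseline + spec$drift * t +
      spec$amplitude * cos(2 * pi * (t / spec$period - phase_x))
    fr <- ifelse(body, osc, 5)
    if (spec$noise_sd > 0) {
      fr <- fr + matrix(stats::rnorm(ny * nx, 0, spec$noise_sd), ny, nx)
    }
    fr[fr < 0] <- 0
    dat[k, , ] <- fr
  }
  v <- spec$wavelength / spec$period  # um/min, signed
  lag_fun <- function(x_post, x_ant) (x_ant - x_post) / v
  events <- numeric(0)
  if (spec$events_on) {
    x_e <- spec$anterior_frac * spec$body_length
    # peaks at t = period * (k + x_e / wavelength)
    k0 <- ceiling(-x_e / spec$wavelength)
    tk <- spec$period * (k0:(k0 + 100) + x_e / spec$wavelength)
    events <- tk[tk >= 0 & tk <= max(times)]
  }
  movie <- image_grid(dat, c(px, px), frame_interval = spec$frame_interval,
                      kind = "movie")
  list(movie = movie,
       truth = list(period = spec$period, wavelength = spec$wavelength,
                    velocity = v, lag_fun = lag_fun, events = events,
                    body_x = c(x0, x1), spec = spec))
}

#' Generate somite-formation event times
#'
#' Events at `k * period + jitter`, jitter ~ Normal(0, sd), sorted, seeded.
#'
#' @param period mean interval in minutes.
#' @param jitter_sd Gaussian jitter SD in minutes.
#' @param n number of events (>= 1).
#' @param seed RNG seed.
#' @return sorted numeric vector of event times (minutes).
#' @export
generate_event_times <- function(period = 300, jitter_sd = 0, n = 4,
                                 seed = 0) {
  stopifnot(n >= 1)
  set.seed(seed)
  sort(seq_len(n) * period + stats::rnorm(n, 0, jitter_sd))
}

#' Generate a synthetic 3-D HCR stack with ground truth
#'
#' A spherocylindrical body along the x axis carries three channels laid out
#' posterior to anterior: a SOX2+/BRACHYURY+ double-positive posterior cap
#' (NMP), a BRACHYURY+ band (PSM), and an anterior region with UNCX4.1+
#' somites (spheres on the axis, or a full band) plus a dorsal SOX2+ slab
#' (neural). Voxels are anisotropic (default Z = 2, XY = 0.391 um).
#'
#' @param body_length,body_radius body geometry in um.
#' @param f_nmp,f_psm axial fractions of the NMP cap and PSM band
#'   (fractions must sum to <= 1; the remainder is the somite region).
#' @param somite_mode `"spheres"` or `"band"`; `"band"` makes the channels
#'   jointly tile the body.
#' @param n_spheres,sphere_radius somite sphere layout (um).
#' @param voxel per-axis voxel size `c(z, y, x)` in um.
#' @param foreground,background,noise_sd channel intensity model.
#' @param seed RNG seed.
#' @return list with `stack` (an [image_grid] of kind `"stack3d"`, channels
#'   SOX2, BRACHYURY, UNCX4.1) and `truth` (per-channel and per-domain
#'   logical arrays, voxel-counted volumes in um^3, analytic body volume,
#'   parameters).
#' @export
generate_hcr_stack <- function(body_length = 110, body_radius = 35,
                               f_nmp = 0.25, f_psm = 0.35,
                               somite_mode = c("spheres", "band"),
                               n_spheres = 3, sphere_radius = 14,
                               voxel = c(z = 2, y = 0.391, x = 0.391),
                               foreground = 200, background = 10,
                               noise_sd = 0, seed = 0) {
  somite_mode <- match.arg(somite_mode)
  if (f_nmp < 0 || f_psm < 0 || f_nmp + f_psm > 1) {
    stop("layout fractions must be >= 0 and sum to <= 1")
  }
  set.seed(seed)
  vz <- voxel[[1L]]; vy <- voxel[[2L]]; vx <- voxel[[3L]]
  margin <- 6
  nz <- ceiling((2 * body_radius + 2 * margin) / vz)
  nyv <- ceiling((2 * body_radius + 2 * margin) / vy)
  nxv <- ceiling((body_length + 2 * margin) / vx)
  zc <- (nz - 1) * vz / 2
  yc <- (nyv - 1) * vy / 2
  z_um <- ((seq_len(nz)) - 1) * vz
  y_um <- ((seq_len(nyv)) - 1) * vy
  x_um <- ((seq_len(nxv)) - 1) * vx
  x0 <- margin
  # spherocylinder: hemispherical caps at both ends
  ax_lo <- x0 + body_radius
  ax_hi <- x0 + body_length - body_radius
  r2 <- array(0, c(nz, nyv, nxv))
  dz2 <- (z_um - zc)^2
  dy2 <- (y_um - yc)^2
  cross2 <- outer(dz2, dy2, `+`)           # nz x ny
  xa <- pmin(pmax(x_um, ax_lo), ax_hi)     # clamp to the cylinder axis
  dx2 <- (x_um - xa)^2
  body <- array(FALSE, c(nz, nyv, nxv))
  for (k in seq_len(nxv)) {
    body[, , k] <- cross2 + dx2[k] <= body_radius^2
  }
  frac_x <- (x_um - x0) / body_length
  in_nmp <- frac_x <= f_nmp
  in_psm <- frac_x > f_nmp & frac_x <= f_nmp + f_psm
  in_ant <- frac_x > f_nmp + f_psm
  slab <- function(sel_x) {
    out <- array(FALSE, c(nz, nyv, nxv))
    out[, , sel_x] <- TRUE
    out & body
  }
  bra <- slab(in_nmp | in_psm)
  neural <- slab(in_ant)
  # dorsal slab: upper z third of the anterior region
  neural <- neural & array(rep(z_um > zc + 0.3 * body_radius,
                               times = nyv * nxv), c(nz, nyv, nxv))
  sox <- slab(in_nmp) | neural
  if (somite_mode == "band") {
    unc <- slab(in_ant)
  } else {
    unc <- array(FALSE, c(nz, nyv, nxv))
    ant_start <- x0 + (f_nmp + f_psm) * body_length
    ant_len <- (1 - f_nmp - f_psm) * body_length
    pitch <- ant_len / n_spheres
    centers <- ant_start + (seq_len(n_spheres) - 0.5) * pitch
    for (cx in centers) {
      dxs <- (x_um - cx)^2
      for (k in which(dxs <= sphere_radius^2)) {
        unc[, , k] <- unc[, , k] | (cross2 + dxs[k] <= sphere_radius^2)
      }
    }
    unc <- unc & body
  }
  mk_channel <- function(m) {
    ch <- background + (foreground - background) * m
    if (noise_sd > 0) ch <- ch + array(stats::rnorm(length(m), 0, noise_sd), dim(m))
    ch[ch < 0] <- 0
    ch
  }
  dat <- array(0, c(nz, nyv, nxv, 3L))
  dat[, , , 1L] <- mk_channel(sox)
  dat[, , , 2L] <- mk_channel(bra)
  dat[, , , 3L] <- mk_channel(unc)
  vvol <- prod(c(vz, vy, vx))
  truth_masks <- list(SOX2 = sox, BRACHYURY = bra, `UNCX4.1` = unc,
                      body = body,
                      neural = sox & !bra, psm = bra & !sox,
                      nmp = sox & bra, somite = unc)
  volumes <- vapply(truth_masks, function(m) sum(m) * vvol, numeric(1L))
  cyl_len <- max(ax_hi - ax_lo, 0)
  analytic_body <- pi * body_radius^2 * cyl_len + 4 / 3 * pi * body_radius^3
  stack <- image_grid(dat, c(z = vz, y = vy, x = vx),
                      channel_names = c("SOX2", "BRACHYURY", "UNCX4.1"),
                      kind = "stack3d")
  list(stack = stack,
       truth = list(masks = truth_masks, volumes = volumes,
                    analytic_body_volume = analytic_body,
                    voxel = c(z = vz, y = vy, x = vx),
                    params = list(body_length = body_length,
                                  body_radius = body_radius,
                                  f_nmp = f_nmp, f_psm = f_psm,
                                  somite_mode = somite_mode)))
}
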