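test_that("frame registration recovers known integer drifts", {
  set.seed(30)
  base <- matrix(5, 80, 120)
  base[30:60, 40:80] <- 150
  base <- base + matrix(rnorm(80 * 120, 0, 2), 80, 120)
  shifts_true <- cbind(dx = c(0, 3, -2, 5), dy = c(0, 1, 4, -3))
  dat <- array(0, c(4, 80, 120))
  for (t in 1:4) {
    new <- matrix(5, 80, 120)
    sy <- (1:80) - shifts_true[t, "dy"]; sx <- (1:120) - shifts_true[t, "dx"]
    oky <- sy >= 1 & sy <= 80; okx <- sx >= 1 & sx <= 120
    new[which(oky), which(okx)] <- base[sy[oky], sx[okx]]
    dat[t, , ] <- pmax(new, 0)
  }
  mv <- image_grid(dat, c(2, 2), frame_interval = 10, kind = "movie")
  reg <- register_frames(mv)
  expect_true(all(abs(reg$shifts$dx_px - shifts_true[, "dx"]) <= 1))
  expect_true(all(abs(reg$shifts$dy_px - shifts_true[, "dy"]) <= 1))
  expect_false(any(reg$shifts$low_confidence))
  # an already-registered movie reports zero shifts
  reg2 <- register_frames(reg$movie)
  expect_true(all(reg2$shifts$dx_px == 0 & reg2$shifts$dy_px == 0))
})

test_that("pure-noise frames are flagged low-confidence", {
  set.seed(31)
  dat <- array(pmax(rnorm(3 * 50 * 50, 50, 10), 0), c(3, 50, 50))
  mv <- image_grid(dat, c(2, 2), frame_interval = 10, kind = "movie")
  reg <- register_frames(mv)
  expect_true(all(reg$shifts$low_confidence))
  # constant (empty) frames are an error
  dat[2, , ] <- 7
  mv2 <- image_grid(dat, c(2, 2), frame_interval = 10, kind = "movie")
  expect_error(register_frames(mv2), "empty")
})

test_that("kymograph of a static gradient has identical rows", {
  fr <- outer(rep(1, 40), seq(10, 100, length.out = 60))
  dat <- array(0, c(10, 40, 60))
  for (t in 1:10) dat[t, , ] <- fr
  mv <- image_grid(dat, c(1, 1), frame_interval = 5, kind = "movie")
  ky <- build_kymograph(mv, rbind(c(5, 20), c(55, 20)), half_width = 4,
                        median_radius = 0)
  expect_true(all(apply(ky$mat, 2, function(col) diff(range(col))) < 1e-9))
  expect_error(build_kymograph(mv, rbind(c(-5, 20), c(70, 20)), 0, 0),
               "exits")
})

test_that("pure line sampling equals an independent bilinear oracle", {
  set.seed(32)
  fr <- matrix(runif(50 * 70, 10, 100), 50, 70)
  dat <- array(0, c(2, 50, 70)); dat[1, , ] <- fr; dat[2, , ] <- fr
  mv <- image_grid(dat, c(1, 1), frame_interval = 5, kind = "movie")
  ax <- rbind(c(3.2, 7.9), c(60.4, 41.3))
  ky <- build_kymograph(mv, ax, half_width = 0, median_radius = 0)
  dvec <- (ax[2, ] - ax[1, ]) / sqrt(sum((ax[2, ] - ax[1, ])^2))
  xs <- ax[1, 1] + dvec[1] * ky$positions
  ys <- ax[1, 2] + dvec[2] * ky$positions
  expect_equal(ky$mat[1, ], oracle_bilinear(fr, xs, ys), tolerance = 1e-9)
})

test_that("a traveling-wave kymograph shows the generated wave direction", {
  g <- generate_clock_movie(clock_spec(n_frames = 60, noise_sd = 0, seed = 0))
  ax <- rbind(c(40, 90), c(540, 90))
  ky <- build_kymograph(g$movie, ax, half_width = 10, median_radius = 0)
  lag <- phase_lag(ky, c(30, 90), c(150, 210))
  truth <- g$truth$lag_fun(60, 180)
  expect_gt(lag$lag_min, 0)
  expect_equal(lag$lag_min, truth, tolerance = 0.1 * truth)
})

test_that("detrending removes trends and matches the filter gain", {
  expect_true(all(detrend_trace(rep(7, 80), 50) == 0))
  n <- 400; P <- 30; A <- 3
  x <- A * sin(2 * pi * (1:n) / P) + 0.05 * (1:n) + 10
  d <- detrend_trace(x, 50)
  interior <- 60:(n - 60)
  # centered 51-frame moving average gain at period 30
  gain <- sin(51 * pi / P) / (51 * sin(pi / P))
  amp <- (max(d[interior]) - min(d[interior])) / 2
  expect_equal(amp, A * (1 - gain), tolerance = 0.05 * A)
  expect_lt(abs(coef(lm(d[interior] ~ interior))[2]), 1e-3)
  # low-frequency cutoff: periods far above the window are attenuated
  slow <- sin(2 * pi * (1:n) / 300)
  gain_slow <- sin(51 * pi / 300) / (51 * sin(pi / 300))
  ds <- detrend_trace(slow, 50)
  expect_lt(max(abs(ds[interior])), 1.2 * (1 - gain_slow))
  expect_lt(1 - gain_slow, 0.25)
  expect_error(detrend_trace(rep(1, 20), 50), "exceed")
})

test_that("gap handling interpolates short gaps and splits on long ones", {
  x <- sin(2 * pi * (1:200) / 30)
  x_gap <- x; x_gap[50:52] <- NA
  d <- detrend_trace(x_gap, 50)
  expect_false(anyNA(d))
  x_long <- x; x_long[80:90] <- NA
  expect_error(detrend_trace(x_long, 50), "split")
  segs <- trace_segments(x_long, 3)
  expect_length(segs, 2)
  expect_identical(segs[[1]], 1:79)
  expect_identical(segs[[2]], 91:200)
})

test_that("instantaneous phase recovers frequency and offsets", {
  n <- 300; T0 <- 50
  x <- cos(2 * pi * (1:n) / T0)
  ph <- instantaneous_phase(x)
  interior <- 30:(n - 30)
  slope <- unname(coef(lm(ph[interior] ~ interior))[2])
  expect_equal(slope, 2 * pi / T0, tolerance = 0.02 * 2 * pi / T0)
  y <- cos(2 * pi * ((1:n) - T0 / 4) / T0)
  dphi <- instantaneous_phase(x)[interior] - instantaneous_phase(y)[interior]
  expect_true(all(abs(dphi - pi / 2) < 0.1))
  expect_error(instantaneous_phase(rep(0, 50)), "phase")
})

test_that("peak-to-peak period is exact on a noiseless sinusoid", {
  tmin <- seq(0, 1190, by = 10)
  x <- cos(2 * pi * (tmin - 150) / 300)  # peaks at 150, 450, 750, 1050
  per <- peak_to_peak_period(x, 10)
  expect_equal(per$period_h, 5, tolerance = 1e-9)
  expect_equal(per$period_sd_h, 0, tolerance = 1e-9)
  expect_equal(per$n_peaks, 4)
  expect_equal(per$peak_times, c(150, 450, 750, 1050))
  # peaks and troughs alternate
  both <- sort(c(per$peak_times, per$trough_times))
  is_peak <- both %in% per$peak_times
  expect_true(all(diff(is_peak) != 0))
  expect_error(peak_to_peak_period(x[1:20], 10), "peaks")
})

test_that("the period survives 20 % amplitude noise across seeds", {
  errs <- vapply(1:10, function(seed) {
    set.seed(seed)
    tmin <- seq(0, 1790, by = 10)
    x <- cos(2 * pi * tmin / 300) + rnorm(length(tmin), 0, 0.2)
    d <- detrend_trace(x, 50)
    abs(peak_to_peak_period(d, 10)$period_h * 60 - 300)
  }, numeric(1))
  expect_lte(mean(errs), 10)
})

test_that("the period is recovered from a damped oscillation", {
  tmin <- seq(0, 1490, by = 10)
  x <- exp(-tmin / 800) * cos(2 * pi * tmin / 300)
  per <- peak_to_peak_period(x, 10, min_prominence = 0.1)
  expect_gte(per$n_peaks, 2)
  expect_equal(per$period_h * 60, 300, tolerance = 10)
})

test_that("time-shift invariance and phase-slope consistency hold", {
  tmin <- seq(0, 1490, by = 10)
  x <- cos(2 * pi * (tmin - 100) / 300)
  x_shift <- cos(2 * pi * (tmin - 150) / 300)
  p0 <- peak_to_peak_period(x, 10)
  p1 <- peak_to_peak_period(x_shift, 10)
  expect_equal(p1$period_h, p0$period_h, tolerance = 1e-9)
  expect_equal(p1$peak_times[1] - p0$peak_times[1], 50, tolerance = 1e-9)
  ph <- instantaneous_phase(x)
  interior <- 20:130
  slope <- unname(coef(lm(ph[interior] ~ seq_along(interior)))[2]) / 10
  expect_lte(abs(p0$period_h * 60 - 2 * pi / slope), 10)
  expect_equal(p1$peak_times - p0$peak_times,
               rep(50, length(p0$peak_times)), tolerance = 1e-9)
})

test_that("phase lag is zero for synchrony and flips with wave direction", {
  sync <- generate_clock_movie(clock_spec(wavelength = 1e9, n_frames = 90,
                                          noise_sd = 0, seed = 1))
  ax <- rbind(c(40, 90), c(540, 90))
  ky_s <- build_kymograph(sync$movie, ax, half_width = 10, median_radius = 0)
  lag_s <- phase_lag(ky_s, c(30, 90), c(300, 360))
  expect_lte(abs(lag_s$lag_min), 10)
  fwd <- generate_clock_movie(clock_spec(n_frames = 90, noise_sd = 0, seed = 1))
  rev <- generate_clock_movie(clock_spec(wavelength = -400, n_frames = 90,
                                         noise_sd = 0, seed = 1))
  ky_f <- build_kymograph(fwd$movie, ax, half_width = 10, median_radius = 0)
  ky_r <- build_kymograph(rev$movie, ax, half_width = 10, median_radius = 0)
  lf <- phase_lag(ky_f, c(30, 90), c(150, 210))$lag_min
  lr <- phase_lag(ky_r, c(30, 90), c(150, 210))$lag_min
  expect_gt(lf, 0)
  expect_lt(lr, 0)
  expect_equal(lf, -lr, tolerance = 0.15 * abs(lf))
})

test_that("event periods are exact, jitter-robust, and need two events", {
  ep <- event_period(c(0, 300, 600, 900))
  expect_equal(ep$period_h, 5)
  expect_equal(ep$period_sd_h, 0)
  errs <- vapply(1:10, function(seed) {
    ev <- generate_event_times(period = 300, jitter_sd = 15, n = 10,
                               seed = seed)
    abs(event_period(ev)$period_h * 60 - 300)
  }, numeric(1))
  expect_lte(mean(errs), 10)
  expect_error(event_period(600), "at least 2")
  expect_error(event_period(c(0, 100, 100)), "strictly increasing")
})

test_that("somite events are locked to the oscillation cycle", {
  g <- generate_clock_movie(clock_spec(n_frames = 120, noise_sd = 0, seed = 2))
  expect_gte(length(g$truth$events), 2)
  ep <- event_period(g$truth$events)
  ax <- rbind(c(40, 90), c(540, 90))
  ky <- build_kymograph(g$movie, ax, half_width = 10, median_radius = 0)
  tr <- detrend_trace(rowMeans(ky$mat[, 180:220]), 50)
  pp <- peak_to_peak_period(tr, g$movie$frame_interval)
  expect_lte(abs(ep$period_h - pp$period_h) * 60, g$movie$frame_interval)
})
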