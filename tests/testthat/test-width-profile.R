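test_that("width of a rectangle equals its height everywhere inside", {
  m <- matrix(FALSE, 81, 401)
  m[11:70, 11:390] <- TRUE  # 60 px tall
  lm <- labeled_mask(m, c(1, 1))
  mid <- straight_midline(330, y0 = 40)
  # shift midline to start inside the rectangle
  mid$points[, "x"] <- mid$points[, "x"] + 30
  prof <- compute_width_profile(lm, mid)
  interior <- prof$s > 5 & prof$s < 325
  expect_true(all(abs(prof$w[interior] - 60) < 1))
})

test_that("width across a disc center equals its diameter", {
  disc <- raster_disc(55, 1)
  lm <- labeled_mask(disc, c(1, 1))
  cc <- (nrow(disc) - 1) / 2
  mid <- straight_midline(2 * cc, y0 = cc)
  prof <- compute_width_profile(lm, mid)
  w_center <- prof$w[which.min(abs(prof$s - cc))]
  expect_equal(w_center, 110, tolerance = 1)
})

test_that("a tangent-disc chain yields ~110-um maxima at the disc centers", {
  gen <- generate_somitoid(somitoid_spec(n_somites = 5, somite_diameter = 110,
                                         gap = 0, spacing = 110,
                                         noise_sd = 0, seed = 0))
  res <- run_morphometry(gen)
  ex <- find_profile_extrema(res$profile)
  calls <- res$calls
  expect_equal(nrow(calls), 5)
  expect_true(all(abs(calls$width_um - 110) <= 3))
  # interior boundaries sit near the tangency midpoints
  tr <- gen$truth$somites
  interior <- 2:5
  expect_true(all(abs(calls$s_start[interior] - tr$s_start[interior]) <= 5))
})

test_that("width profile agrees with the brute-force normal-scan oracle", {
  for (seed in c(0, 3, 5)) {
    gen <- generate_somitoid(somitoid_spec(seed = seed, n_somites = 3,
                                           body_length = 150))
    res <- run_morphometry(gen)
    idx <- seq(5, length(res$profile$s) - 5, by = 25)
    ev <- midline_eval(res$midline, res$profile$s[idx])
    for (q in seq_along(idx)) {
      w_o <- oracle_width(res$mask$mask, 1, ev$point[q, ], ev$normal[q, ])
      expect_lt(abs(res$profile$w[idx[q]] - w_o), 1)
    }
  }
})

test_that("extrema of an analytic cosine profile are found exactly", {
  s <- seq(0, 600, by = 1)
  mk <- function(w) structure(list(s = s, w = w, step = 1,
                                   flagged = rep(FALSE, length(s))),
                              class = "width_profile")
  w0 <- 100 + 20 * cos(2 * pi * s / 120)
  ex <- find_profile_extrema(mk(w0), 10, 40)
  # analytic extrema under the stated end-discard rule: maxima at multiples
  # of 120 excluding 0 and 600; minima at 60 + 120k, none near the ends
  expect_equal(ex$maxima, c(120, 240, 360, 480), tolerance = 1)
  expect_equal(ex$minima, c(60, 180, 300, 420, 540), tolerance = 1)
  # uniform noise of amplitude 2 um does not change the counts
  for (seed in 1:10) {
    set.seed(seed)
    exn <- find_profile_extrema(mk(w0 + runif(length(s), -2, 2)), 10, 40)
    expect_length(exn$maxima, 4)
    expect_length(exn$minima, 5)
  }
  # a monotone profile has no interior extrema
  exm <- find_profile_extrema(mk(50 + s / 10), 10, 40)
  expect_length(exm$maxima, 0)
  expect_length(exm$minima, 0)
})

test_that("one bracketed maximum yields exactly one somite call", {
  s <- seq(0, 300, by = 1)
  w <- 80 + 30 * exp(-((s - 150) / 40)^2) - 20 * exp(-((s - 60) / 25)^2) -
    20 * exp(-((s - 240) / 25)^2)
  prof <- structure(list(s = s, w = w, step = 1,
                         flagged = rep(FALSE, length(s))),
                    class = "width_profile")
  ex <- find_profile_extrema(prof, 5, 30)
  calls <- call_somites(prof, ex)
  expect_equal(nrow(calls), 1)
  expect_true(calls$s_start < calls$s_peak & calls$s_peak < calls$s_end)
  expect_false(calls$end_capped)
  # no bracketed maxima -> empty call table
  empty <- call_somites(prof, list(minima = numeric(0), maxima = 150))
  expect_equal(nrow(empty), 0)
})

test_that("the default somitoid is recovered with small errors", {
  res <- default_morph()
  tr <- default_somitoid()$truth$somites
  expect_equal(nrow(res$calls), 8)
  expect_identical(count_somite_rows(res$calls), 8L)
  expect_lte(mean(abs(res$calls$width_um - tr$width)), 5)
  expect_lte(mean(abs(res$calls$length_um - tr$spacing)), 5)
  expect_true(res$calls$end_capped[8])
  expect_false(any(res$calls$end_capped[1:7]))
  # invariant: bounds ordered, width at least the boundary widths
  with(res$calls, expect_true(all(s_start < s_peak & s_peak < s_end)))
  expect_true(all(res$calls$circularity > 0 & res$calls$circularity <= 1))
})

test_that("a width/spacing gradient yields monotone calls", {
  diams <- seq(95, 150, length.out = 6)
  gen <- generate_somitoid(somitoid_spec(n_somites = 6,
                                         somite_diameter = diams,
                                         seed = 3))
  res <- run_morphometry(gen)
  expect_equal(nrow(res$calls), 6)
  expect_true(all(diff(res$calls$width_um) > 0))
  expect_true(all(diff(res$calls$length_um) > 0))
})

test_that("somite counts follow the generated count", {
  expect_identical(count_somite_rows(default_morph()$calls), 8L)
  gen3 <- generate_somitoid(somitoid_spec(n_somites = 3, seed = 5))
  expect_identical(count_somite_rows(run_morphometry(gen3)$calls), 3L)
  gen0 <- generate_somitoid(somitoid_spec(n_somites = 0, seed = 6))
  mask <- clean_mask(binarize(gen0$image, "yen"))
  pts <- midline_ridge_points(mask)
  ord <- order_midline_points(pts, gen0$truth$anchors$posterior,
                              gen0$truth$anchors$anterior)
  mid <- fit_midline_spline(ord$points)
  prof <- compute_width_profile(mask, mid)
  calls <- call_somites(prof, find_profile_extrema(prof))
  expect_identical(count_somite_rows(calls), 0L)
})

test_that("a paired string projects to one width maximum per pair", {
  # geometric claim on the emitted mask: along the central axis the 2-D
  # projection of a bilateral pair gives a single width maximum, so a pair
  # is counted once (automatic midline extraction itself assumes an
  # unpaired string, as in the source morphometry)
  gen <- generate_somitoid(somitoid_spec(n_somites = 4, paired = TRUE,
                                         noise_sd = 0, seed = 7))
  mask <- labeled_mask(gen$truth$mask, c(1, 1))
  mid <- fit_midline_spline(gen$truth$centerline[, c("x", "y")])
  prof <- compute_width_profile(mask, mid)
  calls <- call_somites(prof, find_profile_extrema(prof))
  expect_equal(nrow(calls), 4)
  expect_identical(count_somite_rows(calls), 4L)
  # projection width of a pair is about twice the single-somite diameter
  expect_true(all(abs(calls$width_um - 220) < 15))
})

test_that("ellipse shape statistics match their analytic forms", {
  circ <- somite_shape_stats(110, 110)
  expect_equal(circ$area_um2, pi * 110^2 / 4, tolerance = 1e-12)
  expect_equal(circ$circularity, 1, tolerance = 1e-9)
  # printed paired-somite dimensions
  st <- somite_shape_stats(110, 104)
  expect_equal(st$area_um2, pi * 110 * 104 / 4, tolerance = 1e-12)
  # quadrature oracle for the perimeter at 2:1 aspect
  a <- 100; b <- 50
  per_num <- stats::integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                              0, 2 * pi, subdivisions = 2000L)$value
  st2 <- somite_shape_stats(2 * a, 2 * b)
  circ_oracle <- 4 * pi * (pi * a * b) / per_num^2
  expect_equal(st2$circularity, circ_oracle, tolerance = 1e-4)
  # symmetry and maximization at L = W
  expect_equal(somite_shape_stats(80, 120)$circularity,
               somite_shape_stats(120, 80)$circularity)
  expect_gt(somite_shape_stats(100, 100)$circularity,
            somite_shape_stats(100, 99)$circularity)
  expect_error(somite_shape_stats(-1, 10), "> 0")
})

test_that("first-somite geometry matches analytic straight-line cases", {
  mid <- straight_midline(1000, y0 = 0)
  vert <- rbind(c(200, -80), c(200, 80))
  r1 <- first_somite_metrics(mid, vert)
  expect_equal(r1$relative_position, 0.20, tolerance = 1e-6)
  expect_equal(r1$angle_deg, 0, tolerance = 1e-6)
  th <- 30 * pi / 180
  tilted <- rbind(c(300, 0) - 80 * c(sin(th), cos(th)),
                  c(300, 0) + 80 * c(sin(th), cos(th)))
  r2 <- first_somite_metrics(mid, tilted)
  expect_equal(r2$angle_deg, 30, tolerance = 1e-6)
  expect_error(first_somite_metrics(mid, rbind(c(200, 50), c(200, 150))),
               "closest approach")
})

test_that("first-somite arc fraction is recovered on a sinusoidal midline", {
  gen <- generate_somitoid(somitoid_spec(seed = 8, midline_shape = "sinusoidal"))
  res <- run_morphometry(gen)
  lr <- generate_lr_segment(gen$truth, fraction = 0.35)
  r <- first_somite_metrics(res$midline, lr)
  expect_equal(r$relative_position, 0.35, tolerance = 0.01)
})
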