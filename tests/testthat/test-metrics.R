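test_that("TAWSS averages the shear magnitude over the cycle", {
  m <- mesh_triangle()
  T_ <- 0.22
  t <- seq(0, T_, length.out = 101)

  f <- field_from_series(m, t, rep(5, 101), T_)
  expect_equal(compute_tawss(f)$values, rep(5, 3))

  # |sin| cycle mean is 2/pi of the amplitude
  t2 <- seq(0, T_, length.out = 2001)
  f2 <- field_from_series(m, t2, 3 * sin(2 * pi * t2 / T_), T_)
  expect_equal(compute_tawss(f2)$values, rep(6 / pi, 3), tolerance = 1e-5)

  z <- field_from_series(m, t, rep(0, 101), T_)
  tz <- compute_tawss(z)
  expect_equal(tz$values, rep(0, 3))
  expect_true(all(tz$flags))
})

test_that("OSI separates unidirectional from reversing shear", {
  m <- mesh_triangle()
  T_ <- 0.22
  t <- seq(0, T_, length.out = 101)

  uni <- field_from_series(m, t, 2 + sin(2 * pi * t / T_), T_)
  expect_equal(compute_osi(uni)$values, rep(0, 3), tolerance = 1e-15)

  rev_ <- field_from_series(m, t, sin(2 * pi * t / T_), T_)
  expect_equal(compute_osi(rev_)$values, rep(0.5, 3), tolerance = 1e-12)

  # offset sinusoid against the independent loop oracle
  f <- field_from_series(m, t, 1 + sin(2 * pi * t / T_), T_)
  osi <- compute_osi(f)$values
  orc <- oracle_metrics(f$times, f$tau, T_)
  expect_equal(osi, orc$osi, tolerance = 1e-6)

  zf <- field_from_series(m, t, rep(0, 101), T_)
  expect_message(oz <- compute_osi(zf), "degenerate")
  expect_equal(oz$values, rep(0, 3))
  expect_true(all(oz$flags))
})

test_that("RRT is the reciprocal of (1 - 2 OSI) TAWSS with an infinity sentinel", {
  m <- mesh_triangle()
  tw <- metric_map(m, "TAWSS", rep(2, 3))
  os <- metric_map(m, "OSI", rep(0, 3))
  expect_equal(compute_rrt(tw, os)$values, rep(0.5, 3))

  os5 <- metric_map(m, "OSI", rep(0.5, 3))
  r <- compute_rrt(tw, os5)
  expect_true(all(is.infinite(r$values)))
  expect_true(all(r$flags))

  cube <- mesh_cube()
  f <- random_field(cube, n_times = 24L, seed = 8)
  tw <- compute_tawss(f)
  os <- suppressMessages(compute_osi(f))
  rr <- compute_rrt(tw, os)
  ok <- !rr$flags
  expect_true(any(ok))
  expect_equal(rr$values[ok] * (1 - 2 * os$values[ok]) * tw$values[ok],
               rep(1, sum(ok)), tolerance = 1e-12)

  expect_error(compute_rrt(tw, metric_map(mesh_triangle(), "OSI", rep(0, 3))),
               "different meshes")
  expect_error(compute_rrt(os, os), "TAWSS map")
})

test_that("area_fraction applies strict thresholds with area weights", {
  cube <- mesh_cube()
  ww <- whole_wall_mask(cube)
  uni <- metric_map(cube, "TAWSS", rep(10, 8))
  expect_equal(area_fraction(uni, ww, 20, "below"), 1)
  expect_equal(area_fraction(uni, ww, 5, "below"), 0)
  expect_equal(area_fraction(uni, ww, 10, "below"), 0)  # tie does not qualify
  expect_equal(area_fraction(uni, ww, 10, "above"), 0)

  # nodes carrying exactly half the area pushed over the threshold
  areas <- cube$node_areas
  ord <- order(areas)
  half_ids <- ord[cumsum(areas[ord]) <= sum(areas) / 2 + 1e-12]
  vals <- rep(1, 8); vals[half_ids] <- 30
  mm <- metric_map(cube, "TAWSS", vals)
  expect_equal(area_fraction(mm, ww, 20, "above"),
               sum(areas[half_ids]) / sum(areas))

  # above + below partition when no tie, infinity counts as above
  rmap <- metric_map(cube, "RRT", c(0.1, 0.2, Inf, 0.4, 1, 2, 3, 0.05))
  expect_equal(area_fraction(rmap, ww, 0.5, "above") +
                 area_fraction(rmap, ww, 0.5, "below"), 1)
  solo <- region_mask("solo", 3L, cube)
  expect_equal(area_fraction(rmap, solo, 1e9, "above"), 1)
})

test_that("tawss_histogram bins area into seven 20 Pa ranges", {
  cube <- mesh_cube()
  ww <- whole_wall_mask(cube)
  h <- tawss_histogram(metric_map(cube, "TAWSS", rep(10, 8)), ww)
  expect_equal(unname(h), c(1, 0, 0, 0, 0, 0, 0))
  h2 <- tawss_histogram(metric_map(cube, "TAWSS", rep(130, 8)), ww)
  expect_equal(unname(h2[7]), 1)

  vals <- c(5, 25, 25, 45, 200, 119.9, 120, 60)
  h3 <- tawss_histogram(metric_map(cube, "TAWSS", vals), ww)
  areas <- cube$node_areas
  expect_equal(unname(h3),
               c(areas[1], areas[2] + areas[3], areas[4], areas[8], 0,
                 areas[6], areas[5] + areas[7]) / sum(areas))
  expect_equal(sum(h3), 1)
  expect_error(tawss_histogram(metric_map(cube, "OSI", rep(0.1, 8)), ww),
               "TAWSS map")
})

test_that("regional_mean weights by node area and excludes sentinels", {
  cube <- mesh_cube()
  ww <- whole_wall_mask(cube)
  expect_equal(regional_mean(metric_map(cube, "OSI", rep(0.3, 8)), ww), 0.3)

  two <- region_mask("two", c(1L, 8L), cube)  # opposite corners, equal areas
  mm <- metric_map(cube, "OSI", c(0.3, rep(0, 6), 0.5))
  expect_equal(regional_mean(mm, two), 0.4)

  vals <- seq(0.5, 12, length.out = 8)
  tm <- metric_map(cube, "TAWSS", vals)
  expect_equal(regional_mean(tm, ww),
               sum(vals * cube$node_areas) / sum(cube$node_areas))

  rmap <- metric_map(cube, "RRT", c(Inf, rep(2, 7)))
  expect_warning(mu <- regional_mean(rmap, ww), "non-finite")
  expect_equal(mu, 2)
  allinf <- metric_map(cube, "RRT", rep(Inf, 8))
  expect_error(suppressWarnings(regional_mean(allinf, ww)), "non-finite")
})

test_that("OSI is invariant to positive scaling and rigid rotation of the field", {
  cube <- mesh_cube()
  f <- random_field(cube, n_times = 20L, seed = 3)
  osi <- suppressMessages(compute_osi(f))$values
  tawss <- compute_tawss(f)$values

  for (s in c(0.01, 7, 1234)) {
    fs <- wss_field(cube, f$times, f$tau * s, f$period)
    expect_equal(suppressMessages(compute_osi(fs))$values, osi, tolerance = 1e-12)
  }

  set.seed(99)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  taur <- f$tau
  for (i in seq_len(dim(taur)[1])) taur[i, , ] <- f$tau[i, , ] %*% t(Q)
  fr <- wss_field(cube, f$times, taur, f$period)
  expect_equal(suppressMessages(compute_osi(fr))$values, osi, tolerance = 1e-12)
  expect_equal(compute_tawss(fr)$values, tawss, tolerance = 1e-12)
})

test_that("time-step refinement converges at second order on an analytic field", {
  m <- mesh_triangle()
  T_ <- 0.22
  truth <- osi_offset_sine(1, 2)$osi
  err <- vapply(c(100, 200, 400), function(nt) {
    t <- seq(0, T_, length.out = nt + 1)
    f <- field_from_series(m, t, 1 + 2 * sin(2 * pi * t / T_), T_)
    abs(compute_osi(f)$values[1] - truth)
  }, numeric(1))
  ratios <- err[-3] / err[-1]
  expect_true(all(ratios > 3 & ratios < 5))
})

test_that("WSS fields and metric maps round-trip through CSV", {
  cube <- mesh_cube()
  f <- random_field(cube, n_times = 8L, seed = 21)
  p <- withr::local_tempfile(fileext = ".csv")
  write_wss_csv(f, p)
  f2 <- read_wss_csv(p, cube, f$period)
  expect_equal(f2$tau, f$tau)
  expect_equal(f2$times, f$times)

  mm <- compute_tawss(f)
  pm <- withr::local_tempfile(fileext = ".csv")
  write_metric_csv(mm, pm)
  back <- utils::read.csv(pm)
  expect_equal(back$value, mm$values)

  expect_error(wss_field(cube, c(0, 0.1), array(0, c(8, 2, 3)), 0.2),
               "at least 3")
  expect_error(wss_field(cube, c(0, 0.1, 0.05), array(0, c(8, 3, 3)), 0.2),
               "increasing")
})
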