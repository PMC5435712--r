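test_that("arch mesh area matches the analytic torus segment and masks partition", {
  arch <- make_arch_mesh(arch_spec(centerline_radius = 10, vessel_radius = 1,
                                   arch_angle = pi / 2))
  expect_lt(abs(sum(arch$mesh$node_areas) - 10 * pi^2) / (10 * pi^2), 0.01)

  expect_length(intersect(arch$masks$inner_arch$node_ids,
                          arch$masks$outer_arch$node_ids), 0)
  expect_true(all(arch$masks$inner_arch$node_ids %in%
                    arch$masks$whole_wall$node_ids))

  # inner nodes sit closer to the rotation axis than outer nodes
  rad <- sqrt(arch$mesh$vertices[, 1]^2 + arch$mesh$vertices[, 2]^2)
  expect_lt(max(rad[arch$masks$inner_arch$node_ids]),
            min(rad[arch$masks$outer_arch$node_ids]))

  coarse <- make_arch_mesh(arch_spec(n_theta = 8L, n_phi = 8L))
  fine <- make_arch_mesh(arch_spec(n_theta = 16L, n_phi = 16L))
  expect_equal(nrow(fine$mesh$triangles), 4L * nrow(coarse$mesh$triangles))

  expect_error(arch_spec(vessel_radius = 5, centerline_radius = 3), "smaller")
  expect_error(arch_spec(n_theta = 4), "at least 8")
})

test_that("rat-like waveforms honour heart rate, peak velocity and seed", {
  w <- make_waveform(271, 1521, seed = 3)
  expect_equal(w$period, 60 / 271)
  expect_equal(max(w$values), 1521)
  expect_true(all(w$values >= 0))

  w2 <- make_waveform(271, 1521, seed = 3)
  expect_identical(w$values, w2$values)
  w3 <- make_waveform(271, 1521, seed = 4)
  expect_false(identical(w$values, w3$values))

  expect_error(make_waveform(-10, 1521), "positive")
  expect_error(make_waveform(271, 0), "positive")
})

test_that("closed-form offset-sinusoid OSI/TAWSS matches dense numerical integration", {
  set.seed(14)
  tt <- seq(0, 2 * pi, length.out = 2e5 + 1)
  for (k in 1:8) {
    a <- runif(1, 0, 4); b <- runif(1, 0, 4)
    num_mean <- mean(abs(a + b * sin(tt))[-1])
    cf <- osi_offset_sine(a, b)
    expect_equal(cf$tawss, num_mean, tolerance = 1e-6)
    osi_num <- 0.5 * (1 - abs(mean((a + b * sin(tt))[-1])) / num_mean)
    expect_equal(cf$osi, osi_num, tolerance = 1e-6)
  }
  expect_equal(osi_offset_sine(0, 2)$osi, 0.5)
  expect_equal(osi_offset_sine(3, 1)$osi, 0)
  expect_equal(osi_offset_sine(3, 1)$tawss, 3)
})

test_that("planted WSS fields carry their analytic ground truth", {
  arch <- make_arch_mesh(arch_spec(n_theta = 16L, n_phi = 24L))

  none <- make_wss_field(arch, planted_field_spec(inner_amp_ratio = 0,
                                                  noise_cv = 0, seed = 1))
  expect_equal(none$truth$osi_true, rep(0, nrow(arch$mesh$vertices)))
  expect_equal(suppressMessages(compute_osi(none$field))$values,
               none$truth$osi_true, tolerance = 1e-12)

  pure <- make_wss_field(arch, planted_field_spec(inner_steady_scale = 0,
                                                  noise_cv = 0, seed = 1))
  inner <- arch$masks$inner_arch$node_ids
  expect_equal(pure$truth$osi_true[inner], rep(0.5, length(inner)))

  pf <- make_wss_field(arch, planted_field_spec(seed = 42))
  osi <- suppressMessages(compute_osi(pf$field))$values
  expect_lt(max(abs(osi - pf$truth$osi_true)), 1e-3)
  tawss <- compute_tawss(pf$field)$values
  expect_lt(max(abs(tawss - pf$truth$tawss_true) / pf$truth$tawss_true), 1e-3)

  pf2 <- make_wss_field(arch, planted_field_spec(seed = 42))
  expect_identical(pf$field$tau, pf2$field$tau)
  expect_error(planted_field_spec(), "mandatory")
})

test_that("study tables plant the requested metric-remodelling relationship", {
  set.seed(31)
  metric <- runif(24, 0.35, 0.45)

  exact <- planted_study_spec(noise_sd = 0, elastin_noise_sd = 0, seed = 5)
  tab <- make_study_table(exact, metric)
  expect_equal(correlate(tab, "osi_inner", "wall_thickness_mm")$r, 1)
  expect_equal(correlate(tab, "osi_inner", "wall_thickness_mm")$slope, 3.3)
  expect_equal(tab$wall_thickness_mm, -1.0 + 3.3 * metric)
  expect_equal(sort(unique(tab$group)),
               sort(c("WKY-CON", "SHR-CON", "WKY-NIF", "SHR-NIF")))
  expect_equal(as.vector(table(tab$group)), rep(6L, 4))

  # slope 0 with pure noise: no systematic correlation
  null_spec <- function(s) planted_study_spec(slope = 0, noise_sd = 0.05,
                                              elastin_noise_sd = 0.05, seed = s)
  rs <- vapply(1:40, function(s) {
    correlate(make_study_table(null_spec(s), metric),
              "osi_inner", "wall_thickness_mm")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
  expect_gt(mean(abs(rs) < 0.5), 0.9)

  tab2 <- make_study_table(planted_study_spec(seed = 5), metric)
  tab3 <- make_study_table(planted_study_spec(seed = 5), metric)
  expect_identical(tab2, tab3)
  expect_error(make_study_table(planted_study_spec(seed = 5), metric[1:5]),
               "per animal")
})

test_that("noise_sd_for_r hits the target population correlation", {
  # at the derived SD the expected sample r is close to the target
  slope <- 3.3; r_target <- 0.62
  set.seed(7)
  x <- rnorm(24, 0.4, 0.02)
  sdn <- noise_sd_for_r(slope, sd(x), r_target)
  rs <- vapply(1:400, function(i) {
    y <- 1 + slope * x + rnorm(24, 0, sdn)
    cor(x, y)
  }, numeric(1))
  expect_equal(mean(rs), r_target, tolerance = 0.05)
  expect_error(noise_sd_for_r(1, 1, 1.5), "in \\(0, 1\\]")
})
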