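test_that("fourier_decompose recovers known harmonic content", {
  T_ <- 0.25
  t <- seq(0, T_, length.out = 65)[1:64]

  const <- waveform(t, rep(3.2, 64), T_, "flow")
  co <- fourier_decompose(const, 4)
  expect_equal(Re(co[1]), 3.2)
  expect_lt(max(Mod(co[-1])), 1e-12)

  sine <- waveform(t, sin(2 * pi * t / T_), T_, "flow")
  co <- fourier_decompose(sine, 4)
  expect_equal(co[2], complex(real = 0, imaginary = -0.5), tolerance = 1e-12)
  expect_lt(max(Mod(co[-2])), 1e-12)

  # two-harmonic rat-like waveform built from known coefficients
  c_true <- c(5 + 0i, 1.5 - 0.8i, -0.4 + 0.3i)
  y <- Re(c_true[1]) +
    Re(2 * c_true[2] * exp(2i * pi * t / T_)) +
    Re(2 * c_true[3] * exp(4i * pi * t / T_))
  co <- fourier_decompose(waveform(t, y, T_, "flow"), 2)
  expect_equal(co, c_true, tolerance = 1e-10)

  expect_error(fourier_decompose(waveform(c(0, 0.1, 0.2), 1:3, T_, "flow"), 4),
               "need >=")
})

test_that("womersley_wss reduces to Poiseuille for steady flow and in the low-frequency limit", {
  fl <- fluid_properties()
  p <- pipe_spec(radius = 1e-3)

  # steady Q = pi/4 mm^3/s -> tau = 3.5e-3 Pa
  w <- womersley_wss(p, fl, complex(real = pi / 4 * 1e-9), 0.22)
  expect_equal(w$tau_Pa, rep(3.5e-3, 101), tolerance = 1e-12)

  w0 <- womersley_wss(p, fl, complex(real = c(0, 0)), 0.22)
  expect_equal(w0$tau_Pa, rep(0, 101))

  # alpha -> 0: slow oscillation tracks quasi-steady Poiseuille within 1%
  T_ <- 100
  Q0 <- 1e-8
  harm <- complex(real = c(Q0, 0.25 * Q0))
  w <- womersley_wss(p, fl, harm, T_)
  qs <- 4 * fl$viscosity * (Q0 + 2 * 0.25 * Q0 * cos(2 * pi * w$time_s / T_)) /
    (pi * p$radius^3)
  expect_lt(max(abs(w$tau_Pa - qs)) / max(abs(qs)), 0.01)

  expect_error(pipe_spec(radius = -1), "positive")
  expect_error(womersley_wss(p, fl, harm, -2), "positive")
})

test_that("fd solver converges to Poiseuille under constant forcing", {
  fl <- fluid_properties()
  p <- pipe_spec(radius = 1e-3, nr = 100L)
  G <- 100
  T_ <- 0.22
  wf <- waveform(c(0, T_), c(G, G), T_, "pressure_gradient")
  sol <- fd_pipe_solver(p, fl, wf, n_cycles = 3)
  tau_exact <- G * p$radius / 2
  expect_lt(abs(sol$tau[length(sol$tau)] - tau_exact) / tau_exact, 0.01)
  u_exact <- G * (p$radius^2 - sol$r^2) / (4 * fl$viscosity)
  expect_lt(max(abs(sol$u[, ncol(sol$u)] - u_exact)) / max(u_exact), 0.01)

  z <- fd_pipe_solver(p, fl, waveform(c(0, T_), c(0, 0), T_, "pressure_gradient"))
  expect_equal(z$tau, rep(0, p$nt + 1))
})

test_that("fd solver matches the analytic pulsatile solution and settles to periodicity", {
  fl <- fluid_properties()
  p <- pipe_spec(radius = 1e-3, nr = 100L)
  T_ <- 0.22
  t <- seq(0, T_, length.out = 101)
  G0 <- 100; Ghat <- 60 + 0i
  wf <- waveform(t, G0 + Re(Ghat * exp(2i * pi * t / T_)), T_, "pressure_gradient")
  sol <- fd_pipe_solver(p, fl, wf, n_cycles = 3)
  an <- wssmetrics:::womersley_wss_pressure(p, fl, G0, Ghat, T_)
  expect_lt(max(abs(sol$tau - an$tau_Pa)) / max(abs(an$tau_Pa)), 0.02)

  # periodic steady state: cycle-to-cycle wall shear change below 1e-6
  sol8 <- fd_pipe_solver(p, fl, wf, n_cycles = 8)
  expect_lt(sol8$cycle_delta, 1e-6)
})

test_that("fd solver wall shear is second-order accurate in the radial grid", {
  fl <- fluid_properties()
  T_ <- 0.22
  # forcing sampled at the solver step so waveform interpolation error
  # cannot mask the spatial convergence being measured
  t <- seq(0, T_, length.out = 3201)
  G0 <- 100; Ghat <- 60 + 0i
  wf <- waveform(t, G0 + Re(Ghat * exp(2i * pi * t / T_)), T_, "pressure_gradient")
  # fine time stepping so the temporal error floor does not mask the
  # spatial convergence being measured
  err <- vapply(c(25L, 50L, 100L), function(nr) {
    p <- pipe_spec(radius = 1e-3, nr = nr, nt = 1600L)
    sol <- fd_pipe_solver(p, fl, wf, n_cycles = 6)
    an <- wssmetrics:::womersley_wss_pressure(p, fl, G0, Ghat, T_)
    max(abs(sol$tau - an$tau_Pa))
  }, numeric(1))
  orders <- log2(err[-3] / err[-1])
  expect_true(all(orders >= 1.8))
})

test_that("split_flow distributes branch flows in ratio and conserves volume", {
  T_ <- 0.2
  t <- seq(0, T_, length.out = 41)[1:40]

  inlet <- waveform(t, rep(25, 40), T_, "flow")
  br <- split_flow(inlet, c(10, 7, 8))
  expect_equal(vapply(br, function(b) b$values[1], numeric(1)),
               c(branch1 = 10, branch2 = 7, branch3 = 8))

  half <- split_flow(inlet, c(1, 1))
  expect_equal(half[[1]]$values, half[[2]]$values)
  expect_equal(half[[1]]$values, inlet$values / 2)

  set.seed(5)
  rnd <- waveform(t, runif(40, 0, 50), T_, "flow")
  br <- split_flow(rnd, c(2.3, 0.1, 5), branch_fraction = 0.3)
  total <- Reduce(`+`, lapply(br, function(b) b$values))
  expect_equal(total, rnd$values, tolerance = 1e-15)

  expect_error(split_flow(inlet, c(0, 0)), "all-zero")
  expect_error(split_flow(inlet, numeric()), "nonnegative")
})

test_that("reynolds_number follows rho v d / mu and warns past the laminar range", {
  fl <- fluid_properties()
  expect_equal(reynolds_number(0, 0.002, fl), 0)
  expect_equal(reynolds_number(1, 0.002, fl), 1060 * 1 * 0.002 / 3.5e-3)
  expect_equal(reynolds_number(2, 0.002, fl), 2 * reynolds_number(1, 0.002, fl))
  expect_warning(reynolds_number(4, 0.002, fl), "laminar")
  expect_error(reynolds_number(1, 0, fl), "positive")
  expect_error(fluid_properties(density = -1), "positive")
})

test_that("waveforms enforce periodic closure and survive CSV round-trips", {
  w <- waveform(c(0, 0.05, 0.1), c(1, 4, 1), 0.2, "velocity")
  expect_equal(w$times[length(w$times)], 0.2)
  expect_equal(w$values[length(w$values)], w$values[1])
  expect_warning(waveform(c(0, 0.1, 0.2), c(1, 4, 3), 0.2, "velocity"),
                 "periodicity")
  expect_error(waveform(c(0.01, 0.1), c(1, 2), 0.2), "start at 0")
  expect_error(waveform(c(0, 0.3), c(1, 2), 0.2), "exceed")

  p <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, p)
  w2 <- read_waveform_csv(p)
  expect_equal(w2$values, w$values)
  expect_equal(w2$period, w$period)
})
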