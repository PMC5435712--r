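#' Fluid properties of blood
#'
#' Newtonian blood model. Defaults are the values commonly used for rat
#' blood in CFD work: density 1060 kg/m^3 and dynamic viscosity 3.5 mPa.s.
#'
#' @param density kg/m^3, > 0.
#' @param viscosity dynamic viscosity in Pa.s, > 0.
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1060, viscosity = 3.5e-3) {
  if (!is.finite(density) || density <= 0) stop("`density` must be positive")
  if (!is.finite(viscosity) || viscosity <= 0) stop("`viscosity` must be positive")
  structure(list(density = density, viscosity = viscosity),
            class = "fluid_properties")
}

#' Pipe model discretization
#'
#' Geometry and resolution for the reduced-order pulsatile pipe models.
#' `nt = 100` time steps per cardiac cycle is the default temporal
#' resolution of the transient solver.
#'
#' @param radius pipe radius in metres, > 0.
#' @param harmonics number of Fourier harmonics H (>= 1) kept by the
#'   analytic solution.
#' @param nr radial grid intervals (>= 16) for the finite-difference solver.
#' @param nt time steps per cycle (>= 4).
#' @return An object of class `pipe_spec`.
#' @export
pipe_spec <- function(radius, harmonics = 8L, nr = 100L, nt = 100L) {
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be positive")
  harmonics <- as.integer(harmonics); nr <- as.integer(nr); nt <- as.integer(nt)
  if (harmonics < 1L) stop("`harmonics` must be >= 1")
  if (nr < 16L) stop("`nr` must be >= 16")
  if (nt < 4L) stop("`nt` must be >= 4")
  structure(list(radius = radius, harmonics = harmonics, nr = nr, nt = nt),
            class = "pipe_spec")
}

#' Fourier decomposition of a periodic waveform
#'
#' Least-squares fit of the truncated series
#' `w(t) = c_0 + sum_{n=1}^{H} 2 Re( c_n exp(i n w t) )`, `w = 2 pi / T`,
#' to the waveform samples (the duplicated closing sample at `t = T` is
#' dropped first). On a uniform grid this reproduces the DFT coefficients;
#' `c_0` is the cycle mean.
#'
#' @param w a [waveform()].
#' @param H number of harmonics; the waveform must have at least `2H + 1`
#'   distinct samples.
#' @return Complex vector `c(c_0, c_1, ..., c_H)`.
#' @export
fourier_decompose <- function(w, H = 8L) {
  stopifnot(inherits(w, "waveform"))
  H <- as.integer(H)
  if (H < 1L) stop("`H` must be >= 1")
  t <- w$times[-length(w$times)]          # drop duplicated closing sample
  y <- w$values[-length(w$values)]
  if (length(t) < 2L * H + 1L) {
    stop("waveform has ", length(t), " distinct samples; need >= ", 2L * H + 1L,
         " for H = ", H)
  }
  om <- 2 * pi / w$period
  X <- cbind(1, do.call(cbind, lapply(1:H, function(n) {
    cbind(cos(n * om * t), sin(n * om * t))
  })))
  beta <- qr.solve(X, y)
  a <- beta[seq(2L, by = 2L, length.out = H)]
  b <- beta[seq(3L, by = 2L, length.out = H)]
  # a cos + b sin = 2 Re( c exp(i n w t) ) with c = (a - i b)/2
  c(complex(real = beta[1], imaginary = 0),
    complex(real = a / 2, imaginary = -b / 2))
}

# complex Bessel J0/J1 by power series; adequate for |z| <~ 25, i.e. any
# Womersley number alpha reachable at rat (or human) scale with H <= ~20.
besselJ0_c <- function(z) {
  term <- rep(1 + 0i, length(z))
  total <- term
  q <- -(z * z) / 4
  for (k in 1:80) {
    term <- term * q / (k * k)
    total <- total + term
    if (all(Mod(term) <= 1e-17 * (Mod(total) + 1e-300))) break
  }
  total
}

besselJ1_c <- function(z) {
  term <- z / 2
  total <- term
  q <- -(z * z) / 4
  for (k in 1:80) {
    term <- term * q / (k * (k + 1))
    total <- total + term
    if (all(Mod(term) <= 1e-17 * (Mod(total) + 1e-300))) break
  }
  total
}

# complex wall-shear amplitude per unit complex flow amplitude at angular
# frequency om (rad/s): tau_hat = K(om) * Q_hat. Lambda = i^{3/2} alpha.
womersley_tau_per_flow <- function(om, R, fluid) {
  if (om == 0) return(4 * fluid$viscosity / (pi * R^3))
  alpha <- R * sqrt(om * fluid$density / fluid$viscosity)
  Lam <- complex(modulus = 1, argument = 3 * pi / 4) * alpha
  J0 <- besselJ0_c(Lam)
  J1 <- besselJ1_c(Lam)
  F10 <- 2 * J1 / (Lam * J0)
  -fluid$viscosity * (Lam / R) * (J1 / J0) / (pi * R^2 * (1 - F10))
}

#' Analytic pulsatile (Womersley) wall shear stress in a rigid pipe
#'
#' Evaluates the wall shear stress time series of fully developed laminar
#' oscillatory pipe flow driven by a flow-rate waveform given as Fourier
#' harmonics. The steady component contributes the Poiseuille wall shear
#' `tau = 4 mu Q_mean / (pi R^3)`; each oscillatory harmonic uses the
#' classical Bessel-function solution at its Womersley number
#' `alpha_n = R sqrt(n w rho / mu)`.
#'
#' All quantities are SI: radius in m, flow harmonics in m^3/s, output in Pa.
#'
#' @param pipe a [pipe_spec()] (radius and `nt` are used).
#' @param fluid a [fluid_properties()].
#' @param flow_harmonics complex coefficients `c_0..c_H` from
#'   [fourier_decompose()] of a flow-rate waveform in m^3/s.
#' @param period cardiac cycle duration T in seconds.
#' @return `data.frame(time_s, tau_Pa)` with `nt + 1` rows spanning one
#'   cycle (closed at `t = T`). Sign convention: positive in the direction
#'   of mean flow.
#' @export
womersley_wss <- function(pipe, fluid, flow_harmonics, period) {
  stopifnot(inherits(pipe, "pipe_spec"), inherits(fluid, "fluid_properties"))
  if (!is.finite(period) || period <= 0) stop("`period` must be positive")
  R <- pipe$radius
  om <- 2 * pi / period
  t <- seq(0, period, length.out = pipe$nt + 1L)
  tau <- rep(Re(flow_harmonics[1]) * womersley_tau_per_flow(0, R, fluid), length(t))
  H <- length(flow_harmonics) - 1L
  if (H >= 1L) {
    for (n in 1:H) {
      K <- womersley_tau_per_flow(n * om, R, fluid)
      tau <- tau + Re(2 * flow_harmonics[n + 1L] * K * exp(1i * n * om * t))
    }
  }
  data.frame(time_s = t, tau_Pa = tau)
}

# analytic wall shear for a pressure-gradient drive G(t) = G0 + Re(Ghat e^{iwt});
# used as the independent oracle for the finite-difference solver.
womersley_wss_pressure <- function(pipe, fluid, G0, Ghat, period) {
  R <- pipe$radius
  om <- 2 * pi / period
  t <- seq(0, period, length.out = pipe$nt + 1L)
  tau <- rep(G0 * R / 2, length(t))
  if (Mod(Ghat) > 0) {
    alpha <- R * sqrt(om * fluid$density / fluid$viscosity)
    Lam <- complex(modulus = 1, argument = 3 * pi / 4) * alpha
    tau_hat <- -fluid$viscosity * (Ghat / (1i * fluid$density * om)) *
      (Lam / R) * besselJ1_c(Lam) / besselJ0_c(Lam)
    tau <- tau + Re(tau_hat * exp(1i * om * t))
  }
  data.frame(time_s = t, tau_Pa = tau)
}

#' Transient finite-difference pulsatile pipe solver
#'
#' Solves the axisymmetric laminar axial momentum equation
#' `rho du/dt = G(t) + mu (1/r) d/dr (r du/dr)` on `[0, R]` with no-slip at
#' the wall and symmetry at the axis, using Crank-Nicolson time stepping
#' (second order, unconditionally stable) with `nt` steps per cycle. The
#' `1/r` singularity at the axis is removed by L'Hopital regularization
#' (`(1/r) du/dr -> d2u/dr2` at `r = 0`). Wall shear is recovered from a
#' one-sided second-order difference of the velocity profile. The run
#' covers `n_cycles` cardiac cycles and the final cycle is returned, along
#' with the relative change in the wall-shear series between the last two
#' cycles (`cycle_delta`) as the periodicity-convergence diagnostic.
#'
#' @param pipe a [pipe_spec()].
#' @param fluid a [fluid_properties()].
#' @param pressure_gradient a [waveform()] of kind `"pressure_gradient"`
#'   giving the driving gradient `G(t) = -dp/dz` in Pa/m over one cycle.
#' @param n_cycles number of cardiac cycles to integrate (>= 1; default 3).
#' @return List with `times` (s, final cycle, length `nt + 1`), `tau` (Pa),
#'   `r` (m), `u` (velocity profiles of the final cycle, `(nr+1) x (nt+1)`,
#'   m/s), and `cycle_delta`.
#' @export
fd_pipe_solver <- function(pipe, fluid, pressure_gradient, n_cycles = 3L) {
  stopifnot(inherits(pipe, "pipe_spec"), inherits(fluid, "fluid_properties"),
            inherits(pressure_gradient, "waveform"))
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("`n_cycles` must be >= 1")
  T_ <- pressure_gradient$period
  R <- pipe$radius
  nr <- pipe$nr
  nt <- pipe$nt
  nu <- fluid$viscosity / fluid$density
  dr <- R / nr
  dt <- T_ / nt
  r <- seq(0, R, length.out = nr + 1L)

  # spatial operator L (m = nr+1 rows); wall row handled as Dirichlet
  m <- nr + 1L
  L <- matrix(0, m, m)
  L[1, 1] <- -4 * nu / dr^2        # axis: 2 nu u_rr with symmetric ghost
  L[1, 2] <- 4 * nu / dr^2
  for (j in 2:nr) {
    rj <- r[j]
    L[j, j - 1L] <- nu * (1 / dr^2 - 1 / (2 * dr * rj))
    L[j, j]      <- nu * (-2 / dr^2)
    L[j, j + 1L] <- nu * (1 / dr^2 + 1 / (2 * dr * rj))
  }
  A <- diag(m) - (dt / 2) * L
  B <- diag(m) + (dt / 2) * L
  A[m, ] <- 0; A[m, m] <- 1        # u(R) = 0
  B[m, ] <- 0
  Ainv <- solve(A)

  wall_tau <- function(u) fluid$viscosity * (4 * u[nr] - u[nr - 1L]) / (2 * dr)

  u <- numeric(m)
  nsteps <- n_cycles * nt
  tau_all <- numeric(nsteps + 1L)
  tau_all[1] <- wall_tau(u)
  u_last <- matrix(0, m, nt + 1L)
  u_last[, 1] <- u
  G_at <- function(t) waveform_at(pressure_gradient, t)
  force <- numeric(m)
  for (k in seq_len(nsteps)) {
    tk <- (k - 1L) * dt
    g <- (G_at(tk) + G_at(tk + dt)) / 2
    force[1:nr] <- dt * g / fluid$density
    u <- Ainv %*% (B %*% u + force)
    if (any(!is.finite(u))) {
      stop("fd_pipe_solver: non-finite solution at step ", k,
           " (t = ", format(tk + dt), " s); check the forcing waveform")
    }
    tau_all[k + 1L] <- wall_tau(u)
    if (k > nsteps - nt) u_last[, k - (nsteps - nt) + 1L] <- u
  }

  last <- tau_all[(nsteps - nt + 1L):(nsteps + 1L)]
  if (n_cycles >= 2L) {
    prev <- tau_all[(nsteps - 2L * nt + 1L):(nsteps - nt + 1L)]
    scale <- max(abs(last))
    cycle_delta <- if (scale > 0) max(abs(last - prev)) / scale else 0
  } else {
    cycle_delta <- NA_real_
  }

  list(times = seq(0, T_, length.out = nt + 1L), tau = last, r = r,
       u = u_last, cycle_delta = cycle_delta)
}

#' Split an inlet flow waveform across branch vessels
#'
#' Distributes an inlet flow-rate waveform over branches in fixed
#' proportions (a time-invariant split), e.g. innominate : left common
#' carotid : left subclavian ratios of 10:7:8 (SHR) or 9:6:10 (WKY). When
#' `branch_fraction < 1`, only that fraction of the inlet flow is shared
#' among the named branches and the remainder is returned as an extra
#' `"residual"` branch (the descending aorta). Branch flows sum to the
#' inlet flow at every instant.
#'
#' @param inlet a [waveform()] of kind `"flow"`.
#' @param ratios positive branch weights (at least one > 0).
#' @param branch_fraction fraction of inlet flow carried by the listed
#'   branches, in (0, 1]; default 1.
#' @return Named list of [waveform()]s, one per branch (plus `"residual"`
#'   when `branch_fraction < 1`).
#' @export
split_flow <- function(inlet, ratios, branch_fraction = 1) {
  stopifnot(inherits(inlet, "waveform"))
  nms <- names(ratios)
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L || any(!is.finite(ratios)) || any(ratios < 0)) {
    stop("`ratios` must be finite and nonnegative")
  }
  if (sum(ratios) <= 0) stop("all-zero branch ratios")
  if (!is.finite(branch_fraction) || branch_fraction <= 0 || branch_fraction > 1) {
    stop("`branch_fraction` must be in (0, 1]")
  }
  weights <- branch_fraction * ratios / sum(ratios)
  nms <- nms %||% paste0("branch", seq_along(ratios))
  out <- stats::setNames(lapply(weights, function(w) {
    waveform(inlet$times, inlet$values * w, inlet$period, kind = inlet$kind)
  }), nms)
  if (branch_fraction < 1) {
    out$residual <- waveform(inlet$times, inlet$values * (1 - branch_fraction),
                             inlet$period, kind = inlet$kind)
  }
  out
}

#' Reynolds number of pipe blood flow
#'
#' `Re = rho v d / mu` with mean velocity `v` (m/s) and diameter `d` (m).
#' A warning is emitted when `Re > 2000`, the conventional upper bound of
#' the laminar-flow assumption used throughout the flow models.
#'
#' @param v mean velocity in m/s (>= 0).
#' @param d vessel diameter in m (> 0).
#' @param fluid a [fluid_properties()].
#' @return Reynolds number (dimensionless).
#' @export
reynolds_number <- function(v, d, fluid = fluid_properties()) {
  stopifnot(inherits(fluid, "fluid_properties"))
  if (!is.finite(d) || d <= 0) stop("`d` must be positive")
  if (!is.finite(v) || v < 0) stop("`v` must be nonnegative")
  re <- fluid$density * v * d / fluid$viscosity
  if (re > 2000) {
    warning("Re = ", format(re, digits = 4),
            " exceeds 2000: laminar-flow assumption questionable")
  }
  re
}
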