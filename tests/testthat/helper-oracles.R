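# Independent brute-force reimplementation of the cycle-metric integrals:
# plain per-node / per-interval loops with scalar accumulation (periodic
# trapezoid), no shared code with the package internals.
oracle_metrics <- function(times, tau, period) {
  n <- dim(tau)[1]
  m <- length(times)
  if (abs(times[m] - period) > 1e-9 * period) {
    times <- c(times, period)
    tau2 <- array(0, c(n, m + 1L, 3))
    tau2[, 1:m, ] <- tau
    tau2[, m + 1L, ] <- tau[, 1L, ]
    tau <- tau2
    m <- m + 1L
  }
  tawss <- osi <- rrt <- numeric(n)
  for (i in seq_len(n)) {
    int_vec <- c(0, 0, 0)
    int_mag <- 0
    for (k in seq_len(m - 1L)) {
      dt <- times[k + 1L] - times[k]
      for (c in 1:3) {
        int_vec[c] <- int_vec[c] + 0.5 * (tau[i, k, c] + tau[i, k + 1L, c]) * dt
      }
      m0 <- sqrt(tau[i, k, 1]^2 + tau[i, k, 2]^2 + tau[i, k, 3]^2)
      m1 <- sqrt(tau[i, k + 1L, 1]^2 + tau[i, k + 1L, 2]^2 + tau[i, k + 1L, 3]^2)
      int_mag <- int_mag + 0.5 * (m0 + m1) * dt
    }
    tawss[i] <- int_mag / period
    osi[i] <- if (int_mag < 1e-12) 0 else {
      0.5 * (1 - sqrt(sum(int_vec^2)) / int_mag)
    }
    d <- (1 - 2 * osi[i]) * tawss[i]
    rrt[i] <- if (d < 1e-12) Inf else 1 / d
  }
  list(tawss = tawss, osi = osi, rrt = rrt)
}

# single equilateral triangle of side 1 mm in the xy plane
mesh_triangle <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)),
               rbind(c(1L, 2L, 3L)))
}

# unit cube surface, 12 triangles
mesh_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  tr <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0
    c(5, 6, 7), c(6, 8, 7),   # z = 1
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, tr)
}

# wss_field with every node carrying the same fixed-direction series
field_from_series <- function(mesh, times, series, period, dir = c(1, 0, 0)) {
  n <- nrow(mesh$vertices)
  tau <- array(0, c(n, length(times), 3))
  for (k in 1:3) tau[, , k] <- outer(rep(dir[k], n), series)
  wss_field(mesh, times, tau, period)
}

# random smooth per-node field (two harmonics, random direction per node)
random_field <- function(mesh, n_times = 16L, period = 0.22, seed = 1L) {
  set.seed(seed)
  n <- nrow(mesh$vertices)
  t <- seq(0, period, length.out = n_times + 1L)[seq_len(n_times)]
  tau <- array(0, c(n, n_times, 3))
  for (i in seq_len(n)) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    a <- stats::runif(1, 0.5, 5)
    b <- stats::runif(1, 0, 6)
    ph <- stats::runif(1, 0, 2 * pi)
    s <- a + b * sin(2 * pi * t / period + ph) +
      0.3 * b * cos(4 * pi * t / period)
    for (k in 1:3) tau[i, , k] <- s * d[k]
  }
  wss_field(mesh, t, tau, period)
}
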