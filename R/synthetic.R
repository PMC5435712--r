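#' Parametric curved-arch vessel geometry specification
#'
#' A torus-segment tube emulating an aortic arch: a circular centerline of
#' radius `centerline_radius` swept by a circular cross-section of radius
#' `vessel_radius` through `arch_angle` radians. The tube-circumference
#' angle `phi` is 0 on the outer (greater) curvature and `pi` on the inner
#' (lesser) curvature; the inner-arch region is the angular window of width
#' `inner_window` centred on `phi = pi`, mirroring where disturbed flow
#' concentrates on real arches. Default dimensions are rat-scale
#' (aorta ~2 mm across, tight arch).
#'
#' @param centerline_radius arch centerline radius of curvature (mm).
#' @param vessel_radius tube (lumen) radius (mm); must be smaller than
#'   `centerline_radius`.
#' @param n_theta axial resolution (>= 8 intervals along the arch).
#' @param n_phi circumferential resolution (>= 8 intervals around the tube).
#' @param arch_angle swept angle in radians, in (0, 2 pi]; default `pi`.
#' @param inner_window angular width of the inner-arch window, in (0, 2 pi).
#' @return An object of class `arch_spec`.
#' @export
arch_spec <- function(centerline_radius = 3, vessel_radius = 1,
                      n_theta = 48L, n_phi = 32L,
                      arch_angle = pi, inner_window = pi / 3) {
  if (!is.finite(centerline_radius) || centerline_radius <= 0) {
    stop("`centerline_radius` must be positive")
  }
  if (!is.finite(vessel_radius) || vessel_radius <= 0) {
    stop("`vessel_radius` must be positive")
  }
  if (vessel_radius >= centerline_radius) {
    stop("`vessel_radius` must be smaller than `centerline_radius` (no self-intersection)")
  }
  n_theta <- as.integer(n_theta); n_phi <- as.integer(n_phi)
  if (n_theta < 8L || n_phi < 8L) stop("resolution must be at least 8 x 8")
  if (!is.finite(arch_angle) || arch_angle <= 0 || arch_angle > 2 * pi) {
    stop("`arch_angle` must be in (0, 2 pi]")
  }
  if (!is.finite(inner_window) || inner_window <= 0 || inner_window >= 2 * pi) {
    stop("`inner_window` must be in (0, 2 pi)")
  }
  structure(list(centerline_radius = centerline_radius,
                 vessel_radius = vessel_radius,
                 n_theta = n_theta, n_phi = n_phi,
                 arch_angle = arch_angle, inner_window = inner_window),
            class = "arch_spec")
}

#' Generate a curved-arch tube mesh with named regions
#'
#' Builds the torus-segment surface described by an [arch_spec()]:
#' `(n_theta + 1) * n_phi` nodes (the tube wraps circumferentially, the
#' ends are open — there are no cap nodes, so every node is wall), and
#' `2 * n_theta * n_phi` triangles. Returns the mesh together with the
#' `inner_arch`, `outer_arch` and `whole_wall` region masks and the local
#' surface frame needed by [make_wss_field()].
#'
#' The analytic lateral area of the segment is
#' `arch_angle * 2 pi * vessel_radius * centerline_radius`; the mesh total
#' area converges to it under refinement (within 1% at the default
#' resolution).
#'
#' @param spec an [arch_spec()].
#' @return An object of class `arch_geometry`: list with `mesh`
#'   ([surface_mesh()]), `masks` (named list of [region_mask()]s), `phi`,
#'   `theta` (per-node tube/arch angles), `axial_tangent` (per-node unit
#'   vector along the flow direction) and `spec`.
#' @export
make_arch_mesh <- function(spec) {
  stopifnot(inherits(spec, "arch_spec"))
  Rc <- spec$centerline_radius
  rt <- spec$vessel_radius
  nth <- spec$n_theta
  nph <- spec$n_phi
  theta1 <- seq(0, spec$arch_angle, length.out = nth + 1L)
  phi1 <- seq(0, 2 * pi, length.out = nph + 1L)[-(nph + 1L)]  # wraps

  theta <- rep(theta1, each = nph)
  phi <- rep(phi1, times = nth + 1L)
  rad <- Rc + rt * cos(phi)
  vertices <- cbind(rad * cos(theta), rad * sin(theta), rt * sin(phi))

  node_id <- function(i, j) i * nph + (j %% nph) + 1L  # i in 0..nth, j in 0..nph-1
  i <- rep(0:(nth - 1L), each = nph)
  j <- rep(0:(nph - 1L), times = nth)
  v00 <- node_id(i, j); v10 <- node_id(i + 1L, j)
  v11 <- node_id(i + 1L, j + 1L); v01 <- node_id(i, j + 1L)
  triangles <- rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))

  mesh <- surface_mesh(vertices, triangles)

  dphi <- abs(atan2(sin(phi - pi), cos(phi - pi)))  # angular distance to inner line
  masks <- list(
    inner_arch = region_mask("inner_arch", which(dphi <= spec$inner_window / 2), mesh),
    outer_arch = region_mask("outer_arch", which(dphi >= pi - spec$inner_window / 2), mesh),
    whole_wall = whole_wall_mask(mesh)
  )
  axial_tangent <- cbind(-sin(theta), cos(theta), 0)

  structure(list(mesh = mesh, masks = masks, phi = phi, theta = theta,
                 axial_tangent = axial_tangent, spec = spec),
            class = "arch_geometry")
}

# run expr with a temporary RNG state seeded by `seed` (NULL = leave RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Rat-like cardiac velocity waveform
#'
#' A smooth periodic velocity waveform with period `60 / heart_rate`
#' seconds: a raised-cosine systolic pulse occupying a fraction of the
#' cycle on top of a small diastolic baseline flow. The maximum equals
#' `peak_velocity` exactly. With a `seed`, the systolic-duration fraction
#' is jittered slightly (+/- 0.02) to give animal-to-animal variety; the
#' same seed always reproduces the same waveform.
#'
#' @param heart_rate beats per minute, > 0 (rat-scale values are ~270-380).
#' @param peak_velocity peak systolic velocity in mm/s, > 0.
#' @param seed optional integer seed for shape jitter.
#' @param n_samples samples per cycle before periodic closure (default 100).
#' @param systolic_fraction nominal fraction of the cycle in systole.
#' @param diastolic_fraction diastolic baseline as a fraction of the peak.
#' @return A [waveform()] of kind `"velocity"`.
#' @export
make_waveform <- function(heart_rate, peak_velocity, seed = NULL,
                          n_samples = 100L, systolic_fraction = 0.35,
                          diastolic_fraction = 0.03) {
  if (!is.finite(heart_rate) || heart_rate <= 0) stop("`heart_rate` must be positive")
  if (!is.finite(peak_velocity) || peak_velocity <= 0) stop("`peak_velocity` must be positive")
  if (systolic_fraction <= 0 || systolic_fraction >= 1) {
    stop("`systolic_fraction` must be in (0, 1)")
  }
  period <- 60 / heart_rate
  fs <- systolic_fraction +
    with_seed(seed, if (is.null(seed)) 0 else stats::runif(1, -0.02, 0.02))
  t <- seq(0, period, length.out = n_samples + 1L)[-(n_samples + 1L)]
  base <- diastolic_fraction * peak_velocity
  pulse <- ifelse(t < fs * period,
                  0.5 * (1 - cos(2 * pi * t / (fs * period))), 0)
  pulse <- pulse / max(pulse)   # grid maximum hits the requested peak exactly
  v <- base + (peak_velocity - base) * pulse
  waveform(t, v, period, kind = "velocity")
}

#' Planted oscillatory WSS field specification
#'
#' Parameters of the synthetic WSS fields laid over an arch mesh: per node
#' the shear is `tau(t) = (a + b sin(2 pi t / T)) d_hat` along the local
#' axial tangent, with steady magnitude `a` near `baseline_wss` (log-free
#' multiplicative noise of coefficient of variation `noise_cv`) and
#' oscillatory amplitude `b = gamma a_ref`, where the amplitude ratio
#' `gamma` is `inner_amp_ratio` on the inner-arch line and decays as
#' `exp(-dphi / decay_scale)` with angular distance `dphi` from it — so the
#' oscillatory (high-OSI) character concentrates on the inner curvature.
#'
#' @param baseline_wss steady WSS magnitude scale in Pa (>= 0). The default
#'   20 Pa sits at the rodent-aorta scale implied by a 20 Pa low-TAWSS
#'   threshold.
#' @param inner_amp_ratio oscillation-to-steady amplitude ratio on the
#'   inner-arch line (>= 0); the default 8 drives inner-arch OSI to ~0.4.
#' @param decay_scale angular e-folding scale (radians) of the oscillation
#'   away from the inner line.
#' @param period cardiac cycle T in seconds.
#' @param n_samples time samples per cycle (default 100).
#' @param noise_cv coefficient of variation of per-node steady magnitude.
#' @param inner_steady_scale multiplier on the steady component inside the
#'   inner-arch window (0 gives pure oscillation there, OSI 0.5).
#' @param seed integer seed; mandatory (every field draw is reproducible).
#' @return An object of class `planted_field_spec`.
#' @export
planted_field_spec <- function(baseline_wss = 20, inner_amp_ratio = 8,
                               decay_scale = 0.2, period = 60 / 378,
                               n_samples = 100L, noise_cv = 0.05,
                               inner_steady_scale = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  if (!is.finite(baseline_wss) || baseline_wss < 0) stop("`baseline_wss` must be >= 0")
  if (!is.finite(inner_amp_ratio) || inner_amp_ratio < 0) stop("`inner_amp_ratio` must be >= 0")
  if (!is.finite(decay_scale) || decay_scale <= 0) stop("`decay_scale` must be positive")
  if (!is.finite(period) || period <= 0) stop("`period` must be positive")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("`noise_cv` must be >= 0")
  if (!is.finite(inner_steady_scale) || inner_steady_scale < 0) {
    stop("`inner_steady_scale` must be >= 0")
  }
  structure(list(baseline_wss = baseline_wss, inner_amp_ratio = inner_amp_ratio,
                 decay_scale = decay_scale, period = period,
                 n_samples = as.integer(n_samples), noise_cv = noise_cv,
                 inner_steady_scale = inner_steady_scale,
                 seed = as.integer(seed)),
            class = "planted_field_spec")
}

#' Closed-form OSI and cycle-mean magnitude of an offset sinusoid
#'
#' For a fixed-direction shear `tau(t) = a + b sin(2 pi t / T)` (`a, b >= 0`),
#' the cycle mean of `|tau|` is `a` when `b <= a` (no reversal) and
#' `(2 b / pi) (s asin s + sqrt(1 - s^2))` with `s = a / b` otherwise, and
#' `OSI = (1 - a / mean|tau|) / 2`. These are the ground-truth values the
#' planted fields are built from.
#'
#' @param a steady magnitude (>= 0).
#' @param b oscillatory amplitude (>= 0). Vectorized over `a` and `b`.
#' @return `data.frame(tawss, osi)` of the closed-form values.
#' @export
osi_offset_sine <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(abs(a), n); b <- rep_len(abs(b), n)
  tawss <- ifelse(b <= a, a, NA_real_)
  rev_ <- b > a & b > 0
  s <- ifelse(rev_, a / b, 0)
  m <- (2 * b / pi) * (s * asin(s) + sqrt(pmax(1 - s^2, 0)))
  tawss[rev_] <- m[rev_]
  osi <- numeric(n)
  nz <- tawss > 0
  osi[nz & rev_] <- 0.5 * (1 - a[nz & rev_] / tawss[nz & rev_])
  data.frame(tawss = tawss, osi = osi)
}

#' Generate a planted oscillatory WSS field on an arch
#'
#' Realizes the [planted_field_spec()] on an [make_arch_mesh()] geometry
#' and returns both the sampled field and the per-node analytic ground
#' truth (closed form via [osi_offset_sine()]), so recovery of the planted
#' structure by [compute_osi()]/[area_fraction()] can be checked exactly.
#'
#' @param arch an `arch_geometry` from [make_arch_mesh()].
#' @param spec a [planted_field_spec()].
#' @return List with `field` (a [wss_field()]) and `truth`
#'   (`data.frame(node_id, steady, osc, tawss_true, osi_true)`).
#' @export
make_wss_field <- function(arch, spec) {
  stopifnot(inherits(arch, "arch_geometry"), inherits(spec, "planted_field_spec"))
  n <- nrow(arch$mesh$vertices)
  dphi <- abs(atan2(sin(arch$phi - pi), cos(arch$phi - pi)))
  gamma <- spec$inner_amp_ratio * exp(-dphi / spec$decay_scale)

  steady_scale <- rep(1, n)
  steady_scale[arch$masks$inner_arch$node_ids] <- spec$inner_steady_scale
  noise <- with_seed(spec$seed, pmax(1 + spec$noise_cv * stats::rnorm(n), 0.05))
  a <- spec$baseline_wss * steady_scale * noise
  b <- spec$baseline_wss * gamma

  t <- seq(0, spec$period, length.out = spec$n_samples + 1L)
  s <- sin(2 * pi * t / spec$period)
  mag <- outer(a, rep(1, length(t))) + outer(b, s)   # n x (n_samples+1)
  tau <- array(0, dim = c(n, length(t), 3))
  for (k in 1:3) tau[, , k] <- mag * arch$axial_tangent[, k]

  truth <- osi_offset_sine(a, b)
  list(field = wss_field(arch$mesh, t, tau, spec$period),
       truth = data.frame(node_id = seq_len(n), steady = a, osc = b,
                          tawss_true = truth$tawss, osi_true = truth$osi))
}

#' Planted study-table specification
#'
#' Parameters for synthetic per-animal remodelling measurements with a
#' planted linear relationship to a regional haemodynamic metric:
#' `thickness = intercept + slope * metric + N(0, sd)`. The noise SD can be
#' given directly or derived from a target Pearson correlation via
#' [noise_sd_for_r()]. Defaults emulate a 4-group (WKY/SHR x saline/
#' nifedipine), n = 6 per group design with wall-thickness correlation
#' ~0.62 and elastin-layer correlation ~0.67 against inner-arch OSI.
#'
#' @param group_sizes integer vector of animals per group (each >= 2).
#' @param groups group labels, same length as `group_sizes`.
#' @param slope,intercept wall-thickness regression on the metric (mm).
#' @param noise_sd wall-thickness noise SD in mm, or `NULL` to derive from
#'   `target_r`.
#' @param target_r target Pearson correlation used when `noise_sd` is NULL.
#' @param elastin_slope,elastin_intercept,elastin_noise_sd,elastin_target_r
#'   same for the elastin layer thickness (mm).
#' @param seed integer seed; mandatory.
#' @return An object of class `planted_study_spec`.
#' @export
planted_study_spec <- function(group_sizes = rep(6L, 4L),
                               groups = c("WKY-CON", "SHR-CON", "WKY-NIF", "SHR-NIF"),
                               slope = 3.3, intercept = -1.0,
                               noise_sd = NULL, target_r = 0.62,
                               elastin_slope = 1.5, elastin_intercept = -0.53,
                               elastin_noise_sd = NULL, elastin_target_r = 0.672,
                               seed) {
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory")
  group_sizes <- as.integer(group_sizes)
  if (any(group_sizes < 2L)) stop("each group needs at least 2 animals")
  if (length(groups) != length(group_sizes)) stop("`groups`/`group_sizes` length mismatch")
  if (!is.null(noise_sd) && (!is.finite(noise_sd) || noise_sd < 0)) {
    stop("`noise_sd` must be >= 0")
  }
  structure(list(group_sizes = group_sizes, groups = as.character(groups),
                 slope = slope, intercept = intercept,
                 noise_sd = noise_sd, target_r = target_r,
                 elastin_slope = elastin_slope, elastin_intercept = elastin_intercept,
                 elastin_noise_sd = elastin_noise_sd, elastin_target_r = elastin_target_r,
                 seed = as.integer(seed)),
            class = "planted_study_spec")
}

#' Noise SD giving a target population Pearson correlation
#'
#' For `y = intercept + slope x + N(0, sd)` the population correlation is
#' `|slope| sd_x / sqrt(slope^2 sd_x^2 + sd^2)`; inverting gives
#' `sd = |slope| sd_x sqrt(1 / r^2 - 1)`.
#'
#' @param slope regression slope.
#' @param sd_x SD of the predictor.
#' @param r target correlation magnitude in (0, 1].
#' @return Noise standard deviation.
#' @export
noise_sd_for_r <- function(slope, sd_x, r) {
  if (!is.finite(r) || r <= 0 || r > 1) stop("`r` must be in (0, 1]")
  if (!is.finite(sd_x) || sd_x < 0) stop("`sd_x` must be >= 0")
  abs(slope) * sd_x * sqrt(1 / r^2 - 1)
}

#' Synthetic per-animal study table with planted remodelling correlations
#'
#' Takes one regional metric value per synthetic animal (e.g. inner-arch
#' OSI) and plants linearly related wall-thickness and elastin-thickness
#' measurements with Gaussian noise, per the [planted_study_spec()].
#' With zero noise the sample correlation is exactly 1.
#'
#' @param spec a [planted_study_spec()].
#' @param metric numeric vector, one regional metric value per animal
#'   (length `sum(spec$group_sizes)`), in group order.
#' @param metric_name column name for the metric (default `"osi_inner"`).
#' @return `data.frame(id, group, <metric_name>, wall_thickness_mm,
#'   elastin_thickness_mm)`.
#' @export
make_study_table <- function(spec, metric, metric_name = "osi_inner") {
  stopifnot(inherits(spec, "planted_study_spec"))
  n <- sum(spec$group_sizes)
  metric <- as.numeric(metric)
  if (length(metric) != n) {
    stop("`metric` must have one value per animal (", n, "), got ", length(metric))
  }
  if (any(!is.finite(metric))) stop("`metric` must be finite")
  sd_x <- stats::sd(metric)
  pick_sd <- function(given, slope, target) {
    if (!is.null(given)) return(given)
    if (sd_x == 0) stop("metric has zero variance; give `noise_sd` explicitly")
    noise_sd_for_r(slope, sd_x, target)
  }
  sd_w <- pick_sd(spec$noise_sd, spec$slope, spec$target_r)
  sd_e <- pick_sd(spec$elastin_noise_sd, spec$elastin_slope, spec$elastin_target_r)
  draws <- with_seed(spec$seed, list(w = stats::rnorm(n, 0, sd_w),
                                     e = stats::rnorm(n, 0, sd_e)))
  out <- data.frame(
    id = sprintf("animal%02d", seq_len(n)),
    group = rep(spec$groups, times = spec$group_sizes),
    metric = metric,
    wall_thickness_mm = spec$intercept + spec$slope * metric + draws$w,
    elastin_thickness_mm = spec$elastin_intercept + spec$elastin_slope * metric + draws$e
  )
  names(out)[names(out) == "metric"] <- metric_name
  out
}
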