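#' Per-node wall shear stress vector time series
#'
#' Binds a wall-shear vector history over one cardiac cycle to a surface
#' mesh. `tau` is an array of dimension `nodes x times x 3` (Pa). Times
#' must be strictly increasing within `[0, T]` with at least 3 samples; the
#' series is interpreted periodically, and a closing sample at `t = T`
#' (copied from `t = 0`) is synthesized during integration when absent.
#'
#' @param mesh a [surface_mesh()].
#' @param times sample instants in seconds.
#' @param tau numeric array `nodes x length(times) x 3`.
#' @param period cardiac cycle duration T in seconds.
#' @return An object of class `wss_field`.
#' @export
wss_field <- function(mesh, times, tau, period) {
  stopifnot(inherits(mesh, "surface_mesh"))
  times <- as.numeric(times)
  if (length(times) < 3L) stop("wss_field needs at least 3 time samples")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (!is.finite(period) || period <= 0) stop("`period` must be positive")
  if (times[1] < 0 || times[length(times)] > period * (1 + 1e-9)) {
    stop("`times` must lie within [0, T]")
  }
  tau <- as.array(tau)
  d <- dim(tau)
  if (length(d) != 3L || d[2] != length(times) || d[3] != 3L) {
    stop("`tau` must be a nodes x times x 3 array")
  }
  if (d[1] != nrow(mesh$vertices)) stop("`tau` node count does not match mesh")
  if (any(!is.finite(tau))) stop("`tau` contains non-finite values")
  structure(list(mesh = mesh, times = times, tau = tau, period = period),
            class = "wss_field")
}

#' @export
print.wss_field <- function(x, ...) {
  cat("wss_field:", dim(x$tau)[1], "nodes x", dim(x$tau)[2], "time samples, T =",
      format(x$period), "s\n")
  invisible(x)
}

#' Per-node scalar metric map
#'
#' A scalar field (TAWSS in Pa, OSI dimensionless, RRT in 1/Pa) bound to a
#' surface mesh, with a per-node logical `flags` vector marking degenerate
#' nodes (zero WSS over the whole cycle, or an RRT infinity sentinel).
#'
#' @param mesh a [surface_mesh()].
#' @param name `"TAWSS"`, `"OSI"` or `"RRT"`.
#' @param values per-node numeric values (`+Inf` allowed for RRT).
#' @param flags per-node logical degenerate markers (default all `FALSE`).
#' @return An object of class `metric_map`.
#' @export
metric_map <- function(mesh, name, values, flags = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  name <- match.arg(name, c("TAWSS", "OSI", "RRT"))
  values <- as.numeric(values)
  n <- nrow(mesh$vertices)
  if (length(values) != n) stop("`values` length must match node count")
  if (any(is.na(values))) stop("`values` must not contain NA/NaN")
  if (is.null(flags)) flags <- rep(FALSE, n)
  if (length(flags) != n) stop("`flags` length must match node count")
  if (name == "OSI" && (any(values < 0) || any(values > 0.5))) {
    stop("OSI values must lie in [0, 0.5]")
  }
  if (name == "TAWSS" && any(values < 0)) stop("TAWSS values must be >= 0")
  structure(list(mesh = mesh, name = name, values = values,
                 flags = as.logical(flags)),
            class = "metric_map")
}

#' @export
print.metric_map <- function(x, ...) {
  fin <- is.finite(x$values)
  cat("metric_map ", x$name, ": ", length(x$values), " nodes, range [",
      format(min(x$values[fin])), ", ", format(max(x$values[fin])), "], ",
      sum(x$flags), " flagged\n", sep = "")
  invisible(x)
}

# same mesh (cheap structural check, not identity)
same_mesh <- function(a, b) {
  nrow(a$vertices) == nrow(b$vertices) &&
    isTRUE(all.equal(sum(a$node_areas), sum(b$node_areas)))
}

# closing trapezoid weights over [0, T]; appends the t = T sample index 1
# when the series stops short of the period.
periodic_grid <- function(times, period) {
  n <- length(times)
  closed <- abs(times[n] - period) <= 1e-9 * period
  t_ext <- if (closed) times else c(times, period)
  src <- if (closed) seq_len(n) else c(seq_len(n), 1L)
  dt <- diff(t_ext)
  w <- numeric(length(t_ext))
  w[-length(w)] <- w[-length(w)] + dt / 2
  w[-1] <- w[-1] + dt / 2
  list(src = src, weights = w)
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Per node, `TAWSS = (1/T) int_0^T |tau(t)| dt`, the cycle average of the
#' WSS vector magnitude, integrated by the periodic trapezoidal rule.
#' Nodes whose WSS is identically zero over the cycle are flagged
#' degenerate (TAWSS = 0).
#'
#' @param field a [wss_field()].
#' @return A [metric_map()] named `"TAWSS"` (Pa).
#' @export
compute_tawss <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  g <- periodic_grid(field$times, field$period)
  mag <- sqrt(field$tau[, g$src, 1]^2 + field$tau[, g$src, 2]^2 +
                field$tau[, g$src, 3]^2)
  vals <- as.vector(mag %*% g$weights) / field$period
  metric_map(field$mesh, "TAWSS", vals, flags = vals <= 0)
}

#' Oscillatory shear index (OSI)
#'
#' Per node, `OSI = 1/2 (1 - |int_0^T tau dt| / int_0^T |tau| dt)`: the
#' vector integral is taken componentwise and its magnitude forms the
#' numerator. OSI is 0 for unidirectional WSS, 0.5 for fully reversing
#' zero-mean WSS. Values are clamped to `[0, 0.5]` against floating-point
#' drift. Nodes with cycle-integrated magnitude below 1e-12 Pa.s are
#' assigned OSI 0 and flagged degenerate.
#'
#' @param field a [wss_field()].
#' @return A [metric_map()] named `"OSI"` (dimensionless).
#' @export
compute_osi <- function(field) {
  stopifnot(inherits(field, "wss_field"))
  g <- periodic_grid(field$times, field$period)
  ix <- field$tau[, g$src, 1] %*% g$weights
  iy <- field$tau[, g$src, 2] %*% g$weights
  iz <- field$tau[, g$src, 3] %*% g$weights
  num <- sqrt(ix^2 + iy^2 + iz^2)
  mag <- sqrt(field$tau[, g$src, 1]^2 + field$tau[, g$src, 2]^2 +
                field$tau[, g$src, 3]^2)
  den <- as.vector(mag %*% g$weights)
  degen <- den < 1e-12
  osi <- numeric(length(den))
  osi[!degen] <- 0.5 * (1 - num[!degen] / den[!degen])
  osi <- pmin(pmax(osi, 0), 0.5)
  if (any(degen)) {
    message(sum(degen), " degenerate node(s): zero WSS over the cycle, OSI set to 0")
  }
  metric_map(field$mesh, "OSI", osi, flags = degen)
}

#' Relative residence time (RRT)
#'
#' Per node, `RRT = 1 / ((1 - 2 OSI) * TAWSS)` in 1/Pa, a surrogate for
#' near-wall particle residence: large where WSS is low and oscillatory.
#' Where the denominator falls below 1e-12 (OSI at 0.5, or zero TAWSS) the
#' node receives an `+Inf` sentinel and is flagged.
#'
#' @param tawss a `"TAWSS"` [metric_map()].
#' @param osi an `"OSI"` [metric_map()] on the same mesh.
#' @return A [metric_map()] named `"RRT"` (1/Pa).
#' @export
compute_rrt <- function(tawss, osi) {
  stopifnot(inherits(tawss, "metric_map"), inherits(osi, "metric_map"))
  if (tawss$name != "TAWSS" || osi$name != "OSI") {
    stop("compute_rrt needs a TAWSS map and an OSI map")
  }
  if (!same_mesh(tawss$mesh, osi$mesh)) stop("metric maps are on different meshes")
  delta <- (1 - 2 * osi$values) * tawss$values
  bad <- delta < 1e-12
  vals <- ifelse(bad, Inf, 1 / delta)
  metric_map(tawss$mesh, "RRT", vals, flags = bad | tawss$flags | osi$flags)
}

#' Area fraction above / below a threshold
#'
#' Area-weighted fraction of a region where the metric is strictly above
#' (or strictly below) a threshold, using the lumped node areas. Ties at
#' the threshold never qualify. `+Inf` sentinel nodes count as above any
#' finite threshold.
#'
#' @param map a [metric_map()].
#' @param mask a [region_mask()] on the map's mesh.
#' @param threshold finite scalar, in the metric's units.
#' @param direction `"above"` or `"below"`.
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction <- function(map, mask, threshold, direction = c("above", "below")) {
  stopifnot(inherits(map, "metric_map"), inherits(mask, "region_mask"))
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  ids <- mask$node_ids
  if (length(ids) == 0L) stop("empty mask")
  areas <- map$mesh$node_areas[ids]
  vals <- map$values[ids]
  hit <- if (direction == "above") vals > threshold else vals < threshold
  sum(areas[hit]) / sum(areas)
}

#' Area-weighted TAWSS histogram over fixed 20 Pa bins
#'
#' Divides TAWSS into 7 ranges at 20 Pa intervals —
#' `[0,20), [20,40), ..., [120, Inf)` — and returns the area fraction of
#' the region falling in each bin. Fractions sum to 1.
#'
#' @param map a `"TAWSS"` [metric_map()].
#' @param mask a [region_mask()] on the map's mesh.
#' @return Numeric vector of 7 fractions, named by bin.
#' @export
tawss_histogram <- function(map, mask) {
  stopifnot(inherits(map, "metric_map"), inherits(mask, "region_mask"))
  if (map$name != "TAWSS") stop("tawss_histogram needs a TAWSS map")
  ids <- mask$node_ids
  if (length(ids) == 0L) stop("empty mask")
  areas <- map$mesh$node_areas[ids]
  bin <- pmin(floor(map$values[ids] / 20), 6)
  out <- vapply(0:6, function(b) sum(areas[bin == b]), numeric(1)) / sum(areas)
  names(out) <- c(sprintf("[%d,%d)", seq(0, 100, 20), seq(20, 120, 20)), "[120,Inf)")
  out
}

#' Area-weighted regional mean of a metric
#'
#' Mean of the metric over a region, weighted by lumped node areas.
#' Non-finite nodes (RRT infinity sentinels) are excluded with a warning;
#' if every node in the region is non-finite an error is raised.
#'
#' @param map a [metric_map()].
#' @param mask a [region_mask()] on the map's mesh.
#' @return Scalar mean in the metric's units.
#' @export
regional_mean <- function(map, mask) {
  stopifnot(inherits(map, "metric_map"), inherits(mask, "region_mask"))
  ids <- mask$node_ids
  if (length(ids) == 0L) stop("empty mask")
  vals <- map$values[ids]
  areas <- map$mesh$node_areas[ids]
  fin <- is.finite(vals)
  if (!any(fin)) stop("all nodes in region '", mask$name, "' are non-finite")
  if (!all(fin)) {
    warning(sum(!fin), " non-finite node(s) excluded from regional mean of ",
            map$name)
  }
  sum(vals[fin] * areas[fin]) / sum(areas[fin])
}

#' Read / write WSS fields as long-format CSV
#'
#' Layout: `node_id,time_s,tx,ty,tz` with 1-based node ids; every node must
#' carry the same time samples.
#'
#' @param field a [wss_field()].
#' @param path CSV path.
#' @param mesh mesh to bind the field to on read.
#' @param period cycle duration T in seconds (read).
#' @return `write_wss_csv` returns `path` invisibly; `read_wss_csv` a
#'   [wss_field()].
#' @export
write_wss_csv <- function(field, path) {
  stopifnot(inherits(field, "wss_field"))
  d <- dim(field$tau)
  df <- data.frame(
    node_id = rep(seq_len(d[1]), times = d[2]),
    time_s = rep(field$times, each = d[1]),
    tx = as.vector(field$tau[, , 1]),
    ty = as.vector(field$tau[, , 2]),
    tz = as.vector(field$tau[, , 3]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path, mesh, period) {
  df <- utils::read.csv(path)
  need <- c("node_id", "time_s", "tx", "ty", "tz")
  if (!all(need %in% names(df))) stop("WSS CSV needs columns ", paste(need, collapse = ","))
  times <- sort(unique(df$time_s))
  nodes <- sort(unique(df$node_id))
  n <- length(nodes); m <- length(times)
  if (nrow(df) != n * m) stop("WSS CSV is not a complete node x time grid")
  df <- df[order(df$time_s, df$node_id), ]
  tau <- array(0, dim = c(n, m, 3))
  tau[, , 1] <- matrix(df$tx, n, m)
  tau[, , 2] <- matrix(df$ty, n, m)
  tau[, , 3] <- matrix(df$tz, n, m)
  wss_field(mesh, times, tau, period)
}

#' Write a metric map as CSV (`node_id,value,flag`)
#'
#' @param map a [metric_map()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_metric_csv <- function(map, path) {
  stopifnot(inherits(map, "metric_map"))
  utils::write.csv(data.frame(node_id = seq_along(map$values),
                              value = map$values, flag = map$flags),
                   path, row.names = FALSE)
  invisible(path)
}
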