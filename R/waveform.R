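#' Periodic cardiac-cycle waveform
#'
#' One cardiac cycle of a velocity (mm/s), flow-rate (mm^3/s) or
#' pressure-gradient (Pa/m) signal. Times must start at 0, be strictly
#' increasing, and end at or before the period `T`. The waveform is
#' interpreted periodically: a closing sample at `t = T` equal to the `t = 0`
#' value is enforced on construction (appended when absent; the final value
#' is replaced, with a warning if it disagrees by more than 1e-8 of the
#' signal range).
#'
#' @param times sample instants in seconds.
#' @param values signal values at `times`.
#' @param period cycle duration T in seconds.
#' @param kind one of `"velocity"`, `"flow"`, `"pressure_gradient"`.
#' @return An object of class `waveform` with elements `times`, `values`,
#'   `period`, `kind`.
#' @export
waveform <- function(times, values, period, kind = c("velocity", "flow", "pressure_gradient")) {
  kind <- match.arg(kind)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) stop("`times` and `values` lengths differ")
  if (length(times) < 2L) stop("waveform needs at least 2 samples")
  if (!is.finite(period) || period <= 0) stop("`period` must be positive")
  if (any(!is.finite(times)) || any(!is.finite(values))) stop("non-finite waveform samples")
  if (times[1] != 0) stop("`times` must start at 0")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  tol <- 1e-9 * period
  if (times[length(times)] > period + tol) stop("`times` must not exceed the period")

  if (abs(times[length(times)] - period) <= tol) {
    rng <- max(abs(values)) + .Machine$double.eps
    if (abs(values[length(values)] - values[1]) > 1e-8 * rng) {
      warning("closing sample at t = T differs from t = 0; replaced to enforce periodicity")
    }
    values[length(values)] <- values[1]
    times[length(times)] <- period
  } else {
    times <- c(times, period)
    values <- c(values, values[1])
  }

  structure(list(times = times, values = values, period = period, kind = kind),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat("waveform (", x$kind, "): ", length(x$times), " samples, T = ",
      format(x$period), " s, range [", format(min(x$values)), ", ",
      format(max(x$values)), "]\n", sep = "")
  invisible(x)
}

# periodic linear interpolation of a waveform at arbitrary times
waveform_at <- function(w, t) {
  tt <- t %% w$period
  stats::approx(w$times, w$values, xout = tt, rule = 2)$y
}

#' Read / write waveforms as two-column CSV
#'
#' The CSV layout is `time_s,value`; the period is taken from (or written
#' as) the last sample time, which by the [waveform()] closure convention
#' equals `T`.
#'
#' @param w a [waveform()].
#' @param path CSV file path.
#' @param kind signal kind, passed to [waveform()] on read.
#' @return `write_waveform_csv` returns `path` invisibly;
#'   `read_waveform_csv` a [waveform()].
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  utils::write.csv(data.frame(time_s = w$times, value = w$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, kind = "velocity") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(df))) {
    stop("waveform CSV needs columns time_s,value")
  }
  waveform(df$time_s, df$value, period = df$time_s[nrow(df)], kind = kind)
}
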