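#' Construct a one-cycle waveform
#'
#' @param times Strictly increasing sample times (s) with `times[1] = 0` and
#'   `times[length(times)] = period`.
#' @param values Sample values (mL/s for flow, mmHg for pressure).
#' @param period Cycle period T (s).
#' @param units Unit label carried with the waveform.
#' @return A `waveform`.
#' @export
waveform <- function(times, values, period, units = "mL/s") {
  stopifnot(length(times) >= 2, length(times) == length(values))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (abs(times[1]) > 1e-12 || abs(times[length(times)] - period) > 1e-9)
    stop("times must span [0, period]")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = period, units = units),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples over T = %.3g s, range [%.3g, %.3g] %s\n",
              length(x$times), x$period, min(x$values), max(x$values),
              x$units))
  invisible(x)
}

#' Generate a pulsatile one-cycle flow waveform
#'
#' A two-bump template (systolic peak plus a smaller dicrotic bump) sampled
#' at `n_frames` equidistant frames per cycle, affinely scaled so that the
#' trapezoidal cycle mean equals `q_mean` and the maximum equals `q_peak`
#' exactly on the sample grid. With a seed, a small smooth harmonic
#' perturbation is added before rescaling, emulating beat-shape variability.
#'
#' @param period Cycle period T (s).
#' @param q_mean,q_peak Cycle-mean and peak flow (mL/s), `q_peak > q_mean > 0`.
#' @param n_frames Frames per cycle (time step `period / n_frames`;
#'   `n_frames + 1` samples including both cycle endpoints). Default 40.
#' @param seed Optional integer seed for shape perturbation (`NULL` = pure
#'   template).
#' @return A flow `waveform` in mL/s.
#' @export
make_flow_waveform <- function(period = 1.0, q_mean = 6, q_peak = 20,
                               n_frames = 40, seed = NULL) {
  if (!(q_peak > q_mean) || q_mean <= 0)
    stop("need q_peak > q_mean > 0")
  if (n_frames < 8) stop("n_frames must be >= 8")
  t <- seq(0, period, length.out = n_frames + 1)
  u <- t / period
  shape <- exp(-(u - 0.16)^2 / (2 * 0.055^2)) +
           0.28 * exp(-(u - 0.45)^2 / (2 * 0.09^2))
  if (!is.null(seed)) {
    pert <- with_seed(seed, {
      a <- rnorm(3, sd = 0.02)
      ph <- runif(3, 0, 2 * pi)
      Reduce(`+`, lapply(1:3, function(k)
        a[k] * sin(2 * pi * k * u + ph[k])))
    })
    # keep the cycle periodic: the perturbation is periodic in u by design
    shape <- shape + pert
  }
  shape <- (shape - min(shape)) / (max(shape) - min(shape))  # to [0, 1]
  sbar <- trapz_int(t, shape) / period
  b <- (q_peak - q_mean) / (1 - sbar)
  a <- q_peak - b
  q <- a + b * shape
  if (min(q) <= 0)
    stop("waveform dips non-positive; q_peak/q_mean ratio too extreme for ",
         "the template shape")
  waveform(t, q, period, units = "mL/s")
}

#' Scale a flow waveform into a pressure waveform
#'
#' Affine map of the flow values so that the minimum maps to the diastolic
#' and the maximum to the systolic pressure; the time grid is unchanged.
#'
#' @param flow A flow `waveform`.
#' @param p_dia,p_sys Diastolic and systolic pressures (mmHg),
#'   `p_sys > p_dia > 0`.
#' @return A pressure `waveform` in mmHg.
#' @export
scale_pressure_waveform <- function(flow, p_dia = 80, p_sys = 120) {
  stopifnot(inherits(flow, "waveform"))
  if (!(p_sys > p_dia) || p_dia <= 0) stop("need p_sys > p_dia > 0")
  rng <- range(flow$values)
  if (diff(rng) < 1e-12)
    stop("constant flow waveform: pressure scaling undefined")
  p <- p_dia + (flow$values - rng[1]) / diff(rng) * (p_sys - p_dia)
  waveform(flow$times, p, flow$period, units = "mmHg")
}

#' Write / read a waveform as 2-column CSV
#'
#' Columns `time_s` and `value`; units go in a header comment-free second
#' column name suffix is avoided to keep the file strictly 2-column.
#'
#' @param wave A `waveform`.
#' @param path File path.
#' @return `read_waveform` returns a `waveform` (units must be re-supplied).
#' @export
write_waveform <- function(wave, path) {
  df <- data.frame(time_s = wave$times, value = wave$values)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @param units Units of the stored values.
#' @export
read_waveform <- function(path, units = "mL/s") {
  df <- read.csv(path)
  waveform(df$time_s, df$value, period = df$time_s[nrow(df)], units = units)
}
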