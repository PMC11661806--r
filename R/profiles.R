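# Calibrated constants of the packaged synthetic diurnal cortisol curve.
# The nadir (1.45 nM at 03:00) and peak time (08:00) are fixed from the
# reported free-cortisol microdialysis measurements; the peak height and
# shape exponent were calibrated once (scripts/calibrate_cortisol.R) so
# that the full steady-state model reproduces a peak relative activity of
# 0.39 and a 24-h mean relative activity (GTQ) of 0.17.
GR_CORTISOL_NADIR_NM <- 1.45
GR_CORTISOL_NADIR_MIN <- 180
GR_CORTISOL_PEAK_MIN <- 480
GR_CORTISOL_PEAK_NM <- 29.568809
GR_CORTISOL_SHAPE <- 4.098953

new_gr_profile <- function(fun, domain, period = NA_real_,
                           breaks = numeric(0), label = "profile") {
  stopifnot(is.function(fun), length(domain) == 2L, domain[2] > domain[1])
  structure(list(fun = fun, domain = domain, period = period,
                 breaks = sort(unique(breaks)), label = label),
            class = "gr_profile")
}

#' Evaluate a concentration profile
#'
#' @param profile a `gr_profile`.
#' @param t time(s) in minutes; must lie within the profile domain.
#' @return free concentration(s) in nM (clipped at 0).
#' @export
gr_profile_value <- function(profile, t) {
  stopifnot(inherits(profile, "gr_profile"))
  if (any(t < profile$domain[1] - 1e-9 | t > profile$domain[2] + 1e-9)) {
    stop("time outside the profile domain [", profile$domain[1], ", ",
         profile$domain[2], "] min")
  }
  pmax(profile$fun(t), 0)
}

#' @export
print.gr_profile <- function(x, ...) {
  cat(sprintf("<gr_profile> %s on [%g, %g] min%s\n", x$label,
              x$domain[1], x$domain[2],
              if (is.na(x$period)) "" else sprintf(", period %g min", x$period)))
  invisible(x)
}

#' @export
plot.gr_profile <- function(x, by = 1, ...) {
  tt <- seq(x$domain[1], x$domain[2], by = by)
  graphics::plot(tt, gr_profile_value(x, tt), type = "l",
                 xlab = "time (min)", ylab = "free concentration (nM)", ...)
  invisible(x)
}

#' Constant concentration profile
#'
#' @param value free concentration in nM (>= 0).
#' @param t_end end of the domain in minutes (default two days).
#' @return a `gr_profile`.
#' @export
gr_profile_constant <- function(value, t_end = 2880) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  new_gr_profile(function(t) rep(value, length(t)), c(0, t_end),
                 label = sprintf("constant %g nM", value))
}

#' Piecewise-constant (step) concentration profile
#'
#' Right-continuous step profile: `levels` gives the start time of each
#' segment and its concentration; the first segment must start at t = 0
#' and start times must be strictly increasing.
#'
#' @param levels data.frame (or 2-column matrix) with columns
#'   `start_min`, `nM`.
#' @param t_end end of the domain (default two days).
#' @return a `gr_profile` carrying the segment boundaries as integration
#'   break points.
#' @examples
#' gr_profile_step(data.frame(start_min = c(0, 100), nM = c(100, 20100)))
#' @export
gr_profile_step <- function(levels, t_end = 2880) {
  levels <- as.data.frame(levels)
  names(levels) <- c("start_min", "nM")
  if (nrow(levels) < 1L || levels$start_min[1] != 0) {
    stop("step profile must start at t = 0")
  }
  if (any(diff(levels$start_min) <= 0)) {
    stop("segment start times must be strictly increasing (no zero-duration segments)")
  }
  if (any(levels$nM < 0)) stop("concentrations must be non-negative")
  starts <- levels$start_min
  vals <- levels$nM
  fun <- function(t) vals[findInterval(t, starts)]
  new_gr_profile(fun, c(0, t_end), breaks = starts[-1], label = "step profile")
}

#' Smooth profile through tabulated samples
#'
#' Periodic (or natural) cubic-spline interpolant through measured
#' (time, concentration) samples, clipped at zero. With `periodic = TRUE`
#' the samples are treated as one 24-h day and the curve repeats daily.
#'
#' @param time_min sample times in minutes, strictly increasing, within
#'   one day for periodic profiles; at least 4 samples.
#' @param nM free concentrations (nM, >= 0).
#' @param periodic repeat with a 1440-min period (default `TRUE`).
#' @param t_end domain end (default two days).
#' @return a `gr_profile`.
#' @export
gr_profile_table <- function(time_min, nM, periodic = TRUE, t_end = 2880) {
  if (length(time_min) < 4L) stop("need at least 4 samples")
  if (any(diff(time_min) <= 0)) stop("sample times must be strictly increasing")
  if (any(nM < 0)) stop("concentrations must be non-negative")
  if (periodic) {
    if (time_min[length(time_min)] - time_min[1] >= 1440) {
      stop("periodic samples must lie within one day")
    }
    sf <- stats::splinefun(c(time_min, time_min[1] + 1440), c(nM, nM[1]),
                           method = "periodic")
    fun <- function(t) sf(t)
    new_gr_profile(fun, c(0, t_end), period = 1440, label = "tabulated (periodic)")
  } else {
    sf <- stats::splinefun(time_min, nM, method = "natural")
    new_gr_profile(function(t) sf(t), range(time_min), label = "tabulated")
  }
}

#' Read / write two-column profile CSV
#'
#' @param path CSV file with columns `time_min`, `nM`.
#' @param periodic passed to [gr_profile_table()].
#' @return a `gr_profile`.
#' @export
gr_read_profile <- function(path, periodic = TRUE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  gr_profile_table(d$time_min, d$nM, periodic = periodic)
}

#' @rdname gr_read_profile
#' @param profile a `gr_profile`.
#' @param by sampling step (min).
#' @export
gr_write_profile <- function(profile, path, by = 1) {
  tt <- seq(profile$domain[1], profile$domain[2], by = by)
  utils::write.csv(data.frame(time_min = tt, nM = gr_profile_value(profile, tt)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Specification of the synthetic diurnal cortisol curve
#'
#' A deterministic 24-h periodic stand-in for measured free-plasma
#' cortisol: an asymmetric raised-cosine bump that attains `nadir_nM`
#' exactly at `nadir_time` and `peak_nM` exactly at `peak_time`, with a
#' short rising limb (nadir to peak, 5 h by default) and a long falling
#' limb. `shape` is a dimensionless width exponent (> 0): larger values
#' concentrate the curve around the morning peak. Defaults are the
#' packaged calibration (see [gr_cortisol_profile()]).
#'
#' @param nadir_nM,peak_nM nadir and peak free concentrations (nM).
#' @param nadir_time,peak_time clock times in minutes since midnight.
#' @param shape width exponent (> 0).
#' @return a list of class `gr_cortisol_spec`.
#' @export
gr_cortisol_spec <- function(nadir_nM = GR_CORTISOL_NADIR_NM,
                             nadir_time = GR_CORTISOL_NADIR_MIN,
                             peak_nM = GR_CORTISOL_PEAK_NM,
                             peak_time = GR_CORTISOL_PEAK_MIN,
                             shape = GR_CORTISOL_SHAPE) {
  stopifnot(nadir_nM >= 0, peak_nM > nadir_nM, shape > 0,
            nadir_time >= 0, nadir_time < 1440,
            peak_time >= 0, peak_time < 1440, nadir_time != peak_time)
  structure(list(nadir_nM = nadir_nM, nadir_time = nadir_time,
                 peak_nM = peak_nM, peak_time = peak_time, shape = shape),
            class = "gr_cortisol_spec")
}

#' Synthetic diurnal endogenous-cortisol profile
#'
#' Deterministic 24-h periodic free-cortisol forcing used as the packaged
#' stand-in for measured diurnal microdialysis data. The curve is
#' \deqn{G(t) = nadir + (peak - nadir)\,\left(\frac{1+\cos\theta(t)}2\right)^{shape},}
#' where the phase runs linearly from 0 at the peak to pi at the nadir
#' along each limb, making the bump asymmetric (5-h rise, 19-h decline by
#' default). With the default calibrated spec the full model yields a peak
#' relative activity of 0.39 and a day-2 GTQ of 0.17.
#'
#' @param spec a [gr_cortisol_spec()].
#' @param days number of repeated days in the domain (default 2).
#' @return a `gr_profile` with period 1440 min.
#' @examples
#' p <- gr_cortisol_profile()
#' gr_profile_value(p, 180) # 1.45 nM at 03:00
#' @export
gr_cortisol_profile <- function(spec = gr_cortisol_spec(), days = 2) {
  stopifnot(inherits(spec, "gr_cortisol_spec"), days >= 1)
  fall <- (spec$nadir_time - spec$peak_time) %% 1440
  rise <- 1440 - fall
  fun <- function(t) {
    u <- (t - spec$peak_time) %% 1440
    th <- ifelse(u <= fall, pi * u / fall, pi + pi * (u - fall) / rise)
    spec$nadir_nM + (spec$peak_nM - spec$nadir_nM) * ((1 + cos(th)) / 2)^spec$shape
  }
  new_gr_profile(fun, c(0, days * 1440), period = 1440,
                 label = "synthetic diurnal cortisol")
}
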