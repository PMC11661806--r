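#' Glucocorticoid transcription quotient (GTQ)
#'
#' The GTQ summarises a 24-hour exposure as the time-average of the
#' receptor activity relative to its theoretical maximum:
#' \deqn{GTQ = \frac{1}{1440}\int_{day} \frac{f_{RnGN}(t)}{RnGN_{max}}\,dt,}
#' so `GTQ = 1` for an infinite constant dose and 0 for no exposure. To
#' eliminate initial-value effects the model is run over a burn-in day and
#' the quotient is evaluated on the second (midnight-to-midnight) day;
#' the integral is a trapezoid on the output grid.
#'
#' `method = "time-dependent"` (default) integrates the kinetic model
#' under the forcing profile; `method = "steady-state"` applies the
#' analytic steady state pointwise to G(t), which is accurate whenever the
#' forcing varies slowly compared with the receptor cycle (diurnal and
#' dosing time-scales).
#'
#' @param ligand,rates model parameters.
#' @param profile a `gr_profile` covering at least `window`.
#' @param method `"time-dependent"` or `"steady-state"`.
#' @param dt integration/quadrature grid step (min, default 1).
#' @param window measurement window (min, exactly 24 h; default the
#'   second simulated day, c(1440, 2880)).
#' @param description free-text label stored in the result.
#' @return an object of class `gr_gtq` with fields `value`, `window`,
#'   `method`, `dt`, `description`.
#' @examples
#' gr_gtq("cortisol", profile = gr_cortisol_profile())
#' @export
gr_gtq <- function(ligand, rates = gr_rates(), profile,
                   method = c("time-dependent", "steady-state"), dt = 1,
                   window = c(1440, 2880), description = profile$label) {
  ligand <- as_gr_ligand(ligand)
  method <- match.arg(method)
  stopifnot(inherits(profile, "gr_profile"), length(window) == 2L)
  if (abs(diff(window) - 1440) > 1e-9) stop("GTQ window must span exactly 24 h")
  if (profile$domain[1] > 0 || profile$domain[2] < window[2] - 1e-9) {
    stop("profile must cover the burn-in plus the measurement window [0, ",
         window[2], "] min")
  }
  if (method == "time-dependent") {
    traj <- gr_simulate(ligand, rates, profile, t_start = 0, t_end = window[2],
                        dt = dt)
    keep <- traj$time >= window[1] - 1e-9
    tt <- traj$time[keep]
    act <- traj$relative_activity[keep]
  } else {
    tt <- seq(window[1], window[2], by = dt)
    rmax <- rngn_max(rates)
    act <- vapply(gr_profile_value(profile, tt), function(g)
      f_rngn(gr_steady_state(ligand, rates, g)) / rmax, numeric(1))
  }
  value <- sum(diff(tt) * (act[-1] + act[-length(act)]) / 2) / 1440
  value <- min(max(value, 0), 1)
  structure(list(value = value, window = window, method = method, dt = dt,
                 description = description),
            class = "gr_gtq")
}

#' @export
print.gr_gtq <- function(x, ...) {
  cat(sprintf("GTQ = %.3f  (%s; %s; day window [%g, %g] min)\n", x$value,
              x$description, x$method, x$window[1], x$window[2]))
  invisible(x)
}

#' GTQ of a dosing regimen
#'
#' Composes [gr_free_concentration()] with [gr_gtq()]. The
#' pharmacodynamically active ligand is inferred from the drug (for
#' prednisone regimens it is prednisolone). The default activity model is
#' the analytic steady state applied to G(t), appropriate for the slowly
#' varying plasma profiles of dosing regimens.
#'
#' @param regimen a [gr_regimen()] (needs `days >= 2`).
#' @param params PK parameters, defaulting to the packaged set.
#' @param ligand PD parameters; default inferred from the drug.
#' @param rates a [gr_rates()].
#' @param method,dt passed to [gr_gtq()].
#' @return a `gr_gtq`.
#' @examples
#' gr_regimen_gtq(gr_regimen("methylprednisolone", 320, "q.d.", "IV"))
#' @export
gr_regimen_gtq <- function(regimen, params = gr_pk_params(regimen$drug),
                           ligand = NULL, rates = gr_rates(),
                           method = "steady-state", dt = 1) {
  stopifnot(inherits(regimen, "gr_regimen"))
  if (regimen$days < 2) stop("regimen must cover at least 2 days (burn-in + measurement)")
  if (is.null(ligand)) ligand <- GR_PD_LIGAND[[regimen$drug]]
  profile <- gr_free_concentration(regimen, params)
  desc <- sprintf("%s %g mg %s %s", regimen$drug, regimen$total_daily_mg,
                  regimen$route, if (regimen$schedule == "bid") "b.i.d." else "q.d.")
  gr_gtq(ligand, rates, profile, method = method, dt = dt, description = desc)
}

#' Regimen comparison table
#'
#' Computes the GTQ for the packaged battery of dosing regimens (the
#' dexamethasone, methylprednisolone and prednisone dose ladders plus
#' endogenous cortisol under the synthetic diurnal profile). Drug rows use
#' the steady-state activity model; the endogenous cortisol row uses the
#' exact time-dependent model.
#'
#' @param rates a [gr_rates()].
#' @param dt grid step (min).
#' @return data.frame with columns drug, dose, schedule, route, GTQ.
#' @export
gr_table4 <- function(rates = gr_rates(), dt = 1) {
  specs <- list(
    list("dexamethasone", 1, "qd", "IV"), list("dexamethasone", 10, "qd", "IV"),
    list("dexamethasone", 10, "bid", "IV"), list("dexamethasone", 40, "qd", "IV"),
    list("dexamethasone", 1, "qd", "oral"), list("dexamethasone", 10, "qd", "oral"),
    list("dexamethasone", 40, "qd", "oral"),
    list("methylprednisolone", 5, "qd", "IV"), list("methylprednisolone", 20, "qd", "IV"),
    list("methylprednisolone", 20, "bid", "IV"), list("methylprednisolone", 80, "qd", "IV"),
    list("methylprednisolone", 80, "bid", "IV"), list("methylprednisolone", 320, "qd", "IV"),
    list("methylprednisolone", 320, "bid", "IV"),
    list("prednisone", 5, "qd", "oral"), list("prednisone", 10, "qd", "oral"),
    list("prednisone", 10, "bid", "oral"), list("prednisone", 20, "qd", "oral"),
    list("prednisone", 100, "qd", "oral"), list("prednisone", 100, "bid", "oral"),
    list("prednisone", 400, "qd", "oral"))
  rows <- lapply(specs, function(s) {
    reg <- gr_regimen(s[[1]], s[[2]], s[[3]], s[[4]])
    q <- gr_regimen_gtq(reg, rates = rates, dt = dt)
    data.frame(drug = s[[1]], dose_mg_per_day = s[[2]],
               schedule = if (s[[3]] == "bid") "b.i.d." else "q.d.",
               route = s[[4]], GTQ = round(q$value, 3),
               stringsAsFactors = FALSE)
  })
  cort <- gr_gtq("cortisol", rates, gr_cortisol_profile(), method = "time-dependent",
                 dt = dt)
  rbind(data.frame(drug = "cortisol", dose_mg_per_day = NA, schedule = "endogenous",
                   route = "", GTQ = round(cort$value, 3), stringsAsFactors = FALSE),
        do.call(rbind, rows))
}
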