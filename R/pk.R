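GR_PD_LIGAND <- c(dexamethasone = "dexamethasone",
                  methylprednisolone = "methylprednisolone",
                  prednisone = "prednisolone")

mg_to_nmol <- function(mg, MW) mg * 1e6 / MW

#' Pharmacokinetic parameter sets
#'
#' Packaged PK constants per drug. Dexamethasone and methylprednisolone
#' use linear two-compartment disposition with first-order oral
#' absorption; prednisone uses a nonlinear prodrug model (see
#' [gr_free_concentration()]). The plasma free fractions (0.23), the oral
#' dexamethasone bioavailability (0.59) and the molecular weights are
#' reference values; the clearances, volumes, absorption and
#' interconversion constants are literature-plausible placeholder values
#' (flagged in the `param_status` field) pending an authoritative
#' transcription, so regimen-level outputs should be read as structural,
#' not quantitative, predictions.
#'
#' @param drug `"dexamethasone"`, `"methylprednisolone"` or `"prednisone"`.
#' @return a list of class `gr_pk_linear` or `gr_pk_prednisone`.
#' @export
gr_pk_params <- function(drug) {
  drug <- match.arg(tolower(drug), names(GR_PD_LIGAND))
  if (drug == "prednisone") {
    tab <- utils::read.csv(.gr_extdata("gr_pk_prednisone.csv"),
                           stringsAsFactors = FALSE)
    p <- as.list(stats::setNames(tab$value, tab$param))
    p$drug <- "prednisone"
    p$param_status <- "placeholder"
    class(p) <- "gr_pk_prednisone"
    return(p)
  }
  tab <- utils::read.csv(.gr_extdata("gr_pk_linear.csv"), stringsAsFactors = FALSE)
  row <- tab[tab$drug == drug, ]
  p <- as.list(row)
  class(p) <- "gr_pk_linear"
  p
}

#' Build a dosing regimen
#'
#' `schedule = "q.d."` gives one dose per day at `dose_time`;
#' `"b.i.d."` splits the daily total into two equal doses 12 h apart.
#' Doses repeat daily for `days` days (default 2: burn-in day plus
#' measurement day).
#'
#' @param drug drug name.
#' @param total_daily_mg total daily dose in mg (> 0).
#' @param schedule `"q.d."` or `"b.i.d."` (also accepts `"qd"`, `"bid"`).
#' @param route `"IV"` or `"oral"`.
#' @param days number of dosing days.
#' @param dose_time clock time of the (first) daily dose, minutes since
#'   midnight (default 480 = 08:00) or `"HH:MM"`.
#' @param salt salt/ester form of the administered dose; `"default"`
#'   picks the conventional form (dexamethasone IV is given as the
#'   phosphate ester and converted by molecular-weight ratio).
#' @return an object of class `gr_regimen` with an `events` data.frame
#'   (drug, route, amount_mg, time_min, salt).
#' @examples
#' gr_regimen("methylprednisolone", 320, "b.i.d.", "IV")
#' @export
gr_regimen <- function(drug, total_daily_mg, schedule = c("q.d.", "b.i.d."),
                       route = c("IV", "oral"), days = 2, dose_time = 480,
                       salt = "default") {
  drug <- match.arg(tolower(drug), names(GR_PD_LIGAND))
  schedule <- gsub("\\.", "", tolower(schedule[1]))
  if (!schedule %in% c("qd", "bid")) stop("schedule must be q.d. or b.i.d.")
  route <- match.arg(route)
  if (drug == "prednisone" && route == "IV") {
    stop("prednisone is only administered orally")
  }
  stopifnot(total_daily_mg > 0, days >= 1)
  if (is.character(dose_time)) dose_time <- .gr_parse_clock(dose_time)
  stopifnot(dose_time >= 0, dose_time < 1440)
  if (identical(salt, "default")) {
    salt <- if (drug == "dexamethasone" && route == "IV") "phosphate" else "none"
  }
  within_day <- if (schedule == "bid") c(dose_time, dose_time + 720) else dose_time
  within_day <- within_day %% 1440
  amt <- total_daily_mg / length(within_day)
  times <- as.vector(outer(within_day, (seq_len(days) - 1L) * 1440, `+`))
  events <- data.frame(drug = drug, route = route, amount_mg = amt,
                       time_min = sort(times), salt = salt,
                       stringsAsFactors = FALSE)
  structure(list(drug = drug, route = route, schedule = schedule,
                 total_daily_mg = total_daily_mg, days = days,
                 events = events),
            class = "gr_regimen")
}

.gr_parse_clock <- function(x) {
  parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(parts) != 2L || any(is.na(parts))) stop("clock time must be HH:MM")
  parts[1] * 60 + parts[2]
}

#' Parse a compact regimen description
#'
#' @param text e.g. `"prednisone 100mg oral b.i.d."`.
#' @param days number of dosing days.
#' @return a [gr_regimen()].
#' @export
gr_parse_regimen <- function(text, days = 2) {
  tok <- strsplit(trimws(text), "\\s+")[[1]]
  if (length(tok) != 4L) stop("expected 'drug DOSEmg route schedule'")
  mg <- as.numeric(sub("mg$", "", tok[2], ignore.case = TRUE))
  if (is.na(mg)) stop("could not parse dose: ", tok[2])
  route <- if (tolower(tok[3]) == "iv") "IV" else "oral"
  gr_regimen(tok[1], mg, schedule = tok[4], route = route, days = days)
}

#' @export
print.gr_regimen <- function(x, ...) {
  cat(sprintf("<gr_regimen> %s %g mg/day %s %s, %d day(s)\n", x$drug,
              x$total_daily_mg, x$route,
              if (x$schedule == "bid") "b.i.d." else "q.d.", x$days))
  print(x$events)
  invisible(x)
}

# --- linear two-compartment disposition -------------------------------------

.gr_linear_macro <- function(p) {
  k10 <- (p$CL_L_per_h / 60) / p$Vc_L
  k12 <- (p$Q_L_per_h / 60) / p$Vc_L
  k21 <- (p$Q_L_per_h / 60) / p$Vp_L
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  list(alpha = (s + disc) / 2, beta = (s - disc) / 2, k21 = k21)
}

# total central concentration (nM) for a unit dose of 1 nmol at t = 0
.gr_unit_conc <- function(t, p, route) {
  m <- .gr_linear_macro(p)
  a <- m$alpha; b <- m$beta; k21 <- m$k21
  pos <- t >= 0
  out <- numeric(length(t))
  if (route == "IV") {
    A <- (a - k21) / (a - b)
    B <- (k21 - b) / (a - b)
    out[pos] <- (A * exp(-a * t[pos]) + B * exp(-b * t[pos])) / p$Vc_L
  } else {
    ka <- p$ka_per_min
    if (any(abs(c(ka - a, ka - b)) < 1e-12)) stop("degenerate PK eigenvalues")
    A <- (k21 - a) / ((ka - a) * (b - a))
    B <- (k21 - b) / ((ka - b) * (a - b))
    C <- (k21 - ka) / ((a - ka) * (b - ka))
    out[pos] <- p$F * ka * (A * exp(-a * t[pos]) + B * exp(-b * t[pos]) +
                              C * exp(-ka * t[pos])) / p$Vc_L
  }
  out
}

.gr_active_nmol <- function(ev, p) {
  mg <- ev$amount_mg
  if (ev$salt != "none") {
    if (is.na(p$MW_salt)) stop("no salt molecular weight available for ", ev$drug)
    mg <- mg * p$MW / p$MW_salt # active-drug equivalents of the dosed ester
  }
  mg_to_nmol(mg, p$MW)
}

#' Free plasma concentration profile of a regimen
#'
#' Computes the free (unbound) concentration of the pharmacodynamically
#' active species over the regimen horizon. Dexamethasone and
#' methylprednisolone use analytic linear two-compartment kinetics (IV
#' bolus or first-order oral absorption); the regimen profile is the exact
#' superposition of single-dose solutions, and IV ester doses are
#' converted to active-drug equivalents by molecular-weight ratio before
#' absorption/bioavailability scaling. For prednisone the nonlinear
#' prodrug system is integrated (see details) and the returned profile is
#' the free prednisolone concentration.
#'
#' The prednisone model tracks total plasma prednisone and prednisolone.
#' Absorbed drug is split at first pass: a fraction `f_firstpass` enters
#' the circulation already converted to prednisolone (hepatic
#' 11beta-HSD1), the remainder as prednisone.
#' Elimination and the two-way interconversion act on the free
#' concentrations; free prednisone is a fixed fraction `fu_pred` of total,
#' while free prednisolone follows the saturable transcortin + linear
#' (albumin-like) binding equilibrium solved by
#' [prednisolone_free_fraction()]. Binding saturation makes the free
#' fraction, and hence clearance, rise with concentration, so
#' superposition fails and the total prednisolone/prednisone ratio varies
#' nonlinearly with dose.
#'
#' @param regimen a [gr_regimen()].
#' @param params a [gr_pk_params()] set; defaults to the packaged set for
#'   the regimen's drug.
#' @param dt internal grid step for the nonlinear model (min).
#' @return a `gr_profile` of free active-species concentration (nM) on
#'   `[0, days*1440]`. For prednisone the profile carries a `species`
#'   attribute: data.frame of time, total and free prednisolone and total
#'   prednisone (nM).
#' @export
gr_free_concentration <- function(regimen, params = gr_pk_params(regimen$drug),
                                  dt = 1) {
  stopifnot(inherits(regimen, "gr_regimen"))
  t_end <- regimen$days * 1440
  if (inherits(params, "gr_pk_linear")) {
    if (params$drug != regimen$drug) {
      stop("PK parameters are for ", params$drug, ", regimen is for ", regimen$drug)
    }
    ev <- regimen$events
    doses_nmol <- vapply(seq_len(nrow(ev)), function(i)
      .gr_active_nmol(ev[i, ], params), numeric(1))
    fun <- function(t) {
      tot <- rep(0, length(t))
      for (i in seq_len(nrow(ev))) {
        tot <- tot + doses_nmol[i] *
          .gr_unit_conc(t - ev$time_min[i], params, ev$route[i])
      }
      params$fu * tot
    }
    return(new_gr_profile(fun, c(0, t_end), breaks = unique(ev$time_min),
                          label = sprintf("%s free plasma (linear PK)", regimen$drug)))
  }
  if (!inherits(params, "gr_pk_prednisone") || regimen$drug != "prednisone") {
    stop("mismatched regimen and PK parameters")
  }
  .gr_prednisone_profile(regimen, params, dt)
}

#' Free fraction of prednisolone under saturable plasma binding
#'
#' Solves the binding equilibrium
#' `C_total = C_free (1 + NS) + Bmax C_free / (Kd + C_free)` for the free
#' concentration, where `Bmax`/`Kd` describe high-affinity saturable
#' transcortin (corticosteroid-binding globulin) binding and `NS` is the
#' linear albumin-like bound:free ratio. The free fraction increases
#' monotonically with total concentration as transcortin saturates; with
#' `Bmax = 0` it is the constant `1/(1+NS)`.
#'
#' @param total_nM total plasma prednisolone (nM, >= 0); vectorised.
#' @param params a `gr_pk_prednisone` parameter set.
#' @return free fraction(s) in (0, 1\].
#' @export
prednisolone_free_fraction <- function(total_nM, params = gr_pk_params("prednisone")) {
  stopifnot(all(total_nM >= 0))
  free <- .gr_prednisolone_free(total_nM, params)
  ifelse(total_nM > 0, free / total_nM, 1 / (1 + params$NS_bound_per_free +
                                               params$transcortin_Bmax_nM / params$transcortin_Kd_nM))
}

.gr_prednisolone_free <- function(total_nM, p) {
  a <- 1 + p$NS_bound_per_free
  b <- a * p$transcortin_Kd_nM + p$transcortin_Bmax_nM - total_nM
  (-b + sqrt(b^2 + 4 * a * total_nM * p$transcortin_Kd_nM)) / (2 * a)
}

.gr_prednisone_profile <- function(regimen, p, dt) {
  t_end <- regimen$days * 1440
  ev <- regimen$events
  # amounts in nmol: gut prednisone, plasma prednisone, plasma prednisolone
  rhs <- function(t, y, parms) {
    Ct_E <- y[2] / p$V_pred_L
    Ct_L <- y[3] / p$V_prednisolone_L
    Cf_E <- p$fu_pred * Ct_E
    Cf_L <- .gr_prednisolone_free(Ct_L, p)
    dgut <- -p$ka_per_min * y[1]
    absorbed <- p$ka_per_min * p$F * y[1]
    dE <- (1 - p$f_firstpass) * absorbed -
      (p$CL_pred_L_per_min + p$CL_conv_L_per_min) * Cf_E +
      p$CL_back_L_per_min * Cf_L
    dL <- p$f_firstpass * absorbed + p$CL_conv_L_per_min * Cf_E -
      (p$CL_prednisolone_L_per_min + p$CL_back_L_per_min) * Cf_L
    list(c(dgut, dE, dL))
  }
  grid <- seq(0, t_end, by = dt)
  segs <- sort(unique(c(0, ev$time_min[ev$time_min > 0 & ev$time_min < t_end], t_end)))
  y <- c(gut = 0, E = 0, L = 0)
  if (any(ev$time_min == 0)) {
    y["gut"] <- sum(mg_to_nmol(ev$amount_mg[ev$time_min == 0], 358.4))
  }
  out <- NULL
  for (i in seq_len(length(segs) - 1L)) {
    tt <- unique(c(segs[i], grid[grid > segs[i] & grid < segs[i + 1L]], segs[i + 1L]))
    sol <- deSolve::ode(y, tt, rhs, parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-8)
    y <- sol[nrow(sol), -1]
    hit <- which(abs(ev$time_min - segs[i + 1L]) < 1e-9)
    if (length(hit)) y["gut"] <- y["gut"] + sum(mg_to_nmol(ev$amount_mg[hit], 358.4))
    out <- if (is.null(out)) sol else rbind(out, sol[-1, , drop = FALSE])
  }
  out <- out[out[, 1] %in% grid, , drop = FALSE]
  Ct_E <- out[, "E"] / p$V_pred_L
  Ct_L <- out[, "L"] / p$V_prednisolone_L
  Cf_L <- .gr_prednisolone_free(Ct_L, p)
  species <- data.frame(time = out[, 1], prednisone_total_nM = Ct_E,
                        prednisolone_total_nM = Ct_L,
                        prednisolone_free_nM = Cf_L)
  af <- stats::approxfun(species$time, pmax(Cf_L, 0), rule = 2)
  prof <- new_gr_profile(af, c(0, t_end), breaks = unique(ev$time_min),
                         label = "free prednisolone (nonlinear PK)")
  attr(prof, "species") <- species
  prof
}
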