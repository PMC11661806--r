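#' Time-dependent integration of the receptor cycle
#'
#' Integrates the trafficking model under an arbitrary free-concentration
#' forcing profile. The two loose-binding steps are treated as
#' instantaneous equilibria, so the stiff system is integrated over the
#' five pooled quantities (Rc+RcG, RcGt, RnGt, RnGN, Rn+RnG) with
#' time-varying bound fractions G(t)/(Kc+G(t)) and G(t)/(Kn+G(t)); the
#' full seven-state trajectory is reconstructed on output. Discontinuities
#' of the profile (step/dose times) are handled by segment-wise
#' integration with solver restarts, not smoothing.
#'
#' @param ligand a [gr_ligand()] (or name, or record).
#' @param rates a [gr_rates()].
#' @param profile a `gr_profile` forcing function.
#' @param t_start,t_end simulation window (min); default the profile domain.
#' @param dt output grid step (min, default 1).
#' @param init `"cytoplasmic"` (drug-naive: all receptor in Rc, the
#'   default), `"steady"` (steady state at G(t_start)) or a `gr_state`.
#' @param rtol,atol solver tolerances (lsoda).
#' @return a `gr_trajectory`: data.frame with `time`, the seven state
#'   occupancies, `G_nM`, `fRnGN`, `relative_activity` and
#'   `nuclear_fraction`; attributes carry `Rtot` and `rngn_max`.
#' @examples
#' p <- gr_profile_step(data.frame(start_min = 0, nM = 1), t_end = 300)
#' traj <- gr_simulate("dexamethasone", profile = p)
#' @export
gr_simulate <- function(ligand, rates = gr_rates(), profile,
                        t_start = profile$domain[1], t_end = profile$domain[2],
                        dt = 1, init = "cytoplasmic",
                        rtol = 1e-8, atol = 1e-12) {
  ligand <- as_gr_ligand(ligand)
  validate_gr_rates(rates)
  stopifnot(inherits(profile, "gr_profile"), t_end > t_start, dt > 0)
  scheme <- gr_scheme(ligand, rates)
  Rtot <- ligand$Rtot

  y0 <- if (inherits(init, "gr_state")) {
    init
  } else if (identical(init, "cytoplasmic")) {
    new_gr_state(stats::setNames(c(Rtot, 0, 0, 0, 0, 0, 0), GR_STATES), Rtot = Rtot)
  } else if (identical(init, "steady")) {
    gr_steady_state(ligand, rates, gr_profile_value(profile, t_start))
  } else {
    stop("init must be 'cytoplasmic', 'steady' or a gr_state")
  }
  pools0 <- c(Pc = unname(y0[["Rc"]] + y0[["RcG"]]),
              RcGt = unname(y0[["RcGt"]]),
              RnGt = unname(y0[["RnGt"]]),
              RnGN = unname(y0[["RnGN"]]),
              Pn = unname(y0[["Rn"]] + y0[["RnG"]]))

  rhs <- function(t, y, parms) {
    # lsoda may probe marginally outside the current segment
    tc <- min(max(t, profile$domain[1]), profile$domain[2])
    G <- gr_profile_value(profile, tc)
    list(as.vector(.gr_generator(scheme, ligand, G) %*% y))
  }

  grid <- seq(t_start, t_end, by = dt)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  cuts <- profile$breaks[profile$breaks > t_start & profile$breaks < t_end]
  segs <- sort(unique(c(t_start, cuts, t_end)))

  out <- NULL
  y <- pools0
  for (i in seq_len(length(segs) - 1L)) {
    tt <- unique(c(segs[i], grid[grid > segs[i] & grid < segs[i + 1L]], segs[i + 1L]))
    sol <- deSolve::ode(y, tt, rhs, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop("ODE solver failure; last valid time = ", max(sol[, 1]))
    }
    y <- sol[nrow(sol), -1]
    out <- if (is.null(out)) sol else rbind(out, sol[-1, , drop = FALSE])
  }
  out <- out[out[, 1] %in% grid, , drop = FALSE]

  G <- gr_profile_value(profile, out[, 1])
  fc <- G / (ligand$Kc + G)
  fn <- G / (ligand$Kn + G)
  rmax <- rngn_max(rates)
  traj <- data.frame(time = out[, 1],
                     Rc = out[, "Pc"] * (1 - fc),
                     RcG = out[, "Pc"] * fc,
                     RcGt = out[, "RcGt"],
                     RnGt = out[, "RnGt"],
                     RnGN = out[, "RnGN"],
                     Rn = out[, "Pn"] * (1 - fn),
                     RnG = out[, "Pn"] * fn,
                     G_nM = G)
  traj$fRnGN <- traj$RnGN / Rtot
  traj$relative_activity <- traj$fRnGN / rmax
  traj$nuclear_fraction <- (traj$Rn + traj$RnG + traj$RnGt + traj$RnGN) / Rtot
  structure(traj, Rtot = Rtot, rngn_max = rmax, ligand = ligand$name,
            class = c("gr_trajectory", "data.frame"))
}

#' Relative-activity time series of a trajectory
#'
#' @param trajectory a `gr_trajectory` from [gr_simulate()].
#' @return data.frame with `time` and `relative_activity`
#'   (fRnGN(t) / rngn_max).
#' @export
gr_activity_series <- function(trajectory) {
  stopifnot(inherits(trajectory, "gr_trajectory"))
  data.frame(time = trajectory$time,
             relative_activity = trajectory$relative_activity)
}

#' @export
plot.gr_trajectory <- function(x, what = "relative_activity", ...) {
  graphics::plot(x$time, x[[what]], type = "l", xlab = "time (min)",
                 ylab = what, ...)
  invisible(x)
}

#' Cold-chase protocol
#'
#' Competition protocol: labeled ligand at `labeled_conc` is present from
#' t = 0; at `label_duration` an excess of unlabeled ligand
#' (`chase_conc`) is added on top.
#'
#' @param labeled_conc labeled ligand concentration (nM).
#' @param label_duration time of the chase addition (min).
#' @param chase_conc unlabeled ligand concentration added at the chase
#'   (nM). The packaged default is 20000 nM, a 200-fold excess over the
#'   100 nM label.
#' @param total_duration simulated time (min).
#' @return a list of class `gr_chase_protocol`.
#' @export
gr_chase_protocol <- function(labeled_conc = 100, label_duration = 100,
                              chase_conc = 20000, total_duration = 300) {
  stopifnot(labeled_conc >= 0, chase_conc >= 0, label_duration > 0,
            total_duration > label_duration)
  structure(list(labeled_conc = labeled_conc, label_duration = label_duration,
                 chase_conc = chase_conc, total_duration = total_duration),
            class = "gr_chase_protocol")
}

#' Two-species labeled/unlabeled competition simulation
#'
#' Duplicated-species variant of the trafficking model for cold-chase
#' experiments: labeled and unlabeled ligand share the free receptor pools
#' Rc and Rn and have identical affinities and rate constants; each loose
#' pool partitions between the species in proportion to their free
#' concentrations, and the tight states (RcGt, RnGt, RnGN) are tracked per
#' species. With zero unlabeled ligand the system reduces exactly to
#' [gr_simulate()]. The experimental observable is the labeled tightly
#' bound nuclear fraction, RnGt* + RnGN*.
#'
#' @param ligand,rates model parameters.
#' @param protocol a [gr_chase_protocol()].
#' @param dt output step (min).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `time`, the pooled and per-species states,
#'   `labeled_nuclear` (= RnGt_lab + RnGN_lab) and the two free
#'   concentrations.
#' @examples
#' ch <- gr_chase("dexamethasone", protocol = gr_chase_protocol())
#' @export
gr_chase <- function(ligand, rates = gr_rates(),
                     protocol = gr_chase_protocol(), dt = 1,
                     rtol = 1e-8, atol = 1e-12) {
  ligand <- as_gr_ligand(ligand)
  validate_gr_rates(rates)
  stopifnot(inherits(protocol, "gr_chase_protocol"))
  Rtot <- ligand$Rtot

  conc <- function(t) {
    gl <- rep(protocol$labeled_conc, length(t))
    gu <- ifelse(t >= protocol$label_duration, protocol$chase_conc, 0)
    cbind(gl, gu)
  }

  # state vector: Pc, Pn, RcGt_l, RnGt_l, RnGN_l, RcGt_u, RnGt_u, RnGN_u
  rhs <- function(t, y, p) {
    g <- conc(t); gl <- g[1]; gu <- g[2]; gtot <- gl + gu
    fc <- gtot / (ligand$Kc + gtot)
    fn <- gtot / (ligand$Kn + gtot)
    wl <- if (gtot > 0) gl / gtot else 0
    wu <- if (gtot > 0) gu / gtot else 0
    Pc <- y[1]; Pn <- y[2]
    cyt_in <- rates$k1 * fc * Pc   # pooled loose -> tight flux, split by species
    nuc_in <- rates$k6 * fn * Pn
    dRcGt_l <- cyt_in * wl - rates$k2 * y[3]
    dRnGt_l <- rates$k2 * y[3] + nuc_in * wl - rates$k3 * y[4]
    dRnGN_l <- rates$k3 * y[4] - rates$k4 * y[5]
    dRcGt_u <- cyt_in * wu - rates$k2 * y[6]
    dRnGt_u <- rates$k2 * y[6] + nuc_in * wu - rates$k3 * y[7]
    dRnGN_u <- rates$k3 * y[7] - rates$k4 * y[8]
    dPc <- rates$k5 * (1 - fn) * Pn - cyt_in
    dPn <- rates$k4 * (y[5] + y[8]) - (rates$k5 * (1 - fn) + rates$k6 * fn) * Pn
    list(c(dPc, dPn, dRcGt_l, dRnGt_l, dRnGN_l, dRcGt_u, dRnGt_u, dRnGN_u))
  }

  y0 <- c(Pc = Rtot, Pn = 0, RcGt_l = 0, RnGt_l = 0, RnGN_l = 0,
          RcGt_u = 0, RnGt_u = 0, RnGN_u = 0)
  grid <- seq(0, protocol$total_duration, by = dt)
  segs <- sort(unique(c(0, protocol$label_duration, protocol$total_duration)))
  out <- NULL; y <- y0
  for (i in seq_len(length(segs) - 1L)) {
    tt <- unique(c(segs[i], grid[grid > segs[i] & grid < segs[i + 1L]], segs[i + 1L]))
    sol <- deSolve::ode(y, tt, rhs, parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    y <- sol[nrow(sol), -1]
    out <- if (is.null(out)) sol else rbind(out, sol[-1, , drop = FALSE])
  }
  out <- as.data.frame(out[out[, 1] %in% grid, , drop = FALSE])
  names(out)[1] <- "time"
  g <- conc(out$time)
  out$G_labeled_nM <- g[, 1]
  out$G_unlabeled_nM <- g[, 2]
  out$labeled_nuclear <- (out$RnGt_l + out$RnGN_l) / Rtot
  structure(out, Rtot = Rtot, class = c("gr_chase_trajectory", "data.frame"))
}

#' Post-chase dissociation half-time
#'
#' Time, after the chase addition, at which the labeled tightly bound
#' nuclear signal has fallen halfway from its value at the chase to its
#' terminal value (log-linear interpolation between grid points).
#'
#' @param chase a `gr_chase_trajectory` from [gr_chase()].
#' @param chase_time time of the chase addition (min).
#' @return half-time in minutes.
#' @export
gr_chase_halftime <- function(chase, chase_time = 100) {
  post <- chase[chase$time >= chase_time, ]
  y0 <- post$labeled_nuclear[1]
  yend <- post$labeled_nuclear[nrow(post)]
  target <- yend + (y0 - yend) / 2
  below <- which(post$labeled_nuclear <= target)
  if (length(below) == 0L) return(Inf)
  i <- below[1]
  if (i == 1L) return(0)
  t1 <- post$time[i - 1L]; t2 <- post$time[i]
  y1 <- post$labeled_nuclear[i - 1L]; y2 <- post$labeled_nuclear[i]
  t1 + (t2 - t1) * (y1 - target) / (y1 - y2) - chase_time
}

#' Export a trajectory to CSV
#'
#' @param trajectory a `gr_trajectory`.
#' @param path output file.
#' @export
gr_write_trajectory <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[, c(
    "time", GR_STATES, "fRnGN", "relative_activity", "nuclear_fraction", "G_nM")],
    path, row.names = FALSE)
  invisible(path)
}
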