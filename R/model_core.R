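GR_STATES <- c("Rc", "RcG", "RcGt", "RnGt", "RnGN", "Rn", "RnG")

#' Reaction scheme of the seven-state receptor cycle
#'
#' The canonical edge list of the trafficking model. Two edges are
#' instantaneous equilibria (the loose binding steps, characterised by the
#' dissociation constants `Kc` and `Kn`); the six others are irreversible
#' first-order transitions (`k1`..`k6`). This edge list is the single
#' source of truth: both the steady-state linear solver and the ODE
#' right-hand side are built from it.
#'
#' @param ligand a [gr_ligand()] (or name, or record).
#' @param rates a [gr_rates()].
#' @return data.frame with columns `from`, `to`, `kind`
#'   (`"equilibrium"`/`"rate"`), `constant` and `value`.
#' @examples
#' gr_scheme("dexamethasone")
#' @export
gr_scheme <- function(ligand, rates = gr_rates()) {
  ligand <- as_gr_ligand(ligand)
  validate_gr_rates(rates)
  data.frame(
    from = c("Rc",  "RcG",  "RcGt", "RnGt", "RnGN", "Rn", "Rn",  "RnG"),
    to   = c("RcG", "RcGt", "RnGt", "RnGN", "Rn",   "Rc", "RnG", "RnGt"),
    kind = c("equilibrium", "rate", "rate", "rate", "rate", "rate",
             "equilibrium", "rate"),
    constant = c("Kc", "k1", "k2", "k3", "k4", "k5", "Kn", "k6"),
    value = c(ligand$Kc, rates$k1, rates$k2, rates$k3, rates$k4, rates$k5,
              ligand$Kn, rates$k6),
    stringsAsFactors = FALSE)
}

# Pooled representation: the two loose-binding equilibria are collapsed so
# the dynamics evolve Pc = Rc + RcG and Pn = Rn + RnG. Bound fractions at
# free concentration G are G/(Kc+G) and G/(Kn+G).
GR_POOLS <- c(Rc = "Pc", RcG = "Pc", RcGt = "RcGt", RnGt = "RnGt",
              RnGN = "RnGN", Rn = "Pn", RnG = "Pn")
GR_POOL_NAMES <- c("Pc", "RcGt", "RnGt", "RnGN", "Pn")

# Weight of a sub-state within its pool at free concentration G.
.gr_substate_weight <- function(state, ligand, G) {
  fc <- G / (ligand$Kc + G)
  fn <- G / (ligand$Kn + G)
  switch(state, Rc = 1 - fc, RcG = fc, Rn = 1 - fn, RnG = fn, 1)
}

# 5x5 generator matrix over the pooled states, built from the edge list.
# dy/dt = M %*% y; columns sum to zero (mass conservation).
.gr_generator <- function(scheme, ligand, G) {
  M <- matrix(0, 5, 5, dimnames = list(GR_POOL_NAMES, GR_POOL_NAMES))
  kin <- scheme[scheme$kind == "rate", ]
  for (i in seq_len(nrow(kin))) {
    from <- kin$from[i]; to <- kin$to[i]
    pf <- GR_POOLS[[from]]; pt <- GR_POOLS[[to]]
    if (pf == pt) next # within-pool move, already at equilibrium
    eff <- kin$value[i] * .gr_substate_weight(from, ligand, G)
    M[pt, pf] <- M[pt, pf] + eff
    M[pf, pf] <- M[pf, pf] - eff
  }
  M
}

.gr_expand_pools <- function(y, ligand, G) {
  fc <- G / (ligand$Kc + G)
  fn <- G / (ligand$Kn + G)
  c(Rc = unname(y["Pc"]) * (1 - fc),
    RcG = unname(y["Pc"]) * fc,
    RcGt = unname(y["RcGt"]),
    RnGt = unname(y["RnGt"]),
    RnGN = unname(y["RnGN"]),
    Rn = unname(y["Pn"]) * (1 - fn),
    RnG = unname(y["Pn"]) * fn)
}

new_gr_state <- function(x, Rtot = 1, G = NA_real_, time = NA_real_) {
  stopifnot(identical(names(x), GR_STATES))
  structure(x, Rtot = Rtot, G = G, time = time, class = "gr_state")
}

#' @export
print.gr_state <- function(x, digits = 4, ...) {
  cat(sprintf("<gr_state> G = %g nM, Rtot = %g\n", attr(x, "G"), attr(x, "Rtot")))
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  cat(sprintf("fRnGN = %.4g, nuclear fraction = %.4g\n",
              f_rngn(x), nuclear_fraction(x)))
  invisible(x)
}

#' Analytic steady state of the receptor cycle
#'
#' Closed-form steady-state occupancies of the seven states at free
#' glucocorticoid concentration `G`. With the two loose binding steps at
#' equilibrium (RcG = Rc G/Kc, RnG = Rn G/Kn), flux balance around the
#' cycle gives occupancies proportional, per unit of unbound nuclear
#' receptor Rn, to
#' \deqn{Rc : k_5 K_c/(k_1 G),\; RcG : k_5/k_1,\; RcGt : k_5/k_2,\;
#'   RnGt : (k_5 + k_6 G/K_n)/k_3,\; RnGN : (k_5 + k_6 G/K_n)/k_4,\;
#'   Rn : 1,\; RnG : G/K_n,}
#' normalised so the seven occupancies sum to `Rtot`. At `G = 0` the whole
#' receptor sits in Rc (export-only dynamics). `method = "solve"` instead
#' solves the pooled flux-balance linear system built from [gr_scheme()];
#' it is the independent cross-check route used by the test suite.
#'
#' @param ligand a [gr_ligand()] (or name, or record).
#' @param rates a [gr_rates()].
#' @param G free glucocorticoid concentration (nM, >= 0; scalar).
#' @param method `"closed"` (default) or `"solve"`.
#' @return a `gr_state` (named numeric of the 7 occupancies, with `Rtot`
#'   and `G` attributes).
#' @examples
#' gr_steady_state("cortisol", G = 1.45)
#' @export
gr_steady_state <- function(ligand, rates = gr_rates(), G,
                            method = c("closed", "solve")) {
  ligand <- as_gr_ligand(ligand)
  validate_gr_rates(rates)
  method <- match.arg(method)
  if (!is.numeric(G) || length(G) != 1L || is.na(G) || G < 0) {
    stop("G must be a single non-negative concentration in nM")
  }
  Rtot <- ligand$Rtot
  if (G == 0) {
    occ <- stats::setNames(c(Rtot, 0, 0, 0, 0, 0, 0), GR_STATES)
    return(new_gr_state(occ, Rtot = Rtot, G = 0))
  }
  if (method == "closed") {
    tin <- rates$k5 + rates$k6 * G / ligand$Kn
    w <- c(Rc = rates$k5 * ligand$Kc / (rates$k1 * G),
           RcG = rates$k5 / rates$k1,
           RcGt = rates$k5 / rates$k2,
           RnGt = tin / rates$k3,
           RnGN = tin / rates$k4,
           Rn = 1,
           RnG = G / ligand$Kn)
    occ <- w[GR_STATES] / sum(w) * Rtot
  } else {
    M <- .gr_generator(gr_scheme(ligand, rates), ligand, G)
    M[5, ] <- 1 # replace one balance row by the conservation constraint
    y <- solve(M, c(0, 0, 0, 0, Rtot))
    names(y) <- GR_POOL_NAMES
    occ <- .gr_expand_pools(y, ligand, G)
  }
  new_gr_state(occ, Rtot = Rtot, G = G)
}

#' Fraction of receptor in the active (RnGN) state
#'
#' @param state a `gr_state` from [gr_steady_state()] (or any named vector
#'   with an `RnGN` entry and an `Rtot` attribute).
#' @param Rtot total receptor scale; defaults to the state's attribute.
#' @return RnGN / Rtot, in \[0, 1\].
#' @export
f_rngn <- function(state, Rtot = attr(state, "Rtot")) {
  if (is.null(Rtot)) Rtot <- sum(state)
  unname(state[["RnGN"]] / Rtot)
}

#' Fraction of receptor located in the nucleus
#'
#' @inheritParams f_rngn
#' @return (Rn + RnG + RnGt + RnGN) / Rtot.
#' @export
nuclear_fraction <- function(state, Rtot = attr(state, "Rtot")) {
  if (is.null(Rtot)) Rtot <- sum(state)
  unname((state[["Rn"]] + state[["RnG"]] + state[["RnGt"]] + state[["RnGN"]]) / Rtot)
}

new_gr_mm <- function(Vmax, Km, denom_const, regime) {
  stopifnot(Vmax > 0, Vmax <= 1, Km > 0, denom_const >= 1)
  structure(list(Vmax = Vmax, Km = Km, denom_const = denom_const,
                 regime = regime), class = "gr_mm")
}

#' @export
print.gr_mm <- function(x, ...) {
  cat(sprintf("<gr_mm> %s regime: Vmax = %.4g, Km = %.4g nM, denominator constant = %.4g\n",
              x$regime, x$Vmax, x$Km, x$denom_const))
  invisible(x)
}

#' High-concentration Michaelis-Menten reduction
#'
#' In the experimentally relevant concentration range the receptor is
#' essentially 100 % nuclear and the slow export (`k5`) is negligible
#' against the nuclear recycling flux. The steady state then collapses to
#' \deqn{f_{RnGN} = \frac{V_{maxH}\,G}{K_{mH} + G},\qquad
#'   C = 1 + k_6/k_3 + k_6/k_4,\quad V_{maxH} = (k_6/k_4)/C,\quad
#'   K_{mH} = K_n / C.}
#' The reduction depends only on `Kn`, `k3`, `k4` and `k6` - none of the
#' cytoplasmic parameters (`Kc`, `k1`, `k2`, `k5`) enter. With the
#' packaged rates C = 31, so the apparent transcriptional EC50 is 31-fold
#' below the intrinsic nuclear affinity `Kn`. Note: with the packaged
#' rates `VmaxH` equals [rngn_max()] = 25/31 = 0.8065; the source
#' reference prints 0.769 for the same quantity (and 0.806 for the
#' infinite-dose maximum), a discrepancy recorded by
#' [gr_validation_report()].
#'
#' @inheritParams gr_steady_state
#' @return a `gr_mm` object (fields `Vmax`, `Km`, `denom_const`, `regime`).
#' @examples
#' mm_high("dexamethasone")
#' @export
mm_high <- function(ligand, rates = gr_rates()) {
  ligand <- as_gr_ligand(ligand)
  validate_gr_rates(rates)
  C <- 1 + rates$k6 / rates$k3 + rates$k6 / rates$k4
  new_gr_mm(Vmax = (rates$k6 / rates$k4) / C,
            Km = ligand$Kn / C,
            denom_const = C,
            regime = "high")
}

#' Nuclear affinity implied by an experimental EC50
#'
#' Inverts the high-concentration reduction: the intrinsic nuclear loose
#' binding constant is `Kn = KmT * C` with `C = 1 + k6/k3 + k6/k4`.
#'
#' @param KmT experimental transcriptional EC50 (nM, > 0).
#' @param rates a [gr_rates()].
#' @return Kn in nM.
#' @examples
#' kn_from_kmt(5)  # dexamethasone -> 155 nM
#' kn_from_kmt(50) # cortisol -> 1550 nM
#' @export
kn_from_kmt <- function(KmT, rates = gr_rates()) {
  stopifnot(is.numeric(KmT), KmT > 0)
  validate_gr_rates(rates)
  KmT * (1 + rates$k6 / rates$k3 + rates$k6 / rates$k4)
}

#' Very-low-concentration Michaelis-Menten reduction
#'
#' At concentrations far below the experimental EC50 the nuclear loose
#' binding (`G/Kn`) is negligible and there is no nuclear recycling: the
#' receptor traverses the full cycle Rc -> RcGt -> RnGt -> RnGN -> Rn ->
#' Rc, rate-limited by the very slow export `k5`. Flux balance gives
#' \deqn{f_{RnGN} = \frac{G}{D\,G + K_c k_4 / k_1} =
#'   \frac{V_{maxL}\,G}{K_{mL} + G},}
#' with
#' \deqn{D = k_4\left(\frac1{k_1}+\frac1{k_2}+\frac1{k_3}+\frac1{k_4}+\frac1{k_5}\right),
#'   \quad V_{maxL} = 1/D,\quad K_{mL} = \frac{K_c k_4}{k_1 D}.}
#' `KmL` is proportional to `Kc` and inversely proportional to `k1`. With
#' the packaged dexamethasone parameters D = 24.93, VmaxL = 0.0401 and
#' KmL = 0.000802 nM - an apparent affinity several thousand-fold higher
#' than the experimental EC50 of 5 nM, produced by the fast import / very
#' slow export asymmetry. (The source reference prints D = 31.5,
#' VmaxL = 0.0317, KmL = 0.000787 nM for this reduction; the difference is
#' tracked by [gr_consistency_report()] and [gr_validation_report()].)
#'
#' @inheritParams gr_steady_state
#' @return a `gr_mm` object.
#' @examples
#' mm_low("dexamethasone")
#' mm_low("dexamethasone", gr_rates(k1 = 1)) # KmL ten-fold larger
#' @export
mm_low <- function(ligand, rates = gr_rates()) {
  ligand <- as_gr_ligand(ligand)
  validate_gr_rates(rates)
  D <- rates$k4 * (1 / rates$k1 + 1 / rates$k2 + 1 / rates$k3 +
                     1 / rates$k4 + 1 / rates$k5)
  new_gr_mm(Vmax = 1 / D,
            Km = ligand$Kc * rates$k4 / (rates$k1 * D),
            denom_const = D,
            regime = "low")
}

#' Evaluate a Michaelis-Menten relation
#'
#' @param mm a `gr_mm` object from [mm_high()], [mm_low()] or [mm_experimental()].
#' @param G free concentration(s) in nM (>= 0); vectorised.
#' @param relative if `TRUE`, return activity relative to the curve's own
#'   maximum, i.e. `G/(Km+G)`.
#' @return activity fraction(s).
#' @examples
#' mm_activity(mm_experimental(KmT = 50), 1.45, relative = TRUE) # 0.028
#' @export
mm_activity <- function(mm, G, relative = FALSE) {
  stopifnot(inherits(mm, "gr_mm"), all(G >= 0))
  v <- if (relative) 1 else mm$Vmax
  v * G / (mm$Km + G)
}

#' Experimental Michaelis-Menten dose-response
#'
#' The standard empirical relation `VmaxT * G / (KmT + G)` fitted to
#' reporter-gene transcription measurements; `KmT` equals the measured
#' EC50 (or IC50 for inhibitory readouts).
#'
#' @param KmT experimental EC50 (nM, > 0).
#' @param VmaxT maximal activity (default 1, i.e. relative reporting).
#' @return a `gr_mm` object with regime `"experimental"`.
#' @export
mm_experimental <- function(KmT, VmaxT = 1) {
  new_gr_mm(Vmax = VmaxT, Km = KmT, denom_const = 1, regime = "experimental")
}

#' Steady-state dose-response table
#'
#' @param ligand,rates model parameters.
#' @param G vector of free concentrations (nM, >= 0).
#' @return data.frame with columns `G_nM`, `fRnGN`, `relative_activity`
#'   (fRnGN normalised by [rngn_max()]) and `nuclear_fraction`.
#' @examples
#' gr_dose_response("dexamethasone", G = 10^seq(-4, 3, by = 1))
#' @export
gr_dose_response <- function(ligand, rates = gr_rates(), G) {
  ligand <- as_gr_ligand(ligand)
  rmax <- rngn_max(rates)
  rows <- lapply(G, function(g) {
    s <- gr_steady_state(ligand, rates, g)
    data.frame(G_nM = g, fRnGN = f_rngn(s),
               relative_activity = f_rngn(s) / rmax,
               nuclear_fraction = nuclear_fraction(s))
  })
  do.call(rbind, rows)
}
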