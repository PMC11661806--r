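#' Derived-versus-reference validation battery
#'
#' Recomputes, from the packaged parameter sets, the model quantities for
#' which the source reference prints a value, and diffs each against that
#' printed value: the high- and low-limit reduction constants, the
#' infinite-dose maximum, the nadir-cortisol activity anchors, the nuclear
#' localisation threshold and (optionally) the endogenous-cortisol GTQ
#' calibration. Rows whose relative difference exceeds `tol` are flagged
#' rather than failed: for the reduction constants the derivation
#' documented in [mm_high()]/[mm_low()] is known to differ from the
#' printed constants (see those help pages).
#'
#' @param rates a [gr_rates()].
#' @param include_gtq also run the (slower) diurnal-cortisol simulation
#'   checks (default `TRUE`).
#' @param tol relative tolerance for `pass` (default 0.05).
#' @return data.frame with columns quantity, derived, reference,
#'   rel_diff, status.
#' @export
gr_validation_report <- function(rates = gr_rates(), include_gtq = TRUE,
                                 tol = 0.05) {
  dex <- get_gr_ligand("dexamethasone")$params
  cort <- get_gr_ligand("cortisol")$params
  hi <- mm_high(dex, rates)
  lo <- mm_low(dex, rates)
  lo_k1 <- mm_low(dex, gr_rates(k1 = 1))
  lo_cort <- mm_low(cort, rates)
  nadir <- 1.45
  rel_full <- f_rngn(gr_steady_state(cort, rates, nadir)) / rngn_max(rates)
  rel_mm <- mm_activity(mm_experimental(cort$KmT), nadir, relative = TRUE)
  rows <- list(
    c("C (high-limit denominator constant)", hi$denom_const, 31),
    c("VmaxH", hi$Vmax, 0.769),
    c("KmH dexamethasone (nM)", hi$Km, 5),
    c("Kn dexamethasone from KmT (nM)", kn_from_kmt(dex$KmT, rates), 155),
    c("Kn cortisol from KmT (nM)", kn_from_kmt(cort$KmT, rates), 1550),
    c("Kn prednisolone/MP from KmT (nM)", kn_from_kmt(15, rates), 465),
    c("D (low-limit denominator constant)", lo$denom_const, 31.5),
    c("VmaxL", lo$Vmax, 0.0317),
    c("KmL dexamethasone (nM)", lo$Km, 0.000787),
    c("KmL dexamethasone, k1 = 1 (nM)", lo_k1$Km, 0.0079),
    c("KmL cortisol (nM)", lo_cort$Km, 0.0118),
    c("RnGN max at infinite dose", rngn_max(rates), 0.806),
    c("relative activity, cortisol 1.45 nM (full model)", rel_full, 0.074),
    c("relative activity, cortisol 1.45 nM (experimental MM)", rel_mm, 0.028),
    c("full/MM activity ratio at nadir", rel_full / rel_mm, 2.6),
    c("nuclear fraction, dexamethasone 0.01 nM",
      nuclear_fraction(gr_steady_state(dex, rates, 0.01)), 0.90))
  if (include_gtq) {
    prof <- gr_cortisol_profile()
    gtq <- gr_gtq(cort, rates, prof, method = "time-dependent")
    peak <- f_rngn(gr_steady_state(cort, rates, GR_CORTISOL_PEAK_NM)) / rngn_max(rates)
    rows <- c(rows, list(
      c("endogenous cortisol GTQ (day 2)", gtq$value, 0.17),
      c("peak relative activity, endogenous cortisol", peak, 0.39)))
  }
  rep <- data.frame(quantity = vapply(rows, `[[`, "", 1),
                    derived = as.numeric(vapply(rows, `[[`, "", 2)),
                    reference = as.numeric(vapply(rows, `[[`, "", 3)),
                    stringsAsFactors = FALSE)
  rep$rel_diff <- abs(rep$derived - rep$reference) / abs(rep$reference)
  rep$status <- ifelse(rep$rel_diff <= tol, "pass", "flag")
  rep
}
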