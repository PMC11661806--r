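#' Ligand (glucocorticoid) equilibrium parameters
#'
#' A glucocorticoid is characterised, within the shared trafficking cycle,
#' by two equilibrium dissociation constants: `Kc` for the loose
#' cytoplasmic binding step Rc + G <-> RcG and `Kn` for the loose nuclear
#' step Rn + G <-> RnG (both nM). `KmT` is the experimentally measured
#' transcriptional EC50 (nM), carried along as a reference value. `Rtot`
#' is the total receptor amount; it is a pure scale factor and defaults
#' to 1 so that state occupancies are fractions.
#'
#' @param name ligand identifier.
#' @param Kc cytoplasmic loose-binding dissociation constant (nM, > 0).
#' @param Kn nuclear loose-binding dissociation constant (nM, > 0).
#' @param KmT experimental transcriptional EC50 (nM) or `NA`.
#' @param Rtot total receptor scale (> 0), default 1.
#' @return an object of class `gr_ligand`.
#' @seealso [get_gr_ligand()] for the packaged parameter sets.
#' @examples
#' gr_ligand("dexamethasone", Kc = 5, Kn = 155, KmT = 5)
#' @export
gr_ligand <- function(name, Kc, Kn, KmT = NA_real_, Rtot = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  for (v in list(Kc = Kc, Kn = Kn, Rtot = Rtot)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("Kc, Kn and Rtot must be single strictly positive numbers")
    }
  }
  structure(list(name = name, Kc = Kc, Kn = Kn, KmT = KmT, Rtot = Rtot),
            class = "gr_ligand")
}

#' @export
print.gr_ligand <- function(x, ...) {
  cat(sprintf("<gr_ligand> %s: Kc = %g nM, Kn = %g nM, KmT = %g nM, Rtot = %g\n",
              x$name, x$Kc, x$Kn, x$KmT, x$Rtot))
  invisible(x)
}

.gr_ligand_table <- function() {
  if (is.null(.gr_cache$ligand_table)) {
    .gr_cache$ligand_table <- utils::read.csv(.gr_extdata("gr_ligands.csv"),
                                              stringsAsFactors = FALSE)
  }
  .gr_cache$ligand_table
}

#' Packaged glucocorticoid parameter library
#'
#' Returns the reference affinity table shipped with the package:
#' dexamethasone, cortisol, prednisolone and methylprednisolone, each with
#' `Kc`, `Kn`, the experimental transcriptional EC50 `KmT` and, for
#' reference, the low-concentration Michaelis constant `KmL` as printed in
#' the source affinity table. The prednisolone `KmL` entry is flagged
#' `suspected_erratum`: identical `Kc`/`Kn` to methylprednisolone should
#' give an identical `KmL` (the value scales with `Kc`), yet the printed
#' table lists 0.0044 vs 0.00236 nM. Both are exposed unmodified; see
#' [gr_consistency_report()].
#'
#' @return data.frame, one row per ligand. The library is immutable: a
#'   fresh copy is returned on each call.
#' @export
gr_ligands <- function() {
  tab <- .gr_ligand_table()
  tab[] <- tab # force copy
  tab
}

#' Look up a packaged glucocorticoid parameter set
#'
#' @param name one of `"dexamethasone"`, `"cortisol"`, `"prednisolone"`,
#'   `"methylprednisolone"` (unambiguous prefixes such as `"dex"` work).
#' @return a `gr_ligand_record`: list with `ligand` (name), `params` (a
#'   [gr_ligand()]), `KmT_reference`, `KmL_reference` (nM, as printed),
#'   `KmL_flag` and `source`.
#' @examples
#' get_gr_ligand("dexamethasone")$params
#' @export
get_gr_ligand <- function(name) {
  tab <- .gr_ligand_table()
  i <- pmatch(tolower(name), tab$ligand)
  if (is.na(i)) {
    stop("unknown ligand '", name, "'; available: ",
         paste(tab$ligand, collapse = ", "))
  }
  row <- tab[i, ]
  structure(list(ligand = row$ligand,
                 params = gr_ligand(row$ligand, Kc = row$Kc_nM, Kn = row$Kn_nM,
                                    KmT = row$KmT_nM),
                 KmT_reference = row$KmT_nM,
                 KmL_reference = row$KmL_printed_nM,
                 KmL_flag = row$KmL_flag,
                 source = row$source),
            class = "gr_ligand_record")
}

#' @export
print.gr_ligand_record <- function(x, ...) {
  print(x$params)
  cat(sprintf("  reference KmT = %g nM, printed KmL = %g nM (%s)\n",
              x$KmT_reference, x$KmL_reference, x$KmL_flag))
  invisible(x)
}

# Accept a gr_ligand, a gr_ligand_record or a ligand name everywhere.
as_gr_ligand <- function(x) {
  if (inherits(x, "gr_ligand")) return(x)
  if (inherits(x, "gr_ligand_record")) return(x$params)
  if (is.character(x) && length(x) == 1L) return(get_gr_ligand(x)$params)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a gr_ligand")
}

#' Cell-line transcriptional EC50 survey
#'
#' Reference table of cell-culture `KmT` (EC50) measurements: the absolute
#' dexamethasone value per cell line and the ratios of the other
#' glucocorticoids relative to dexamethasone. Documentation/sensitivity
#' data only; it feeds no default computation.
#'
#' @return data.frame.
#' @export
gr_cellline_kmt <- function() {
  utils::read.csv(.gr_extdata("gr_cellline_kmt.csv"), stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Derived-versus-printed consistency report for the ligand library
#'
#' Recomputes, for every packaged ligand and from the model reductions
#' ([mm_high()], [mm_low()], [kn_from_kmt()]), the denominator constant C,
#' the nuclear affinity Kn implied by the experimental KmT, and the
#' low-concentration Michaelis constant KmL, and diffs them against the
#' printed reference values. A row is flagged when derived and printed
#' disagree by more than `tol` (relative).
#'
#' @param rates a [gr_rates()] object.
#' @param tol relative tolerance for a `pass` (default 0.05).
#' @return data.frame with columns ligand, quantity, derived, printed,
#'   rel_diff, status.
#' @export
gr_consistency_report <- function(rates = gr_rates(), tol = 0.05) {
  tab <- .gr_ligand_table()
  out <- list()
  for (i in seq_len(nrow(tab))) {
    rec <- get_gr_ligand(tab$ligand[i])
    lig <- rec$params
    kn_derived <- kn_from_kmt(rec$KmT_reference, rates)
    low <- mm_low(lig, rates)
    out[[length(out) + 1L]] <- data.frame(
      ligand = rec$ligand,
      quantity = c("Kn_nM", "KmL_nM"),
      derived = c(kn_derived, low$Km),
      printed = c(lig$Kn, rec$KmL_reference),
      stringsAsFactors = FALSE)
  }
  rep <- do.call(rbind, out)
  rep$rel_diff <- abs(rep$derived - rep$printed) / rep$printed
  rep$status <- ifelse(rep$rel_diff <= tol, "pass", "flag")
  rep
}
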