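.gr_cache <- new.env(parent = emptyenv())

.gr_extdata <- function(file) {
  path <- system.file("extdata", file, package = "grpkpd")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

.gr_default_rates_table <- function() {
  if (is.null(.gr_cache$rates_table)) {
    .gr_cache$rates_table <- utils::read.csv(.gr_extdata("gr_rate_constants.csv"),
                                             stringsAsFactors = FALSE)
  }
  .gr_cache$rates_table
}

#' Kinetic rate constants of the receptor trafficking cycle
#'
#' The six first-order rate constants of the seven-state glucocorticoid
#' receptor (GR) trafficking scheme, all in min^-1:
#' `k1` (cytoplasmic loose-to-tight conversion, RcG -> RcGt),
#' `k2` (nuclear import, RcGt -> RnGt),
#' `k3` (activation to the DNA-binding-competent state, RnGt -> RnGN),
#' `k4` (ligand release and recycle, RnGN -> Rn),
#' `k5` (nuclear export of the unbound receptor, Rn -> Rc) and
#' `k6` (nuclear loose-to-tight conversion, RnG -> RnGt).
#'
#' Defaults are the packaged reference set shipped in
#' `inst/extdata/gr_rate_constants.csv` (k1 = 10, k2 = 0.2, k3 = 0.2,
#' k4 = 0.04, k5 = 0.0017, k6 = 1 min^-1). The rate constants are shared
#' across glucocorticoids; only the equilibrium constants `Kc` and `Kn`
#' are ligand dependent (see [gr_ligand()]). Individual rates can be
#' overridden for sensitivity studies.
#'
#' @param k1,k2,k3,k4,k5,k6 rate constants in min^-1; `NULL` means the
#'   packaged default.
#' @return an object of class `gr_rates` (named list of the six rates).
#' @examples
#' gr_rates()
#' gr_rates(k1 = 1) # ten-fold slower cytoplasmic tight-binding conversion
#' @export
gr_rates <- function(k1 = NULL, k2 = NULL, k3 = NULL, k4 = NULL,
                     k5 = NULL, k6 = NULL) {
  tab <- .gr_default_rates_table()
  defaults <- stats::setNames(tab$value, tab$param)
  r <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6)
  for (nm in names(r)) {
    if (is.null(r[[nm]])) r[[nm]] <- unname(defaults[[nm]])
  }
  validate_gr_rates(r)
  structure(r, class = "gr_rates")
}

validate_gr_rates <- function(r) {
  for (nm in c("k1", "k2", "k3", "k4", "k5", "k6")) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("rate constant ", nm, " must be a single strictly positive finite number")
    }
  }
  invisible(r)
}

#' @export
print.gr_rates <- function(x, ...) {
  cat("GR trafficking rate constants (min^-1):\n")
  print(unlist(x))
  invisible(x)
}

#' Maximum attainable fraction of receptor in the active state
#'
#' The infinite-concentration limit of the steady-state fraction of
#' receptor in the DNA-binding-competent state RnGN. At saturating ligand
#' the receptor is confined to the nuclear tight cycle
#' RnGt -> RnGN -> Rn(G) -> RnGt, and flux balance gives
#' \deqn{RnGN_{max} = \frac{k_6/k_4}{1 + k_6/k_3 + k_6/k_4}.}
#' The limit is independent of the ligand affinities and of every
#' cytoplasmic parameter. With the packaged rates it equals 25/31 = 0.8065.
#' It is the normaliser used for all relative-activity reporting.
#'
#' @param rates a [gr_rates()] object.
#' @return scalar fraction in (0, 1).
#' @examples
#' rngn_max(gr_rates())
#' @export
rngn_max <- function(rates = gr_rates()) {
  validate_gr_rates(rates)
  a <- rates$k6 / rates$k3
  b <- rates$k6 / rates$k4
  b / (1 + a + b)
}
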