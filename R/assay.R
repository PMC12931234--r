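#' Dissociation constant from native-MS species abundances
#'
#' Computes `K_D = [L]free [P]free / [PL]` for a 1:1 protein-ligand
#' complex. When the inputs are relative abundances (fractions) rather
#' than concentrations, supply `p_total` and `l_total` to reconstruct
#' concentrations: the protein-containing species abundances are assumed
#' proportional to their concentrations (uniform detector response), so
#' `[P]free = p_total * p_free / (p_free + pl)` and
#' `[L]free = l_total - [PL]`. A 1:2 complex abundance, when present, is
#' counted in the protein mass balance but excluded from the 1:1 constant.
#'
#' @param l_free,p_free,pl_complex Free-ligand, free-protein and 1:1
#'   complex abundances (a.u. or uM) — `pl_complex` must be > 0.
#' @param pl2_complex Optional 1:2 complex abundance.
#' @param p_total,l_total Total concentrations in uM; when supplied the
#'   abundances are treated as relative and converted.
#' @return K_D in the concentration units of the inputs (uM).
#' @examples
#' kd_from_abundances(5, 5, 5)  # 5 uM
#' @export
kd_from_abundances <- function(l_free, p_free, pl_complex, pl2_complex = 0,
                               p_total = NULL, l_total = NULL) {
  if (any(c(l_free, p_free, pl_complex, pl2_complex) < 0))
    stop("abundances must be >= 0", call. = FALSE)
  if (pl_complex <= 0)
    stop("K_D is undefined when the complex abundance is zero", call. = FALSE)
  if (!is.null(p_total) && !is.null(l_total)) {
    pscale <- p_total / (p_free + pl_complex + pl2_complex)
    p_free_c <- p_free * pscale
    pl_c <- pl_complex * pscale
    l_free_c <- l_total - pl_c - 2 * pl2_complex * pscale
    if (l_free_c <= 0)
      stop("ligand mass balance gives non-positive free ligand", call. = FALSE)
    return(l_free_c * p_free_c / pl_c)
  }
  l_free * p_free / pl_complex
}

#' Equilibrium species of a 1:1 binding reaction
#'
#' Solves the binding quadratic exactly for `P + L <-> PL` with
#' dissociation constant `kd`:
#' `[PL]` is the smaller root of
#' `x^2 - (p_total + l_total + kd) x + p_total l_total = 0`.
#' Mass balance (`p_free + pl = p_total`, `l_free + pl = l_total`) holds
#' to floating-point accuracy.
#'
#' @param p_total,l_total Total protein and ligand concentrations, uM (> 0).
#' @param kd Dissociation constant, uM (> 0).
#' @return List with `p_free`, `l_free`, `pl` (uM).
#' @examples
#' equilibrium_abundances(10, 10, 8)
#' @export
equilibrium_abundances <- function(p_total, l_total, kd) {
  if (any(c(p_total, l_total, kd) <= 0))
    stop("p_total, l_total and kd must be > 0", call. = FALSE)
  b <- p_total + l_total + kd
  # numerically stable smaller root
  pl <- 2 * p_total * l_total / (b + sqrt(b^2 - 4 * p_total * l_total))
  list(p_free = p_total - pl, l_free = l_total - pl, pl = pl)
}

#' Normalize SEC chromatogram peak areas to species fractions
#'
#' Converts integrated peak areas (e.g. monomer, intermediate oligomer,
#' high-molecular-weight oligomer) into relative fractions by dividing by
#' the total area; the result sums to 1 exactly and is invariant to the
#' detector scale.
#'
#' @param areas Named or unnamed non-negative peak areas, at least one
#'   positive.
#' @return Numeric vector of fractions, same names, summing to 1.
#' @examples
#' sec_fractions(c(monomer = 1, oligomer = 1, hmw = 2))
#' @export
sec_fractions <- function(areas) {
  if (any(areas < 0)) stop("peak areas must be >= 0", call. = FALSE)
  tot <- sum(areas)
  if (tot <= 0) stop("all peak areas are zero", call. = FALSE)
  areas / tot
}
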