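#' Fractional saturation under the Langmuir (single-ligand) model
#'
#' Occupancy of a response element treated as a single binding reaction with
#' apparent dissociation constant \code{k_app}:
#' \deqn{\bar{Y} = x / (k_{app} + x)}
#' where \code{x} is the free receptor monomer concentration. This is the
#' hyperbolic model that resolves the apparent affinity of a site; it ignores
#' receptor dimerization at palindromic elements.
#'
#' All constants in this package follow the dissociation convention: larger
#' values mean weaker binding (the association constant is \code{1/k}).
#'
#' @param x free receptor monomer concentration (molar), non-negative;
#'   vectorized.
#' @param k_app apparent dissociation constant (molar), strictly positive.
#' @return fractional saturation in \code{[0, 1)}, same length as \code{x}.
#' @seealso [ybar_dimer()] for the dimer-assembly (total affinity) model.
#' @examples
#' ybar_langmuir(32e-9, 32e-9)  # midpoint: 0.5
#' @export
ybar_langmuir <- function(x, k_app) {
  check_conc(x, "x")
  check_positive(k_app, "k_app")
  x / (k_app + x)
}

#' Fractional saturation under the dimer-assembly (total affinity) model
#'
#' Occupancy of a palindromic response element via the total binding reaction
#' assembling two receptor monomers, with macroscopic total dissociation
#' constant \code{k_tot} (units molar squared):
#' \deqn{\bar{Y} = x^2 / (k_{tot} + x^2)}
#' The curve is sigmoidal with a Hill slope of 2 at the midpoint, which sits
#' exactly at \code{x = sqrt(k_tot)}. Singly-ligated intermediates are not
#' resolved by this macroscopic formulation: the element is either empty or
#' doubly bound.
#'
#' A note on units: printed tables in this field report \code{K_tot} in
#' "fM^2", meaning 1e-15 M^2 (femto-(molar squared)), \emph{not}
#' (1 fM)^2 = 1e-30 M^2. Only the former is self-consistent with the printed
#' apparent affinities (sqrt(0.800e-15 M^2) = 28 nM, matching a ~32 nM
#' K_app), so that is the convention used throughout.
#'
#' @param x free receptor monomer concentration (molar), non-negative;
#'   vectorized.
#' @param k_tot total dissociation constant (molar^2), strictly positive.
#' @return fractional saturation in \code{[0, 1)}.
#' @examples
#' ybar_dimer(sqrt(0.800e-15), 0.800e-15)  # midpoint: 0.5
#' @export
ybar_dimer <- function(x, k_tot) {
  check_conc(x, "x")
  check_positive(k_tot, "k_tot")
  x^2 / (k_tot + x^2)
}

#' Free monomer concentration from total receptor and dimerization constant
#'
#' Receptors dimerize in solution (2M <-> M2, dissociation constant
#' \code{k_dim}), so the free monomer concentration \code{x} available for DNA
#' binding is set by conservation of total receptor:
#' \deqn{R_{tot} = x + 2 x^2 / k_{dim}}
#' Solved in closed form for the unique non-negative root. With
#' \code{k_dim = NULL} (no detectable dimerization) all receptor is monomeric
#' and \code{x = r_total}.
#'
#' @param r_total total receptor concentration in monomer units (molar),
#'   non-negative; vectorized.
#' @param k_dim dimerization dissociation constant (molar), strictly
#'   positive, or \code{NULL}/\code{NA} for a non-dimerizing species.
#' @return free monomer concentration (molar), \code{<= r_total}.
#' @examples
#' free_monomer(1.5e-6, 1e-6)  # 0.6514 uM
#' @export
free_monomer <- function(r_total, k_dim = NULL) {
  check_conc(r_total, "r_total")
  if (is.null(k_dim) || all(is.na(k_dim))) {
    return(r_total)
  }
  check_positive(k_dim, "k_dim")
  # root of 2x^2/k_dim + x - r = 0, written to avoid cancellation at small r
  2 * r_total / (1 + sqrt(1 + 8 * r_total / k_dim))
}

#' Solution dimer concentration at a given free monomer concentration
#'
#' \deqn{[M_2] = x^2 / k_{dim}}
#' Consistent with [free_monomer()]: \code{x + 2 * dimer_conc(x, k_dim)}
#' reconstructs the total receptor concentration.
#'
#' @param x free monomer concentration (molar), non-negative; vectorized.
#' @param k_dim dimerization dissociation constant (molar), strictly positive.
#' @return dimer concentration (molar).
#' @export
dimer_conc <- function(x, k_dim) {
  check_conc(x, "x")
  check_positive(k_dim, "k_dim")
  x^2 / k_dim
}

# -- input checks shared across modules ---------------------------------------

check_conc <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop("invalid parameter: '", name, "' must be finite and non-negative",
         call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("invalid parameter: '", name, "' must be a single positive number",
         call. = FALSE)
  }
  invisible(x)
}
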