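#' Allocation-model parameters
#'
#' Constants of the three-sector proteome allocation model. The proteome is
#' partitioned into a ribosome-affiliated sector (mass fraction `phi_R`), a
#' metabolic sector (`phi_M`) and a growth-rate-independent housekeeping
#' sector (`phi_Q`). The growth-linked budget is
#' `phi_max = 1 - phi_Q = phi_R + phi_M`. On the translation-limited branch
#' growth follows `lambda = gamma * phi_R`; on the metabolic branch
#' `lambda = nu * phi_M`.
#'
#' @param gamma Translational efficiency: growth rate produced per unit of
#'   ribosomal proteome fraction (1/h). Must be positive.
#' @param nu Metabolic efficiency: growth rate per unit of metabolic proteome
#'   fraction (1/h). Must be positive.
#' @param phi_max Growth-linked proteome fraction, about 0.40 in E. coli.
#'   The housekeeping fraction is derived as `phi_Q = 1 - phi_max`.
#' @param rho Conversion between the RNA/protein mass ratio and the
#'   ribosome-affiliated proteome fraction, `phi_R = (R/P) * rho`;
#'   default 0.76.
#' @return An object of class `allocation_params`: a named list with fields
#'   `gamma`, `nu`, `phi_max`, `phi_Q`, `rho`.
#' @examples
#' allocation_params(gamma = 6, nu = 3)
#' @seealso [balanced_growth()], [perturbed_growth()], [phi_R_from_rp()]
#' @export
allocation_params <- function(gamma, nu, phi_max = 0.40, rho = 0.76) {
  ppa_stopifnot_scalar(gamma, "gamma", lower = 0, strict_lower = TRUE)
  ppa_stopifnot_scalar(nu, "nu", lower = 0, strict_lower = TRUE)
  ppa_stopifnot_scalar(phi_max, "phi_max", lower = 0, upper = 1,
                       strict_lower = TRUE)
  ppa_stopifnot_scalar(rho, "rho", lower = 0, upper = 1, strict_lower = TRUE)
  structure(
    list(gamma = gamma, nu = nu, phi_max = phi_max,
         phi_Q = 1 - phi_max, rho = rho),
    class = "allocation_params"
  )
}

#' @export
print.allocation_params <- function(x, ...) {
  cat("<allocation_params>\n")
  cat(sprintf("  gamma   = %g /h (translational efficiency)\n", x$gamma))
  cat(sprintf("  nu      = %g /h (metabolic efficiency)\n", x$nu))
  cat(sprintf("  phi_max = %g (growth-linked budget; phi_Q = %g)\n",
              x$phi_max, x$phi_Q))
  cat(sprintf("  rho     = %g (phi_R per unit R/P)\n", x$rho))
  invisible(x)
}

#' Ribosome and reporter constants
#'
#' Physical constants used to convert between the RNA/protein mass ratio,
#' ribosome number density and translational flux. The defaults are standard
#' E. coli values; all are overridable so every deduction is auditable.
#'
#' @param f_rrna rRNA fraction of total RNA mass (default 0.86).
#' @param m_aa Mean amino-acid residue mass in protein, Da (default 109).
#' @param m_rrna rRNA mass per ribosome, Da (default 1.507e6).
#' @param lacz_len Length of the LacZ monomer in amino acids (default 1023),
#'   used to convert the first-completion lag of an induction curve into an
#'   elongation rate.
#' @return An object of class `ribosome_constants`.
#' @examples
#' ribosome_constants()
#' @export
ribosome_constants <- function(f_rrna = 0.86, m_aa = 109,
                               m_rrna = 1.507e6, lacz_len = 1023) {
  ppa_stopifnot_scalar(f_rrna, "f_rrna", lower = 0, upper = 1,
                       strict_lower = TRUE)
  ppa_stopifnot_scalar(m_aa, "m_aa", lower = 0, strict_lower = TRUE)
  ppa_stopifnot_scalar(m_rrna, "m_rrna", lower = 0, strict_lower = TRUE)
  ppa_stopifnot_scalar(lacz_len, "lacz_len", lower = 0, strict_lower = TRUE)
  structure(
    list(f_rrna = f_rrna, m_aa = m_aa, m_rrna = m_rrna, lacz_len = lacz_len),
    class = "ribosome_constants"
  )
}

#' @export
print.ribosome_constants <- function(x, ...) {
  cat("<ribosome_constants>\n")
  cat(sprintf("  f_rrna = %g, m_aa = %g Da, m_rrna = %g Da, lacz_len = %g aa\n",
              x$f_rrna, x$m_aa, x$m_rrna, x$lacz_len))
  invisible(x)
}
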