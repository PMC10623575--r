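#' Generalized-Born / surface-area calculation settings
#'
#' Bundles the numeric constants entering the implicit-solvent energy model:
#' interior and exterior dielectric constants, the electrostatic conversion
#' constant, the surface-tension coefficient and intercept of the nonpolar
#' solvation term, and the probe radius and lattice density used for
#' solvent-accessible surface area (SASA).
#'
#' Defaults are standard AMBER-compatible values: \code{eps_in = 1},
#' \code{eps_out = 78.5}, \code{coulomb_k = 332.0636} kcal A / (mol e^2),
#' \code{sasa_gamma = 0.0072} kcal/(mol A^2), \code{sasa_beta = 0},
#' \code{probe_radius = 1.4} A, \code{sasa_points = 960}.
#'
#' @param eps_in interior (solute) dielectric constant, >= 1.
#' @param eps_out exterior (solvent) dielectric constant, > \code{eps_in}.
#' @param coulomb_k electrostatic constant in kcal A / (mol e^2).
#' @param sasa_gamma surface tension, kcal/(mol A^2).
#' @param sasa_beta nonpolar intercept, kcal/mol.
#' @param probe_radius solvent probe radius in A, >= 0.
#' @param sasa_points number of lattice points per atom for SASA.
#' @return An object of class \code{gb_settings}.
#' @export
#' @examples
#' s <- gb_settings()
#' s$eps_out
gb_settings <- function(eps_in = 1.0, eps_out = 78.5, coulomb_k = 332.0636,
                        sasa_gamma = 0.0072, sasa_beta = 0.0,
                        probe_radius = 1.4, sasa_points = 960L) {
  stopifnot(is.numeric(eps_in), is.numeric(eps_out), length(eps_in) == 1L,
            length(eps_out) == 1L)
  if (!(eps_in >= 1))
    stop("eps_in must be >= 1, got ", eps_in)
  if (!(eps_out > eps_in))
    stop("eps_out (", eps_out, ") must exceed eps_in (", eps_in, ")")
  if (probe_radius < 0)
    stop("probe_radius must be >= 0")
  sasa_points <- as.integer(sasa_points)
  if (sasa_points < 1L)
    stop("sasa_points must be a positive integer")
  structure(list(eps_in = eps_in, eps_out = eps_out, coulomb_k = coulomb_k,
                 sasa_gamma = sasa_gamma, sasa_beta = sasa_beta,
                 probe_radius = probe_radius, sasa_points = sasa_points),
            class = "gb_settings")
}

#' @export
print.gb_settings <- function(x, ...) {
  cat("GB/SA settings: eps_in =", x$eps_in, " eps_out =", x$eps_out,
      "\n  coulomb_k =", x$coulomb_k, "kcal*A/(mol*e^2)",
      "\n  nonpolar: gamma =", x$sasa_gamma, "kcal/(mol*A^2), beta =",
      x$sasa_beta, "kcal/mol",
      "\n  SASA: probe =", x$probe_radius, "A,", x$sasa_points,
      "points/atom\n")
  invisible(x)
}
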