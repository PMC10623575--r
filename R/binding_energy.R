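#' @title End-point binding free energy (MM-GBSA + WSAS entropy)
#' @description Single-trajectory protocol: every component is
#'   E(complex) - E(receptor alone) - E(ligand alone) evaluated on identical
#'   coordinates, so internal bonded terms cancel by construction.  The
#'   entropy change is estimated with a weighted-SASA (WSAS) linear model on
#'   an evenly spaced snapshot subsample.
#' @name binding_energy
NULL

#' WSAS entropy-model weights
#'
#' The weighted-SASA entropy estimate of a system is
#' \eqn{S = \sum_{atoms} w(\mathrm{atom\_type}) \cdot SASA_{atom} +
#' intercept} (kcal/mol, i.e. the weights absorb the temperature factor).
#' The default is the zero model (TdS = 0, so dG reduces to dE); supply a
#' named weight vector to enable it.
#'
#' @param weights named numeric vector, atom_type -> kcal/(mol A^2).
#'   Atom types absent from the vector get weight 0.
#' @param intercept kcal/mol.
#' @param temperature absolute temperature (K); metadata, default 298.15.
#' @return a \code{wsas_weights} object.
#' @export
wsas_weights <- function(weights = numeric(0), intercept = 0,
                         temperature = 298.15) {
  if (length(weights) && (is.null(names(weights)) || !all(is.finite(weights))))
    stop("weights must be a finite named numeric vector")
  structure(list(weights = weights, intercept = intercept,
                 temperature = temperature),
            class = "wsas_weights")
}

# All-pairs MM + GB + SASA energies of one subsystem on given coordinates.
system_energy <- function(xyz, params, settings, want_sasa = TRUE) {
  n <- nrow(xyz)
  ele <- 0; vdw <- 0
  if (n > 1L) {
    d <- dist_matrix(xyz)
    iu <- upper.tri(d)
    r <- d[iu]
    if (any(r <= 0)) stop("overlapping atoms within a subsystem")
    qq <- outer(params$charge, params$charge)[iu]
    ele <- settings$coulomb_k / settings$eps_in * sum(qq / r)
    rmin <- outer(params$lj_rmin_half, params$lj_rmin_half, "+")[iu]
    epsij <- sqrt(outer(params$lj_epsilon, params$lj_epsilon))[iu]
    x6 <- (rmin / r)^6
    vdw <- sum(epsij * (x6 * x6 - 2 * x6))
  }
  gb <- gb_polar_energy(xyz, params$charge, params$gb_radius,
                        params$gb_screen, settings)$total
  sas <- if (want_sasa)
    sasa(xyz, params$gb_radius, settings$probe_radius, settings$sasa_points)
  else numeric(n)
  list(ele = ele, vdw = vdw, gb = gb, sasa = sas,
       nonpolar = settings$sasa_gamma * sum(sas) + settings$sasa_beta)
}

wsas_entropy <- function(sas, atom_type, w) {
  wt <- if (length(w$weights)) {
    v <- w$weights[atom_type]
    v[is.na(v)] <- 0
    unname(v)
  } else rep.int(0, length(sas))
  sum(wt * sas) + w$intercept
}

#' MM-GBSA binding energy and MM-GBSA/WSAS free energy
#'
#' For every retained snapshot the complex, the receptor alone, and the
#' ligand alone are evaluated on identical coordinates;
#' \eqn{\Delta E = \Delta E_{ele} + \Delta E_{vdw} + \Delta G^{sol}_{p} +
#' \Delta G^{sol}_{np}} is averaged over the \code{stride_de} subsample and
#' \eqn{T\Delta S} (WSAS) over the \code{stride_tds} subsample;
#' \eqn{\Delta G = \Delta E - T\Delta S}.  Default strides mirror the
#' decompose-everything / entropy-on-1-in-25 convention (5000 snapshots ->
#' 200 for the entropy analysis).
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param settings a \code{\link{gb_settings}}.
#' @param stride_de snapshot stride for the energy components.
#' @param stride_tds snapshot stride for the entropy estimate.
#' @param weights a \code{\link{wsas_weights}} object.
#' @return an \code{energy_report}: \code{de_ele, de_vdw, dg_polar,
#'   dg_nonpolar, de_total, tds, dg_total, n_snapshots_de,
#'   n_snapshots_tds, polar_method}.
#' @export
binding_energy <- function(ensemble, settings = gb_settings(),
                           stride_de = 1L, stride_tds = 25L,
                           weights = wsas_weights()) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  ens_de <- subsample_ensemble(ensemble, stride_de)
  ens_ts <- subsample_ensemble(ensemble, stride_tds)
  a <- ensemble$atoms
  p <- ensemble$params
  lig <- which(a$segment == "ligand")
  rec <- which(a$segment == "receptor")
  if (length(lig) == 0L) stop("ensemble has an empty ligand segment")

  comp_one <- function(xyz) {
    ec <- system_energy(xyz, p, settings)
    er <- system_energy(xyz[rec, , drop = FALSE],
                        p[rec, , drop = FALSE], settings)
    el <- system_energy(xyz[lig, , drop = FALSE],
                        p[lig, , drop = FALSE], settings)
    c(ele = ec$ele - er$ele - el$ele,
      vdw = ec$vdw - er$vdw - el$vdw,
      gb = ec$gb - er$gb - el$gb,
      np = ec$nonpolar - er$nonpolar - el$nonpolar)
  }
  de <- rowMeans(vapply(ens_de$coords, comp_one, numeric(4L)))

  tds_one <- function(xyz) {
    sc <- sasa(xyz, p$gb_radius, settings$probe_radius, settings$sasa_points)
    sr <- sasa(xyz[rec, , drop = FALSE], p$gb_radius[rec],
               settings$probe_radius, settings$sasa_points)
    sl <- sasa(xyz[lig, , drop = FALSE], p$gb_radius[lig],
               settings$probe_radius, settings$sasa_points)
    wsas_entropy(sc, p$atom_type, weights) -
      wsas_entropy(sr, p$atom_type[rec], weights) -
      wsas_entropy(sl, p$atom_type[lig], weights)
  }
  tds <- mean(vapply(ens_ts$coords, tds_one, numeric(1L)))

  de_total <- sum(de)
  structure(list(de_ele = de[["ele"]], de_vdw = de[["vdw"]],
                 dg_polar = de[["gb"]], dg_nonpolar = de[["np"]],
                 de_total = de_total, tds = tds,
                 dg_total = de_total - tds,
                 n_snapshots_de = length(ens_de$coords),
                 n_snapshots_tds = length(ens_ts$coords),
                 polar_method = "GB(HCT)"),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Binding energy report (polar: %s)\n",
    "  dE_ele = %10.4f  dE_vdw = %10.4f\n",
    "  dG_pol = %10.4f  dG_np  = %10.4f   [kcal/mol]\n",
    "  dE     = %10.4f  (over %d snapshots)\n",
    "  TdS    = %10.4f  (over %d snapshots)\n",
    "  dG     = %10.4f\n"),
    x$polar_method, x$de_ele, x$de_vdw, x$dg_polar, x$dg_nonpolar,
    x$de_total, x$n_snapshots_de, x$tds, x$n_snapshots_tds, x$dg_total))
  invisible(x)
}

#' Binding-energy gate of the screening decision flow
#'
#' \code{TRUE} iff the binding energy is strictly better (more negative)
#' than the threshold; a compound exactly at -10 kcal/mol is rejected.
#'
#' @param report an \code{energy_report} (or a single dE value).
#' @param threshold gate threshold, kcal/mol.
#' @return logical.
#' @export
classify_energy_gate <- function(report, threshold = -10) {
  de <- if (inherits(report, "energy_report")) report$de_total
        else as.numeric(report)
  if (!is.finite(de)) stop("binding energy is not finite")
  de < threshold
}
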