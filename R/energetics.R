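#' @title Molecular-mechanics and implicit-solvent energetics
#' @description Coulomb and Lennard-Jones pair energies, Hawkins-Cramer-
#'   Truhlar (HCT) effective Born radii, Still-form generalized-Born polar
#'   solvation, Shrake-Rupley SASA, and the ligand-residue decomposition
#'   of the intermolecular energy.  All sums are exact O(N^2) with no
#'   cutoffs; only intermolecular pairs enter the decomposition, so 1-4 and
#'   intramolecular exclusions never arise.
#' @name energetics
NULL

#' Coulomb pair energy
#'
#' \eqn{E = k q_i q_j / (\epsilon_{in} r_{ij})} in kcal/mol with charges in
#' elementary charge units and distances in Angstrom.
#'
#' @param qi,qj partial charges (e).
#' @param rij interatomic distance (A), > 0.
#' @param eps_in interior dielectric constant.
#' @param coulomb_k conversion constant, kcal A / (mol e^2).
#' @return energy in kcal/mol (vectorized).
#' @export
coulomb_pair <- function(qi, qj, rij, eps_in = 1.0, coulomb_k = 332.0636) {
  if (any(rij <= 0))
    stop("overlapping atoms: rij must be > 0")
  coulomb_k * qi * qj / (eps_in * rij)
}

#' Lennard-Jones 12-6 pair energy
#'
#' Lorentz-Berthelot-style combining: \eqn{R_{min,ij} = R_{min,i}/2 +
#' R_{min,j}/2}, \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}};
#' \eqn{E = \epsilon_{ij}[(R_{min,ij}/r)^{12} - 2 (R_{min,ij}/r)^6]}, so the
#' minimum is exactly \eqn{-\epsilon_{ij}} at \eqn{r = R_{min,ij}}.
#'
#' @param rmin_half_i,rmin_half_j Rmin/2 parameters (A).
#' @param eps_i,eps_j well depths (kcal/mol).
#' @param rij interatomic distance (A), > 0.
#' @return energy in kcal/mol (vectorized).
#' @export
lj_pair <- function(rmin_half_i, eps_i, rmin_half_j, eps_j, rij) {
  if (any(rij <= 0))
    stop("overlapping atoms: rij must be > 0")
  rmin <- rmin_half_i + rmin_half_j
  epsij <- sqrt(eps_i * eps_j)
  x6 <- (rmin / rij)^6
  epsij * (x6 * x6 - 2 * x6)
}

# Pairwise distance matrix for an n x 3 coordinate matrix.
dist_matrix <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

#' Effective Born radii by HCT pairwise descreening
#'
#' The inverse effective radius of atom i is its inverse intrinsic radius
#' minus the sum over all other atoms j of the analytic descreening integral
#' of the Coulomb-field approximation, evaluated over atom j's scaled sphere
#' (radius \code{gb_screen[j] * gb_radius[j]}) excluding the region inside
#' atom i's intrinsic sphere.  An isolated atom's effective radius equals
#' its intrinsic radius.
#'
#' @param xyz n x 3 coordinate matrix (A).
#' @param gb_radius intrinsic GB radii (A), > 0.
#' @param gb_screen dimensionless screening factors.
#' @return numeric vector of effective radii (A).
#' @export
effective_born_radii <- function(xyz, gb_radius, gb_screen) {
  n <- nrow(xyz)
  stopifnot(length(gb_radius) == n, length(gb_screen) == n)
  if (any(gb_radius <= 0)) stop("gb_radius must be > 0")
  if (n == 1L) return(gb_radius)
  d <- dist_matrix(xyz)
  s <- gb_screen * gb_radius
  inv <- 1 / gb_radius
  for (i in seq_len(n)) {
    rho <- gb_radius[i]
    r <- d[i, -i]
    sj <- s[-i]
    inv[i] <- inv[i] - sum(hct_integral(r, rho, sj))
  }
  if (any(inv <= 0)) {
    bad <- which(inv <= 0)
    stop("nonpositive effective Born radius for atom(s): ",
         paste(bad, collapse = ", "))
  }
  1 / inv
}

# HCT descreening integral H(r, rho_i, s_j) (vectorized over r, sj):
#   H = 0                                     if r >= rho + s never triggers;
#   H = 0                                     if rho >= r + s (j buried in i)
#   else, with U = r + s, L = max(rho, |r - s|):
#   H = 1/2 [ 1/L - 1/U + (r - s^2/r)(1/U^2 - 1/L^2)/4 + ln(L/U)/(2r) ]
#       + (1/rho - 1/L)  when s - r > rho  (atom i engulfed by scaled j)
hct_integral <- function(r, rho, sj) {
  out <- numeric(length(r))
  active <- (r + sj) > rho
  if (!any(active)) return(out)
  r <- r[active]; sj2 <- sj[active]
  U <- r + sj2
  L <- pmax(rho, abs(r - sj2))
  h <- 0.5 * (1 / L - 1 / U +
              0.25 * (r - sj2 * sj2 / r) * (1 / (U * U) - 1 / (L * L)) +
              0.5 * log(L / U) / r)
  engulf <- (sj2 - r) > rho
  h[engulf] <- h[engulf] + (1 / rho - 1 / L[engulf])
  out[active] <- h
  out
}

#' Still-form generalized-Born polar solvation energy
#'
#' \deqn{\Delta G_{GB} = -\frac{k}{2}\Big(\frac{1}{\epsilon_{in}} -
#'   \frac{1}{\epsilon_{out}}\Big) \sum_{i,j}
#'   \frac{q_i q_j}{f_{GB}(r_{ij}, R_i, R_j)}}
#' with \eqn{f_{GB} = \sqrt{r_{ij}^2 + R_i R_j \exp(-r_{ij}^2 / (4 R_i
#' R_j))}}; the sum runs over all ordered pairs including the self terms
#' (\eqn{i = j}, \eqn{f_{GB} = R_i}).  For a single ion this reduces to the
#' Born formula.
#'
#' @param xyz n x 3 coordinate matrix (A).
#' @param charge partial charges (e).
#' @param gb_radius,gb_screen intrinsic radii / screening factors for the
#'   HCT effective radii.
#' @param settings a \code{\link{gb_settings}} object.
#' @param born_radii optional precomputed effective radii (skips HCT).
#' @return list with \code{total} (kcal/mol), \code{pair} (n x n matrix of
#'   ordered-pair terms, \code{sum(pair) == total}), and \code{radii}.
#' @export
gb_polar_energy <- function(xyz, charge, gb_radius, gb_screen,
                            settings = gb_settings(), born_radii = NULL) {
  n <- nrow(xyz)
  if (is.null(born_radii))
    born_radii <- effective_born_radii(xyz, gb_radius, gb_screen)
  d <- if (n > 1L) dist_matrix(xyz) else matrix(0, 1L, 1L)
  RiRj <- outer(born_radii, born_radii)
  fgb <- sqrt(d * d + RiRj * exp(-d * d / (4 * RiRj)))
  # diagonal: f_GB(0, Ri, Ri) = Ri exactly
  diag(fgb) <- born_radii
  pref <- -0.5 * settings$coulomb_k *
    (1 / settings$eps_in - 1 / settings$eps_out)
  pair <- pref * outer(charge, charge) / fgb
  list(total = sum(pair), pair = pair, radii = born_radii)
}

# Deterministic unit-sphere lattice: golden-spiral (Fibonacci) points.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Places a deterministic golden-spiral lattice of \code{sasa_points} points
#' on each atom's solvent-expanded sphere (radius + probe) and counts the
#' points not buried inside any other expanded sphere.
#'
#' @param xyz n x 3 coordinate matrix (A).
#' @param radii per-atom radii (A), > 0.
#' @param probe_radius solvent probe radius (A).
#' @param sasa_points lattice points per atom.
#' @return numeric vector of per-atom areas (A^2), >= 0.
#' @export
sasa <- function(xyz, radii, probe_radius = 1.4, sasa_points = 960L) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  if (any(radii <= 0)) stop("radii must be > 0")
  pts <- fibonacci_sphere(as.integer(sasa_points))
  ext <- radii + probe_radius
  ext2 <- ext * ext
  area <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * ext[i], 2L, xyz[i, ], "+")
    exposed <- rep.int(TRUE, nrow(p))
    for (j in seq_len(n)) {
      if (j == i) next
      dx <- p[, 1L] - xyz[j, 1L]
      dy <- p[, 2L] - xyz[j, 2L]
      dz <- p[, 3L] - xyz[j, 3L]
      exposed <- exposed & (dx * dx + dy * dy + dz * dz > ext2[j])
      if (!any(exposed)) break
    }
    area[i] <- 4 * pi * ext2[i] * sum(exposed) / nrow(pts)
  }
  area
}

# ---- ligand-residue decomposition ------------------------------------------

#' Decompose the intermolecular energy by receptor residue
#'
#' For each snapshot and each receptor residue r:
#' \itemize{
#'   \item \code{ele(r)}, \code{vdw(r)}: sums of Coulomb / Lennard-Jones pair
#'     energies over all (ligand atom, residue-r atom) pairs;
#'   \item \code{gb_polar(r)}: the full GB cross term of each unordered
#'     (ligand atom, residue atom) pair, with effective radii computed on the
#'     whole complex snapshot; self terms and receptor-receptor or
#'     ligand-internal terms are excluded;
#'   \item \code{nonpolar(r)} (optional): \eqn{\gamma \sum_{j \in r}
#'     [SASA_j(\mathrm{receptor\ alone}) - SASA_j(\mathrm{complex})]} on the
#'     same snapshot, i.e. the residue's ligand-induced burial.
#' }
#' Summing \code{ele + vdw + gb_polar} over residues reproduces the total
#' intermolecular Coulomb + LJ + GB-cross energy of the snapshot exactly.
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param settings a \code{\link{gb_settings}}.
#' @param include_nonpolar logical; add the per-residue SASA term
#'   (default \code{FALSE}).
#' @param stride snapshot stride (see \code{\link{subsample_ensemble}}).
#' @return data.frame with columns \code{snapshot, residue_label, ele, vdw,
#'   gb_polar, nonpolar, total}.
#' @export
decompose_ligand_residue <- function(ensemble, settings = gb_settings(),
                                     include_nonpolar = FALSE, stride = 1L) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  if (stride != 1L) ensemble <- subsample_ensemble(ensemble, stride)
  a <- ensemble$atoms
  p <- ensemble$params
  lig <- which(a$segment == "ligand")
  rec <- which(a$segment == "receptor")
  if (length(lig) == 0L) stop("ensemble has an empty ligand segment")
  if (length(rec) == 0L) stop("ensemble has an empty receptor segment")
  rlab <- a$residue_label[rec]
  labs <- sort(unique(rlab))
  res_atoms <- split(rec, rlab)

  out <- vector("list", length(ensemble$coords))
  for (m in seq_along(ensemble$coords)) {
    xyz <- ensemble$coords[[m]]
    d <- dist_matrix(xyz)
    dlr <- d[lig, rec, drop = FALSE]
    if (any(dlr <= 0))
      stop("overlapping ligand/receptor atoms in snapshot ", m)
    ele_m <- settings$coulomb_k / settings$eps_in *
      outer(p$charge[lig], p$charge[rec]) / dlr
    rmin <- outer(p$lj_rmin_half[lig], p$lj_rmin_half[rec], "+")
    epsij <- sqrt(outer(p$lj_epsilon[lig], p$lj_epsilon[rec]))
    x6 <- (rmin / dlr)^6
    vdw_m <- epsij * (x6 * x6 - 2 * x6)
    gb <- gb_polar_energy(xyz, p$charge, p$gb_radius, p$gb_screen, settings)
    # ordered-pair matrix: unordered cross term (i,j) = pair[i,j] + pair[j,i]
    gbx <- 2 * gb$pair[lig, rec, drop = FALSE]

    if (include_nonpolar) {
      sas_c <- sasa(xyz, p$gb_radius, settings$probe_radius,
                    settings$sasa_points)
      sas_r <- numeric(nrow(a))
      sas_r[rec] <- sasa(xyz[rec, , drop = FALSE], p$gb_radius[rec],
                         settings$probe_radius, settings$sasa_points)
      dsas <- sas_r - sas_c   # burial upon complexation, receptor atoms
    }

    rows <- data.frame(snapshot = m, residue_label = labs,
                       ele = 0, vdw = 0, gb_polar = 0, nonpolar = 0)
    for (k in seq_along(labs)) {
      cols <- match(res_atoms[[labs[k]]], rec)
      rows$ele[k] <- sum(ele_m[, cols])
      rows$vdw[k] <- sum(vdw_m[, cols])
      rows$gb_polar[k] <- sum(gbx[, cols])
      if (include_nonpolar)
        rows$nonpolar[k] <- settings$sasa_gamma *
          sum(dsas[res_atoms[[labs[k]]]])
    }
    out[[m]] <- rows
  }
  res <- do.call(rbind, out)
  res$total <- res$ele + res$vdw + res$gb_polar +
    if (include_nonpolar) res$nonpolar else 0
  res
}
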