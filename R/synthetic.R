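#' @title Seeded synthetic fixtures
#' @description Deterministic generators for toy receptor-ligand ensembles
#'   and correlated synthetic profiles, plus accessors for the packaged
#'   in-text fixtures.  Everything is bit-reproducible given the seed.
#' @name synthetic_fixtures
NULL

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a seeded toy receptor-ligand ensemble
#'
#' Receptor residues sit on a ring (radius 8 A) around a compact ligand at
#' the origin; partial charges are drawn uniformly in [-0.5, 0.5] e and
#' shifted so each segment's total charge is an exact integer; LJ and GB
#' parameters are drawn within physically sensible ranges.  Snapshots are
#' the base coordinates plus seeded isotropic Gaussian jitter of standard
#' deviation \code{jitter_sd}, emulating thermal fluctuation about a bound
#' pose.  The same arguments and seed always produce an identical ensemble
#' (and byte-identical files via \code{\link{write_toy_complex}}).
#'
#' @param n_residues receptor residue count, >= 1.
#' @param atoms_per_residue atoms per receptor residue, >= 1.
#' @param n_ligand_atoms ligand atom count, >= 1.
#' @param n_snapshots snapshot count, >= 1.
#' @param jitter_sd per-coordinate jitter sd (A), >= 0.
#' @param seed integer RNG seed.
#' @return a \code{conformation_ensemble}.
#' @export
make_toy_complex <- function(n_residues = 8L, atoms_per_residue = 3L,
                             n_ligand_atoms = 6L, n_snapshots = 5L,
                             jitter_sd = 0.15, seed = 1L) {
  stopifnot(n_residues >= 1L, atoms_per_residue >= 1L,
            n_ligand_atoms >= 1L, n_snapshots >= 1L, jitter_sd >= 0)
  with_seed(seed, {
    n_rec <- n_residues * atoms_per_residue
    n <- n_rec + n_ligand_atoms

    # ligand: points on a 1.5 A sphere, evenly spread (golden spiral)
    lig_xyz <- fibonacci_sphere(n_ligand_atoms) * 1.5
    # receptor: residue centers on a ring; atoms offset along a short helix
    rec_xyz <- matrix(0, n_rec, 3L)
    for (k in seq_len(n_residues)) {
      ang <- 2 * pi * (k - 1) / n_residues
      ctr <- c(8 * cos(ang), 8 * sin(ang), 0)
      for (a in seq_len(atoms_per_residue)) {
        off <- c(0.6 * cos(2.1 * a), 0.6 * sin(2.1 * a), 1.2 * (a - 1))
        rec_xyz[(k - 1) * atoms_per_residue + a, ] <- ctr + off
      }
    }
    base <- rbind(rec_xyz, lig_xyz)

    balance <- function(q) q - (sum(q) - round(sum(q))) / length(q)
    charge <- c(balance(stats::runif(n_rec, -0.5, 0.5)),
                balance(stats::runif(n_ligand_atoms, -0.5, 0.5)))
    params <- data.frame(
      atom_id = seq_len(n),
      charge = charge,
      lj_rmin_half = stats::runif(n, 1.3, 2.1),
      lj_epsilon = stats::runif(n, 0.05, 0.2),
      gb_radius = stats::runif(n, 1.2, 1.9),
      gb_screen = stats::runif(n, 0.72, 0.9),
      atom_type = sample(c("C", "N", "O", "H", "S"), n, replace = TRUE),
      stringsAsFactors = FALSE)

    atoms <- data.frame(
      atom_id = seq_len(n),
      name = c(paste0("R", seq_len(n_rec)), paste0("L", seq_len(n_ligand_atoms))),
      chain = c(rep.int("A", n_rec), rep.int("L", n_ligand_atoms)),
      resid = c(rep(seq_len(n_residues), each = atoms_per_residue),
                rep.int(n_residues + 1L, n_ligand_atoms)),
      resname = c(rep.int("GLY", n_rec), rep.int("LIG", n_ligand_atoms)),
      stringsAsFactors = FALSE)

    labels <- data.frame(
      chain = c(rep.int("A", n_residues), "L"),
      resid = c(seq_len(n_residues), n_residues + 1L),
      resname = c(rep.int("GLY", n_residues), "LIG"),
      label = c(sprintf("R%d", seq_len(n_residues)), "LIG"),
      segment = c(rep.int("receptor", n_residues), "ligand"),
      stringsAsFactors = FALSE)

    coords <- lapply(seq_len(n_snapshots), function(m)
      base + matrix(stats::rnorm(3L * n, 0, jitter_sd), n, 3L))

    build_ensemble(atoms, coords, params, labels)
  })
}

#' Write a toy complex to disk as PDB + parameter + label files
#'
#' @inheritParams make_toy_complex
#' @param dir output directory (created if absent).
#' @return named character vector of the three file paths (\code{pdb},
#'   \code{params}, \code{labels}).
#' @export
write_toy_complex <- function(dir, n_residues = 8L, atoms_per_residue = 3L,
                              n_ligand_atoms = 6L, n_snapshots = 5L,
                              jitter_sd = 0.15, seed = 1L) {
  ens <- make_toy_complex(n_residues, atoms_per_residue, n_ligand_atoms,
                          n_snapshots, jitter_sd, seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pdb = file.path(dir, "complex.pdb"),
             params = file.path(dir, "params.tsv"),
             labels = file.path(dir, "labels.tsv"))
  write_ensemble_pdb(ens, paths[["pdb"]])
  write_params_table(ens$params, paths[["params"]])
  write_labels_table(ens$labels, paths[["labels"]])
  paths
}

#' Simulate profiles with a prescribed correlation to a signature
#'
#' Each profile is constructed as \code{rho} times the standardized
#' signature mean vector plus \code{sqrt(1 - rho^2)} times an
#' orthogonalized standardized Gaussian direction, rescaled to the
#' signature's location and spread, so the sample Pearson correlation with
#' the signature equals \code{rho} exactly; independent Gaussian noise of
#' sd \code{noise_sd} is then added per residue.
#'
#' @param signature a \code{signature_profile} with >= 3 residues.
#' @param rho target correlation in [-1, 1].
#' @param noise_sd residue-wise Gaussian noise sd (kcal/mol), >= 0.
#' @param n_compounds number of profiles to generate.
#' @param seed integer RNG seed.
#' @return list of \code{interaction_profile} (ids \code{sim1, sim2, ...}).
#' @export
simulate_profiles <- function(signature, rho, noise_sd = 0,
                              n_compounds = 1L, seed = 1L) {
  stopifnot(inherits(signature, "signature_profile"))
  if (abs(rho) > 1) stop("|rho| must be <= 1, got ", rho)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  p <- length(signature$residues)
  if (p < 3L) stop("signature must contain at least 3 residues")
  mu <- unname(signature$mean_energy)
  cmu <- mu - mean(mu)
  if (sqrt(sum(cmu^2)) == 0)
    stop("signature mean energies are constant; correlation target undefined")
  u <- cmu / sqrt(sum(cmu^2))
  with_seed(seed, {
    lapply(seq_len(n_compounds), function(i) {
      repeat {
        z <- stats::rnorm(p)
        cz <- z - mean(z)
        cz <- cz - sum(cz * u) * u
        nz <- sqrt(sum(cz^2))
        if (nz > 1e-12) break
      }
      dirn <- rho * u + sqrt(1 - rho^2) * cz / nz
      e <- mean(mu) + dirn * sqrt(sum(cmu^2)) +
        stats::rnorm(p, 0, noise_sd)
      names(e) <- signature$residues
      new_interaction_profile(paste0("sim", i), signature$receptor_state,
                              e, 1L)
    })
  })
}
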