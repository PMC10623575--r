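# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written as plain scalar loops / textbook formula
# transcriptions, sharing no code path with the package implementation.

KCAL <- 332.0636

# HCT pairwise-descreening effective radii, term-by-term transcription of
# the analytic integral (four-term arrangement, scalar loops).
oracle_hct_radii <- function(xyz, rho, screen) {
  n <- nrow(xyz)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 1 / rho[i]
    for (j in seq_len(n)) {
      if (j == i) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sj <- screen[j] * rho[j]
      if (rho[i] >= r + sj) next
      L <- max(rho[i], abs(r - sj))
      U <- r + sj
      term <- (1 / L - 1 / U) +
        (r / 4) * (1 / U^2 - 1 / L^2) +
        (1 / (2 * r)) * log(L / U) +
        (sj^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
      term <- term / 2
      if (sj - r > rho[i]) term <- term + (1 / rho[i] - 1 / L)
      acc <- acc - term
    }
    out[i] <- 1 / acc
  }
  out
}

# Total intermolecular Coulomb + LJ by direct scalar double loop.
oracle_intermolecular_mm <- function(xyz, charge, rmin_half, eps,
                                     lig_idx, rec_idx, eps_in = 1) {
  ele <- 0; vdw <- 0
  for (i in lig_idx) {
    for (j in rec_idx) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      ele <- ele + KCAL * charge[i] * charge[j] / (eps_in * r)
      rm <- rmin_half[i] + rmin_half[j]
      e <- sqrt(eps[i] * eps[j])
      vdw <- vdw + e * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  list(ele = ele, vdw = vdw)
}

# Total intermolecular GB cross energy (full unordered-pair terms), given
# effective radii, by scalar double loop over ligand x receptor pairs.
oracle_gb_cross <- function(xyz, charge, born, lig_idx, rec_idx,
                            eps_in = 1, eps_out = 78.5) {
  pref <- -KCAL * (1 / eps_in - 1 / eps_out)
  total <- 0
  for (i in lig_idx) {
    for (j in rec_idx) {
      r2 <- sum((xyz[i, ] - xyz[j, ])^2)
      f <- sqrt(r2 + born[i] * born[j] * exp(-r2 / (4 * born[i] * born[j])))
      total <- total + pref * charge[i] * charge[j] / f
    }
  }
  total
}

# Whole-system GB total (ordered pairs + self terms), scalar loops.
oracle_gb_total <- function(xyz, charge, born, eps_in = 1, eps_out = 78.5) {
  n <- nrow(xyz)
  pref <- -0.5 * KCAL * (1 / eps_in - 1 / eps_out)
  total <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        f <- born[i]
      } else {
        r2 <- sum((xyz[i, ] - xyz[j, ])^2)
        f <- sqrt(r2 + born[i] * born[j] *
                    exp(-r2 / (4 * born[i] * born[j])))
      }
      total <- total + pref * charge[i] * charge[j] / f
    }
  }
  total
}

# Four similarity metrics by literal formula transcription.
oracle_metrics <- function(q, s) {
  n <- length(q)
  d <- q - s
  num <- sum((q - mean(q)) * (s - mean(s)))
  den <- sqrt(sum((q - mean(q))^2) * sum((s - mean(s))^2))
  r <- num / den
  list(r = r, r2 = r^2,
       rmse = sqrt(sum(d^2) / n),
       aue = sum(abs(d)) / n,
       ase = sum(d) / n)
}

# Welford streaming mean per residue over snapshot rows.
oracle_streaming_means <- function(rows) {
  acc <- list()
  cnt <- list()
  for (k in seq_len(nrow(rows))) {
    lab <- rows$residue_label[k]
    if (is.null(acc[[lab]])) { acc[[lab]] <- 0; cnt[[lab]] <- 0 }
    cnt[[lab]] <- cnt[[lab]] + 1
    acc[[lab]] <- acc[[lab]] + (rows$total[k] - acc[[lab]]) / cnt[[lab]]
  }
  unlist(acc)[sort(names(acc))]
}

# Unit-sphere golden-spiral points (local copy for fixture construction).
fibonacci_sphere_pts <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

# Shared toy ensemble (memoised per test run).
toy_env <- new.env()
get_toy <- function(n_snapshots = 3L, seed = 7L, jitter_sd = 0.1) {
  key <- paste(n_snapshots, seed, jitter_sd)
  if (is.null(toy_env[[key]]))
    toy_env[[key]] <- make_toy_complex(n_snapshots = n_snapshots,
                                       seed = seed, jitter_sd = jitter_sd)
  toy_env[[key]]
}

# Minimal hand-written 2-model, 5-atom PDB + matching tables.
write_mini_pdb_set <- function(dir, drop_param_atom = NULL,
                               truncate_model2 = FALSE) {
  pdb <- file.path(dir, "mini.pdb")
  atoms <- function(dx) sprintf(
    "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    1:5, c("N", "CA", "C", "O", "C1"),
    c("ALA", "ALA", "ALA", "ALA", "LIG"),
    c("A", "A", "A", "A", "L"), c(1L, 1L, 1L, 1L, 2L),
    c(0, 1.5, 3.0, 4.5, 8.0) + dx, c(0, 0.5, 0, 0.5, 0), c(0, 0, 0, 0, 1))
  m2 <- atoms(0.2)
  if (truncate_model2) m2 <- m2[1:4]
  writeLines(c("MODEL     1", atoms(0), "ENDMDL",
               "MODEL     2", m2, "ENDMDL", "END"), pdb)
  ids <- setdiff(1:5, drop_param_atom)
  params <- file.path(dir, "mini_params.tsv")
  writeLines(c(
    "atom_id\tcharge\tlj_rmin_half\tlj_epsilon\tgb_radius\tgb_screen\tatom_type",
    sprintf("%d\t%.2f\t1.8\t0.1\t1.5\t0.8\tC", ids,
            c(-0.4, 0.1, 0.5, -0.4, 0.2)[ids])), params)
  labels <- file.path(dir, "mini_labels.tsv")
  writeLines(c("chain\tresid\tresname\tlabel\tsegment",
               "A\t1\tALA\tA1\treceptor",
               "L\t2\tLIG\tLIG\tligand"), labels)
  c(pdb = pdb, params = params, labels = labels)
}
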