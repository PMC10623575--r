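#' @title Ligand-residue interaction profiles and signatures
#' @description Turns per-snapshot residue decomposition rows into a
#'   ligand-residue interaction profile (LRIP), selects key residues, builds
#'   signature profiles from reference ligands, and scores profile
#'   similarity with the four metrics R (and R^2), RMSE, AUE, and ASE.
#' @name lrip_profiles
NULL

receptor_states <- c("CB1_active", "CB1_inactive",
                     "CB2_active", "CB2_inactive", "other")

new_interaction_profile <- function(compound_id, receptor_state, energies,
                                    n_snapshots) {
  if (!receptor_state %in% receptor_states)
    stop("unknown receptor_state: ", receptor_state)
  if (length(energies) && !all(is.finite(energies)))
    stop("profile energies must be finite")
  if (n_snapshots < 1L) stop("n_snapshots must be >= 1")
  structure(list(compound_id = compound_id,
                 receptor_state = receptor_state,
                 energies = energies,
                 n_snapshots = as.integer(n_snapshots)),
            class = "interaction_profile")
}

#' Create an interaction profile from a named energy vector
#'
#' @param energies named numeric vector: residue label -> mean interaction
#'   energy (kcal/mol).
#' @param compound_id compound identifier.
#' @param receptor_state one of \code{CB1_active, CB1_inactive, CB2_active,
#'   CB2_inactive, other}.
#' @param n_snapshots number of snapshots the means were taken over.
#' @return an \code{interaction_profile}.
#' @export
interaction_profile <- function(energies, compound_id = "unknown",
                                receptor_state = "other", n_snapshots = 1L) {
  stopifnot(is.numeric(energies), !is.null(names(energies)))
  if (anyDuplicated(names(energies)))
    stop("duplicate residue labels in profile")
  new_interaction_profile(compound_id, receptor_state,
                          energies[order(names(energies))], n_snapshots)
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat("LRIP for", x$compound_id, "(", x$receptor_state, "),",
      length(x$energies), "residues, mean over", x$n_snapshots,
      "snapshot(s)\n")
  print(round(x$energies, 4))
  invisible(x)
}

#' Build an LRIP from per-snapshot decomposition rows
#'
#' Averages the per-residue \code{total} column over snapshots with uniform
#' weights.  All snapshots must report the same residue-label set.
#'
#' @param rows data.frame from \code{\link{decompose_ligand_residue}} with
#'   columns \code{snapshot, residue_label, total}.
#' @param compound_id,receptor_state profile metadata.
#' @return an \code{interaction_profile}.
#' @export
build_profile <- function(rows, compound_id = "unknown",
                          receptor_state = "other") {
  stopifnot(is.data.frame(rows),
            all(c("snapshot", "residue_label", "total") %in% names(rows)))
  snaps <- split(rows, rows$snapshot)
  if (length(snaps) == 0L) stop("no snapshot rows supplied")
  ref <- sort(snaps[[1L]]$residue_label)
  for (s in snaps) {
    lab <- sort(s$residue_label)
    if (!identical(lab, ref)) {
      diff <- c(setdiff(lab, ref), setdiff(ref, lab))
      stop("inconsistent residue-label sets across snapshots; ",
           "symmetric difference: ", paste(unique(diff), collapse = ", "))
    }
  }
  means <- tapply(rows$total, rows$residue_label, mean)
  e <- as.numeric(means)
  names(e) <- names(means)
  new_interaction_profile(compound_id, receptor_state, e[order(names(e))],
                          length(snaps))
}

#' Select key residues of a profile
#'
#' A key residue interacts with the ligand more strongly (more negatively)
#' than -0.1 kcal/mol; the boundary value -0.1 is included.  Labels are
#' returned in sorted order.
#'
#' @param profile an \code{interaction_profile}.
#' @param threshold key-residue energy threshold (kcal/mol).
#' @return character vector of residue labels.
#' @export
#' @examples
#' p <- interaction_profile(c(F183 = -2.16, X1 = -0.05))
#' select_key_residues(p)  # "F183"
select_key_residues <- function(profile, threshold = -0.1) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (length(profile$energies) == 0L) stop("profile is empty")
  sort(names(profile$energies)[profile$energies <= threshold])
}

#' Build a signature profile from reference ligands
#'
#' Key residues of each reference profile are combined (union by default,
#' intersection by flag); per residue, the mean and sample standard
#' deviation across references are computed, a residue missing from a
#' reference contributing 0 kcal/mol.  Optionally residues whose sd exceeds
#' \code{sd_cap} are dropped (the "small deviations" rule; default keeps
#' all).
#'
#' @param reference_profiles list of \code{interaction_profile}, all with
#'   the same \code{receptor_state}.
#' @param residue_rule \code{"union"} or \code{"intersection"}.
#' @param sd_cap numeric sd cap in kcal/mol, or \code{NULL} (no cap).
#' @param key_threshold key-residue threshold (kcal/mol).
#' @return a \code{signature_profile}: list with \code{receptor_state},
#'   \code{residues}, \code{mean_energy}, \code{sd_energy},
#'   \code{reference_ids}.
#' @export
build_signature <- function(reference_profiles,
                            residue_rule = c("union", "intersection"),
                            sd_cap = NULL, key_threshold = -0.1) {
  residue_rule <- match.arg(residue_rule)
  stopifnot(length(reference_profiles) >= 1L,
            all(vapply(reference_profiles, inherits, logical(1L),
                       "interaction_profile")))
  states <- unique(vapply(reference_profiles, `[[`, character(1L),
                          "receptor_state"))
  if (length(states) != 1L)
    stop("reference profiles mix receptor states: ",
         paste(states, collapse = ", "))
  keys <- lapply(reference_profiles, select_key_residues,
                 threshold = key_threshold)
  residues <- Reduce(if (residue_rule == "union") union else intersect, keys)
  residues <- sort(residues)
  if (length(residues) == 0L)
    stop("signature residue set is empty under rule '", residue_rule, "'")
  mat <- vapply(reference_profiles, function(p) {
    v <- p$energies[residues]
    v[is.na(v)] <- 0
    unname(v)
  }, numeric(length(residues)))
  mat <- matrix(mat, nrow = length(residues))
  mean_e <- rowMeans(mat)
  sd_e <- if (ncol(mat) > 1L) apply(mat, 1L, stats::sd)
          else numeric(length(residues))
  if (!is.null(sd_cap)) {
    keep <- sd_e <= sd_cap
    if (!any(keep))
      stop("signature residue set is empty after sd_cap = ", sd_cap)
    residues <- residues[keep]; mean_e <- mean_e[keep]; sd_e <- sd_e[keep]
  }
  structure(list(receptor_state = states,
                 residues = residues,
                 mean_energy = stats::setNames(mean_e, residues),
                 sd_energy = stats::setNames(sd_e, residues),
                 reference_ids = vapply(reference_profiles, `[[`,
                                        character(1L), "compound_id")),
            class = "signature_profile")
}

#' @export
print.signature_profile <- function(x, ...) {
  cat("Signature profile (", x$receptor_state, "):",
      length(x$residues), "residues, references:",
      paste(x$reference_ids, collapse = ", "), "\n")
  print(round(rbind(mean = x$mean_energy, sd = x$sd_energy), 4))
  invisible(x)
}

#' Write / read a signature profile table
#'
#' TSV with columns \code{residue_label, mean_energy, sd_energy}; receptor
#' state and reference ids travel in \code{#}-comment header lines.
#'
#' @param signature a \code{signature_profile}.
#' @param path file path.
#' @return \code{write_signature}: invisibly, \code{path};
#'   \code{read_signature}: a \code{signature_profile}.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "signature_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# receptor_state\t", signature$receptor_state),
    paste0("# reference_ids\t",
           paste(signature$reference_ids, collapse = ",")),
    "residue_label\tmean_energy\tsd_energy"), con)
  writeLines(sprintf("%s\t%.12g\t%.12g", signature$residues,
                     unname(signature$mean_energy),
                     unname(signature$sd_energy)), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  state <- "other"; refs <- character(0)
  for (h in hdr) {
    parts <- strsplit(sub("^# ", "", h), "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[1L] == "receptor_state")
      state <- parts[2L]
    if (length(parts) == 2L && parts[1L] == "reference_ids")
      refs <- strsplit(parts[2L], ",", fixed = TRUE)[[1L]]
  }
  df <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                          stringsAsFactors = FALSE)
  if (anyDuplicated(df$residue_label))
    stop("duplicate residue labels in signature file")
  ord <- order(df$residue_label)
  df <- df[ord, , drop = FALSE]
  structure(list(receptor_state = state,
                 residues = df$residue_label,
                 mean_energy = stats::setNames(df$mean_energy,
                                               df$residue_label),
                 sd_energy = stats::setNames(df$sd_energy,
                                             df$residue_label),
                 reference_ids = refs),
            class = "signature_profile")
}

#' Profile-signature similarity scores
#'
#' Evaluated on the signature's residue list; a residue absent from the
#' query contributes 0 kcal/mol.  Returns Pearson correlation \code{r} and
#' \code{r2 = r^2}, signed mean error \code{ase = mean(query - signature)},
#' \code{aue = mean(|query - signature|)}, and
#' \code{rmse = sqrt(mean((query - signature)^2))}.  If either vector has
#' zero variance the correlation is undefined: \code{r}/\code{r2} are
#' \code{NA} and \code{r_defined} is \code{FALSE} (treated as failing the
#' correlation gate downstream).
#'
#' @param query an \code{interaction_profile}.
#' @param signature a \code{signature_profile} with >= 3 residues.
#' @return a \code{similarity_scores} list: \code{r, r2, rmse, aue, ase,
#'   n_residues, r_defined}.
#' @export
similarity <- function(query, signature) {
  stopifnot(inherits(query, "interaction_profile"),
            inherits(signature, "signature_profile"))
  res <- signature$residues
  if (length(res) < 3L)
    stop("signature must contain at least 3 residues")
  q <- query$energies[res]
  q[is.na(q)] <- 0
  q <- unname(q)
  s <- unname(signature$mean_energy[res])
  diff <- q - s
  ok <- stats::sd(q) > 0 && stats::sd(s) > 0
  r <- if (ok) stats::cor(q, s) else NA_real_
  structure(list(r = r, r2 = if (ok) r * r else NA_real_,
                 rmse = sqrt(mean(diff^2)),
                 aue = mean(abs(diff)),
                 ase = mean(diff),
                 n_residues = length(res),
                 r_defined = ok),
            class = "similarity_scores")
}

#' @export
print.similarity_scores <- function(x, ...) {
  cat(sprintf(
    "Similarity over %d residues: R = %s  R2 = %s  RMSE = %.4f  AUE = %.4f  ASE = %.4f\n",
    x$n_residues,
    if (x$r_defined) sprintf("%.4f", x$r) else "undefined",
    if (x$r_defined) sprintf("%.4f", x$r2) else "undefined",
    x$rmse, x$aue, x$ase))
  invisible(x)
}
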