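#' @title Conformational-ensemble and profile I/O
#' @description Readers and writers for multi-model PDB ensembles, per-atom
#'   force-field parameter tables, residue-label maps, and interaction-profile
#'   tables, with cross-file consistency validation.
#' @name complex_io
NULL

# ---- multi-model PDB -------------------------------------------------------

# Fixed-column parse of ATOM/HETATM records; MODEL/ENDMDL delimit snapshots.
# A PDB without MODEL records is treated as a single snapshot.
parse_pdb_models <- function(lines) {
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grepl("^MODEL", lines)
  model_id <- cumsum(model_starts)
  if (!any(model_starts)) model_id <- rep.int(1L, length(lines))
  atom_lines <- lines[is_atom]
  atom_model <- model_id[is_atom]
  if (length(atom_lines) == 0L)
    stop("no ATOM/HETATM records found in PDB input")
  if (any(atom_model == 0L))
    stop("ATOM records found before the first MODEL record")
  df <- data.frame(
    model   = atom_model,
    atom_id = as.integer(substr(atom_lines, 7L, 11L)),
    name    = trimws(substr(atom_lines, 13L, 16L)),
    resname = trimws(substr(atom_lines, 18L, 21L)),
    chain   = trimws(substr(atom_lines, 22L, 22L)),
    resid   = as.integer(substr(atom_lines, 23L, 26L)),
    x = as.numeric(substr(atom_lines, 31L, 38L)),
    y = as.numeric(substr(atom_lines, 39L, 46L)),
    z = as.numeric(substr(atom_lines, 47L, 54L)),
    stringsAsFactors = FALSE)
  if (anyNA(df$x) || anyNA(df$y) || anyNA(df$z))
    stop("malformed coordinate field in PDB input")
  df
}

# Check that every model carries the same atoms in the same order; returns
# the atom template (model 1) and a list of coordinate matrices.
split_models <- function(df) {
  models <- split(df, df$model)
  tmpl <- models[[1L]]
  key <- function(m) paste(m$atom_id, m$name, m$chain, m$resid, m$resname)
  k1 <- key(tmpl)
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (nrow(m) != nrow(tmpl))
      stop("snapshot ", i, " has ", nrow(m), " atoms; snapshot 1 has ",
           nrow(tmpl))
    if (!identical(key(m), k1))
      stop("snapshot ", i, " differs from snapshot 1 in atom ordering")
  }
  coords <- lapply(models, function(m) {
    mt <- cbind(m$x, m$y, m$z)
    dimnames(mt) <- NULL
    mt
  })
  names(coords) <- NULL
  list(atoms = tmpl[, c("atom_id", "name", "chain", "resid", "resname")],
       coords = coords)
}

# ---- parameter and label tables --------------------------------------------

param_cols <- c("atom_id", "charge", "lj_rmin_half", "lj_epsilon",
                "gb_radius", "gb_screen", "atom_type")

read_params_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  missing <- setdiff(param_cols, names(df))
  if (length(missing))
    stop("parameter table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$atom_id))
    stop("duplicate atom_id in parameter table: ",
         paste(unique(df$atom_id[duplicated(df$atom_id)]), collapse = ", "))
  if (any(df$lj_rmin_half <= 0)) stop("lj_rmin_half must be > 0")
  if (any(df$lj_epsilon < 0)) stop("lj_epsilon must be >= 0")
  if (any(df$gb_radius <= 0)) stop("gb_radius must be > 0")
  if (any(df$gb_screen <= 0 | df$gb_screen > 1.5))
    stop("gb_screen must lie in (0, 1.5]")
  df[param_cols]
}

read_labels_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("chain", "resid", "resname", "label", "segment")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("labels table ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$segment), c("receptor", "ligand"))
  if (length(bad))
    stop("unknown segment value(s) in labels table: ",
         paste(bad, collapse = ", "))
  lab <- df$label[df$segment == "receptor"]
  if (anyDuplicated(lab))
    stop("duplicate receptor residue labels: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  df$chain <- as.character(df$chain)
  df
}

# ---- ensemble assembly -----------------------------------------------------

#' Read a receptor-ligand conformational ensemble
#'
#' Loads a multi-model PDB file (one \code{MODEL} block per snapshot), a
#' per-atom force-field parameter table, and a residue-label map, and binds
#' them into a validated ensemble.  The ligand is identified by the residue
#' name(s) declared with \code{segment = "ligand"} in the labels file;
#' receptor residues missing from the map get a default
#' \code{RESNAME+RESID} label.
#'
#' @param pdb_path path to a multi-model PDB file.
#' @param params_path path to a TSV with columns \code{atom_id, charge,
#'   lj_rmin_half, lj_epsilon, gb_radius, gb_screen, atom_type}.
#' @param labels_path path to a TSV with columns \code{chain, resid, resname,
#'   label, segment} (\code{segment} is \code{receptor} or \code{ligand}).
#' @return A \code{conformation_ensemble}: list with \code{atoms}
#'   (data.frame incl. \code{segment} and \code{residue_label}),
#'   \code{coords} (list of n_atoms x 3 matrices, one per snapshot), and
#'   \code{params} (data.frame aligned with \code{atoms}).
#' @export
read_ensemble <- function(pdb_path, params_path, labels_path) {
  parsed <- split_models(parse_pdb_models(readLines(pdb_path)))
  params <- read_params_table(params_path)
  labels <- read_labels_table(labels_path)
  build_ensemble(parsed$atoms, parsed$coords, params, labels)
}

# Core assembly shared by the file reader and the synthetic generator.
build_ensemble <- function(atoms, coords, params, labels) {
  if (anyDuplicated(atoms$atom_id))
    stop("duplicate atom_id within a snapshot: ",
         paste(unique(atoms$atom_id[duplicated(atoms$atom_id)]),
               collapse = ", "))
  idx <- match(atoms$atom_id, params$atom_id)
  if (anyNA(idx)) {
    bad <- atoms$atom_id[is.na(idx)]
    stop("no parameter row for atom id(s): ", paste(bad, collapse = ", "))
  }
  params <- params[idx, , drop = FALSE]
  rownames(params) <- NULL

  lig_resnames <- unique(labels$resname[labels$segment == "ligand"])
  if (length(lig_resnames) == 0L)
    stop("labels table declares no ligand residue (segment == 'ligand')")
  atoms$segment <- ifelse(atoms$resname %in% lig_resnames,
                          "ligand", "receptor")
  if (!any(atoms$segment == "ligand"))
    stop("no atoms match the declared ligand residue name(s): ",
         paste(lig_resnames, collapse = ", "))

  rec_map <- labels[labels$segment == "receptor", , drop = FALSE]
  mkey <- paste(rec_map$chain, rec_map$resid)
  akey <- paste(atoms$chain, atoms$resid)
  hit <- match(akey, mkey)
  atoms$residue_label <- ifelse(
    atoms$segment == "ligand", "<ligand>",
    ifelse(!is.na(hit), rec_map$label[hit],
           paste0(atoms$resname, atoms$resid)))

  for (i in seq_along(coords))
    if (!all(is.finite(coords[[i]])))
      stop("non-finite coordinates in snapshot ", i)

  structure(list(atoms = atoms, coords = coords, params = params,
                 labels = labels),
            class = "conformation_ensemble")
}

#' @export
print.conformation_ensemble <- function(x, ...) {
  nl <- sum(x$atoms$segment == "ligand")
  cat("Conformational ensemble:", length(x$coords), "snapshot(s),",
      nrow(x$atoms), "atoms (", nl, "ligand ),",
      length(unique(x$atoms$residue_label[x$atoms$segment == "receptor"])),
      "receptor residues\n")
  invisible(x)
}

#' Number of snapshots in an ensemble
#' @param ensemble a \code{conformation_ensemble}.
#' @return integer snapshot count.
#' @export
n_snapshots <- function(ensemble) length(ensemble$coords)

#' Evenly subsample the snapshots of an ensemble
#'
#' Keeps frames \code{1, 1+stride, 1+2*stride, ...}; with \code{n} snapshots
#' this returns exactly \code{ceiling(n/stride)} frames in their original
#' order (the "evenly collected" convention).
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param stride positive integer stride.
#' @return the subsampled \code{conformation_ensemble}.
#' @export
subsample_ensemble <- function(ensemble, stride) {
  stride <- as.integer(stride)
  n <- length(ensemble$coords)
  if (stride < 1L) stop("stride must be >= 1")
  if (stride > n) stop("stride (", stride, ") exceeds snapshot count (", n, ")")
  ensemble$coords <- ensemble$coords[seq(1L, n, by = stride)]
  ensemble
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param ensemble a \code{conformation_ensemble}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  a <- ensemble$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble$coords)) {
    xyz <- ensemble$coords[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
      a$atom_id, a$name, a$resname, a$chain, a$resid,
      xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write per-atom force-field parameters / residue labels as TSV
#' @param params parameter data.frame (see \code{\link{read_ensemble}}).
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_params_table <- function(params, path) {
  utils::write.table(params[param_cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_table
#' @param labels labels data.frame with columns \code{chain, resid, resname,
#'   label, segment}.
#' @export
write_labels_table <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- profile I/O -----------------------------------------------------------

#' Write / read an interaction profile table
#'
#' Profiles are stored as TSV with columns \code{residue_label, energy}
#' (kcal/mol), rows ordered by label, energies printed with 12 significant
#' digits so that write-then-read is lossless well past 6 decimals.
#' Compound id, receptor state and snapshot count travel in \code{#}-comment
#' header lines.
#'
#' @param profile an \code{interaction_profile} (see
#'   \code{\link{build_profile}}).
#' @param path file path.
#' @return \code{write_profile}: invisibly, \code{path};
#'   \code{read_profile}: an \code{interaction_profile}.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "interaction_profile"))
  if (length(profile$energies) == 0L)
    stop("cannot write an empty profile")
  ord <- order(names(profile$energies))
  e <- profile$energies[ord]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# compound_id\t", profile$compound_id),
    paste0("# receptor_state\t", profile$receptor_state),
    paste0("# n_snapshots\t", profile$n_snapshots),
    "residue_label\tenergy"), con)
  writeLines(sprintf("%s\t%.12g", names(e), unname(e)), con)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  meta <- list(compound_id = "unknown", receptor_state = "other",
               n_snapshots = 1L)
  for (h in hdr) {
    parts <- strsplit(sub("^# ", "", h), "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 2L && parts[1L] %in% names(meta))
      meta[[parts[1L]]] <- parts[2L]
  }
  df <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                          stringsAsFactors = FALSE)
  if (!all(c("residue_label", "energy") %in% names(df)))
    stop("profile table must have columns residue_label, energy")
  if (anyDuplicated(df$residue_label))
    stop("duplicate residue labels in profile: ",
         paste(unique(df$residue_label[duplicated(df$residue_label)]),
               collapse = ", "))
  e <- df$energy
  names(e) <- df$residue_label
  new_interaction_profile(meta$compound_id, meta$receptor_state,
                          e[order(names(e))],
                          as.integer(meta$n_snapshots))
}
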