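#' @title Agonist / non-agonist function classification and evaluation
#' @description Applies the screening decision flow to per-compound
#'   evidence — docking pass, MD stability, profile correlation against the
#'   active-state agonist signature, and binding energy — and evaluates
#'   predictions against assay outcomes.
#' @name function_classifier
NULL

#' Per-compound evidence record
#'
#' @param compound_id compound identifier.
#' @param docking_pass logical: decent docking score obtained.
#' @param md_stable logical: ligand stayed bound through the MD run.
#' @param r_active Pearson R of the compound's LRIP against the active-state
#'   agonist signature, in [-1, 1] (NA if the correlation was undefined).
#' @param de binding energy dE, kcal/mol.
#' @param r_inactive optional R against the inactive-state antagonist
#'   signature; used only to split non-agonists into antagonist candidates
#'   vs undetermined.
#' @param receptor \code{"CB1"} or \code{"CB2"}.
#' @return a \code{compound_evidence} object.
#' @export
compound_evidence <- function(compound_id, docking_pass, md_stable,
                              r_active, de, r_inactive = NA_real_,
                              receptor = "CB2") {
  for (r in c(r_active, r_inactive))
    if (!is.na(r) && (r < -1 || r > 1))
      stop("correlation out of [-1, 1]: ", r)
  structure(list(compound_id = compound_id,
                 docking_pass = isTRUE(docking_pass),
                 md_stable = isTRUE(md_stable),
                 r_active = r_active, r_inactive = r_inactive,
                 de = de, receptor = receptor),
            class = "compound_evidence")
}

#' Classify a compound as agonist or non-agonist
#'
#' Gates are applied in screening order: docking pass, MD stability,
#' \code{r_active > r_threshold} (strict), \code{de < de_threshold}
#' (strict).  All four pass -> \code{AGONIST}; otherwise
#' \code{NON_AGONIST}, subclassified \code{ANTAGONIST_CANDIDATE} when an
#' inactive-state correlation is available and exceeds the threshold, else
#' \code{UNDETERMINED}.  An undefined (\code{NA}) \code{r_active} fails the
#' correlation gate.
#'
#' @param evidence a \code{compound_evidence} object.
#' @param r_threshold correlation gate (default 0.84, i.e. R^2 > 0.7).
#' @param de_threshold binding-energy gate, kcal/mol (default -10).
#' @return a \code{function_call}: \code{compound_id, predicted,
#'   non_agonist_subclass, rationale}.
#' @export
#' @examples
#' ev <- compound_evidence("cmpd38", TRUE, TRUE, r_active = sqrt(0.77),
#'                         de = -12)
#' classify(ev)$predicted  # "AGONIST"
classify <- function(evidence, r_threshold = 0.84, de_threshold = -10) {
  stopifnot(inherits(evidence, "compound_evidence"))
  if (is.null(evidence$r_active))
    stop("evidence lacks r_active for compound ", evidence$compound_id)
  gates <- c(
    docking = evidence$docking_pass,
    md_stability = evidence$md_stable,
    r_active = !is.na(evidence$r_active) &&
      evidence$r_active > r_threshold,
    binding_energy = is.finite(evidence$de) && evidence$de < de_threshold)
  rationale <- sprintf("%s:%s", names(gates),
                       ifelse(gates, "pass", "fail"))
  predicted <- if (all(gates)) "AGONIST" else "NON_AGONIST"
  subclass <- if (predicted == "AGONIST") NA_character_
  else if (!is.na(evidence$r_inactive) &&
           evidence$r_inactive > r_threshold) "ANTAGONIST_CANDIDATE"
  else "UNDETERMINED"
  structure(list(compound_id = evidence$compound_id,
                 predicted = predicted,
                 non_agonist_subclass = subclass,
                 rationale = rationale),
            class = "function_call")
}

#' @export
print.function_call <- function(x, ...) {
  cat(x$compound_id, "->", x$predicted,
      if (!is.na(x$non_agonist_subclass))
        paste0("(", x$non_agonist_subclass, ")") else "",
      "\n  gates:", paste(x$rationale, collapse = "  "), "\n")
  invisible(x)
}

#' Classify a table of compounds
#'
#' @param df data.frame with columns \code{compound_id, docking_pass,
#'   md_stable, r_active, de} and optionally \code{r_inactive, receptor}.
#' @inheritParams classify
#' @return data.frame with \code{compound_id, predicted,
#'   non_agonist_subclass}.
#' @export
classify_table <- function(df, r_threshold = 0.84, de_threshold = -10) {
  calls <- lapply(seq_len(nrow(df)), function(i) {
    ev <- compound_evidence(
      df$compound_id[i], df$docking_pass[i], df$md_stable[i],
      df$r_active[i], df$de[i],
      if ("r_inactive" %in% names(df)) df$r_inactive[i] else NA_real_,
      if ("receptor" %in% names(df)) df$receptor[i] else "CB2")
    classify(ev, r_threshold, de_threshold)
  })
  data.frame(
    compound_id = vapply(calls, `[[`, character(1L), "compound_id"),
    predicted = vapply(calls, `[[`, character(1L), "predicted"),
    non_agonist_subclass = vapply(calls, `[[`, character(1L),
                                  "non_agonist_subclass"),
    stringsAsFactors = FALSE)
}

#' Evaluate predictions against assay outcomes
#'
#' A prediction is correct when (AGONIST, AGONIST), (NON_AGONIST,
#' ANTAGONIST), or (NON_AGONIST, INACTIVE).  Percentages are rounded to the
#' nearest integer.
#'
#' @param calls data.frame with columns \code{compound_id, predicted}
#'   (values \code{AGONIST} / \code{NON_AGONIST}).
#' @param outcomes data.frame with columns \code{compound_id, truth}
#'   (values \code{AGONIST} / \code{ANTAGONIST} / \code{INACTIVE}).
#' @return an \code{evaluation_summary}: \code{n_total, n_pred_agonist,
#'   n_pred_non_agonist, n_correct_agonist, n_correct_antagonist,
#'   n_correct_inactive, overall_accuracy_pct, agonist_success_pct}.
#' @export
evaluate <- function(calls, outcomes) {
  stopifnot(all(c("compound_id", "predicted") %in% names(calls)),
            all(c("compound_id", "truth") %in% names(outcomes)))
  only_c <- setdiff(calls$compound_id, outcomes$compound_id)
  only_o <- setdiff(outcomes$compound_id, calls$compound_id)
  if (length(only_c) || length(only_o))
    stop("unmatched compound ids: ",
         paste(c(only_c, only_o), collapse = ", "))
  if (anyDuplicated(calls$compound_id) || anyDuplicated(outcomes$compound_id))
    stop("duplicate compound ids")
  truth <- outcomes$truth[match(calls$compound_id, outcomes$compound_id)]
  pred <- calls$predicted
  stopifnot(all(pred %in% c("AGONIST", "NON_AGONIST")),
            all(truth %in% c("AGONIST", "ANTAGONIST", "INACTIVE")))
  n_ca <- sum(pred == "AGONIST" & truth == "AGONIST")
  n_cb <- sum(pred == "NON_AGONIST" & truth == "ANTAGONIST")
  n_ci <- sum(pred == "NON_AGONIST" & truth == "INACTIVE")
  n_pa <- sum(pred == "AGONIST")
  n <- length(pred)
  structure(list(
    n_total = n,
    n_pred_agonist = n_pa,
    n_pred_non_agonist = n - n_pa,
    n_correct_agonist = n_ca,
    n_correct_antagonist = n_cb,
    n_correct_inactive = n_ci,
    overall_accuracy_pct = round(100 * (n_ca + n_cb + n_ci) / n),
    agonist_success_pct = if (n_pa > 0) round(100 * n_ca / n_pa)
                          else NA_real_),
    class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Evaluation over %d compounds\n",
    "  predicted agonists:      %d (of which %d confirmed agonists; success %s%%)\n",
    "  predicted non-agonists:  %d (%d confirmed antagonists, %d confirmed inactive)\n",
    "  overall accuracy:        %d%%\n"),
    x$n_total, x$n_pred_agonist, x$n_correct_agonist,
    as.character(x$agonist_success_pct),
    x$n_pred_non_agonist, x$n_correct_antagonist, x$n_correct_inactive,
    x$overall_accuracy_pct))
  invisible(x)
}

#' Combine CB2 and CB1 calls into a selectivity verdict
#'
#' @param cb2_call,cb1_call \code{function_call} objects (or their
#'   \code{predicted} strings).
#' @return \code{"CB2_SELECTIVE_AGONIST"}, \code{"NONSELECTIVE_AGONIST"},
#'   or \code{"OTHER"}.
#' @export
combine_selectivity <- function(cb2_call, cb1_call) {
  pred <- function(x) if (inherits(x, "function_call")) x$predicted
                      else as.character(x)
  p2 <- pred(cb2_call); p1 <- pred(cb1_call)
  stopifnot(p2 %in% c("AGONIST", "NON_AGONIST"),
            p1 %in% c("AGONIST", "NON_AGONIST"))
  if (p2 == "AGONIST" && p1 == "NON_AGONIST") "CB2_SELECTIVE_AGONIST"
  else if (p2 == "AGONIST" && p1 == "AGONIST") "NONSELECTIVE_AGONIST"
  else "OTHER"
}
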