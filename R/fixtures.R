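#' Packaged in-text fixtures
#'
#' Accessor for the small plain-text tables shipped with the package:
#' \describe{
#'   \item{\code{cmpd6_lrip}}{LRIP hotspots of the potent agonist compound
#'     6 on active CB2 (F183 -2.16, W5.43 -1.35, I186 -0.50 kcal/mol; the
#'     additional hotspots F2.61 and F2.64 are listed with no energy value,
#'     flagged \code{quantified = FALSE}).}
#'   \item{\code{cmpd39_lrip}}{LRIP hotspots of the potent antagonist
#'     compound 39 on inactive CB2 (L17 -1.24, W6.48 -1.31, V6.51 -0.78,
#'     C7.42 -1.52, F183 -1.12 kcal/mol).}
#'   \item{\code{reference_sets}}{the four reference-ligand lists used to
#'     build the CB1/CB2 active/inactive signatures.}
#'   \item{\code{evaluation_42}}{42 (predicted, truth) label pairs
#'     consistent with the published category counts: 26 predicted
#'     agonists of which 16 confirmed, and 16 predicted non-agonists of
#'     which 3 confirmed antagonists and 10 confirmed inactive.  Only a
#'     handful of compound identities are recoverable from the main text;
#'     the remaining rows carry synthetic ids and \code{provenance =
#'     "synthetic"}.}
#'   \item{\code{toy_complex}}{paths to the packaged seed-1 toy-complex
#'     files (PDB + parameters + labels).}
#' }
#'
#' @param name one of \code{"cmpd6_lrip"}, \code{"cmpd39_lrip"},
#'   \code{"reference_sets"}, \code{"evaluation_42"}, \code{"toy_complex"}.
#' @return a data.frame (or, for \code{toy_complex}, a named character
#'   vector of file paths).
#' @export
#' @examples
#' paper_fixture("cmpd6_lrip")
paper_fixture <- function(name) {
  valid <- c("cmpd6_lrip", "cmpd39_lrip", "reference_sets",
             "evaluation_42", "toy_complex")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown fixture name; expected one of: ",
         paste(valid, collapse = ", "))
  if (name == "toy_complex") {
    d <- system.file("extdata", "toy_complex", package = "lripscreen",
                     mustWork = TRUE)
    return(c(pdb = file.path(d, "complex.pdb"),
             params = file.path(d, "params.tsv"),
             labels = file.path(d, "labels.tsv")))
  }
  path <- system.file("extdata", paste0(name, ".tsv"),
                      package = "lripscreen", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (name == "evaluation_42" && nrow(df) != 42L)
    stop("corrupt evaluation_42 fixture: expected 42 rows, got ", nrow(df))
  df
}

#' Fixture LRIP as an interaction profile
#'
#' Convenience wrapper turning a packaged LRIP fixture into an
#' \code{\link{interaction_profile}} (unquantified hotspots dropped).
#'
#' @param name \code{"cmpd6_lrip"} or \code{"cmpd39_lrip"}.
#' @return an \code{interaction_profile}.
#' @export
fixture_profile <- function(name) {
  stopifnot(name %in% c("cmpd6_lrip", "cmpd39_lrip"))
  df <- paper_fixture(name)
  df <- df[df$quantified, , drop = FALSE]
  e <- df$energy
  names(e) <- df$residue_label
  interaction_profile(
    e,
    compound_id = sub("_lrip$", "", name),
    receptor_state = if (name == "cmpd6_lrip") "CB2_active"
                     else "CB2_inactive")
}
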