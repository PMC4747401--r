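#' Clinical DEG list of one chemotherapy regimen
#'
#' Bundles a regimen's drug composition with the directional DEG set
#' derived from its responder/non-responder comparison. The direction
#' convention for clinical lists is that `"up"` means higher in
#' non-responders (the resistant phenotype), matching the cell-line
#' convention where `"up"` means higher in the resistant line.
#'
#' @param label Regimen name (e.g. `"mFOLFOX6"`).
#' @param drugs Character vector of drug names in the regimen (non-empty).
#' @param deg A [directional_gene_set()].
#' @param provenance Free-text note on the datasets/thresholds used.
#' @return An object of class `"regimen_deg"`.
#' @export
regimen_deg <- function(label, drugs, deg, provenance = "") {
  drugs <- unique(as.character(drugs))
  if (!length(drugs)) stop("'drugs' must be non-empty")
  stopifnot(inherits(deg, "directional_gene_set"))
  structure(list(label = label, drugs = drugs, deg = deg,
                 provenance = provenance), class = "regimen_deg")
}

#' Attribute resistance genes to shared drugs by regimen intersection
#'
#' If two (or more) regimens share one or several drugs and the drugs in
#' each combination act without antagonism, genes differentially expressed
#' between non-responders and responders in *every* regimen, with the same
#' direction throughout, are attributable to the shared drug(s). Genes
#' present in all lists but with conflicting directions are excluded and
#' reported separately.
#'
#' @param regimens List of at least two [regimen_deg()] objects whose drug
#'   sets have a non-empty intersection.
#' @return An object of class `"crg_set"`: a list with `shared_drugs`,
#'   `members` (a [directional_gene_set()]), `conflicts` (gene ids present
#'   everywhere but direction-inconsistent), and `support` (the
#'   contributing regimen labels).
#' @export
intersect_regimens <- function(regimens) {
  if (length(regimens) < 2) stop("need at least two regimens")
  lapply(regimens, function(r) stopifnot(inherits(r, "regimen_deg")))
  shared_drugs <- Reduce(intersect, lapply(regimens, `[[`, "drugs"))
  if (!length(shared_drugs))
    stop("regimens share no drug; the attribution is undefined")
  in_all <- Reduce(intersect, lapply(regimens, function(r) names(r$deg)))
  dirs <- vapply(regimens, function(r) unclass(r$deg)[in_all],
                 character(length(in_all)))
  if (length(in_all) == 1L) dirs <- matrix(dirs, nrow = 1)
  consistent <- if (length(in_all))
    apply(dirs, 1, function(d) length(unique(d)) == 1L) else logical(0)
  members <- in_all[consistent]
  first <- unclass(regimens[[1]]$deg)
  structure(list(
    shared_drugs = shared_drugs,
    members = directional_gene_set(
      stats::setNames(as.vector(first[members]), members),
      label = paste0("CRG_", paste(shared_drugs, collapse = "/"))),
    conflicts = in_all[!consistent],
    support = vapply(regimens, `[[`, "", "label")),
    class = "crg_set")
}

#' @export
print.crg_set <- function(x, ...) {
  cat(sprintf("crg_set for drug(s) %s: %d genes (%d direction conflicts excluded)\n",
              paste(x$shared_drugs, collapse = "/"), length(x$members),
              length(x$conflicts)))
  invisible(x)
}

#' Two-tier discovery/confirmation CRG selection
#'
#' Genes passing the FDR threshold in a discovery cohort that are
#' additionally confirmed — nominal p-value below `p_confirm` with the
#' same direction — in every confirmation cohort. With no confirmation
#' tables the discovery genes are returned flagged as unconfirmed.
#'
#' @param discovery A `"deg_table"` from [rank_product()].
#' @param confirmations List (possibly empty) of confirmation
#'   `"deg_table"`s.
#' @param fdr_discovery FDR threshold in the discovery cohort (default
#'   0.2).
#' @param p_confirm Nominal p threshold in each confirmation cohort
#'   (default 0.05).
#' @param label Label for the resulting set.
#' @return A `"crg_set"`-like list with `members`
#'   (a [directional_gene_set()]), `n_discovery`, and `confirmed`
#'   (`FALSE` when no confirmation cohorts were supplied).
#' @export
tiered_crg <- function(discovery, confirmations = list(),
                       fdr_discovery = 0.2, p_confirm = 0.05,
                       label = "CRG") {
  disc <- deg_filter(discovery, fdr_max = fdr_discovery, label = label)
  members <- names(disc)
  dirs <- unclass(disc)
  for (conf in confirmations) {
    idx <- match(members, conf$gene_id)
    ok <- !is.na(idx) & conf$p[idx] < p_confirm &
      conf$direction[idx] == dirs[members]
    members <- members[ok]
  }
  structure(list(
    members = directional_gene_set(
      stats::setNames(as.vector(dirs[members]), members), label),
    n_discovery = length(disc),
    confirmed = length(confirmations) > 0,
    fdr_discovery = fdr_discovery, p_confirm = p_confirm),
    class = "crg_set")
}

#' ID_clinical genes from a post-chemotherapy cohort
#'
#' DEGs between post-chemotherapy specimens of responders and
#' non-responders: the clinical analogue of the cell-line ID contrast,
#' since both groups are in the drug-exposed state and differ in their
#' response to it.
#'
#' @param post_chemo_table A `"deg_table"` from a post-chemotherapy
#'   responder/non-responder comparison.
#' @param fdr_max FDR threshold (default 0.1).
#' @return A [directional_gene_set()].
#' @export
id_clinical <- function(post_chemo_table, fdr_max = 0.1) {
  deg_filter(post_chemo_table, fdr_max = fdr_max, label = "ID_clinical")
}
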