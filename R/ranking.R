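#' Directional gene set
#'
#' The universal currency of the pipeline: a set of genes each labelled
#' with a deregulation direction (`"up"` or `"down"`). BD/IP/ID lists,
#' clinical DEG lists and CRG sets are all carried in this form.
#'
#' @param directions Named character vector; names are gene ids, values
#'   `"up"` or `"down"`.
#' @param label Optional label describing the set.
#' @return An object of class `"directional_gene_set"`.
#' @export
directional_gene_set <- function(directions, label = "") {
  directions <- unlist(directions)
  if (length(directions) && is.null(names(directions)))
    stop("'directions' must be named by gene id")
  if (anyDuplicated(names(directions)))
    stop("each gene may appear once")
  if (length(directions) && !all(directions %in% c("up", "down")))
    stop("directions must be 'up' or 'down'")
  structure(directions, label = label, class = "directional_gene_set")
}

#' @export
print.directional_gene_set <- function(x, ...) {
  cat(sprintf("directional_gene_set '%s': %d genes (%d up, %d down)\n",
              attr(x, "label"), length(x), sum(x == "up"),
              sum(x == "down")))
  invisible(x)
}

#' @export
as.data.frame.directional_gene_set <- function(x, ...) {
  data.frame(gene_id = names(x), direction = as.vector(unclass(x)),
             stringsAsFactors = FALSE)
}

#' Read/write a directional gene set as a two-column TSV
#'
#' @param file Path to a TSV with columns `gene_id` and `direction`.
#' @param label Label for the resulting set.
#' @return [read_gene_dirs()] returns a [directional_gene_set()];
#'   [write_gene_dirs()] returns its input invisibly.
#' @export
read_gene_dirs <- function(file, label = file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  directional_gene_set(stats::setNames(tab$direction, tab$gene_id), label)
}

#' @rdname read_gene_dirs
#' @param set A [directional_gene_set()].
#' @export
write_gene_dirs <- function(set, file) {
  utils::write.table(as.data.frame(set), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(set)
}

.group_means <- function(em, idx, epsilon = 1.0) {
  m <- rowMeans(em$values[, idx, drop = FALSE])
  m[m <= 0] <- epsilon
  m
}

.make_ranked <- function(gene_id, stat, magnitude, direction, method,
                         label_A, label_B) {
  ord <- order(-magnitude, gene_id)
  out <- data.frame(gene_id = gene_id[ord], stat = stat[ord],
                    magnitude = magnitude[ord], direction = direction[ord],
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  structure(out, method = method, group_A = label_A, group_B = label_B,
            class = c("ranked_genes", "data.frame"))
}

#' Fold-change gene ranking between two sample groups
#'
#' For each gene, the ratio of the group-A mean to the group-B mean of the
#' non-log expression values. Genes are ranked by the symmetric change
#' magnitude `max(FC, 1/FC)` so that the top of the list mixes up- and
#' down-regulated genes; ties break by gene id for determinism. A gene is
#' `"up"` when FC > 1, `"down"` when FC < 1, `"none"` when FC = 1.
#'
#' @param em A linear-scale [expression_matrix()] (a log2 matrix is
#'   delogged automatically).
#' @param group_A,group_B Sample selectors: column indices, sample ids, a
#'   logical vector, or a named list of annotation conditions as accepted
#'   by [samples_where()]. Group A is the resistant/treated member so that
#'   `"up"` means higher in the resistant or treated samples.
#' @param epsilon Floor applied to non-positive group means before the
#'   ratio (default 1). With `epsilon = 0` a zero denominator is an error
#'   naming the offending gene.
#'
#' @return A `"ranked_genes"` data frame with columns `gene_id`, `stat`,
#'   `magnitude`, `direction`, `rank`.
#' @export
compute_fc <- function(em, group_A, group_B, epsilon = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "log2") em <- suppressWarnings(delog(em))
  ia <- .resolve_group(em, group_A, "group_A")
  ib <- .resolve_group(em, group_B, "group_B")
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  ma <- .group_means(em, ia, epsilon)
  mb <- .group_means(em, ib, epsilon)
  if (any(mb == 0))
    stop("zero denominator for gene(s): ",
         paste(utils::head(names(mb)[mb == 0], 5), collapse = ", "))
  fc <- ma / mb
  dir <- ifelse(fc > 1, "up", ifelse(fc < 1, "down", "none"))
  .make_ranked(rownames(em$values), fc, pmax(fc, 1 / fc), dir, "FC",
               deparse(substitute(group_A)), deparse(substitute(group_B)))
}

#' Average-difference gene ranking between two sample groups
#'
#' For each gene, the difference of the group-A and group-B means of the
#' non-log expression values, ranked by `|AD|`. A gene is `"up"` when
#' AD > 0 and `"down"` when AD < 0. Unlike fold change, the average
#' difference favours genes expressed at high absolute levels even when
#' their ratios are modest.
#'
#' @inheritParams compute_fc
#' @return A `"ranked_genes"` data frame (see [compute_fc()]).
#' @export
compute_ad <- function(em, group_A, group_B, epsilon = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "log2") em <- suppressWarnings(delog(em))
  ia <- .resolve_group(em, group_A, "group_A")
  ib <- .resolve_group(em, group_B, "group_B")
  if (!length(ia) || !length(ib)) stop("both groups must be non-empty")
  ad <- .group_means(em, ia, epsilon) - .group_means(em, ib, epsilon)
  dir <- ifelse(ad > 0, "up", ifelse(ad < 0, "down", "none"))
  .make_ranked(rownames(em$values), ad, abs(ad), dir, "AD",
               deparse(substitute(group_A)), deparse(substitute(group_B)))
}

#' Top-N directional genes from a ranked list
#'
#' Takes the `n` genes with the largest change magnitude (symmetric FC
#' magnitude or |AD|); genes with no direction are excluded. With
#' `signed = TRUE` the list is instead ordered by the signed statistic and
#' the top `n` (most up-regulated) genes are taken.
#'
#' @param ranked A `"ranked_genes"` data frame from [compute_fc()] or
#'   [compute_ad()].
#' @param n Number of genes to select; must not exceed the number of
#'   directional genes.
#' @param signed Rank by the signed statistic instead of the magnitude.
#'
#' @return A [directional_gene_set()].
#' @export
top_n <- function(ranked, n, signed = FALSE) {
  stopifnot(inherits(ranked, "ranked_genes"), n >= 1)
  keep <- ranked[ranked$direction != "none", , drop = FALSE]
  if (n > nrow(keep))
    stop(sprintf("n = %d exceeds the %d directional genes available",
                 n, nrow(keep)))
  if (signed) keep <- keep[order(-keep$stat, keep$gene_id), , drop = FALSE]
  sel <- keep[seq_len(n), ]
  directional_gene_set(stats::setNames(sel$direction, sel$gene_id),
                       label = sprintf("top%d_%s", n, attr(ranked, "method")))
}

#' BD / IP / ID gene lists from a cell-line experiment
#'
#' The three gene classes of drug-induced resistance designs:
#' \describe{
#'   \item{BD}{basally deregulated — untreated resistant vs untreated
#'     parental cells.}
#'   \item{IP}{inducible in parental — drug-treated parental at
#'     `time_h` vs untreated parental cells.}
#'   \item{ID}{inducible difference — drug-treated resistant vs
#'     drug-treated parental cells at the same `time_h`.}
#' }
#' Group A is always the resistant/treated member, so `"up"` means higher
#' in the resistant (or treated) samples.
#'
#' @param em An [expression_matrix()] of the cell-line experiment.
#' @param design `"BD"`, `"IP"` or `"ID"`.
#' @param drug Drug name for the treated conditions (IP/ID).
#' @param time_h Treatment time in hours (IP/ID).
#' @param method Ranking statistic, `"FC"` or `"AD"`.
#' @param n Size of the top list (default 3000).
#' @param signed Passed to [top_n()].
#'
#' @return A [directional_gene_set()] labelled with the design.
#' @export
define_gene_class <- function(em, design = c("BD", "IP", "ID"), drug = NULL,
                              time_h = NULL, method = c("FC", "AD"),
                              n = 3000, signed = FALSE) {
  design <- match.arg(design)
  method <- match.arg(method)
  if (design %in% c("IP", "ID") && (is.null(drug) || is.null(time_h)))
    stop(design, " requires 'drug' and 'time_h'")
  groups <- switch(design,
    BD = list(A = list(resistance_status = "resistant", drug = "none"),
              B = list(resistance_status = "parental", drug = "none")),
    IP = list(A = list(resistance_status = "parental", drug = drug,
                       treatment_time_h = time_h),
              B = list(resistance_status = "parental", drug = "none")),
    ID = list(A = list(resistance_status = "resistant", drug = drug,
                       treatment_time_h = time_h),
              B = list(resistance_status = "parental", drug = drug,
                       treatment_time_h = time_h)))
  ia <- do.call(samples_where, c(list(em), groups$A))
  ib <- do.call(samples_where, c(list(em), groups$B))
  if (!length(ia) || !length(ib))
    stop(sprintf(
      "%s design needs samples with %s (A) and %s (B)", design,
      paste(names(groups$A), unlist(groups$A), sep = "=", collapse = ","),
      paste(names(groups$B), unlist(groups$B), sep = "=", collapse = ",")))
  ranked <- if (method == "FC") compute_fc(em, ia, ib) else
    compute_ad(em, ia, ib)
  out <- top_n(ranked, n, signed = signed)
  attr(out, "label") <- sprintf("%s_%s_%s", design,
                                if (is.null(time_h)) "basal" else time_h,
                                method)
  out
}

#' Direction-consistent overlap of two drugs' gene lists
#'
#' The BD_two / ID_two construction: genes present in the top lists of
#' both drugs with the same deregulation direction, carrying that
#' direction.
#'
#' @param set1,set2 Two [directional_gene_set()] objects.
#' @return A [directional_gene_set()] of the consistent overlap.
#' @export
two_drug_intersection <- function(set1, set2) {
  shared <- intersect(names(set1), names(set2))
  same <- shared[unclass(set1)[shared] == unclass(set2)[shared]]
  directional_gene_set(stats::setNames(as.vector(unclass(set1)[same]), same),
                       label = paste(attr(set1, "label"),
                                     attr(set2, "label"), sep = "&"))
}

#' Expression-level bias of method-exclusive genes
#'
#' Compares genes found exclusively by one ranking method (e.g. AD) versus
#' the other (e.g. FC) on the same comparison: for each exclusive list the
#' report gives the average of the group-mean expression values. The
#' average difference is biased toward highly expressed genes while fold
#' change is biased toward low expression, so AD-exclusive genes typically
#' sit at higher absolute levels.
#'
#' @param setX,setY Two [directional_gene_set()] objects derived from the
#'   same comparison by different methods.
#' @param em The linear-scale [expression_matrix()] of that comparison.
#' @param group_A,group_B The sample selectors of the comparison.
#' @param labels Character vector of length 2 naming the two methods.
#'
#' @return A list with the exclusive gene vectors (`only_X`, `only_Y`) and
#'   a data frame `report` with per-list mean expression in each group.
#' @export
expression_bias_report <- function(setX, setY, em, group_A, group_B,
                                   labels = c("X", "Y")) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "log2") em <- suppressWarnings(delog(em))
  ia <- .resolve_group(em, group_A, "group_A")
  ib <- .resolve_group(em, group_B, "group_B")
  ma <- rowMeans(em$values[, ia, drop = FALSE])
  mb <- rowMeans(em$values[, ib, drop = FALSE])
  only_x <- setdiff(names(setX), names(setY))
  only_y <- setdiff(names(setY), names(setX))
  row_for <- function(genes, lab) {
    data.frame(list = lab, n = length(genes),
               mean_A = if (length(genes)) mean(ma[genes]) else NA_real_,
               mean_B = if (length(genes)) mean(mb[genes]) else NA_real_,
               mean_overall = if (length(genes))
                 mean(c(ma[genes], mb[genes])) else NA_real_,
               stringsAsFactors = FALSE)
  }
  list(only_X = only_x, only_Y = only_y,
       report = rbind(row_for(only_x, labels[1]), row_for(only_y, labels[2])))
}
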