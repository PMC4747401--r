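#' Collapse probe-level rows to gene level
#'
#' Probes mapping to the same gene are summarized by the arithmetic mean of
#' their rows, computed on whatever scale the matrix is currently on.
#' Probes absent from the map are dropped and counted in the attached
#' report.
#'
#' @param em An [expression_matrix()] whose features are probe ids.
#' @param map Data frame with columns `probe_id` and `gene_id`; each probe
#'   maps to exactly one gene (many probes per gene allowed).
#'
#' @return A gene-level [expression_matrix()] on the same scale, with an
#'   `"aggregation_report"` attribute listing the number of probes used,
#'   dropped, and genes produced.
#' @export
aggregate_probes <- function(em, map) {
  stopifnot(inherits(em, "expression_matrix"))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(map)))
    stop("'map' needs columns probe_id and gene_id")
  if (anyDuplicated(map$probe_id))
    stop("each probe must map to exactly one gene")
  probes <- rownames(em$values)
  idx <- match(probes, map$probe_id)
  mapped <- !is.na(idx)
  if (!any(mapped))
    stop("no overlap between matrix features and probe map")
  genes <- map$gene_id[idx[mapped]]
  sub <- em$values[mapped, , drop = FALSE]
  # group means: rowsum sums rows by gene, then divide by probe counts
  sums <- rowsum(sub, group = genes, reorder = TRUE)
  counts <- as.vector(table(genes)[rownames(sums)])
  vals <- sums / counts
  out <- expression_matrix(vals, scale = em$scale, samples = em$samples)
  attr(out, "aggregation_report") <- list(
    n_probes_in = length(probes),
    n_probes_used = sum(mapped),
    n_probes_dropped = sum(!mapped),
    dropped_probes = probes[!mapped],
    n_genes_out = nrow(vals),
    scale = em$scale)
  out
}

#' Log2-transform and quantile-normalize a linear-scale matrix
#'
#' Values at or below zero are floored to `epsilon` before taking log2
#' (background-corrected microarray intensities can be non-positive).
#' Quantile normalization forces every column onto the mean quantile
#' profile; ties receive the mean of the quantile values they span. With a
#' single sample the matrix is returned log2-transformed with a warning,
#' since quantile normalization is degenerate there.
#'
#' @param em A linear-scale [expression_matrix()].
#' @param epsilon Floor applied to values `<= 0` before log2 (default 1).
#'
#' @return A log2-scale [expression_matrix()].
#' @export
log2_quantile_normalize <- function(em, epsilon = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "linear")
    stop("matrix must be on the linear scale")
  v <- em$values
  v[v <= 0] <- epsilon
  lv <- log2(v)
  if (ncol(lv) == 1L) {
    warning("single sample: quantile normalization skipped")
    return(expression_matrix(lv, scale = "log2", samples = em$samples))
  }
  nv <- limma::normalizeQuantiles(lv, ties = TRUE)
  dimnames(nv) <- dimnames(lv)
  expression_matrix(nv, scale = "log2", samples = em$samples)
}

#' Log2-transform without normalizing
#'
#' @inheritParams log2_quantile_normalize
#' @return A log2-scale [expression_matrix()].
#' @export
log2_transform <- function(em, epsilon = 1.0) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "linear") stop("matrix must be on the linear scale")
  v <- em$values
  v[v <= 0] <- epsilon
  expression_matrix(log2(v), scale = "log2", samples = em$samples)
}

#' Return a log2-scale matrix to the linear scale
#'
#' Fold change and average difference are defined on non-log expression
#' values, so log2 matrices are exponentiated before ranking. Note that
#' group means do not commute with the transform: the mean of delogged
#' values differs from the delog of mean values for any non-constant row.
#'
#' @param em An [expression_matrix()].
#' @return A linear-scale [expression_matrix()]. If `em` is already
#'   linear it is returned unchanged with a warning.
#' @export
delog <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "linear") {
    warning("matrix already on the linear scale; returned unchanged")
    return(em)
  }
  expression_matrix(2 ^ em$values, scale = "linear", samples = em$samples)
}
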