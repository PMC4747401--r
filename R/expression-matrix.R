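#' Expression matrix with sample annotations
#'
#' The central data container: a numeric genes-by-samples (or
#' probes-by-samples) matrix together with per-sample annotations and an
#' explicit scale flag. Downstream change statistics (fold change, average
#' difference) are defined on the linear scale, while rank-product testing
#' and quantile normalization operate on the log2 scale, so the scale is
#' carried explicitly and checked by every operation.
#'
#' @param values Numeric matrix; rows are features (probes or genes) with
#'   unique rownames, columns are samples. On the linear scale all values
#'   must be non-negative.
#' @param scale Either `"linear"` or `"log2"`.
#' @param samples Data frame of per-sample annotations with one row per
#'   column of `values` (see [sample_annotations()]). If `NULL`, a minimal
#'   annotation frame is built from the column names.
#'
#' @return An object of class `"expression_matrix"`: a list with elements
#'   `values`, `scale` and `samples`.
#' @export
expression_matrix <- function(values, scale = c("linear", "log2"),
                              samples = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (is.null(rownames(values))) stop("'values' must have feature rownames")
  if (anyDuplicated(rownames(values)))
    stop("feature ids (rownames) must be unique")
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (is.null(samples)) samples <- sample_annotations(colnames(values))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (nrow(samples) != ncol(values))
    stop("'samples' must have one row per column of 'values'")
  if (!"sample_id" %in% names(samples))
    stop("'samples' must contain a 'sample_id' column")
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop("linear-scale values must be non-negative")
  .check_annotations(samples)
  structure(list(values = values, scale = scale, samples = samples),
            class = "expression_matrix")
}

#' Build a sample-annotation data frame
#'
#' @param sample_id Character vector of sample identifiers.
#' @param cell_line Cell line name, or `""` for clinical samples.
#' @param resistance_status `"parental"`, `"resistant"` or `"n/a"`.
#' @param drug Drug the sample was treated with, or `"none"`.
#' @param treatment_time_h Treatment time in hours; `NA` when untreated.
#' @param cohort `"cell_line"`, `"pre_chemo"` or `"post_chemo"`.
#' @param response `"responder"`, `"non_responder"` or `"n/a"`; only
#'   meaningful for clinical cohorts.
#' @param dataset_id Identifier of the originating dataset/batch.
#'
#' @return A data frame with one row per sample.
#' @export
sample_annotations <- function(sample_id, cell_line = "",
                               resistance_status = "n/a", drug = "none",
                               treatment_time_h = NA_real_,
                               cohort = "cell_line", response = "n/a",
                               dataset_id = "") {
  ann <- data.frame(sample_id = as.character(sample_id),
                    cell_line = cell_line,
                    resistance_status = resistance_status,
                    drug = drug,
                    treatment_time_h = as.numeric(treatment_time_h),
                    cohort = cohort,
                    response = response,
                    dataset_id = dataset_id,
                    stringsAsFactors = FALSE)
  .check_annotations(ann)
  ann
}

.check_annotations <- function(ann) {
  need <- c("sample_id", "resistance_status", "drug", "treatment_time_h",
            "cohort", "response")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation columns missing: ", paste(miss, collapse = ", "))
  bad <- ann$response != "n/a" & !ann$cohort %in% c("pre_chemo", "post_chemo")
  if (any(bad))
    stop("response may only be set for pre_chemo/post_chemo cohorts: ",
         paste(ann$sample_id[bad], collapse = ", "))
  bad <- !is.na(ann$treatment_time_h) & ann$treatment_time_h > 0 &
    ann$drug == "none"
  if (any(bad))
    stop("treatment_time_h set for untreated samples: ",
         paste(ann$sample_id[bad], collapse = ", "))
  if (any(ann$treatment_time_h < 0, na.rm = TRUE))
    stop("treatment_time_h must be non-negative")
  invisible(ann)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d features x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values), x$scale))
  coh <- table(x$samples$cohort)
  cat("  cohorts:", paste(sprintf("%s=%d", names(coh), coh), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Select sample columns by annotation
#'
#' Returns the column indices of samples whose annotations match every
#' named condition. Conditions are matched by equality; `NA` matches `NA`
#' (used for untreated samples with no treatment time).
#'
#' @param em An [expression_matrix()].
#' @param ... Named conditions, e.g. `resistance_status = "parental",
#'   drug = "none"`. Each value may be a vector (matched with `%in%`).
#'
#' @return Integer vector of column indices (possibly empty).
#' @export
samples_where <- function(em, ...) {
  stopifnot(inherits(em, "expression_matrix"))
  cond <- list(...)
  keep <- rep(TRUE, nrow(em$samples))
  for (nm in names(cond)) {
    if (!nm %in% names(em$samples))
      stop("unknown annotation field: ", nm)
    col <- em$samples[[nm]]
    val <- cond[[nm]]
    hit <- if (all(is.na(val))) is.na(col) else col %in% val
    keep <- keep & hit
  }
  which(keep)
}

# Resolve a group selector: integer/logical indices, sample ids, or a
# named list of annotation conditions.
.resolve_group <- function(em, sel, what = "group") {
  if (is.list(sel)) return(do.call(samples_where, c(list(em), sel)))
  if (is.logical(sel)) return(which(sel))
  if (is.character(sel)) {
    idx <- match(sel, em$samples$sample_id)
    if (anyNA(idx)) stop(what, ": unknown sample ids: ",
                         paste(sel[is.na(idx)], collapse = ", "))
    return(idx)
  }
  as.integer(sel)
}

#' Read an expression matrix from TSV files
#'
#' The expression file is tab-separated with feature ids in the first
#' column and a header row of sample ids. The optional metadata file is a
#' tab-separated table keyed by `sample_id` with the annotation columns of
#' [sample_annotations()].
#'
#' @param file Path to the expression TSV.
#' @param metadata Optional path to the sample-metadata TSV.
#' @param scale `"linear"` or `"log2"`; the scale the file is on.
#'
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(file, metadata = NULL,
                                   scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  samples <- NULL
  if (!is.null(metadata)) {
    md <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    idx <- match(colnames(values), md$sample_id)
    if (anyNA(idx))
      stop("metadata missing samples: ",
           paste(colnames(values)[is.na(idx)], collapse = ", "))
    samples <- md[idx, , drop = FALSE]
    rownames(samples) <- NULL
  }
  expression_matrix(values, scale = scale, samples = samples)
}

#' Write an expression matrix (and its metadata) to TSV
#'
#' @param em An [expression_matrix()].
#' @param file Output path for the expression TSV.
#' @param metadata Optional output path for the sample-metadata TSV.
#' @return Invisibly, `em`.
#' @export
write_expression_matrix <- function(em, file, metadata = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  tab <- data.frame(feature_id = rownames(em$values), em$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata))
    utils::write.table(em$samples, metadata, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(em)
}
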