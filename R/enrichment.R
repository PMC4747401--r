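#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member gene ids.
#'
#' @param file Path to a GMT file.
#' @return A named list of class `"gene_set_collection"`; each element is
#'   a list with `description` and `genes`.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    list(description = f[2], genes = unique(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection A `"gene_set_collection"` (named list with
#'   `description` and `genes` per set).
#' @param file Output path.
#' @return Invisibly, `collection`.
#' @export
write_gmt <- function(collection, file) {
  lines <- vapply(names(collection), function(nm) {
    s <- collection[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(collection)
}

#' Hypergeometric over-representation of gene sets in a query list
#'
#' For each set, the upper-tail hypergeometric probability of drawing at
#' least the observed overlap when `n_query` genes are sampled from the
#' universe (the observed count is included in the tail). P-values are
#' Benjamini-Hochberg adjusted across sets. Enrichment is
#' universe-sensitive: the default universe should be all genes measured
#' on the platform. Query genes absent from the universe are dropped with
#' a warning; set members are intersected with the universe before
#' testing.
#'
#' @param query A [directional_gene_set()] or character vector of gene
#'   ids.
#' @param collection A `"gene_set_collection"` from [read_gmt()], or a
#'   named list of character vectors.
#' @param universe Character vector of all assayable gene ids.
#'
#' @return A data frame sorted by p-value with columns `set`,
#'   `n_universe`, `n_set`, `n_query`, `n_overlap`, `p_hyper`, `fdr`,
#'   `overlap_genes` (comma-separated).
#' @export
hypergeom_enrich <- function(query, collection, universe) {
  qgenes <- if (inherits(query, "directional_gene_set")) names(query)
            else as.character(query)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  lost <- setdiff(qgenes, universe)
  if (length(lost))
    warning(length(lost), " query genes absent from the universe dropped")
  qgenes <- intersect(qgenes, universe)
  if (!length(qgenes)) stop("query has no genes in the universe")
  N <- length(universe)
  nq <- length(qgenes)
  rows <- lapply(names(collection), function(nm) {
    s <- collection[[nm]]
    members <- if (is.list(s)) s$genes else s
    members <- intersect(members, universe)
    ov <- intersect(members, qgenes)
    K <- length(members)
    p <- if (K == 0) 1 else
      stats::phyper(length(ov) - 1, K, N - K, nq, lower.tail = FALSE)
    data.frame(set = nm, n_universe = N, n_set = K, n_query = nq,
               n_overlap = length(ov), p_hyper = p,
               overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_hyper)
  out <- out[order(out$p_hyper, out$set),
             c("set", "n_universe", "n_set", "n_query", "n_overlap",
               "p_hyper", "fdr", "overlap_genes")]
  rownames(out) <- NULL
  out
}
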