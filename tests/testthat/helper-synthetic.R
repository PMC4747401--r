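# Shared fixtures: reduced-size generator configs and hand-built objects.

small_config <- function(seed, ...) {
  args <- list(n_genes = 600, n_resistance = 30, n_stratum = 6,
               n_drug_response = 60, n_basal = 30,
               n_responders = 6, n_nonresponders = 6, n_datasets = 2,
               n_responders_post = 5, n_nonresponders_post = 5,
               seed = seed)
  do.call(generator_config, utils::modifyList(args, list(...)))
}

null_config <- function(seed, ...) {
  small_config(seed, n_resistance = 0, n_stratum = 0,
               n_drug_response = 0, n_basal = 0, ...)
}

# two-group linear matrix with exact per-group values
two_group_em <- function(values_A, values_B, genes = NULL) {
  va <- as.matrix(values_A); vb <- as.matrix(values_B)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(va)))
  m <- cbind(va, vb)
  rownames(m) <- genes
  colnames(m) <- c(paste0("A", seq_len(ncol(va))),
                   paste0("B", seq_len(ncol(vb))))
  expression_matrix(m, scale = "linear")
}

group_A_cols <- function(em) grep("^A", em$samples$sample_id)
group_B_cols <- function(em) grep("^B", em$samples$sample_id)

toy_deg_table <- function(gene_id, direction, fdr, p = fdr) {
  structure(data.frame(gene_id = gene_id, direction = direction,
                       p = p, fdr = fdr, stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"))
}

dgs <- function(...) {
  v <- c(...)
  directional_gene_set(v)
}
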