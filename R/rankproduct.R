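#' Rank-product differential expression between two sample classes
#'
#' The two-class (unpaired) rank product: every class-A sample is compared
#' with every class-B sample, genes are ranked within each pairwise
#' difference (rank 1 = most up-regulated for the up statistic, most
#' down-regulated for the down statistic, average ranks on ties), and the
#' per-gene statistic is the geometric mean of its ranks across pairs.
#' Because only within-pair rank orders enter the statistic, any
#' per-sample additive shift on the log scale (e.g. a batch effect) leaves
#' the result unchanged; with `within_dataset = TRUE` (default) pairs are
#' additionally restricted to samples from the same `dataset_id`, so
#' pooled multi-batch cohorts never compare across batches.
#'
#' Significance is assessed by permutation: in each round the gene labels
#' are independently permuted within every sample, all pairwise rankings
#' are recomputed from the permuted columns, and each gene's one-sided
#' p-value is `(1 + #null <= observed) / (n_permutations + 1)` (so
#' p-values are bounded below by `1/(n_permutations + 1)`). Permuting
#' within samples rather than within pairwise difference vectors keeps the
#' correlation between pairwise comparisons that share a sample, which is
#' what calibrates the null when every A sample is compared with every B
#' sample. The combined `p` column is
#' `min(1, 2 * min(p_up, p_down))`, accounting for the two directional
#' tests; Benjamini-Hochberg FDR is computed within each direction and
#' reported for the gene's called direction. Breitling-style expected
#' false positives per gene (`pfp`) are included as an alternative.
#'
#' @param em A log2-scale [expression_matrix()].
#' @param class_A,class_B Sample selectors (see [compute_fc()]); "up"
#'   means higher in class A.
#' @param n_permutations Number of permutation rounds (default 1000; a
#'   warning is issued below 100).
#' @param seed Integer seed for the permutation null (mandatory).
#' @param within_dataset Restrict pairs to samples sharing `dataset_id`.
#'
#' @return A `"deg_table"` data frame with columns `gene_id`, `rp_up`,
#'   `rp_down`, `p_up`, `p_down`, `pfp_up`, `pfp_down`, `p`, `direction`,
#'   `fdr`, and attributes `n_pairs`, `n_permutations`, `seed`.
#' @export
rank_product <- function(em, class_A, class_B, n_permutations = 1000,
                         seed, within_dataset = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale != "log2")
    stop("rank_product expects a log2-scale matrix")
  if (missing(seed)) stop("'seed' is required")
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-values will be coarse")
  ia <- .resolve_group(em, class_A, "class_A")
  ib <- .resolve_group(em, class_B, "class_B")
  if (length(ia) < 1 || length(ib) < 1)
    stop("both classes must be non-empty")
  ds <- em$samples$dataset_id
  pairs <- expand.grid(a = ia, b = ib)
  if (within_dataset) {
    pairs <- pairs[ds[pairs$a] == ds[pairs$b], , drop = FALSE]
    if (!nrow(pairs))
      stop("no same-dataset sample pairs; set within_dataset = FALSE ",
           "to allow cross-dataset pairs")
  }
  P <- nrow(pairs)
  if (P == 1L)
    warning("single pairwise comparison: rank product has degenerate power")
  G <- nrow(em$values)
  v <- em$values
  # per-pair differences and within-pair ranks (ties -> average rank)
  rk_up <- matrix(0, G, P)
  for (j in seq_len(P)) {
    d <- v[, pairs$a[j]] - v[, pairs$b[j]]
    rk_up[, j] <- rank(-d, ties.method = "average")
  }
  rk_down <- (G + 1) - rk_up
  obs_up <- rowMeans(log(rk_up))
  obs_down <- rowMeans(log(rk_down))

  loggrid <- log(seq_len(G))
  used <- sort(unique(c(pairs$a, pairs$b)))
  ja <- match(pairs$a, used); jb <- match(pairs$b, used)
  vu <- v[, used, drop = FALSE]
  cnt_up <- integer(G); cnt_down <- integer(G)
  pool_up <- numeric(G); pool_down <- numeric(G)
  ord_up <- order(obs_up); ord_down <- order(obs_down)
  sorted_up <- obs_up[ord_up]; sorted_down <- obs_down[ord_down]
  rk <- integer(G)
  set.seed(as.integer(seed))
  for (b in seq_len(n_permutations)) {
    pv <- vu
    for (s in seq_along(used)) pv[, s] <- vu[sample.int(G), s]
    acc_up <- numeric(G)
    acc_down <- numeric(G)
    for (j in seq_len(P)) {
      d <- pv[, ja[j]] - pv[, jb[j]]
      o <- sort.list(d, decreasing = TRUE, method = "radix")
      rk[o] <- seq_len(G)
      acc_up <- acc_up + loggrid[rk]
      # the reversed ranking is the down-statistic rank of the same draw
      acc_down <- acc_down + loggrid[(G + 1L) - rk]
    }
    null_up <- acc_up / P
    null_down <- acc_down / P
    cnt_up <- cnt_up + (null_up <= obs_up)
    cnt_down <- cnt_down + (null_down <= obs_down)
    # pooled null counts for Breitling expected false positives
    ns <- sort(null_up)
    pool_up[ord_up] <- pool_up[ord_up] + findInterval(sorted_up, ns)
    ns <- sort(null_down)
    pool_down[ord_down] <- pool_down[ord_down] + findInterval(sorted_down, ns)
  }
  B <- n_permutations
  p_up <- (1 + cnt_up) / (B + 1)
  p_down <- (1 + cnt_down) / (B + 1)
  # pfp: expected number of null genes as extreme, divided by the gene's rank
  e_up <- pool_up / B
  e_down <- pool_down / B
  pfp_up <- e_up / rank(obs_up, ties.method = "max")
  pfp_down <- e_down / rank(obs_down, ties.method = "max")
  direction <- ifelse(p_up < p_down, "up",
                      ifelse(p_down < p_up, "down",
                             ifelse(obs_up <= obs_down, "up", "down")))
  p <- pmin(1, 2 * pmin(p_up, p_down))
  fdr_up <- bh_adjust(p_up)
  fdr_down <- bh_adjust(p_down)
  fdr <- ifelse(direction == "up", fdr_up, fdr_down)
  out <- data.frame(gene_id = rownames(v),
                    rp_up = exp(obs_up), rp_down = exp(obs_down),
                    p_up = p_up, p_down = p_down,
                    pfp_up = pfp_up, pfp_down = pfp_down,
                    p = p, direction = direction, fdr = fdr,
                    stringsAsFactors = FALSE)
  structure(out, n_pairs = P, n_permutations = B, seed = as.integer(seed),
            class = c("deg_table", "data.frame"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, via
#' [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues <= 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter a DEG table into a directional gene set
#'
#' @param table A `"deg_table"` from [rank_product()].
#' @param fdr_max Keep genes with `fdr < fdr_max` (or `NULL` to skip).
#' @param p_max Keep genes with `p < p_max` (or `NULL` to skip).
#' @param label Label for the resulting set.
#' @return A [directional_gene_set()] of the passing genes.
#' @export
deg_filter <- function(table, fdr_max = NULL, p_max = NULL, label = "DEG") {
  stopifnot(inherits(table, "data.frame"))
  for (thr in c(fdr_max, p_max))
    if (!is.null(thr) && (thr <= 0 || thr > 1))
      stop("thresholds must lie in (0, 1]")
  keep <- rep(TRUE, nrow(table))
  if (!is.null(fdr_max)) keep <- keep & table$fdr < fdr_max
  if (!is.null(p_max)) keep <- keep & table$p < p_max
  sel <- table[keep, , drop = FALSE]
  directional_gene_set(stats::setNames(sel$direction, sel$gene_id), label)
}
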