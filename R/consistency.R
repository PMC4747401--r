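#' Exact upper tail of the binomial distribution
#'
#' Probability of observing at least `s` successes in `k` trials with
#' per-trial success probability `p_e`, computed by exact summation of the
#' binomial probability mass in log space (numerically safe for large `k`;
#' no normal approximation). This is the chance model behind the
#' consistency score: under the null each shared gene agrees in direction
#' with probability `p_e` (0.5 by default), so the tail probability is the
#' significance of the observed agreement.
#'
#' @param k Number of trials (shared genes); positive integer.
#' @param s Observed successes (direction-consistent genes), `0 <= s <= k`.
#' @param p_e Chance agreement probability, in (0, 1). Default 0.5.
#'
#' @return The one-sided tail probability `P(X >= s)` in (0, 1].
#' @export
binomial_tail <- function(k, s, p_e = 0.5) {
  if (length(k) != 1 || length(s) != 1 || k < 1 || k != round(k))
    stop("'k' must be a single positive integer")
  if (s < 0 || s > k || s != round(s))
    stop("'s' must be an integer in [0, k]")
  if (p_e <= 0 || p_e >= 1) stop("'p_e' must be in (0, 1)")
  if (s == 0) return(1)
  i <- s:k
  logterms <- lchoose(k, i) + i * log(p_e) + (k - i) * log1p(-p_e)
  m <- max(logterms)
  exp(m + log(sum(exp(logterms - m))))
}

#' Directional consistency of two gene lists
#'
#' Given two directional gene lists sharing `k` genes of which `s` agree
#' in deregulation direction, the consistency score is `100 * s / k` and
#' its significance is the exact one-sided binomial tail [binomial_tail()]
#' with chance agreement probability `p_e`.
#'
#' @param setA,setB Two [directional_gene_set()] objects.
#' @param p_e Chance agreement probability (default 0.5).
#'
#' @return An object of class `"consistency_result"`: a list with `k`,
#'   `s`, `score` (percent, full precision), `p_binomial`, `p_e`, the
#'   shared/consistent gene ids, and `degenerate = TRUE` when `k = 0`
#'   (score `NA`, p 1).
#' @export
overlap_consistency <- function(setA, setB, p_e = 0.5) {
  shared <- intersect(names(setA), names(setB))
  k <- length(shared)
  consistent <- shared[unclass(setA)[shared] == unclass(setB)[shared]]
  s <- length(consistent)
  res <- list(k = k, s = s,
              score = if (k > 0) 100 * s / k else NA_real_,
              p_binomial = if (k > 0) binomial_tail(k, s, p_e) else 1,
              p_e = p_e, shared_genes = shared,
              consistent_genes = consistent, degenerate = k == 0)
  class(res) <- "consistency_result"
  res
}

#' @export
print.consistency_result <- function(x, ...) {
  if (x$degenerate) {
    cat("consistency: no shared genes (k = 0); p = 1 [degenerate]\n")
  } else {
    cat(sprintf("consistency: k = %d, s = %d, score = %.2f%%, binomial P = %.3g\n",
                x$k, x$s, x$score, x$p_binomial))
  }
  invisible(x)
}

#' Pairwise consistency table for a collection of gene lists
#'
#' @param sets Named list of at least two [directional_gene_set()]
#'   objects.
#' @param p_e Chance agreement probability (default 0.5).
#'
#' @return A data frame with one row per unordered pair: `set_a`, `set_b`,
#'   `k`, `s`, `score_percent` (two decimals), `p_binomial`.
#' @export
consistency_matrix <- function(sets, p_e = 0.5) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)))
    names(sets) <- paste0("set", seq_along(sets))
  pairs <- utils::combn(length(sets), 2)
  rows <- apply(pairs, 2, function(ij) {
    r <- overlap_consistency(sets[[ij[1]]], sets[[ij[2]]], p_e)
    data.frame(set_a = names(sets)[ij[1]], set_b = names(sets)[ij[2]],
               k = r$k, s = r$s,
               score_percent = round(r$score, 2),
               p_binomial = r$p_binomial, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
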