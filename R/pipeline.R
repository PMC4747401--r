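#' Per-time-point FC and AD trajectories of selected genes
#'
#' For each positive treatment time, computes the log2 fold change and the
#' average difference of the inducible-difference contrast
#' (treated resistant vs treated parental) for the given genes — the raw
#' material of trajectory plots showing when resistance genes diverge.
#'
#' @param em A linear-scale [expression_matrix()] of a cell-line
#'   experiment.
#' @param genes Character vector of gene ids.
#' @param drug Drug of the treated conditions.
#' @param time_points Positive treatment times to evaluate.
#'
#' @return A data frame with columns `gene_id`, `time_h`, `log2_fc`,
#'   `ad`.
#' @export
trajectory_table <- function(em, genes, drug, time_points) {
  stopifnot(inherits(em, "expression_matrix"))
  if (em$scale == "log2") em <- suppressWarnings(delog(em))
  rows <- lapply(time_points[time_points > 0], function(t) {
    ia <- samples_where(em, resistance_status = "resistant", drug = drug,
                        treatment_time_h = t)
    ib <- samples_where(em, resistance_status = "parental", drug = drug,
                        treatment_time_h = t)
    ma <- rowMeans(em$values[genes, ia, drop = FALSE])
    mb <- rowMeans(em$values[genes, ib, drop = FALSE])
    data.frame(gene_id = genes, time_h = t, log2_fc = log2(ma / mb),
               ad = ma - mb, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.write_tsv <- function(tab, dir, name, params = NULL) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, paste0(name, ".tsv"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(paste0("# ", paste(names(params), unlist(params),
                                  sep = "=", collapse = " ")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full resistance-gene analysis on synthetic data
#'
#' End-to-end orchestration: simulates resistant cell-line experiments for
#' two drugs and the matched clinical cohorts, derives BD/IP/ID gene lists
#' at every time point by both ranking methods, the two-drug
#' direction-consistent overlaps (BD_two/ID_two), clinical DEG tables by
#' rank product, the tiered CRG set and the ID_clinical set, all pairwise
#' consistency tables, an FC-vs-AD expression-bias report, FC/AD
#' trajectories of the combined late ID genes, and a pathway-enrichment
#' table against gene sets built from the planted truth. All randomness
#' derives from `config$seed`; two runs with the same config are
#' identical.
#'
#' @param config A [generator_config()].
#' @param drugs Character vector of two drug names.
#' @param top_n Size of the top-ranked lists (default 400, matched to the
#'   default 2000-gene simulation; use 3000 on genome-scale input).
#' @param methods Ranking methods to run (`"FC"`, `"AD"`).
#' @param n_permutations Permutations for the rank-product tests.
#' @param fdr_discovery,p_confirm Tier thresholds for the CRG selection.
#' @param fdr_id_clinical FDR threshold for ID_clinical genes.
#' @param out_dir Optional directory; when given, every table is written
#'   as TSV with a parameter header line plus a `manifest.txt`.
#'
#' @return A list with components `gene_lists` (named
#'   [directional_gene_set()]s), `deg_tables`, `crg`, `id_clinical`,
#'   `consistency_bd_ip`, `consistency_vs_crg`, `bias_report`,
#'   `trajectories`, `enrichment`, `truths`, and `manifest`.
#' @export
run_full_pipeline <- function(config, drugs = c("5-FU", "L-OHP"),
                              top_n = 400, methods = c("FC", "AD"),
                              n_permutations = 1000, fdr_discovery = 0.2,
                              p_confirm = 0.05, fdr_id_clinical = 0.1,
                              out_dir = NULL) {
  stopifnot(inherits(config, "generator_config"), length(drugs) == 2)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  seed <- config$seed
  times <- config$time_points[config$time_points > 0]
  t_last <- max(times)

  ## cell-line experiments, one per drug
  expts <- list(
    generate_cellline_experiment(config, drugs[1], seed = seed),
    generate_cellline_experiment(config, drugs[2], seed = seed + 1))
  names(expts) <- drugs

  ## BD / IP / ID lists per drug, method, time
  gene_lists <- list()
  for (d in drugs) for (m in methods) {
    em <- expts[[d]]$matrix
    gene_lists[[sprintf("BD_%s_%s", d, m)]] <-
      define_gene_class(em, "BD", method = m, n = top_n)
    for (t in times) {
      gene_lists[[sprintf("IP%d_%s_%s", t, d, m)]] <-
        define_gene_class(em, "IP", drug = d, time_h = t, method = m,
                          n = top_n)
      gene_lists[[sprintf("ID%d_%s_%s", t, d, m)]] <-
        define_gene_class(em, "ID", drug = d, time_h = t, method = m,
                          n = top_n)
    }
  }
  for (m in methods) {
    gene_lists[[sprintf("BDtwo_%s", m)]] <- two_drug_intersection(
      gene_lists[[sprintf("BD_%s_%s", drugs[1], m)]],
      gene_lists[[sprintf("BD_%s_%s", drugs[2], m)]])
    for (t in times)
      gene_lists[[sprintf("IDtwo%d_%s", t, m)]] <- two_drug_intersection(
        gene_lists[[sprintf("ID%d_%s_%s", t, drugs[1], m)]],
        gene_lists[[sprintf("ID%d_%s_%s", t, drugs[2], m)]])
  }

  ## clinical cohorts and DEG tables
  truths <- lapply(expts, `[[`, "truth")
  norm <- function(em) log2_quantile_normalize(em)
  discovery_em <- norm(generate_clinical_cohort(config, truths,
                                                seed = seed + 10))
  confirm_em <- norm(generate_clinical_cohort(
    config, truths, seed = seed + 11, n_responders = 23,
    n_nonresponders = 14, n_datasets = 1))
  post_em <- norm(generate_clinical_cohort(config, truths,
                                           seed = seed + 12,
                                           cohort = "post_chemo"))
  rp <- function(em, s) rank_product(
    em, class_A = list(response = "non_responder"),
    class_B = list(response = "responder"),
    n_permutations = n_permutations, seed = s)
  deg_tables <- list(discovery = rp(discovery_em, seed + 20),
                     confirmation = rp(confirm_em, seed + 21),
                     post_chemo = rp(post_em, seed + 22))
  crg <- tiered_crg(deg_tables$discovery, list(deg_tables$confirmation),
                    fdr_discovery = fdr_discovery, p_confirm = p_confirm,
                    label = paste0("CRG_", paste(drugs, collapse = "/")))
  idc <- id_clinical(deg_tables$post_chemo, fdr_max = fdr_id_clinical)

  ## consistency tables: BD vs IP (per drug/method/time), candidates vs CRG
  bd_ip <- do.call(rbind, lapply(drugs, function(d) {
    do.call(rbind, lapply(methods, function(m) {
      do.call(rbind, lapply(times, function(t) {
        r <- overlap_consistency(
          gene_lists[[sprintf("BD_%s_%s", d, m)]],
          gene_lists[[sprintf("IP%d_%s_%s", t, d, m)]])
        data.frame(drug = d, method = m, ip = sprintf("IP_%d", t),
                   k = r$k, s = r$s, score_percent = round(r$score, 2),
                   p_binomial = r$p_binomial, stringsAsFactors = FALSE)
      }))
    }))
  }))
  candidates <- grep("^(BD|ID)", names(gene_lists), value = TRUE)
  vs_crg <- do.call(rbind, lapply(candidates, function(nm) {
    r1 <- overlap_consistency(gene_lists[[nm]], crg$members)
    r2 <- overlap_consistency(gene_lists[[nm]], idc)
    data.frame(gene_set = nm, reference = c("CRG", "ID_clinical"),
               k = c(r1$k, r2$k), s = c(r1$s, r2$s),
               score_percent = round(c(r1$score, r2$score), 2),
               p_binomial = c(r1$p_binomial, r2$p_binomial),
               stringsAsFactors = FALSE)
  }))

  ## FC-vs-AD expression bias on the late ID contrast of drug 1
  em1 <- expts[[1]]$matrix
  gA <- list(resistance_status = "resistant", drug = drugs[1],
             treatment_time_h = t_last)
  gB <- list(resistance_status = "parental", drug = drugs[1],
             treatment_time_h = t_last)
  bias <- expression_bias_report(
    gene_lists[[sprintf("ID%d_%s_FC", t_last, drugs[1])]],
    gene_lists[[sprintf("ID%d_%s_AD", t_last, drugs[1])]],
    em1, gA, gB, labels = c("FC", "AD"))

  ## trajectories of the combined late ID genes (FC union AD)
  combined <- union(
    names(gene_lists[[sprintf("ID%d_%s_FC", t_last, drugs[1])]]),
    names(gene_lists[[sprintf("ID%d_%s_AD", t_last, drugs[1])]]))
  traj <- trajectory_table(em1, sort(combined), drugs[1], times)

  ## enrichment of the late AD ID list against truth-derived gene sets
  collection <- truth_gene_sets(truths[[1]])
  enr <- hypergeom_enrich(
    gene_lists[[sprintf("ID%d_%s_AD", t_last, drugs[1])]], collection,
    universe = truths[[1]]$gene_id)

  manifest <- list(seed = seed, n_genes = config$n_genes, drugs =
                     paste(drugs, collapse = ","), top_n = top_n,
                   n_permutations = n_permutations,
                   fdr_discovery = fdr_discovery, p_confirm = p_confirm,
                   fdr_id_clinical = fdr_id_clinical,
                   n_crg = length(crg$members),
                   n_id_clinical = length(idc),
                   r_version = as.character(getRversion()))
  if (!is.null(out_dir)) {
    prm <- list(seed = seed, top_n = top_n)
    for (nm in names(gene_lists))
      .write_tsv(as.data.frame(gene_lists[[nm]]), out_dir,
                 paste0("genes_", gsub("[^A-Za-z0-9_]", "_", nm)), prm)
    .write_tsv(bd_ip, out_dir, "consistency_bd_ip", prm)
    .write_tsv(vs_crg, out_dir, "consistency_vs_crg", prm)
    .write_tsv(as.data.frame(crg$members), out_dir, "crg", prm)
    .write_tsv(as.data.frame(idc), out_dir, "id_clinical", prm)
    .write_tsv(bias$report, out_dir, "bias_report", prm)
    .write_tsv(traj, out_dir, "trajectories", prm)
    .write_tsv(enr, out_dir, "enrichment", prm)
    for (nm in names(deg_tables))
      .write_tsv(deg_tables[[nm]], out_dir, paste0("deg_", nm), prm)
    writeLines(paste(names(manifest), unlist(manifest), sep = "="),
               file.path(out_dir, "manifest.txt"))
  }
  list(gene_lists = gene_lists, deg_tables = deg_tables, crg = crg,
       id_clinical = idc, consistency_bd_ip = bd_ip,
       consistency_vs_crg = vs_crg, bias_report = bias,
       trajectories = traj, enrichment = enr, truths = truths,
       manifest = manifest)
}

#' Gene sets derived from a simulation truth table
#'
#' Builds a small gene-set collection from the planted classes of a
#' synthetic experiment (one set per class) — convenient known-positive
#' input for [hypergeom_enrich()].
#'
#' @param truth Truth data frame from [generate_cellline_experiment()].
#' @return A `"gene_set_collection"`.
#' @export
truth_gene_sets <- function(truth) {
  classes <- setdiff(unique(truth$class), "null")
  sets <- lapply(classes, function(cl)
    list(description = paste("planted", cl, "genes"),
         genes = truth$gene_id[truth$class == cl]))
  names(sets) <- paste0("planted_", classes)
  structure(sets, class = "gene_set_collection")
}
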