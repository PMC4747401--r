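#' Configuration for the synthetic-data generator
#'
#' Describes a drug-induced resistance experiment (parental and resistant
#' lines, untreated and treated at several time points, few replicates)
#' and the matched clinical responder/non-responder cohorts. Four planted
#' gene classes drive the signal, all on the log2 scale (multiplicative on
#' the linear scale):
#' \describe{
#'   \item{resistance}{differential drug response between resistant and
#'     parental cells: a ramp reaching `resistance_effect` at the last
#'     time point, present only in treated resistant samples. A
#'     `n_stratum`-gene subset sits on a high baseline with a small
#'     log-effect (`stratum_effect`), producing large average differences
#'     but fold changes below ~1.3 — the expression stratum that separates
#'     AD- from FC-ranking.}
#'   \item{drug_response}{induced by treatment in both cell types:
#'     transient kinetics peaking at `t_peak` and decaying to
#'     `decay_floor` of the peak by the last time point. The chronically
#'     drug-exposed resistant line additionally retains
#'     `sustained_fraction` of the peak in all its samples (treated or
#'     not), which is what makes basally-deregulated lists agree with
#'     treatment-induced lists.}
#'   \item{basal_difference}{constant offset between the lines,
#'     irrelevant to resistance.}
#'   \item{null}{baseline plus noise only.}
#' }
#' Clinical cohorts carry the resistance-gene effects, attenuated by
#' `attenuation` and scaled per patient by a log-normal heterogeneity
#' factor; multi-dataset cohorts receive per-dataset gene-wise batch
#' shifts.
#'
#' @param n_genes Number of genes.
#' @param n_replicates Replicates per cell-line condition.
#' @param time_points Treatment times in hours; 0 means untreated.
#' @param n_resistance,n_drug_response,n_basal Planted class sizes.
#' @param n_stratum High-expression/low-FC subset of the resistance genes.
#' @param baseline_mean,baseline_sd Log2 baseline distribution.
#' @param stratum_baseline_mean,stratum_baseline_sd Log2 baseline of the
#'   high-expression stratum.
#' @param resistance_effect,stratum_effect,basal_effect Log2 effect sizes.
#' @param drug_response_peak Peak log2 induction of drug-response genes.
#' @param t_peak Hour of the transient peak.
#' @param decay_floor Fraction of the peak remaining at the last time
#'   point.
#' @param sustained_fraction Fraction of the peak retained basally by the
#'   resistant line.
#' @param noise_sd Replicate noise sd (log2) in cell-line data.
#' @param n_responders,n_nonresponders Pre-chemotherapy cohort sizes.
#' @param n_responders_post,n_nonresponders_post Post-chemotherapy cohort
#'   sizes.
#' @param n_datasets Number of batches the pre-chemo cohort is split
#'   across.
#' @param batch_sd Sd of per-dataset gene-wise batch shifts (log2).
#' @param attenuation Multiplier mapping cell-line resistance effects to
#'   tissue effects.
#' @param heterogeneity_sd Sd of the per-patient log-normal effect
#'   multiplier.
#' @param clinical_noise_sd Per-sample noise sd (log2) in clinical data.
#' @param seed Integer seed (required).
#'
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_genes = 2000, n_replicates = 3,
                             time_points = c(0, 6, 12, 24),
                             n_resistance = 100, n_stratum = 15,
                             n_drug_response = 200, n_basal = 100,
                             baseline_mean = 8, baseline_sd = 1.5,
                             stratum_baseline_mean = 13,
                             stratum_baseline_sd = 0.5,
                             resistance_effect = 1.5, stratum_effect = 0.30,
                             basal_effect = 1.5, drug_response_peak = 2.0,
                             t_peak = 12, decay_floor = 0.3,
                             sustained_fraction = 0.6, noise_sd = 0.2,
                             n_responders = 19, n_nonresponders = 25,
                             n_responders_post = 13,
                             n_nonresponders_post = 17,
                             n_datasets = 2, batch_sd = 0.5,
                             attenuation = 0.5, heterogeneity_sd = 0.3,
                             clinical_noise_sd = 0.5, seed) {
  if (missing(seed)) stop("'seed' is required")
  cfg <- as.list(environment())
  if (cfg$n_resistance + cfg$n_drug_response + cfg$n_basal > cfg$n_genes)
    stop("planted class sizes exceed n_genes")
  if (cfg$n_stratum > cfg$n_resistance)
    stop("n_stratum must not exceed n_resistance")
  for (f in c("baseline_sd", "noise_sd", "clinical_noise_sd"))
    if (cfg[[f]] <= 0) stop(f, " must be positive")
  class(cfg) <- "generator_config"
  cfg
}

.transient_effect <- function(t, peak, t_peak, t_max, decay_floor) {
  ifelse(t <= 0, 0,
         ifelse(t <= t_peak, peak * t / t_peak,
                peak * (1 - (1 - decay_floor) * (t - t_peak) /
                          max(t_max - t_peak, 1e-9))))
}

.ramp_effect <- function(t, max_eff, t_max) {
  max_eff * pmin(1, pmax(t, 0) / t_max)
}

#' Simulate a drug-induced resistance cell-line experiment
#'
#' Generates a linear-scale expression matrix over the factorial
#' \{parental, resistant\} x \{untreated, treated at each positive time
#' point\} x replicates, with planted gene classes as described in
#' [generator_config()], together with the ground-truth table used by
#' recovery tests.
#'
#' @param config A [generator_config()].
#' @param drug Drug name written into the sample annotations and truth.
#' @param seed Seed for this experiment (defaults to `config$seed`).
#'
#' @return A list with `matrix` (a linear-scale [expression_matrix()])
#'   and `truth` (a data frame with `gene_id`, `class`, `direction`,
#'   `effect`, `stratum`, `baseline`, `drug`).
#' @export
generate_cellline_experiment <- function(config, drug = "5-FU",
                                         seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(as.integer(seed))
  G <- config$n_genes
  genes <- sprintf("g%05d", seq_len(G))
  perm <- sample.int(G)
  cls <- rep("null", G)
  res_idx <- perm[seq_len(config$n_resistance)]
  dr_idx <- perm[config$n_resistance + seq_len(config$n_drug_response)]
  ba_idx <- perm[config$n_resistance + config$n_drug_response +
                   seq_len(config$n_basal)]
  cls[res_idx] <- "resistance"
  cls[dr_idx] <- "drug_response"
  cls[ba_idx] <- "basal_difference"
  stratum <- rep(FALSE, G)
  stratum[res_idx[seq_len(config$n_stratum)]] <- TRUE

  baseline <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
  baseline[stratum] <- stats::rnorm(sum(stratum),
                                    config$stratum_baseline_mean,
                                    config$stratum_baseline_sd)
  sign_of <- function(n) sample(c(-1, 1), n, replace = TRUE)
  eff_sign <- rep(0, G)
  eff_sign[res_idx] <- sign_of(length(res_idx))
  eff_sign[dr_idx] <- sign_of(length(dr_idx))
  eff_sign[ba_idx] <- sign_of(length(ba_idx))
  eff_size <- rep(0, G)
  eff_size[res_idx] <- ifelse(stratum[res_idx], config$stratum_effect,
                              config$resistance_effect)
  eff_size[dr_idx] <- config$drug_response_peak
  eff_size[ba_idx] <- config$basal_effect

  t_max <- max(config$time_points)
  status <- c("parental", "resistant")
  cols <- expand.grid(rep = seq_len(config$n_replicates),
                      time = config$time_points, status = status,
                      stringsAsFactors = FALSE)
  nS <- nrow(cols)
  vals <- matrix(0, G, nS)
  for (j in seq_len(nS)) {
    st <- cols$status[j]; t <- cols$time[j]
    mu <- baseline
    is_res <- st == "resistant"
    treated <- t > 0
    if (is_res)
      mu[ba_idx] <- mu[ba_idx] + eff_sign[ba_idx] * config$basal_effect
    if (treated) {
      dr <- .transient_effect(t, config$drug_response_peak, config$t_peak,
                              t_max, config$decay_floor)
      mu[dr_idx] <- mu[dr_idx] + eff_sign[dr_idx] * dr
    }
    if (is_res) {
      sus <- config$sustained_fraction * config$drug_response_peak
      mu[dr_idx] <- mu[dr_idx] + eff_sign[dr_idx] * sus
    }
    if (is_res && treated) {
      ramp <- .ramp_effect(t, 1, t_max)
      mu[res_idx] <- mu[res_idx] +
        eff_sign[res_idx] * eff_size[res_idx] * ramp
    }
    vals[, j] <- mu + stats::rnorm(G, 0, config$noise_sd)
  }
  rownames(vals) <- genes
  ids <- sprintf("%s_%s_t%02d_r%d", substr(cols$status, 1, 3),
                 gsub("[^A-Za-z0-9]", "", drug), cols$time, cols$rep)
  colnames(vals) <- ids
  ann <- sample_annotations(
    sample_id = ids, cell_line = "synthetic",
    resistance_status = cols$status,
    drug = ifelse(cols$time > 0, drug, "none"),
    treatment_time_h = ifelse(cols$time > 0, cols$time, NA_real_),
    cohort = "cell_line", response = "n/a", dataset_id = "cellline")
  truth <- data.frame(gene_id = genes, class = cls,
                      direction = ifelse(eff_sign > 0, "up",
                                         ifelse(eff_sign < 0, "down",
                                                "none")),
                      effect = eff_size, stratum = stratum,
                      baseline = baseline, drug = drug,
                      stringsAsFactors = FALSE)
  list(matrix = expression_matrix(2 ^ vals, scale = "linear",
                                  samples = ann),
       truth = truth)
}

#' Simulate pre- and post-chemotherapy clinical cohorts
#'
#' Non-responder samples carry the planted resistance-gene effects of one
#' or more cell-line experiments (a regimen combining the corresponding
#' drugs), attenuated to tissue scale and multiplied by a per-patient
#' heterogeneity factor. Post-chemotherapy samples additionally carry the
#' sustained drug-response state in both groups. Multi-dataset cohorts
#' receive per-dataset gene-wise batch shifts.
#'
#' @param config A [generator_config()].
#' @param truths A truth data frame from
#'   [generate_cellline_experiment()], or a list of them (one per drug of
#'   the regimen).
#' @param seed Seed for the cohorts (defaults to `config$seed`).
#' @param n_responders,n_nonresponders,n_datasets Overrides of the
#'   config's pre-chemotherapy design (used for confirmation cohorts).
#' @param cohort Generate a `"pre_chemo"` or `"post_chemo"` cohort.
#'
#' @return A linear-scale [expression_matrix()] with clinical sample
#'   annotations.
#' @export
generate_clinical_cohort <- function(config, truths, seed = config$seed,
                                     n_responders = NULL,
                                     n_nonresponders = NULL,
                                     n_datasets = NULL,
                                     cohort = c("pre_chemo", "post_chemo")) {
  stopifnot(inherits(config, "generator_config"))
  cohort <- match.arg(cohort)
  if (is.data.frame(truths)) truths <- list(truths)
  set.seed(as.integer(seed))
  if (is.null(n_responders))
    n_responders <- if (cohort == "pre_chemo") config$n_responders
                    else config$n_responders_post
  if (is.null(n_nonresponders))
    n_nonresponders <- if (cohort == "pre_chemo") config$n_nonresponders
                       else config$n_nonresponders_post
  if (is.null(n_datasets))
    n_datasets <- if (cohort == "pre_chemo") config$n_datasets else 1L
  baseline <- truths[[1]]$baseline
  genes <- truths[[1]]$gene_id
  G <- length(genes)
  n_tot <- n_responders + n_nonresponders
  response <- c(rep("responder", n_responders),
                rep("non_responder", n_nonresponders))
  dataset <- paste0("D", rep_len(seq_len(n_datasets), n_tot))
  batch <- matrix(stats::rnorm(G * n_datasets, 0, config$batch_sd),
                  G, n_datasets)
  resistance_shift <- rep(0, G)
  for (tr in truths) {
    idx <- which(tr$class == "resistance")
    sgn <- ifelse(tr$direction[idx] == "up", 1, -1)
    resistance_shift[idx] <- resistance_shift[idx] +
      config$attenuation * tr$effect[idx] * sgn
  }
  treated_shift <- rep(0, G)
  if (cohort == "post_chemo") {
    for (tr in truths) {
      idx <- which(tr$class == "drug_response")
      sgn <- ifelse(tr$direction[idx] == "up", 1, -1)
      treated_shift[idx] <- treated_shift[idx] +
        config$sustained_fraction * config$drug_response_peak * sgn
    }
  }
  vals <- matrix(0, G, n_tot)
  het <- exp(stats::rnorm(n_tot, 0, config$heterogeneity_sd))
  for (j in seq_len(n_tot)) {
    mu <- baseline + treated_shift + batch[, match(dataset[j], unique(dataset))]
    if (response[j] == "non_responder")
      mu <- mu + het[j] * resistance_shift
    vals[, j] <- mu + stats::rnorm(G, 0, config$clinical_noise_sd)
  }
  rownames(vals) <- genes
  ids <- sprintf("%s_%s%02d", ifelse(response == "responder", "R", "NR"),
                 substr(cohort, 1, 3), seq_len(n_tot))
  colnames(vals) <- ids
  ann <- sample_annotations(sample_id = ids, cell_line = "",
                            resistance_status = "n/a", drug = "none",
                            treatment_time_h = NA_real_, cohort = cohort,
                            response = response, dataset_id = dataset)
  expression_matrix(2 ^ vals, scale = "linear", samples = ann)
}

#' @rdname generate_clinical_cohort
#' @details `generate_clinical_cohorts()` returns both cohorts at once as
#'   a list with elements `pre_chemo` and `post_chemo` (seeds `seed` and
#'   `seed + 1`).
#' @export
generate_clinical_cohorts <- function(config, truths, seed = config$seed) {
  list(pre_chemo = generate_clinical_cohort(config, truths, seed,
                                            cohort = "pre_chemo"),
       post_chemo = generate_clinical_cohort(config, truths, seed + 1,
                                             cohort = "post_chemo"))
}
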