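#' Configuration for the synthetic sepsis cohort generator
#'
#' Defines the statistical structure of a simulated multi-site bulk RNA-seq
#' sepsis cohort: four latent endotypes of differing 28-day mortality, an
#' endotype-specific up-regulated gene module per endotype, a set of
#' mortality-associated (prognostic) genes coupled to a latent per-patient
#' risk score, negative-binomial counts with a dispersion-mean trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}, lognormal library sizes with site-level
#' offsets, and a 0-3 clinical severity score of controlled discrimination.
#'
#' @param n_patients number of patients (default 500).
#' @param n_sites number of study sites.
#' @param site_proportions probability vector of site membership.
#' @param n_genes_expressed expressed (analysable) genes.
#' @param n_low_expression_genes genes kept below the mean-CPM-10 filter line.
#' @param n_sex_linked_genes genes placed on chromosomes X/Y.
#' @param endotype_proportions probability vector over the four endotypes.
#' @param endotype_mortality marginal 28-day mortality per endotype.
#' @param module_size_per_endotype genes per endotype module.
#' @param module_log2_effect log2 up-shift of module genes in their endotype.
#' @param n_prognostic_genes mortality-coupled genes (half up, half down in
#'   non-survivors).
#' @param prognostic_log2_effect log2 shift per unit of latent risk.
#' @param mortality_latent_slope slope of the latent risk score on the logit
#'   of death; 1.5 puts the oracle risk AUROC near 0.82 so a gene-panel
#'   readout lands around 0.8.
#' @param clinical_score_auroc_target discrimination (AUROC) the simulated
#'   clinical severity score is calibrated to, in (0.5, 1).
#' @param dispersion_trend length-2 vector `(a0, a1)` of the NB
#'   dispersion-mean trend.
#' @param library_size_logmean,library_size_logsd lognormal library sizes.
#' @param site_libsize_factor multiplicative library-size offset per site
#'   (site effects default to sequencing depth only, no expression batch).
#' @param site_batch_log2_shift optional per-site expression shift (log2)
#'   applied to all expressed genes; default 0 (no batch effect).
#' @param mcar_rate fraction of clinical laboratory values masked completely
#'   at random.
#' @param seed integer seed for the single RNG stream all draws flow from.
#' @return A validated list of class `endosep_sim_config`.
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_patients = 500,
                       n_sites = 3,
                       site_proportions = rep(1 / n_sites, n_sites),
                       n_genes_expressed = 3000,
                       n_low_expression_genes = 300,
                       n_sex_linked_genes = 100,
                       endotype_proportions = c(0.20, 0.20, 0.20, 0.40),
                       endotype_mortality = c(0.22, 0.22, 0.20, 0.11),
                       module_size_per_endotype = 50,
                       module_log2_effect = 1.0,
                       n_prognostic_genes = 25,
                       prognostic_log2_effect = 0.8,
                       mortality_latent_slope = 1.5,
                       clinical_score_auroc_target = 0.72,
                       dispersion_trend = c(a0 = 0.05, a1 = 2),
                       library_size_logmean = log(5e6),
                       library_size_logsd = 0.3,
                       site_libsize_factor = NULL,
                       site_batch_log2_shift = rep(0, n_sites),
                       mcar_rate = 0,
                       seed = 1L) {
  for (nm in c("n_patients", "n_sites", "n_genes_expressed",
               "n_low_expression_genes", "n_sex_linked_genes",
               "module_size_per_endotype", "n_prognostic_genes")) {
    abort_if(!is_count(get(nm)), "`%s` must be a positive integer.", nm)
  }
  check_prob_vector(site_proportions, "site_proportions", n_sites)
  check_prob_vector(endotype_proportions, "endotype_proportions", 4L)
  abort_if(length(endotype_mortality) != 4 ||
             any(endotype_mortality <= 0 | endotype_mortality >= 1),
           "`endotype_mortality` must be 4 probabilities strictly in (0, 1).")
  abort_if(length(dispersion_trend) != 2 || any(dispersion_trend <= 0),
           "`dispersion_trend` must be two positive numbers (a0, a1).")
  abort_if(clinical_score_auroc_target <= 0.5 || clinical_score_auroc_target >= 1,
           "`clinical_score_auroc_target` must lie in (0.5, 1).")
  abort_if(module_log2_effect < 0 || prognostic_log2_effect < 0,
           "effect sizes must be non-negative.")
  abort_if(4 * module_size_per_endotype + n_prognostic_genes > n_genes_expressed,
           "module and prognostic genes exceed `n_genes_expressed`.")
  if (is.null(site_libsize_factor)) {
    site_libsize_factor <- exp(seq(-0.15, 0.15, length.out = n_sites))
  }
  abort_if(length(site_libsize_factor) != n_sites || any(site_libsize_factor <= 0),
           "`site_libsize_factor` must be %d positive numbers.", n_sites)
  abort_if(length(site_batch_log2_shift) != n_sites,
           "`site_batch_log2_shift` must have length %d.", n_sites)
  abort_if(mcar_rate < 0 || mcar_rate >= 1, "`mcar_rate` must be in [0, 1).")
  structure(list(
    n_patients = as.integer(n_patients), n_sites = as.integer(n_sites),
    site_proportions = as.numeric(site_proportions),
    n_genes_expressed = as.integer(n_genes_expressed),
    n_low_expression_genes = as.integer(n_low_expression_genes),
    n_sex_linked_genes = as.integer(n_sex_linked_genes),
    endotype_proportions = as.numeric(endotype_proportions),
    endotype_mortality = as.numeric(endotype_mortality),
    module_size_per_endotype = as.integer(module_size_per_endotype),
    module_log2_effect = module_log2_effect,
    n_prognostic_genes = as.integer(n_prognostic_genes),
    prognostic_log2_effect = prognostic_log2_effect,
    mortality_latent_slope = mortality_latent_slope,
    clinical_score_auroc_target = clinical_score_auroc_target,
    dispersion_trend = stats::setNames(as.numeric(dispersion_trend), c("a0", "a1")),
    library_size_logmean = library_size_logmean,
    library_size_logsd = library_size_logsd,
    site_libsize_factor = as.numeric(site_libsize_factor),
    site_batch_log2_shift = as.numeric(site_batch_log2_shift),
    mcar_rate = mcar_rate,
    seed = as.integer(seed)), class = "endosep_sim_config")
}

# endotype intercept so that E_u[ plogis(b0 + gamma * u) ] = target, u ~ N(0,1)
solve_mortality_intercept <- function(target, gamma) {
  marginal <- function(b) {
    stats::integrate(function(u) stats::plogis(b + gamma * u) * stats::dnorm(u),
                     -8, 8)$value
  }
  stats::uniroot(function(b) marginal(b) - target, c(-15, 10), tol = 1e-8)$root
}

#' Simulate a synthetic sepsis cohort with known ground truth
#'
#' Draws a genes-by-patients count matrix, a clinical cohort table and the
#' generating ground truth under the model described in [sim_config()].
#' Counts for gene \eqn{g}, patient \eqn{j} are negative binomial with mean
#' \eqn{s_j \mu_g 2^{\Delta_{gj}}}, where \eqn{\Delta_{gj}} accumulates the
#' endotype-module shift, the prognostic-gene coupling to the latent risk
#' score, and sex-linked shifts; the dispersion follows
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}. Death is Bernoulli on a logistic model
#' with per-endotype intercepts solved numerically so each endotype's
#' marginal mortality matches the configured value.
#'
#' @param config a [sim_config()].
#' @return A list of class `endosep_cohort` with elements
#'   \describe{
#'     \item{counts}{a [count_matrix()] (genes x patients).}
#'     \item{cohort}{tibble: `patient_id`, `site`, `sex`, `age`, `death28`
#'       (0/1), `qsofa` (0-3), and laboratory values `lactate`, `wbc`, `bun`,
#'       `lymphocyte_pct`, `spo2`.}
#'     \item{truth}{list of class `endosep_truth`: `endotype` (1..4 per
#'       patient), `module_genes` (4 gene-id sets), `prognostic` (tibble of
#'       gene_id, sign, effect), `death_probability`, `size_factor_true`,
#'       `latent_risk`, `death`.}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_patients = 60, n_genes_expressed = 300,
#'                                      module_size_per_endotype = 10,
#'                                      n_prognostic_genes = 8,
#'                                      n_low_expression_genes = 30,
#'                                      n_sex_linked_genes = 10, seed = 7))
#' table(cohort$truth$endotype)
#' @export
simulate_cohort <- function(config = sim_config()) {
  abort_if(!inherits(config, "endosep_sim_config"),
           "`config` must come from sim_config().")
  set.seed(config$seed)
  n <- config$n_patients
  a0 <- config$dispersion_trend[["a0"]]
  a1 <- config$dispersion_trend[["a1"]]

  ## ---- genes -------------------------------------------------------------
  n_expr <- config$n_genes_expressed
  n_low <- config$n_low_expression_genes
  n_sex <- config$n_sex_linked_genes
  n_genes <- n_expr + n_low + n_sex
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  class_of <- rep(c("expressed", "low", "sex_linked"), c(n_expr, n_low, n_sex))

  chromosome <- character(n_genes)
  chromosome[class_of == "expressed"] <- sample(as.character(1:22), n_expr, replace = TRUE)
  # a slice of the low-expression genes is left unannotated to exercise the
  # not-mapping-to-known-genes filter
  low_chr <- sample(c(as.character(1:22), NA_character_), n_low,
                    replace = TRUE, prob = c(rep(0.85 / 22, 22), 0.15))
  chromosome[class_of == "low"] <- low_chr
  chromosome[class_of == "sex_linked"] <-
    sample(c("X", "Y"), n_sex, replace = TRUE, prob = c(0.6, 0.4))

  # baseline abundance in CPM units; low-expression genes are pegged in final
  # CPM units (well under the mean-CPM-10 filter), the rest rescaled to fill
  # the remaining library share
  base_cpm <- numeric(n_genes)
  base_cpm[class_of == "expressed"] <- stats::rlnorm(n_expr, log(80), 1.1)
  base_cpm[class_of == "low"] <- stats::runif(n_low, 0.1, 3)
  base_cpm[class_of == "sex_linked"] <- stats::rlnorm(n_sex, log(60), 1.0)
  is_low <- class_of == "low"
  base_cpm[!is_low] <- base_cpm[!is_low] / sum(base_cpm[!is_low]) *
    (1e6 - sum(base_cpm[is_low]))

  expr_ids <- gene_id[class_of == "expressed"]
  special <- sample(expr_ids, 4 * config$module_size_per_endotype +
                      config$n_prognostic_genes)
  module_genes <- split(special[seq_len(4 * config$module_size_per_endotype)],
                        rep(1:4, each = config$module_size_per_endotype))
  names(module_genes) <- paste0("endotype", 1:4)
  prog_ids <- special[-seq_len(4 * config$module_size_per_endotype)]
  prog_sign <- rep(c(1, -1), length.out = config$n_prognostic_genes)
  prognostic <- tibble::tibble(gene_id = prog_ids, sign = prog_sign,
                               effect = prog_sign * config$prognostic_log2_effect)

  ## ---- patients ----------------------------------------------------------
  patient_id <- sprintf("P%04d", seq_len(n))
  site <- paste0("site_", sample.int(config$n_sites, n, replace = TRUE,
                                     prob = config$site_proportions))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- pmin(pmax(round(stats::rnorm(n, 50, 16)), 18), 95)
  endotype <- sample.int(4L, n, replace = TRUE, prob = config$endotype_proportions)
  latent_risk <- stats::rnorm(n)
  site_idx <- as.integer(sub("site_", "", site))
  lib_size <- stats::rlnorm(n, config$library_size_logmean, config$library_size_logsd) *
    config$site_libsize_factor[site_idx]
  size_factor_true <- lib_size / geometric_mean(lib_size)

  ## ---- mortality ---------------------------------------------------------
  gamma <- config$mortality_latent_slope
  b0 <- vapply(config$endotype_mortality, solve_mortality_intercept,
               numeric(1), gamma = gamma)
  death_probability <- stats::plogis(b0[endotype] + gamma * latent_risk)
  death <- stats::rbinom(n, 1L, death_probability)

  ## ---- log2 shift matrix -------------------------------------------------
  delta <- matrix(0, n_genes, n, dimnames = list(gene_id, patient_id))
  for (k in 1:4) {
    in_k <- endotype == k
    if (any(in_k)) {
      delta[module_genes[[k]], in_k] <- delta[module_genes[[k]], in_k] +
        config$module_log2_effect
    }
  }
  delta[prog_ids, ] <- delta[prog_ids, ] +
    outer(prognostic$effect, latent_risk)
  is_f <- sex == "F"
  x_genes <- chromosome == "X" & !is.na(chromosome)
  y_genes <- chromosome == "Y" & !is.na(chromosome)
  delta[x_genes, is_f] <- delta[x_genes, is_f] + 0.3
  delta[y_genes, is_f] <- delta[y_genes, is_f] - 6      # Y silenced in females
  if (any(config$site_batch_log2_shift != 0)) {
    delta <- delta + matrix(config$site_batch_log2_shift[site_idx],
                            n_genes, n, byrow = TRUE)
  }

  ## ---- counts ------------------------------------------------------------
  mu <- (base_cpm / 1e6) * outer(rep(1, n_genes), lib_size) * 2^delta
  alpha <- a0 + a1 / pmax(mu, 1e-8)
  counts <- matrix(stats::rnbinom(length(mu), size = 1 / alpha, mu = mu),
                   n_genes, n, dimnames = list(gene_id, patient_id))

  ## ---- clinical table ----------------------------------------------------
  u <- latent_risk
  lab_noise <- function(sd) stats::rnorm(n, 0, sd)
  lactate <- exp(0.55 + 0.35 * u + lab_noise(0.45))
  wbc <- exp(2.35 + 0.22 * u + lab_noise(0.35))
  bun <- exp(2.85 + 0.40 * u + lab_noise(0.50))
  lymphocyte_pct <- 100 * stats::plogis(-1.1 - 0.45 * u + lab_noise(0.6))
  spo2 <- pmin(100, 97 - 1.8 * pmax(u, 0) + lab_noise(1.5))

  truth <- structure(list(
    endotype = stats::setNames(endotype, patient_id),
    module_genes = module_genes,
    prognostic = prognostic,
    death_probability = stats::setNames(death_probability, patient_id),
    size_factor_true = stats::setNames(size_factor_true, patient_id),
    latent_risk = stats::setNames(latent_risk, patient_id),
    death = stats::setNames(death, patient_id)), class = "endosep_truth")

  qsofa <- simulate_clinical_score(truth, config)

  cohort <- tibble::tibble(
    patient_id = patient_id, site = site, sex = sex, age = age,
    death28 = death, qsofa = qsofa,
    lactate = lactate, wbc = wbc, bun = bun,
    lymphocyte_pct = lymphocyte_pct, spo2 = spo2)
  if (config$mcar_rate > 0) {
    for (lab in c("lactate", "wbc", "bun", "lymphocyte_pct", "spo2")) {
      cohort[[lab]][stats::runif(n) < config$mcar_rate] <- NA_real_
    }
  }

  genes <- tibble::tibble(gene_id = gene_id, chromosome = chromosome,
                          class = class_of, base_cpm = base_cpm)
  structure(list(counts = count_matrix(counts, genes[, c("gene_id", "chromosome")]),
                 genes = genes, cohort = cohort, truth = truth,
                 config = config),
            class = "endosep_cohort")
}

#' Simulate a bedside clinical severity score of controlled discrimination
#'
#' Produces a 0-3 integer score (qSOFA-like) as a discretized noisy monotone
#' transform of each patient's true death probability, calibrated against the
#' realized deaths so the empirical AUROC matches
#' `config$clinical_score_auroc_target`. When the target exceeds what the
#' true risk itself can discriminate (deaths are stochastic given risk), the
#' calibration instead mixes outcome signal into the latent score; pure noise
#' and near-perfect separation are the two ends of the same calibration path.
#'
#' @param truth an `endosep_truth` (needs `death_probability` and `death`).
#' @param config a [sim_config()]; only the AUROC target is used.
#' @return Integer vector of scores 0-3, named by patient.
#' @export
simulate_clinical_score <- function(truth, config) {
  target <- config$clinical_score_auroc_target
  abort_if(target <= 0.5 || target >= 1,
           "clinical score AUROC target must be in (0.5, 1).")
  p <- truth$death_probability
  y <- truth$death
  abort_if(is.null(p) || is.null(y), "truth must carry death_probability and death.")
  n <- length(p)
  z <- as.numeric(scale(stats::qlogis(p)))
  eps <- stats::rnorm(n)
  cuts_at <- c(0.45, 0.75, 0.92)
  discretize <- function(lat) {
    cuts <- stats::quantile(lat, cuts_at, names = FALSE, type = 7)
    findInterval(lat, cuts)
  }
  # calibration path: outcome-weighted (w < 0) ... pure risk (0) ... noisy (w > 0)
  grid <- c(-seq(12, 0.25, length.out = 30), 0,
            exp(seq(log(0.02), log(60), length.out = 60)))
  scores <- vapply(grid, function(w) {
    lat <- if (w < 0) z - w * y else z + w * eps
    auroc(discretize(lat), y)
  }, numeric(1))
  w_star <- grid[which.min(abs(scores - target))]
  lat <- if (w_star < 0) z - w_star * y else z + w_star * eps
  stats::setNames(as.integer(discretize(lat)), names(p))
}
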