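#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [sim_config()]) or `input` (paths to
#' `counts_tsv`, `genes_tsv`, `cohort_csv`) must be given.
#'
#' @param simulation a [sim_config()], or `NULL` when reading from files.
#' @param input named list of file paths, or `NULL` when simulating.
#' @param mapper a [mapper_config()].
#' @param models list: `repeats`, `folds`, `mrmr_m`, `max_features`.
#' @param enrichment list: `n_perm`, `min_size`, `max_size`, `p_cutoff`,
#'   optional `gmt` path (defaults to a bundled synthetic collection).
#' @param cpm_threshold gene filter threshold.
#' @param min_deaths merge threshold for low-mortality groups.
#' @param out_dir output directory for the report bundle (`NULL` = don't
#'   write files).
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @return List of class `endosep_pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(), input = NULL,
                            mapper = mapper_config(),
                            models = list(), enrichment = list(),
                            cpm_threshold = 10, min_deaths = 10,
                            out_dir = NULL, seed = 1L) {
  abort_if(is.null(simulation) == is.null(input),
           "give exactly one of `simulation` or `input`.")
  models <- utils::modifyList(
    list(repeats = 10L, folds = 10L, mrmr_m = 50L, max_features = 50L), models)
  enrichment <- utils::modifyList(
    list(n_perm = 1000L, min_size = 5L, max_size = 500L, p_cutoff = 1,
         gmt = NULL), enrichment)
  structure(list(simulation = simulation, input = input, mapper = mapper,
                 models = models, enrichment = enrichment,
                 cpm_threshold = cpm_threshold, min_deaths = min_deaths,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "endosep_pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
                 parent = e)
  })
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[endosep] ", fmt), ...))

#' Run the full endotype-discovery and prognosis pipeline
#'
#' Stage order: ingest or simulate counts; filter genes; median-of-ratios
#' size factors; VST; full-cohort mortality differential expression; mRMR
#' ranking; step-up panel sizing; comparison against the clinical score;
#' mapper construction and group extraction (with low-mortality merging);
#' per-group differential expression and stratified models; preranked
#' enrichment of the full-cohort and group contrasts; clinical-feature
#' comparisons; heatmap row ordering; report bundle.
#'
#' @param cfg a [pipeline_config()].
#' @return List of class `endosep_report` with all stage outputs and a
#'   `manifest`; written to `cfg$out_dir` as TSV/JSON/GraphML when set.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  abort_if(!inherits(cfg, "endosep_pipeline_config"),
           "`cfg` must come from pipeline_config().")
  seed <- cfg$seed

  sim <- NULL
  if (!is.null(cfg$simulation)) {
    simcfg <- cfg$simulation
    simcfg$seed <- derive_seed(seed, "simulate")
    sim <- stage("simulate", simulate_cohort(simcfg))
    counts <- sim$counts; cohort <- sim$cohort
    log_stage("simulated %d genes x %d patients", nrow(counts), ncol(counts))
  } else {
    counts <- stage("ingest", read_count_matrix(cfg$input$counts_tsv, cfg$input$genes_tsv))
    cohort <- stage("ingest", read_cohort_table(cfg$input$cohort_csv))
    log_stage("read %d genes x %d patients", nrow(counts), ncol(counts))
  }

  prep <- stage("preprocess", preprocess_counts(counts, cfg$cpm_threshold))
  expr <- prep$expr
  log_stage("preprocessing yielded %d genes for %d patients",
            nrow(expr), ncol(expr))

  y <- cohort$death28[match(colnames(expr), cohort$patient_id)]
  de_full <- stage("de_full", de_table(expr, y))
  n_sig <- sum(de_full$p_adjusted <= 0.05)
  log_stage("full-cohort DE: %d genes at p_adjusted <= 0.05", n_sig)

  X <- t(expr)
  candidates <- de_full$gene_id[de_full$p_adjusted <= 0.05]
  if (length(candidates) < cfg$models$mrmr_m) {
    candidates <- de_full$gene_id[de_full$p_value <= 0.05]
  }
  if (length(candidates) < cfg$models$mrmr_m) candidates <- de_full$gene_id
  mrmr <- stage("mrmr", mrmr_rank(X, y, m = cfg$models$mrmr_m, candidates = candidates))
  log_stage("mRMR ranked %d of %d candidate genes", nrow(mrmr), length(candidates))

  model_seed <- derive_seed(seed, "models")
  stepup <- stage("stepup", stepup_select(
    X, y, mrmr$gene_id, max_n = cfg$models$max_features,
    repeats = cfg$models$repeats, folds = cfg$models$folds, seed = model_seed))
  log_stage("step-up panel size: %d transcripts", stepup$n_star)

  clinical <- cohort$qsofa[match(rownames(X), cohort$patient_id)]
  model_full <- stage("clinical_comparison", compare_with_clinical_score(
    X, y, stepup$features, clinical,
    repeats = cfg$models$repeats, folds = cfg$models$folds, seed = model_seed))
  log_stage("panel AUROC %.3f +/- %.3f vs clinical score %.3f +/- %.3f",
            model_full$auroc_mean, model_full$auroc_sd,
            model_full$comparator_auroc_mean, model_full$comparator_auroc_sd)

  groups <- stage("mapper", mapper_endotypes(expr, cfg$mapper, cohort))
  groups <- stage("merge_groups", merge_low_mortality(groups, cohort, cfg$min_deaths))
  log_stage("mapper: %d groups, shared fraction %.3f",
            length(groups$groups), groups$shared_fraction)

  de_within <- list(); de_between <- list()
  excl <- exclusive_members(groups)
  for (g in names(groups$groups)) {
    ids <- names(excl)[excl == g]
    ids <- ids[ids %in% colnames(expr)]
    yg <- cohort$death28[match(ids, cohort$patient_id)]
    if (sum(yg == 1, na.rm = TRUE) >= 2 && sum(yg == 0, na.rm = TRUE) >= 2) {
      de_within[[g]] <- stage("de_within", de_table(expr[, ids, drop = FALSE], yg))
    }
    others <- setdiff(names(groups$groups), g)
    de_between[[g]] <- stage("de_between",
                             contrast_between_groups(expr, groups, g, others))
  }

  strat <- stage("stratified_models", stratified_models(
    X, y, groups, mrmr$gene_id, max_n = cfg$models$max_features,
    repeats = cfg$models$repeats, folds = cfg$models$folds,
    seed = model_seed, clinical = clinical))
  log_stage("stratified models: %d groups modelled, %d union features",
            length(strat$reports), length(strat$union_features))

  collection <- if (!is.null(cfg$enrichment$gmt)) {
    stage("enrichment", read_gmt(cfg$enrichment$gmt))
  } else if (!is.null(sim)) {
    synthetic_gene_sets(sim, seed = derive_seed(seed, "genesets"))
  } else {
    synthetic_gene_sets(rownames(expr), seed = derive_seed(seed, "genesets"))
  }
  gsea_seed <- derive_seed(seed, "gsea")
  run_gsea <- function(de, mode) {
    rk <- tryCatch(rank_genes(de, mode), error = function(e) NULL)
    if (is.null(rk)) return(NULL)
    tryCatch(gsea_preranked(rk, collection, n_perm = cfg$enrichment$n_perm,
                            min_size = cfg$enrichment$min_size,
                            max_size = cfg$enrichment$max_size,
                            p_cutoff = cfg$enrichment$p_cutoff, seed = gsea_seed),
             error = function(e) NULL)
  }
  enrich <- list(full_cohort = stage("enrichment", run_gsea(de_full, "all")))
  for (g in names(de_within)) enrich[[paste0("within_", g)]] <-
    stage("enrichment", run_gsea(de_within[[g]], "all"))
  for (g in names(de_between)) enrich[[paste0("between_", g)]] <-
    stage("enrichment", run_gsea(de_between[[g]], "significant_only"))
  log_stage("enrichment: %d contrasts analysed", sum(!vapply(enrich, is.null, logical(1))))

  clin_cmp <- stage("clinical_features", clinical_compare(cohort, groups))

  # heatmap row order over the union of top DE genes across contrasts
  top_ids <- unique(unlist(lapply(c(list(de_full), de_between), function(d) {
    utils::head(d$gene_id, 25)
  })))
  l2fc_mat <- do.call(cbind, c(
    list(full_cohort = de_full$l2fc[match(top_ids, de_full$gene_id)]),
    lapply(de_between, function(d) d$l2fc[match(top_ids, d$gene_id)])))
  rownames(l2fc_mat) <- top_ids
  l2fc_mat[is.na(l2fc_mat)] <- 0
  heat_order <- stage("heatmap", order_rows_for_heatmap(l2fc_mat, "manhattan", "mcquitty"))

  manifest <- build_manifest(cfg)
  report <- structure(list(
    sim = sim, cohort = cohort, prep = prep, de_full = de_full, mrmr = mrmr,
    stepup = stepup, model_full = model_full, groups = groups,
    de_within = de_within, de_between = de_between, stratified = strat,
    enrichment = enrich, clinical = clin_cmp,
    heatmap = list(matrix = l2fc_mat, row_order = heat_order),
    manifest = manifest), class = "endosep_report")
  if (!is.null(cfg$out_dir)) write_report_bundle(report, cfg$out_dir)
  report
}

config_for_manifest <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(cfg)
}

build_manifest <- function(cfg) {
  hashable <- config_for_manifest(cfg)
  hashable$out_dir <- NULL      # hash covers the analysis, not where it lands
  cfg_json <- jsonlite::toJSON(hashable, auto_unbox = TRUE,
                               digits = NA, null = "null")
  list(config = config_for_manifest(cfg), seed = cfg$seed,
       config_hash = sprintf("%.0f", fnv1a32(as.character(cfg_json))),
       package_version = as.character(utils::packageVersion("endosep")),
       r_version = R.version.string)
}

write_tsv <- function(d, path) {
  d <- as.data.frame(lapply(d, function(col) {
    if (is.list(col)) vapply(col, function(x) paste(unlist(x), collapse = ","), character(1))
    else col
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write the report bundle to disk
#'
#' DE tables, group assignments, mapper graph (GraphML + JSON), model
#' reports (JSON), enrichment tables, heatmap row order, and the run
#' manifest.
#'
#' @param report an `endosep_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(report$de_full, file.path(dir, "de_full_cohort.tsv"))
  for (g in names(report$de_within))
    write_tsv(report$de_within[[g]], file.path(dir, sprintf("de_within_%s.tsv", g)))
  for (g in names(report$de_between))
    write_tsv(report$de_between[[g]], file.path(dir, sprintf("de_between_%s.tsv", g)))
  grp <- tibble::tibble(patient_id = names(report$groups$exclusive),
                        group = unname(report$groups$exclusive))
  grp$exclusive <- grp$group != "shared"
  write_tsv(grp, file.path(dir, "groups.tsv"))
  g_ig <- mapper_igraph(report$groups$graph)
  igraph::write_graph(g_ig, file.path(dir, "mapper_graph.graphml"), format = "graphml")
  jsonlite::write_json(list(nodes = report$groups$graph$nodes,
                            edges = report$groups$graph$edges),
                       file.path(dir, "mapper_graph.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(report$model_full), file.path(dir, "model_full.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(report$stratified$reports, unclass),
                       file.path(dir, "models_groups.json"), auto_unbox = TRUE, digits = NA)
  for (nm in names(report$enrichment)) {
    if (!is.null(report$enrichment[[nm]]))
      write_tsv(report$enrichment[[nm]], file.path(dir, sprintf("enrichment_%s.tsv", nm)))
  }
  write_tsv(tibble::tibble(row = rownames(report$heatmap$matrix)[report$heatmap$row_order],
                           position = seq_along(report$heatmap$row_order)),
            file.path(dir, "heatmap_row_order.tsv"))
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Heatmap row ordering by hierarchical clustering
#'
#' Manhattan distance with McQuitty (WPGMA) or Ward linkage; returns the
#' dendrogram leaf order.
#'
#' @param m numeric matrix (rows to order), no missing values.
#' @param distance `"manhattan"`.
#' @param linkage `"mcquitty"` or `"ward"` (Ward's D).
#' @return Integer vector of row indices in leaf order.
#' @export
order_rows_for_heatmap <- function(m, distance = c("manhattan"),
                                   linkage = c("mcquitty", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  abort_if(nrow(m) < 2, "need at least 2 rows.")
  abort_if(any(!is.finite(m)), "matrix contains missing or non-finite values.")
  hc <- stats::hclust(stats::dist(m, method = distance),
                      method = if (linkage == "ward") "ward.D" else "mcquitty")
  hc$order
}

#' @export
print.endosep_report <- function(x, ...) {
  cat("<endosep_report>\n")
  cat(sprintf("  %d genes x %d patients after preprocessing\n",
              nrow(x$prep$expr), ncol(x$prep$expr)))
  cat(sprintf("  panel: %d transcripts, AUROC %.3f +/- %.3f (clinical %.3f +/- %.3f)\n",
              x$stepup$n_star, x$model_full$auroc_mean, x$model_full$auroc_sd,
              x$model_full$comparator_auroc_mean, x$model_full$comparator_auroc_sd))
  cat(sprintf("  %d endotype groups, shared fraction %.3f\n",
              length(x$groups$groups), x$groups$shared_fraction))
  invisible(x)
}
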