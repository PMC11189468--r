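#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs ranked concordantly, counting ties
#' as half.
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels binary outcome (0/1 or logical); both classes required.
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0))
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  abort_if(length(scores) != length(y), "`scores` and `labels` lengths differ.")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  abort_if(n1 == 0 || n0 == 0, "both outcome classes must be present.")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Minimum-redundancy maximum-relevance gene ranking
#'
#' Greedy forward selection for continuous features against a binary
#' outcome. Relevance is the one-way ANOVA F statistic of the feature
#' against the outcome, z-scored across the candidates once at the start;
#' redundancy of a candidate is the mean absolute Pearson correlation with
#' the already-selected features; the selection score is their difference.
#' The first pick is the most relevant feature; ties break on gene id.
#'
#' @param X patients-by-genes numeric matrix with column names.
#' @param y binary outcome along the rows.
#' @param m number of genes to return (default 50).
#' @param candidates subset of column names to rank (default all).
#' @return Tibble in selection order: `gene_id`, `rank`, `relevance_f`,
#'   `relevance_z`, `redundancy`, `score`.
#' @export
mrmr_rank <- function(X, y, m = 50, candidates = colnames(X)) {
  abort_if(length(candidates) < 1, "need at least one candidate gene.")
  abort_if(!all(candidates %in% colnames(X)), "unknown candidate gene ids.")
  y <- as.integer(as.logical(y))
  abort_if(length(unique(y)) < 2, "both outcome classes must be present.")
  Xc <- X[, candidates, drop = FALSE]
  sds <- apply(Xc, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::warn(sprintf("dropping %d constant candidate column(s).", sum(sds == 0)))
    Xc <- Xc[, sds > 0, drop = FALSE]
  }
  abort_if(ncol(Xc) == 0, "all candidate columns are constant.")
  n <- nrow(Xc)
  # one-way ANOVA F with two groups, vectorized over genes
  n1 <- sum(y == 1); n0 <- n - n1
  m1 <- colMeans(Xc[y == 1, , drop = FALSE])
  m0 <- colMeans(Xc[y == 0, , drop = FALSE])
  gm <- colMeans(Xc)
  ssb <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  sst <- colSums(sweep(Xc, 2, gm)^2)
  ssw <- pmax(sst - ssb, .Machine$double.eps)
  f_stat <- (ssb / 1) / (ssw / (n - 2))
  rel_z <- as.numeric(scale(f_stat))
  if (any(!is.finite(rel_z))) rel_z <- rep(0, length(f_stat))  # all-equal F
  names(rel_z) <- names(f_stat) <- colnames(Xc)

  m_out <- min(m, ncol(Xc))
  ids <- colnames(Xc)
  Xs <- scale(Xc)   # unit-variance columns so redundancy is a plain crossprod
  selected <- character(0)
  red_sum <- stats::setNames(rep(0, length(ids)), ids)
  rows <- vector("list", m_out)
  remaining <- ids
  for (step in seq_len(m_out)) {
    red <- if (step == 1) red_sum[remaining] * 0 else red_sum[remaining] / (step - 1)
    score <- rel_z[remaining] - red
    pick <- remaining[order(-score, remaining)][1]
    rows[[step]] <- tibble::tibble(
      gene_id = pick, rank = step, relevance_f = unname(f_stat[pick]),
      relevance_z = unname(rel_z[pick]), redundancy = unname(red[pick]),
      score = unname(score[pick]))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining)) {
      r_new <- abs(crossprod(Xs[, remaining, drop = FALSE], Xs[, pick])) / (n - 1)
      red_sum[remaining] <- red_sum[remaining] + as.numeric(r_new)
    }
  }
  dplyr::bind_rows(rows)
}

# ridge-penalized logistic regression by Newton iterations.
# Penalty 0.5 * lambda * ||beta||^2, intercept unpenalized; features are
# standardized by the caller. Iteration cap mirrors a max_iter of 1000.
ridge_logistic <- function(X, y, lambda = 1, maxit = 1000, tol = 1e-8) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X1, y - mu)) - pen %*% beta
    hess <- crossprod(X1 * w, X1) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

# deterministic stratified fold assignment keyed by patient id + seed + repeat,
# so subsetting the patients preserves comparability across models
fold_assignments <- function(ids, y, repeats, folds, seed) {
  y <- as.integer(as.logical(y))
  lapply(seq_len(repeats), function(r) {
    u <- hash_unit(paste(ids, seed, r, sep = "|"))
    f <- integer(length(ids))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      ord <- idx[order(u[idx], ids[idx])]
      f[ord] <- (seq_along(ord) - 1L) %% folds + 1L
    }
    f
  })
}

#' Repeated stratified cross-validated AUROC of a ridge logistic model
#'
#' Repeated stratified k-fold cross-validation: in each fold a
#' ridge-penalized logistic model (unit penalty, intercept unpenalized,
#' features standardized on the training split only, Newton iterations
#' capped at 1000) is fit on the training split and scored by AUROC on the
#' held-out split. Fold membership is derived from a hash of patient id,
#' seed and repeat, making it reproducible and invariant to row order.
#'
#' @param X patients-by-genes matrix with row names (patient ids).
#' @param y binary outcome along rows.
#' @param features column names to use.
#' @param repeats,folds cross-validation design (default 10 x 10).
#' @param seed integer driving the fold hash.
#' @return List: `mean`, `sd`, `fold_scores` (length `repeats * folds`),
#'   `fold_ids` (list of per-repeat assignments), `n`.
#' @export
cv_auroc <- function(X, y, features, repeats = 10, folds = 10, seed = 1L) {
  abort_if(is.null(rownames(X)), "`X` needs patient ids as row names.")
  abort_if(!all(features %in% colnames(X)), "unknown feature ids.")
  y <- as.integer(as.logical(y))
  abort_if(min(table(y)) < folds,
           "smallest class (%d) is below the number of folds (%d).",
           min(table(y)), folds)
  ids <- rownames(X)
  ord <- order(ids)           # canonical patient order
  X <- X[ord, features, drop = FALSE]; y <- y[ord]; ids <- ids[ord]
  assign <- fold_assignments(ids, y, repeats, folds, seed)
  scores <- numeric(0)
  for (r in seq_len(repeats)) {
    f <- assign[[r]]
    for (k in seq_len(folds)) {
      tr <- f != k
      mu <- colMeans(X[tr, , drop = FALSE])
      sdv <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sdv, "/")
      beta <- ridge_logistic(Xtr, y[tr])
      pred <- drop(cbind(1, Xte) %*% beta)
      scores <- c(scores, auroc(pred, y[!tr]))
    }
  }
  list(mean = mean(scores), sd = stats::sd(scores), fold_scores = scores,
       fold_ids = assign, n = length(y))
}

#' Step-up panel sizing under cross-validated AUROC
#'
#' Evaluates [cv_auroc()] on the first `n` genes of a ranked list for
#' `n = 1..max_n` and picks the panel size by a one-standard-error rule:
#' the smallest `n` whose mean AUROC is within one standard error (sd at
#' the best `n` divided by `sqrt(repeats * folds)`) of the best mean.
#'
#' @param X,y,repeats,folds,seed as in [cv_auroc()].
#' @param ranked character vector of gene ids in rank order.
#' @param max_n largest panel size tried.
#' @return List of class `stepup_curve`: `n_star`, `features` (the selected
#'   panel), `curve` (tibble `n`, `auroc_mean`, `auroc_sd`).
#' @export
stepup_select <- function(X, y, ranked, max_n = 50, repeats = 10, folds = 10,
                          seed = 1L) {
  abort_if(length(ranked) < 1, "`ranked` must be non-empty.")
  ns <- seq_len(min(max_n, length(ranked)))
  curve <- purrr::map_dfr(ns, function(n) {
    cv <- cv_auroc(X, y, ranked[seq_len(n)], repeats, folds, seed)
    tibble::tibble(n = n, auroc_mean = cv$mean, auroc_sd = cv$sd)
  })
  best <- which.max(curve$auroc_mean)
  se <- curve$auroc_sd[best] / sqrt(repeats * folds)
  n_star <- curve$n[which(curve$auroc_mean >= curve$auroc_mean[best] - se)[1]]
  structure(list(n_star = n_star, features = ranked[seq_len(n_star)],
                 curve = curve), class = "stepup_curve")
}

new_model_report <- function(features, cv, comparator = NULL, group = "full cohort",
                             seed = NA_integer_) {
  structure(list(feature_set = features, n_features = length(features),
                 auroc_mean = cv$mean, auroc_sd = cv$sd,
                 fold_scores = cv$fold_scores,
                 comparator_auroc_mean = comparator$mean %||% NA_real_,
                 comparator_auroc_sd = comparator$sd %||% NA_real_,
                 comparator_fold_scores = comparator$fold_scores,
                 group = group, n = cv$n, seed = seed),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat(sprintf("<model_report> %s: %d features, AUROC %.3f +/- %.3f (n = %d)\n",
              x$group, x$n_features, x$auroc_mean, x$auroc_sd, x$n))
  if (!is.na(x$comparator_auroc_mean)) {
    cat(sprintf("  clinical score: AUROC %.3f +/- %.3f\n",
                x$comparator_auroc_mean, x$comparator_auroc_sd))
  }
  invisible(x)
}

#' Compare a gene panel with a clinical severity score
#'
#' Runs [cv_auroc()] twice on the patients with a non-missing clinical
#' score — once for the gene panel, once for the single-feature clinical
#' model — under identical hash-derived fold assignments, and reports both.
#'
#' @param X patients-by-genes matrix with patient ids as row names.
#' @param y binary outcome along rows.
#' @param features gene panel column names.
#' @param clinical numeric clinical score along rows (NA = unmatched).
#' @param repeats,folds,seed cross-validation design.
#' @param group label recorded on the report.
#' @return A `model_report` with panel and comparator AUROCs.
#' @export
compare_with_clinical_score <- function(X, y, features, clinical,
                                        repeats = 10, folds = 10, seed = 1L,
                                        group = "full cohort") {
  matched <- !is.na(clinical)
  abort_if(sum(matched) < 2 * folds, "matched subset too small for stratification.")
  Xm <- X[matched, , drop = FALSE]
  ym <- as.integer(as.logical(y[matched]))
  cs <- matrix(as.numeric(clinical[matched]), ncol = 1,
               dimnames = list(rownames(Xm), "clinical_score"))
  cv_panel <- cv_auroc(Xm, ym, features, repeats, folds, seed)
  cv_clin <- cv_auroc(cs, ym, "clinical_score", repeats, folds, seed)
  new_model_report(features, cv_panel, cv_clin, group = group, seed = seed)
}

#' Endotype-stratified prognostic models
#'
#' Repeats step-up panel selection within each endotype group, restricted to
#' the group's exclusive patients and to a previously ranked candidate list
#' (e.g. the full-cohort mRMR top 50). Groups whose smaller outcome class
#' falls below the number of folds are skipped with a recorded reason.
#'
#' @param X patients-by-genes matrix (patient ids as row names).
#' @param y binary outcome along rows, named or aligned with `X`.
#' @param groups an `endotype_groups` object.
#' @param ranked character vector of candidate gene ids in rank order.
#' @param max_n,repeats,folds,seed as in [stepup_select()].
#' @param clinical optional clinical score along rows of `X`; when given,
#'   each group's report carries the within-group clinical comparator.
#' @return List: `reports` (named list of `model_report`), `union_features`
#'   (gene ids selected in any group), `skipped` (tibble: group, reason),
#'   `curves` (named list of `stepup_curve`).
#' @export
stratified_models <- function(X, y, groups, ranked, max_n = 50,
                              repeats = 10, folds = 10, seed = 1L,
                              clinical = NULL) {
  excl <- exclusive_members(groups)
  reports <- list(); curves <- list(); skipped <- list()
  for (g in names(groups$groups)) {
    ids <- names(excl)[excl == g]
    ids <- ids[ids %in% rownames(X)]
    yg <- as.integer(as.logical(y[match(ids, rownames(X))]))
    tab <- table(factor(yg, levels = 0:1))
    if (min(tab) < folds) {
      skipped[[g]] <- tibble::tibble(
        group = g,
        reason = sprintf("smallest class has %d patients (< %d folds)", min(tab), folds))
      next
    }
    Xg <- X[ids, , drop = FALSE]
    sel <- stepup_select(Xg, yg, ranked, max_n, repeats, folds, seed)
    cv <- cv_auroc(Xg, yg, sel$features, repeats, folds, seed)
    comp <- NULL
    if (!is.null(clinical)) {
      cg <- clinical[match(ids, rownames(X))]
      if (sum(!is.na(cg)) >= 2 * folds &&
          min(table(factor(yg[!is.na(cg)], levels = 0:1))) >= folds) {
        cm <- matrix(as.numeric(cg[!is.na(cg)]), ncol = 1,
                     dimnames = list(ids[!is.na(cg)], "clinical_score"))
        comp <- cv_auroc(cm, yg[!is.na(cg)], "clinical_score", repeats, folds, seed)
      }
    }
    reports[[g]] <- new_model_report(sel$features, cv, comp, group = g, seed = seed)
    curves[[g]] <- sel
  }
  abort_if(length(reports) == 0, "all groups were skipped.")
  list(reports = reports,
       union_features = sort(unique(unlist(lapply(reports, `[[`, "feature_set")))),
       skipped = dplyr::bind_rows(skipped),
       curves = curves)
}
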