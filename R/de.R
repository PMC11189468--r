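# vectorized Welch machinery shared by welch_test() and de_table()
welch_stats <- function(ma, va, na_, mb, vb, nb) {
  se2 <- va / na_ + vb / nb
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na_)^2 / (na_ - 1) + (vb / nb)^2 / (nb - 1)),
               na_ + nb - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df), 1)
  list(t_stat = t_stat, df = df, p_value = p, zero_se = se2 == 0)
}

#' Welch two-sample t-test
#'
#' @param a,b numeric vectors, each of length at least 2.
#' @return One-row tibble: `t_stat`, `df`, `p_value` (two-sided). A zero
#'   pooled standard error yields `t_stat = 0`, `p_value = 1` with a warning.
#' @examples
#' welch_test(c(1, 2, 3), c(2, 4, 6))
#' @export
welch_test <- function(a, b) {
  abort_if(length(a) < 2 || length(b) < 2, "need at least 2 observations per group.")
  abort_if(any(!is.finite(a)) || any(!is.finite(b)), "inputs must be finite.")
  w <- welch_stats(mean(a), stats::var(a), length(a),
                   mean(b), stats::var(b), length(b))
  if (w$zero_se) rlang::warn("zero pooled standard error; returning t = 0, p = 1.")
  tibble::tibble(t_stat = w$t_stat, df = w$df, p_value = w$p_value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment in input order (wraps `stats::p.adjust`).
#'
#' @param p numeric vector of p-values in \[0, 1\]; no missing values.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  abort_if(anyNA(p), "missing p-values are not allowed.")
  abort_if(any(p < 0 | p > 1), "p-values must lie in [0, 1].")
  stats::p.adjust(p, method = "BH")
}

#' Per-gene Welch differential expression table
#'
#' One Welch test per gene between the two label classes on the VST scale,
#' with BH adjustment across all tested genes. The log2 fold change is the
#' difference of class means (case minus control), positive meaning higher
#' in the case class (for mortality contrasts: higher in non-survivors).
#'
#' @param expr genes-by-patients matrix (VST scale).
#' @param labels logical (or 0/1) vector along the columns: `TRUE` = case
#'   class (e.g. died by day 28). Patients with missing labels are dropped.
#' @param sort_by `"p_adjusted"` (default) or `"p_value"`; ties broken by
#'   descending absolute fold change, then gene id.
#' @return Tibble: `gene_id`, `l2fc`, `t_stat`, `df`, `p_value`,
#'   `p_adjusted`, `n_case`, `n_control`.
#' @export
de_table <- function(expr, labels, sort_by = c("p_adjusted", "p_value")) {
  sort_by <- match.arg(sort_by)
  y <- as.logical(labels)
  keep <- !is.na(y)
  expr <- expr[, keep, drop = FALSE]
  y <- y[keep]
  n1 <- sum(y); n0 <- sum(!y)
  abort_if(n1 < 2 || n0 < 2, "each label class needs at least 2 patients.")
  ma <- rowMeans(expr[, y, drop = FALSE])
  mb <- rowMeans(expr[, !y, drop = FALSE])
  va <- apply(expr[, y, drop = FALSE], 1, stats::var)
  vb <- apply(expr[, !y, drop = FALSE], 1, stats::var)
  w <- welch_stats(ma, va, n1, mb, vb, n0)
  out <- tibble::tibble(
    gene_id = rownames(expr),
    l2fc = ma - mb,
    t_stat = w$t_stat, df = w$df, p_value = w$p_value,
    p_adjusted = bh_adjust(w$p_value),
    n_case = n1, n_control = n0)
  dplyr::arrange(out, .data[[sort_by]], dplyr::desc(abs(.data$l2fc)), .data$gene_id)
}

#' Differential expression between endotype groups
#'
#' Compares VST expression between two (unions of) mapper groups using only
#' patients exclusive to a single group: patients attributable to more than
#' one group are removed before testing.
#'
#' @param expr genes-by-patients VST matrix.
#' @param groups an `endotype_groups` object (see [extract_groups()]).
#' @param group_a,group_b character vectors of group ids; a vector of
#'   several ids is treated as their union (e.g. `c("t1","t2","t3")`).
#' @inheritParams de_table
#' @return As [de_table()]; the case class is `group_a`.
#' @export
contrast_between_groups <- function(expr, groups, group_a, group_b,
                                    sort_by = c("p_adjusted", "p_value")) {
  excl <- exclusive_members(groups)
  in_a <- names(excl)[excl %in% group_a]
  in_b <- names(excl)[excl %in% group_b]
  abort_if(length(in_a) < 2 || length(in_b) < 2,
           "fewer than 2 exclusive patients on one side of the contrast.")
  ids <- c(in_a, in_b)
  ids <- ids[ids %in% colnames(expr)]
  de_table(expr[, ids, drop = FALSE],
           stats::setNames(ids %in% in_a, ids), sort_by = sort_by)
}

#' Compare clinical features across endotype groups
#'
#' One-way ANOVA (via `stats::aov`) of each numeric clinical feature across
#' the exclusive group assignment, plus pairwise Welch tests for requested
#' group contrasts (each side may be a union of groups, merged before
#' testing). Features observed in fewer than two patients of any group are
#' excluded; non-numeric features are skipped.
#'
#' @param cohort cohort tibble with `patient_id` and clinical columns.
#' @param groups an `endotype_groups` object.
#' @param features character vector of column names; defaults to every
#'   numeric column except `patient_id` and `death28`.
#' @param pairs list of contrasts, each a list with elements `a` and `b`
#'   (character vectors of group ids); defaults to all pairs of groups.
#' @return Tibble: `feature`, `anova_p`, `n_per_group` (list), `pairwise`
#'   (nested tibble: `contrast`, `mean_diff`, `p_value`), `skipped_reason`.
#' @export
clinical_compare <- function(cohort, groups, features = NULL, pairs = NULL) {
  excl <- exclusive_members(groups)
  dat <- cohort[match(names(excl), cohort$patient_id), , drop = FALSE]
  dat$.group <- unname(excl)
  gids <- sort(unique(dat$.group))
  if (is.null(pairs)) {
    pairs <- utils::combn(gids, 2, simplify = FALSE)
    pairs <- lapply(pairs, function(p) list(a = p[1], b = p[2]))
  }
  if (is.null(features)) {
    num <- vapply(cohort, is.numeric, logical(1))
    features <- setdiff(names(cohort)[num], c("patient_id", "death28"))
  }
  rows <- lapply(features, function(f) {
    if (!is.numeric(dat[[f]])) {
      return(tibble::tibble(feature = f, anova_p = NA_real_,
                            n_per_group = list(NULL), pairwise = list(NULL),
                            skipped_reason = "non-numeric"))
    }
    ok <- !is.na(dat[[f]])
    n_per <- table(factor(dat$.group[ok], levels = gids))
    if (any(n_per < 2)) {
      return(tibble::tibble(feature = f, anova_p = NA_real_,
                            n_per_group = list(as.list(n_per)), pairwise = list(NULL),
                            skipped_reason = "fewer than 2 observations in a group"))
    }
    fit <- stats::aov(stats::reformulate(".group", f), data = dat[ok, ])
    anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    pw <- purrr::map_dfr(pairs, function(pr) {
      xa <- dat[[f]][ok & dat$.group %in% pr$a]
      xb <- dat[[f]][ok & dat$.group %in% pr$b]
      if (length(xa) < 2 || length(xb) < 2) return(NULL)
      wt <- welch_test(xa, xb)
      tibble::tibble(contrast = paste(paste(pr$a, collapse = "+"), "vs",
                                      paste(pr$b, collapse = "+")),
                     mean_diff = mean(xa) - mean(xb), p_value = wt$p_value)
    })
    tibble::tibble(feature = f, anova_p = anova_p,
                   n_per_group = list(as.list(n_per)), pairwise = list(pw),
                   skipped_reason = NA_character_)
  })
  dplyr::bind_rows(rows)
}
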