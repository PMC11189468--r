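#' Counts per million
#'
#' @param counts a [count_matrix()] or plain genes-by-patients matrix.
#' @return Matrix of the same shape: `counts_gj / colsum_j * 1e6`.
#' @examples
#' m <- matrix(c(1, 3, 2, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("p1", "p2")))
#' compute_cpm(m)
#' @export
compute_cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  tot <- colSums(m)
  bad <- tot == 0
  abort_if(any(bad), "zero library size for patient(s): %s",
           paste(colnames(m)[bad], collapse = ", "))
  sweep(m, 2, tot, "/") * 1e6
}

#' Filter genes by expression level, sex linkage and annotation
#'
#' Retains genes whose mean CPM (computed on the pre-filter library totals)
#' is at least `cpm_threshold` (inclusive), that are not on chromosomes X/Y,
#' and that carry a chromosome annotation. Row order of survivors is
#' preserved; counts removed per criterion are recorded in the
#' `"filter_log"` attribute.
#'
#' @param counts a [count_matrix()].
#' @param cpm_threshold minimum mean CPM retained (default 10).
#' @param drop_sex_linked drop chromosomes X and Y.
#' @param drop_unannotated drop genes with no chromosome annotation.
#' @return Filtered [count_matrix()] with attribute `filter_log`
#'   (tibble: criterion, n_removed).
#' @export
filter_genes <- function(counts, cpm_threshold = 10,
                         drop_sex_linked = TRUE, drop_unannotated = TRUE) {
  cm <- as_count_matrix(counts)
  chr <- cm$genes$chromosome
  abort_if(drop_sex_linked && all(is.na(chr)),
           "chromosome annotation required to drop sex-linked genes.")
  mean_cpm <- rowMeans(compute_cpm(cm$counts))
  low <- mean_cpm < cpm_threshold
  sexl <- if (drop_sex_linked) !is.na(chr) & chr %in% c("X", "Y") else rep(FALSE, nrow(cm$counts))
  unann <- if (drop_unannotated) is.na(chr) else rep(FALSE, nrow(cm$counts))
  keep <- !(low | sexl | unann)
  abort_if(!any(keep), "no genes left after filtering.")
  out <- count_matrix(cm$counts[keep, , drop = FALSE],
                      cm$genes[keep, , drop = FALSE])
  attr(out, "filter_log") <- tibble::tibble(
    criterion = c("low_expression", "sex_linked", "unannotated", "retained"),
    n = c(sum(low), sum(sexl), sum(unann), sum(keep)))
  out
}

#' Median-of-ratios size factors
#'
#' Per-patient size factor as the median, over reference genes, of the ratio
#' of the patient's count to the gene's geometric mean across patients. The
#' reference set is the genes with strictly positive counts in every patient
#' (optionally a pseudo-reference over genes positive in most patients).
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param pseudo_reference if `TRUE`, fall back to genes with positive counts
#'   in at least 90\% of patients (zeros excluded gene-wise) when no gene is
#'   all-positive.
#' @return Named numeric vector of positive size factors, geometric mean 1.
#' @export
median_of_ratios <- function(counts, pseudo_reference = FALSE) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  all_pos <- rowSums(m == 0) == 0
  if (!any(all_pos) && !pseudo_reference) {
    rlang::abort(paste0("no gene has positive counts in every patient; ",
                        "rerun with pseudo_reference = TRUE."))
  }
  log_geo <- rowMeans(log(ifelse(m > 0, m, NA)), na.rm = TRUE)
  use <- if (any(all_pos)) all_pos else rowMeans(m > 0) >= 0.9
  abort_if(!any(use), "no usable reference genes for median-of-ratios.")
  log_ratio <- log(m[use, , drop = FALSE]) - log_geo[use]
  s <- exp(apply(log_ratio, 2, function(r) stats::median(r[is.finite(r)])))
  s <- s / geometric_mean(s)
  stats::setNames(s, colnames(m))
}

#' Fit the dispersion-mean trend of normalized counts
#'
#' Per-gene method-of-moments dispersion
#' \eqn{\hat\alpha_g = \max((v_g - \mu_g)/\mu_g^2, 10^{-8})} on
#' size-factor-normalized counts, then a robust fit of
#' \eqn{\alpha = a_0 + a_1/\mu} by iteratively reweighted least squares that
#' drops genes whose residual exceeds 2 median absolute deviations.
#' Coefficients are clipped at zero.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param s size factors from [median_of_ratios()].
#' @param min_mean genes with normalized mean below this are excluded from
#'   the fit (default 1).
#' @return Named numeric `c(a0, a1)`, with the per-gene table in the
#'   `"gene_dispersion"` attribute.
#' @export
fit_dispersion_trend <- function(counts, s, min_mean = 1) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  norm <- sweep(m, 2, s, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  keep <- mu >= min_mean
  abort_if(sum(keep) < 50, "need at least 50 genes with positive mean for the trend fit.")
  mu <- mu[keep]; v <- v[keep]
  alpha <- pmax((v - mu) / mu^2, 1e-8)
  tab <- tibble::tibble(gene_id = rownames(m)[keep], mean = mu, dispersion = alpha)
  if (all(alpha <= 1e-8)) {
    rlang::warn("all gene dispersions at floor; falling back to (a0, a1) = (0.01, 1).")
    out <- c(a0 = 0.01, a1 = 1)
    attr(out, "gene_dispersion") <- tab
    return(out)
  }
  x <- 1 / mu
  use <- rep(TRUE, length(alpha))
  fit <- c(0, 0)
  for (it in 1:8) {
    f <- stats::lm.fit(cbind(1, x[use]), alpha[use])
    fit <- f$coefficients
    resid <- alpha - (fit[1] + fit[2] * x)
    mad_r <- stats::mad(resid[use])
    if (mad_r == 0) break
    new_use <- abs(resid) <= 2 * mad_r
    # never let the trimming collapse the fit set
    if (sum(new_use) < 50 || identical(new_use, use)) break
    use <- new_use
  }
  out <- c(a0 = max(fit[1], 0), a1 = max(fit[2], 0))
  if (out["a0"] == 0 && out["a1"] == 0) {
    rlang::warn("degenerate dispersion trend; falling back to (0.01, 1).")
    out <- c(a0 = 0.01, a1 = 1)
  }
  attr(out, "gene_dispersion") <- tab
  out
}

# closed-form NB variance-stabilizing transform on the log2-like scale
vst_fun <- function(x, a0, a1) {
  log2((1 + a1 + 2 * a0 * x + 2 * sqrt(a0 * x * (1 + a1 + a0 * x))) / (4 * a0))
}

#' Variance-stabilizing transformation for negative-binomial counts
#'
#' Applies the closed-form VST
#' \deqn{u(x) = \log_2\frac{1 + a_1 + 2 a_0 x + 2\sqrt{a_0 x (1 + a_1 + a_0 x)}}{4 a_0}}
#' elementwise to size-factor-normalized counts \eqn{x = c_{gj}/s_j}, where
#' \eqn{(a_0, a_1)} is the fitted dispersion-mean trend. The transform is
#' strictly increasing and approaches \eqn{\log_2 x} for large \eqn{x}.
#' If `a0` is not positive it falls back to `log2(x + 1)`.
#'
#' @param counts a [count_matrix()] or matrix.
#' @param s size factors; computed by [median_of_ratios()] when missing.
#' @param trend `(a0, a1)`; fitted by [fit_dispersion_trend()] when missing.
#' @return Genes-by-patients numeric matrix of class `expression_matrix`
#'   with attributes `vst_params` and `size_factors`.
#' @export
vst_transform <- function(counts, s = NULL, trend = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  abort_if(any(m < 0), "counts must be non-negative.")
  if (is.null(s)) s <- median_of_ratios(m)
  if (is.null(trend)) trend <- fit_dispersion_trend(m, s)
  a0 <- unname(trend[1]); a1 <- unname(trend[2])
  norm <- sweep(m, 2, s, "/")
  vals <- if (a0 > 0) vst_fun(norm, a0, a1) else log2(norm + 1)
  structure(vals, class = c("expression_matrix", class(vals)),
            vst_params = c(a0 = a0, a1 = a1), size_factors = s)
}

#' Run the full preprocessing stage
#'
#' Convenience composition: [filter_genes()] then [median_of_ratios()] then
#' [fit_dispersion_trend()] then [vst_transform()].
#'
#' @inheritParams filter_genes
#' @return List: `expr` (expression matrix), `counts` (filtered
#'   [count_matrix()]), `size_factors`, `trend`, `filter_log`.
#' @export
preprocess_counts <- function(counts, cpm_threshold = 10,
                              drop_sex_linked = TRUE, drop_unannotated = TRUE) {
  filtered <- filter_genes(counts, cpm_threshold, drop_sex_linked, drop_unannotated)
  s <- median_of_ratios(filtered)
  trend <- fit_dispersion_trend(filtered, s)
  expr <- vst_transform(filtered, s, trend)
  list(expr = expr, counts = filtered, size_factors = s, trend = trend,
       filter_log = attr(filtered, "filter_log"))
}
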