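#' Synthetic Hallmark-like gene-set collection
#'
#' Builds a small gene-set collection over the genes of a (simulated)
#' cohort, for testing and demonstration in place of a licensed pathway
#' database. When ground truth is available, the four endotype modules and
#' the prognostic gene set become named sets (so enrichment against the
#' planted biology is checkable); the remainder are random sets with
#' controlled pairwise overlap.
#'
#' @param gene_ids character vector of gene universe ids, or an
#'   `endosep_cohort` (its filtered-in expressed genes plus truth sets).
#' @param n_sets total number of sets (default 50).
#' @param size_range random-set sizes, drawn uniformly (default 15-80).
#' @param overlap_rate fraction of each random set drawn from the previous
#'   random set, creating controlled overlaps.
#' @param seed integer seed.
#' @return Gene-set tibble as from [read_gmt()]; descriptions mark the
#'   collection as synthetic.
#' @export
synthetic_gene_sets <- function(gene_ids, n_sets = 50, size_range = c(15, 80),
                                overlap_rate = 0.2, seed = 1L) {
  truth_sets <- list()
  if (inherits(gene_ids, "endosep_cohort")) {
    sim <- gene_ids
    gene_ids <- sim$genes$gene_id[sim$genes$class == "expressed"]
    truth_sets <- c(
      stats::setNames(sim$truth$module_genes,
                      c("SYN_INTERFERON_RESPONSE_LIKE", "SYN_INFLAMMATORY_RESPONSE_LIKE",
                        "SYN_HEME_METABOLISM_LIKE", "SYN_IMMUNOSUPPRESSION_LIKE")),
      list(SYN_MORTALITY_PROGNOSTIC = sim$truth$prognostic$gene_id))
  }
  set.seed(seed)
  n_rand <- n_sets - length(truth_sets)
  abort_if(n_rand < 0, "`n_sets` smaller than the number of truth sets.")
  rand_sets <- list()
  prev <- character(0)
  for (i in seq_len(n_rand)) {
    k <- sample(seq(size_range[1], size_range[2]), 1)
    n_carry <- min(length(prev), round(overlap_rate * k))
    carried <- if (n_carry > 0) sample(prev, n_carry) else character(0)
    fresh <- sample(setdiff(gene_ids, carried), k - n_carry)
    rand_sets[[sprintf("SYN_RANDOM_SET_%02d", i)]] <- sort(c(carried, fresh))
    prev <- rand_sets[[length(rand_sets)]]
  }
  sets <- c(truth_sets, rand_sets)
  tibble::tibble(set = names(sets),
                 description = "synthetic gene set (no real pathway content)",
                 genes = unname(sets))
}
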