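#' Read and write GMT gene-set collections
#'
#' Tab-separated, one set per line: name, description, then gene ids.
#'
#' @param path file path.
#' @return `read_gmt()`: tibble with columns `set`, `description`, `genes`
#'   (list-column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  abort_if(any(lengths(parts) < 3), "malformed GMT: every line needs name, description, genes.")
  out <- tibble::tibble(
    set = vapply(parts, `[[`, character(1), 1),
    description = vapply(parts, `[[`, character(1), 2),
    genes = lapply(parts, function(p) unique(p[-(1:2)])))
  abort_if(anyDuplicated(out$set) > 0, "duplicate set names in GMT.")
  out
}

#' @rdname read_gmt
#' @param collection tibble as returned by `read_gmt()`.
#' @export
write_gmt <- function(collection, path) {
  lines <- mapply(function(s, d, g) paste(c(s, d, g), collapse = "\t"),
                  collection$set, collection$description, collection$genes)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Rank genes for preranked enrichment
#'
#' Orders genes by decreasing log2 fold change; optionally keeps only genes
#' with `p_adjusted <= 0.05` (inclusive) first. Ties break on gene id.
#'
#' @param de differential-expression tibble from [de_table()].
#' @param mode `"all"` (whole table; the within-group convention) or
#'   `"significant_only"` (the between-group convention).
#' @return Tibble `gene_id`, `stat` in decreasing `stat` order.
#' @export
rank_genes <- function(de, mode = c("all", "significant_only")) {
  mode <- match.arg(mode)
  abort_if(nrow(de) == 0, "empty DE table.")
  if (mode == "significant_only") {
    de <- de[de$p_adjusted <= 0.05, , drop = FALSE]
    abort_if(nrow(de) == 0, "no genes pass p_adjusted <= 0.05.")
  }
  out <- tibble::tibble(gene_id = de$gene_id, stat = de$l2fc)
  dplyr::arrange(out, dplyr::desc(.data$stat), .data$gene_id)
}

# core running-sum extremum from sorted hit positions.
# w: |stat|^p at those positions; N: ranked-list length.
es_core <- function(pos, w, N) {
  k <- length(pos)
  if (sum(w) <= 0) w <- rep(1, k)
  W <- sum(w)
  cum <- cumsum(w) / W
  miss <- (pos - seq_len(k)) / (N - k)
  up <- cum - miss                       # value just after each hit
  down <- c(0, cum[-k]) - miss           # value just before each hit
  m1 <- max(up); m2 <- min(down, 0)
  # magnitude ties resolve to the positive side (tolerance guards rounding)
  if (m1 >= -m2 - 1e-12) list(es = m1, at = pos[which.max(up)], positive = TRUE)
  else list(es = m2, at = pos[which.min(down)], positive = FALSE)
}

#' Weighted running-sum enrichment score
#'
#' Walks the ranked list; at a gene in the set the running sum rises by
#' \eqn{|s|^p / \sum_{hits} |s|^p}, at other genes it falls by
#' \eqn{1/(N - N_{hits})}. The enrichment score is the signed maximum
#' deviation from zero; the leading edge contains the set genes at or
#' before the extremum (at or after it for a negative score).
#'
#' @param ranked tibble (`gene_id`, `stat`) in rank order (see
#'   [rank_genes()]), or a named numeric vector of stats.
#' @param gene_set character vector of gene ids.
#' @param weight_p stat weighting exponent (default 1).
#' @return List: `es`, `running_sum` (length-N numeric), `leading_edge`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  if (is.numeric(ranked)) {
    ranked <- tibble::tibble(gene_id = names(ranked), stat = unname(ranked))
  }
  N <- nrow(ranked)
  hit <- ranked$gene_id %in% gene_set
  k <- sum(hit)
  abort_if(k == 0, "gene set does not intersect the ranked list.")
  abort_if(k == N, "gene set covers the entire ranked list.")
  pos <- which(hit)
  w <- abs(ranked$stat[pos])^weight_p
  res <- es_core(pos, w, N)
  w_use <- if (sum(w) > 0) w else rep(1, k)
  inc <- rep(-1 / (N - k), N)
  inc[pos] <- w_use / sum(w_use)
  running <- cumsum(inc)
  leading <- if (res$positive) ranked$gene_id[pos[pos <= res$at]]
             else ranked$gene_id[pos[pos >= res$at]]
  list(es = res$es, running_sum = running, leading_edge = leading)
}

#' Preranked gene-set enrichment with a gene-permutation null
#'
#' For every size-eligible set, compares the observed enrichment score with
#' scores of `n_perm` random same-size gene draws from the ranked list. The
#' normalized score divides by the mean absolute null score of matching
#' sign; the p-value uses the add-one estimator over matching-sign nulls.
#' BH adjustment runs across all size-eligible sets; records with
#' `p_value > p_cutoff` are then dropped.
#'
#' @param ranked tibble (`gene_id`, `stat`) in rank order.
#' @param collection gene-set tibble as from [read_gmt()].
#' @param n_perm permutations per set (default 1000).
#' @param min_size,max_size set-size eligibility after intersection.
#' @param p_cutoff retain records with `p_value <=` this (default 1, keep all).
#' @param weight_p stat weighting exponent.
#' @param seed integer seed for the permutation draws.
#' @return Tibble: `set`, `es`, `nes`, `p_value`, `p_adjusted`,
#'   `set_size_used`, `leading_edge` (list-column), sorted by `p_value`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, min_size = 5,
                           max_size = 500, p_cutoff = 1, weight_p = 1,
                           seed = 1L) {
  N <- nrow(ranked)
  sizes <- vapply(collection$genes, function(g) sum(ranked$gene_id %in% g), integer(1))
  eligible <- sizes >= min_size & sizes <= max_size & sizes < N
  abort_if(!any(eligible), "no gene set is size-eligible.")
  coll <- collection[eligible, , drop = FALSE]
  sizes <- sizes[eligible]
  set.seed(seed)
  stats_abs <- abs(ranked$stat)^weight_p
  rows <- purrr::map2_dfr(coll$set, seq_len(nrow(coll)), function(nm, i) {
    obs <- enrichment_score(ranked, coll$genes[[i]], weight_p)
    k <- sizes[i]
    null_es <- vapply(seq_len(n_perm), function(b) {
      pos <- sort(sample.int(N, k))
      es_core(pos, stats_abs[pos], N)$es
    }, numeric(1))
    if (obs$es == 0) {
      nes <- 0; p <- 1
    } else {
      same_sign <- if (obs$es > 0) null_es > 0 else null_es < 0
      denom <- mean(abs(null_es[same_sign]))
      nes <- if (isTRUE(denom > 0)) obs$es / denom else 0
      p <- (1 + sum(same_sign & abs(null_es) >= abs(obs$es))) / (1 + sum(same_sign))
    }
    tibble::tibble(set = nm, es = obs$es, nes = nes, p_value = p,
                   set_size_used = k, leading_edge = list(obs$leading_edge))
  })
  rows$p_adjusted <- bh_adjust(rows$p_value)
  rows <- rows[rows$p_value <= p_cutoff, , drop = FALSE]
  dplyr::arrange(rows, .data$p_value, .data$set)[
    , c("set", "es", "nes", "p_value", "p_adjusted", "set_size_used", "leading_edge")]
}
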