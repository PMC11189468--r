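#' Mapper configuration
#'
#' Parameters of the mapper construction over patients: the mutual k-NN
#' spectral lenses, the overlapping 2-D cover (resolution `R` intervals per
#' axis, gain `g` = fractional overlap), per-bin single-linkage clustering,
#' and the shared-membership cap on extracted groups.
#'
#' @param k_neighbors neighbours for the mutual k-NN lens graph.
#' @param resolution intervals per lens axis (R >= 2).
#' @param gain overlap parameter in (0, 1); adjacent intervals overlap by
#'   `gain * range / R`.
#' @param clustering_bins histogram bins for the single-linkage gap heuristic.
#' @param min_node_size smallest patient cluster kept as a node.
#' @param overlap_cap maximum tolerated fraction of patients shared between
#'   groups (default 0.10).
#' @param top_genes number of most-variable genes the distance is computed
#'   on (`Inf` for all genes).
#' @param seed integer seed recorded for provenance (the construction itself
#'   is deterministic).
#' @return List of class `endosep_mapper_config`.
#' @export
mapper_config <- function(k_neighbors = 15, resolution = 15, gain = 0.35,
                          clustering_bins = 10, min_node_size = 2,
                          overlap_cap = 0.10, top_genes = 1000, seed = 1L) {
  abort_if(!is_count(resolution) || resolution < 1, "`resolution` must be a positive integer.")
  abort_if(gain <= 0 || gain >= 1, "`gain` must lie in (0, 1).")
  abort_if(overlap_cap <= 0 || overlap_cap >= 0.5, "`overlap_cap` must lie in (0, 0.5).")
  abort_if(!is_count(k_neighbors), "`k_neighbors` must be a positive integer.")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 resolution = as.integer(resolution), gain = gain,
                 clustering_bins = as.integer(clustering_bins),
                 min_node_size = as.integer(min_node_size),
                 overlap_cap = overlap_cap, top_genes = top_genes,
                 seed = as.integer(seed)),
            class = "endosep_mapper_config")
}

#' Correlation distance between patients
#'
#' \eqn{d_{ij} = 1 - r_{ij}} with \eqn{r} the Pearson correlation of the two
#' patients' gene-expression profiles; symmetric, zero diagonal, range
#' \[0, 2\].
#'
#' @param expr genes-by-patients matrix.
#' @return Patients-by-patients distance matrix.
#' @export
correlation_distance <- function(expr) {
  abort_if(nrow(expr) < 2, "need at least 2 genes.")
  sds <- apply(expr, 2, stats::sd)
  bad <- sds == 0
  abort_if(any(bad), "constant expression profile for patient(s): %s",
           paste(colnames(expr)[bad], collapse = ", "))
  d <- 1 - stats::cor(expr)
  diag(d) <- 0
  d
}

#' Spectral neighborhood lenses
#'
#' Two per-patient coordinates summarising local neighbourhood geometry: the
#' two leading nontrivial eigenvectors of the symmetric normalized Laplacian
#' of the mutual k-NN graph of the distance matrix (unit edge weights), each
#' min-max scaled to \[0, 1\]. Because a mutual k-NN graph fragments when
#' the cohort contains well-separated expression phenotypes, the graph is
#' augmented by default with the minimum spanning tree of the distance
#' matrix, which guarantees connectivity without disturbing local
#' neighbourhood structure. Eigenvector signs are fixed so the first
#' patient (by id order) with a nonzero entry has a positive one. Patients
#' outside the largest connected component (possible only with
#' `augment_mst = FALSE`) get `NA` coordinates and are dropped from the
#' cover (with a warning).
#'
#' @param dist_mat symmetric patient distance matrix with dimnames.
#' @param k neighbourhood size (`k < n`).
#' @param augment_mst add the distance MST edges to the k-NN graph.
#' @return n x 2 matrix of lens coordinates (rows = patients), with the
#'   excluded patient ids in attribute `"excluded"`.
#' @export
neighborhood_lenses <- function(dist_mat, k = 15, augment_mst = TRUE) {
  n <- nrow(dist_mat)
  abort_if(k <= 0 || k >= n, "`k` must satisfy 0 < k < n_patients.")
  ids <- colnames(dist_mat)
  # mutual k-NN adjacency; all points tied at the k-th distance are included,
  # so duplicated patients receive identical neighbourhoods
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- dist_mat[i, ]
    thresh <- sort(d[-i], partial = k)[k]
    adj[i, ] <- d <= thresh + 1e-12
    adj[i, i] <- FALSE
  }
  adj <- adj & t(adj)
  if (augment_mst) {
    gd <- igraph::graph_from_adjacency_matrix(dist_mat, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    mst_el <- igraph::as_edgelist(igraph::mst(gd), names = FALSE)
    adj[mst_el] <- TRUE
    adj[mst_el[, c(2, 1), drop = FALSE]] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  main <- which.max(comp$csize)
  in_main <- comp$membership == main
  abort_if(mean(in_main) < 0.5,
           "mutual k-NN graph is disconnected beyond 50%% of patients; increase k.")
  if (!all(in_main)) {
    rlang::warn(sprintf("%d patient(s) outside the main k-NN component excluded from lenses.",
                        sum(!in_main)))
  }
  a <- adj[in_main, in_main, drop = FALSE]
  m <- sum(in_main)
  deg <- pmax(rowSums(a), 1)
  dhalf <- 1 / sqrt(deg)
  lap <- diag(m) - (dhalf * t(dhalf * a))   # I - D^-1/2 A D^-1/2
  es <- eigen(lap, symmetric = TRUE)
  # eigenvalues ascending after reversal; skip the trivial first
  ord <- rev(seq_len(m))
  vecs <- es$vectors[, ord, drop = FALSE][, 2:3, drop = FALSE]
  id_order <- order(ids[in_main])   # sign reference independent of row order
  lens_main <- apply(vecs, 2, function(v) {
    nz <- id_order[abs(v[id_order]) > 1e-12]
    if (length(nz) && v[nz[1]] < 0) v <- -v
    if (diff(range(v)) > 0) (v - min(v)) / diff(range(v)) else rep(0.5, length(v))
  })
  lens <- matrix(NA_real_, n, 2, dimnames = list(ids, c("lens1", "lens2")))
  lens[in_main, ] <- lens_main
  attr(lens, "excluded") <- ids[!in_main]
  lens
}

#' Overlapping interval cover of the lens space
#'
#' Per axis, `R` intervals with evenly spaced centers across the data range
#' and common length `range * (1 + g) / R`, clipped to the range; intervals
#' are half-open on the right except the last. Multi-dimensional bins are
#' Cartesian products of the per-axis intervals.
#'
#' @param lens numeric matrix of coordinates (rows = patients, any number of
#'   axes); rows with `NA` are skipped.
#' @param R resolution (intervals per axis).
#' @param g gain in (0, 1).
#' @return List of bins; each bin is a list with `index` (per-axis interval
#'   indices) and `members` (patient ids). Empty bins are dropped.
#' @export
build_cover <- function(lens, R, g) {
  lens <- as.matrix(lens)
  if (is.null(rownames(lens))) rownames(lens) <- as.character(seq_len(nrow(lens)))
  ok <- stats::complete.cases(lens)
  lens <- lens[ok, , drop = FALSE]
  abort_if(any(!is.finite(lens)), "lens coordinates must be finite.")
  axis_membership <- function(x) {
    lo <- min(x); hi <- max(x); rng <- hi - lo
    if (rng == 0) {
      rlang::warn("zero range on a lens axis; using a single full-range interval.")
      return(matrix(TRUE, length(x), 1))
    }
    len <- rng * (1 + g) / R
    centers <- lo + (seq_len(R) - 0.5) * rng / R
    sapply(seq_len(R), function(i) {
      a <- centers[i] - len / 2; b <- centers[i] + len / 2
      if (i < R) x >= a & x < b else x >= a & x <= hi
    })
  }
  per_axis <- lapply(seq_len(ncol(lens)), function(j) axis_membership(lens[, j]))
  idx_grid <- expand.grid(lapply(per_axis, function(m) seq_len(ncol(m))))
  bins <- lapply(seq_len(nrow(idx_grid)), function(r) {
    inb <- rep(TRUE, nrow(lens))
    for (j in seq_along(per_axis)) inb <- inb & per_axis[[j]][, idx_grid[r, j]]
    list(index = as.integer(idx_grid[r, ]), members = rownames(lens)[inb])
  })
  bins[vapply(bins, function(b) length(b$members) > 0, logical(1))]
}

#' Cluster the patients of one cover bin
#'
#' Single-linkage clustering cut at the first empty bar (after the first
#' occupied bar) of a `clustering_bins`-bin histogram of the merge heights —
#' the classic mapper gap heuristic. No gap, a singleton input, or all-equal
#' distances yield a single cluster.
#'
#' @param members patient ids in the bin.
#' @param dist_mat full patient distance matrix.
#' @param clustering_bins histogram bins.
#' @return List of character vectors (sub-clusters partitioning `members`).
#' @export
cluster_bin <- function(members, dist_mat, clustering_bins = 10) {
  abort_if(length(members) < 1, "empty bin.")
  if (length(members) == 1) return(list(members))
  d <- stats::as.dist(dist_mat[members, members, drop = FALSE])
  hc <- stats::hclust(d, method = "single")
  h <- hc$height
  if (max(h) <= 0) return(list(members))
  breaks <- seq(0, max(h), length.out = clustering_bins + 1)
  counts <- tabulate(findInterval(h, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = clustering_bins)
  occupied <- which(counts > 0)
  gap <- which(counts == 0 & seq_along(counts) > occupied[1])
  if (length(gap) == 0) return(list(members))
  cut_h <- breaks[gap[1]]
  cl <- stats::cutree(hc, h = cut_h)
  unname(split(members, cl))
}

#' Assemble the mapper graph from per-bin clusters
#'
#' One node per sub-cluster of at least `min_node_size` patients; an edge
#' joins two nodes whenever they share at least one patient, weighted by the
#' shared count.
#'
#' @param bin_clusters list over bins; each element a list with `index` and
#'   `clusters` (list of patient-id vectors), as produced by running
#'   [cluster_bin()] over [build_cover()] output.
#' @param min_node_size minimum patients per node.
#' @return Object of class `mapper_graph`: list with `nodes` (tibble: `node`,
#'   `bin`, `size`, `patients` list-column) and `edges` (tibble: `from`,
#'   `to`, `shared`).
#' @export
build_graph <- function(bin_clusters, min_node_size = 2) {
  nodes <- list(); bins <- character()
  for (b in bin_clusters) {
    for (cl in b$clusters) {
      if (length(cl) >= min_node_size) {
        nodes[[length(nodes) + 1]] <- sort(cl)
        bins <- c(bins, paste(b$index, collapse = ","))
      }
    }
  }
  abort_if(length(nodes) == 0, "empty mapper graph (no cluster reached min_node_size).")
  node_id <- sprintf("n%03d", seq_along(nodes))
  # edges via patient -> node incidence
  inc <- data.frame(patient = unlist(nodes),
                    node = rep(seq_along(nodes), lengths(nodes)))
  by_patient <- split(inc$node, inc$patient)
  shared <- new.env(parent = emptyenv())
  for (ns in by_patient) {
    if (length(ns) > 1) {
      prs <- utils::combn(sort(ns), 2)
      for (c_i in seq_len(ncol(prs))) {
        key <- paste(prs[1, c_i], prs[2, c_i])
        shared[[key]] <- (shared[[key]] %||% 0) + 1
      }
    }
  }
  keys <- ls(shared)
  edges <- if (length(keys)) {
    prs <- do.call(rbind, strsplit(keys, " "))
    tibble::tibble(from = node_id[as.integer(prs[, 1])],
                   to = node_id[as.integer(prs[, 2])],
                   shared = vapply(keys, function(k) shared[[k]], numeric(1),
                                   USE.NAMES = FALSE))
  } else {
    tibble::tibble(from = character(), to = character(), shared = numeric())
  }
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(
    nodes = tibble::tibble(node = node_id, bin = bins,
                           size = lengths(nodes), patients = nodes),
    edges = edges), class = "mapper_graph")
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat(sprintf("<mapper_graph> %d nodes, %d edges, %d patients\n",
              nrow(x$nodes), nrow(x$edges),
              length(unique(unlist(x$nodes$patients)))))
  invisible(x)
}

mapper_igraph <- function(graph) {
  # deterministic vertex order: descending size, id tiebreak
  ord <- order(-graph$nodes$size, graph$nodes$node)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$node[ord],
                          size = graph$nodes$size[ord]))
  igraph::E(g)$weight <- graph$edges$shared
  g
}

#' Extract endotype groups from a mapper graph
#'
#' Partitions the nodes by greedy modularity maximisation on the node graph
#' weighted by shared-patient counts (deterministic: nodes processed in
#' descending size order with id tiebreak). A patient's groups are the
#' communities of the nodes containing them; patients in more than one group
#' are marked `"shared"`. Fails the overlap cap check only by reporting — the
#' `(R, g)` re-search lives in [mapper_endotypes()].
#'
#' @param graph a `mapper_graph`.
#' @param cfg a [mapper_config()] (for the cap, recorded on the result).
#' @param cohort optional cohort tibble with `death28`; when given, groups
#'   are labelled `t1..tK` by descending mortality, otherwise by size.
#' @return Object of class `endotype_groups`: list with `membership` (tibble
#'   `patient_id`, `group`), `groups` (named list of patient-id sets),
#'   `exclusive` (named vector: group id or `"shared"`), `shared_fraction`,
#'   `mortality` (named, when cohort given), `node_community` (named),
#'   `graph` (the mapper graph).
#' @export
extract_groups <- function(graph, cfg = mapper_config(), cohort = NULL) {
  abort_if(nrow(graph$nodes) == 0, "empty mapper graph.")
  g <- mapper_igraph(graph)
  comm <- if (igraph::vcount(g) == 1) {
    stats::setNames(1L, igraph::V(g)$name)
  } else {
    memb <- igraph::membership(igraph::cluster_fast_greedy(g))
    stats::setNames(as.integer(memb), names(memb))
  }
  node_comm <- comm[graph$nodes$node]
  group_sets <- lapply(split(graph$nodes$patients, node_comm),
                       function(ps) sort(unique(unlist(ps))))
  # provisional order by size (relabelled by mortality below when available)
  group_sets <- group_sets[order(-lengths(group_sets), names(group_sets))]
  names(group_sets) <- paste0("t", seq_along(group_sets))
  build_group_result(group_sets, graph, node_comm, cfg, cohort)
}

build_group_result <- function(group_sets, graph, node_comm, cfg, cohort,
                               merged_from = NULL) {
  membership <- tibble::tibble(
    patient_id = unlist(group_sets, use.names = FALSE),
    group = rep(names(group_sets), lengths(group_sets)))
  n_groups_per_patient <- table(membership$patient_id)
  shared_ids <- names(n_groups_per_patient)[n_groups_per_patient > 1]
  assigned <- names(n_groups_per_patient)
  exclusive <- stats::setNames(rep("shared", length(assigned)), assigned)
  only <- setdiff(assigned, shared_ids)
  first_group <- membership$group[match(only, membership$patient_id)]
  exclusive[only] <- first_group
  mortality <- NULL
  if (!is.null(cohort) && "death28" %in% names(cohort)) {
    mortality <- vapply(group_sets, function(ids) {
      d <- cohort$death28[match(ids, cohort$patient_id)]
      mean(d, na.rm = TRUE)
    }, numeric(1))
    ord <- order(-mortality, names(group_sets))
    relabel <- stats::setNames(paste0("t", seq_along(ord)), names(group_sets)[ord])
    group_sets <- stats::setNames(group_sets[names(relabel)], relabel)
    mortality <- stats::setNames(mortality[names(relabel)], relabel)
    membership$group <- unname(relabel[membership$group])
    exclusive[exclusive != "shared"] <- unname(relabel[exclusive[exclusive != "shared"]])
    if (!is.null(merged_from)) {
      merged_from <- stats::setNames(merged_from[names(relabel)], unname(relabel))
    }
  }
  structure(list(membership = membership, groups = group_sets,
                 exclusive = exclusive,
                 shared_fraction = length(shared_ids) / max(length(assigned), 1),
                 mortality = mortality, node_community = node_comm,
                 merged_from = merged_from, graph = graph,
                 overlap_cap = cfg$overlap_cap),
            class = "endotype_groups")
}

#' @export
print.endotype_groups <- function(x, ...) {
  cat(sprintf("<endotype_groups> %d groups, %d patients, shared fraction %.3f\n",
              length(x$groups), length(x$exclusive), x$shared_fraction))
  for (g in names(x$groups)) {
    cat(sprintf("  %s: %d patients%s\n", g, length(x$groups[[g]]),
                if (!is.null(x$mortality)) sprintf(", mortality %.2f", x$mortality[[g]]) else ""))
  }
  invisible(x)
}

#' Exclusive group assignment
#'
#' @param groups an `endotype_groups` object.
#' @return Named character vector (patient id -> group id), omitting
#'   patients shared between groups.
#' @export
exclusive_members <- function(groups) {
  e <- groups$exclusive
  e[e != "shared"]
}

#' Run the full mapper stage and extract endotype groups
#'
#' Correlation distance on the most-variable genes, spectral neighborhood
#' lenses, overlapping 2-D cover, per-bin single-linkage clustering, graph
#' assembly and modularity-based group extraction. If the extracted groups
#' exceed the shared-membership cap, the cover is re-searched over a small
#' `(R, g)` grid (R in 10/15/20/25, g in 0.20/0.30/0.35/0.40), keeping the
#' setting with the most groups holding at least 5\% of patients subject to
#' the cap.
#'
#' @param expr genes-by-patients VST matrix.
#' @param cfg a [mapper_config()].
#' @param cohort optional cohort tibble (labels groups by mortality).
#' @return An `endotype_groups` object; the winning `(R, g)` is in attribute
#'   `"cover_settings"`, the lens matrix in `"lens"`.
#' @export
mapper_endotypes <- function(expr, cfg = mapper_config(), cohort = NULL) {
  if (is.finite(cfg$top_genes) && nrow(expr) > cfg$top_genes) {
    vars <- apply(expr, 1, stats::var)
    expr <- expr[order(-vars)[seq_len(cfg$top_genes)], , drop = FALSE]
  }
  dmat <- correlation_distance(expr)
  lens <- neighborhood_lenses(dmat, cfg$k_neighbors)

  run_setting <- function(R, g) {
    bins <- build_cover(lens, R, g)
    bin_clusters <- lapply(bins, function(b) {
      list(index = b$index,
           clusters = cluster_bin(b$members, dmat, cfg$clustering_bins))
    })
    graph <- build_graph(bin_clusters, cfg$min_node_size)
    extract_groups(graph, cfg, cohort)
  }

  groups <- run_setting(cfg$resolution, cfg$gain)
  settings <- c(R = cfg$resolution, g = cfg$gain)
  if (groups$shared_fraction > cfg$overlap_cap) {
    grid <- expand.grid(R = c(10L, 15L, 20L, 25L), g = c(0.20, 0.30, 0.35, 0.40))
    n_pat <- ncol(expr)
    best <- NULL; best_score <- c(-1, Inf); best_frac <- groups$shared_fraction
    for (r in seq_len(nrow(grid))) {
      cand <- tryCatch(run_setting(grid$R[r], grid$g[r]), error = function(e) NULL)
      if (is.null(cand)) next
      best_frac <- min(best_frac, cand$shared_fraction)
      if (cand$shared_fraction > cfg$overlap_cap) next
      n_big <- sum(lengths(cand$groups) >= 0.05 * n_pat)
      if (n_big > best_score[1] ||
          (n_big == best_score[1] && cand$shared_fraction < best_score[2])) {
        best <- cand; best_score <- c(n_big, cand$shared_fraction)
        settings <- c(R = grid$R[r], g = grid$g[r])
      }
    }
    abort_if(is.null(best),
             "no (R, g) setting satisfies the %.0f%% sharing cap (best fraction %.3f).",
             100 * cfg$overlap_cap, best_frac)
    groups <- best
  }
  attr(groups, "cover_settings") <- settings
  attr(groups, "lens") <- lens
  groups
}

#' Merge adjacent low-mortality groups
#'
#' Groups holding fewer than `min_deaths` deaths are merged pairwise with an
#' adjacent (patient-sharing or node-graph-connected) group that is also
#' below the threshold, until none remain or no merge candidate exists.
#' Groups are then relabelled `t1..tK` by descending mortality.
#'
#' @param groups an `endotype_groups` object.
#' @param cohort cohort tibble with `patient_id` and `death28`.
#' @param min_deaths merge threshold (default 10).
#' @return An `endotype_groups` object; merged groups record their origins
#'   in `merged_from`.
#' @export
merge_low_mortality <- function(groups, cohort, min_deaths = 10) {
  sets <- groups$groups
  origins <- stats::setNames(as.list(names(sets)), names(sets))
  deaths_of <- function(ids) {
    sum(cohort$death28[match(ids, cohort$patient_id)], na.rm = TRUE)
  }
  # group adjacency from the node graph communities plus shared patients
  adjacent <- function(a, b) {
    if (length(intersect(sets[[a]], sets[[b]])) > 0) return(TRUE)
    # fall back to edge connectivity between the two groups' nodes
    na_ <- names(groups$node_community)[vapply(groups$graph$nodes$patients,
                                               function(p) any(p %in% sets[[a]]), logical(1))]
    nb_ <- names(groups$node_community)[vapply(groups$graph$nodes$patients,
                                               function(p) any(p %in% sets[[b]]), logical(1))]
    any(groups$graph$edges$from %in% na_ & groups$graph$edges$to %in% nb_) ||
      any(groups$graph$edges$from %in% nb_ & groups$graph$edges$to %in% na_)
  }
  repeat {
    d <- vapply(sets, deaths_of, numeric(1))
    low <- names(sets)[d < min_deaths]
    if (length(low) < 2) break
    merged <- FALSE
    for (a in low) {
      partners <- setdiff(low, a)
      partners <- partners[vapply(partners, function(b) adjacent(a, b), logical(1))]
      if (length(partners)) {
        b <- partners[which.min(d[partners])]
        new_name <- paste(sort(c(a, b)), collapse = "+")
        sets[[new_name]] <- sort(unique(c(sets[[a]], sets[[b]])))
        origins[[new_name]] <- unlist(c(origins[[a]], origins[[b]]))
        sets[[a]] <- NULL; sets[[b]] <- NULL
        origins[[a]] <- NULL; origins[[b]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  cfg_like <- list(overlap_cap = groups$overlap_cap)
  build_group_result(sets, groups$graph, groups$node_community, cfg_like,
                     cohort, merged_from = origins)
}
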