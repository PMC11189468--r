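test_that("correlation distance matches hand computation", {
  expr <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 4), d = c(1, 2, 3))
  rownames(expr) <- sprintf("g%d", 1:3)
  d <- correlation_distance(expr)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "d"], 0)                      # identical profiles
  expect_equal(d["a", "b"], 2)                      # perfect anticorrelation
  expect_equal(d["a", "c"], 0.01801949, tolerance = 1e-6)
  expect_equal(d, t(d))
  bad <- cbind(expr, e = c(5, 5, 5))
  expect_error(correlation_distance(bad), "e")
})

test_that("lenses separate well-separated blobs and respect equivariance", {
  set.seed(10)
  n_half <- 30
  # two blobs with distinct gene-expression *patterns* (correlation distance
  # is shift-invariant, so the blobs must differ in profile shape)
  pat1 <- rnorm(20, 0, 2); pat2 <- rnorm(20, 0, 2)
  expr <- cbind(pat1 + matrix(rnorm(20 * n_half, 0, 0.2), 20),
                pat2 + matrix(rnorm(20 * n_half, 0, 0.2), 20))
  colnames(expr) <- sprintf("p%03d", 1:(2 * n_half))
  rownames(expr) <- sprintf("g%d", 1:20)
  d <- correlation_distance(expr)
  lens <- neighborhood_lenses(d, k = 8)
  blob <- rep(1:2, each = n_half)
  m1 <- tapply(lens[, 1], blob, mean)
  pooled_sd <- sqrt(mean(tapply(lens[, 1], blob, var)))
  expect_gt(abs(diff(m1)), 4 * pooled_sd)           # lens 1 bimodal

  # permuting patients permutes coordinates identically
  perm <- sample(ncol(d))
  lens_p <- neighborhood_lenses(d[perm, perm], k = 8)
  expect_equal(lens_p[colnames(d), ], lens[colnames(d), ])

  # duplicated patients get identical coordinates
  expr2 <- cbind(expr, p_dup = expr[, 3])
  d2 <- correlation_distance(expr2)
  lens2 <- neighborhood_lenses(d2, k = 8)
  expect_equal(unname(lens2["p_dup", ]), unname(lens2["p003", ]))

  expect_error(neighborhood_lenses(d, k = 0), "k")
  expect_error(neighborhood_lenses(d, k = ncol(d)), "k")
})

test_that("cover intervals follow the clipped equal-length convention", {
  x <- matrix(seq(0, 1, length.out = 101), ncol = 1,
              dimnames = list(sprintf("p%03d", 1:101), NULL))
  bins <- build_cover(x, R = 2, g = 0.5)
  # intervals [0, 0.625) and [0.375, 1]: overlap length g * range / R = 0.25
  in1 <- x[bins[[1]]$members, 1]; in2 <- x[bins[[2]]$members, 1]
  expect_equal(range(in1), c(0, 0.62))
  expect_equal(range(in2), c(0.38, 1))
  both <- intersect(bins[[1]]$members, bins[[2]]$members)
  expect_equal(range(x[both, 1]), c(0.38, 0.62))
  # tiny gain: generic interior points belong to exactly one bin per axis
  set.seed(40)
  xr <- matrix(runif(80), ncol = 1, dimnames = list(sprintf("r%02d", 1:80), NULL))
  bins0 <- build_cover(xr, R = 4, g = 1e-9)
  counts <- table(unlist(lapply(bins0, `[[`, "members")))
  expect_true(all(counts == 1))
  # R = 1: a single bin holding everyone
  bins1 <- build_cover(x, R = 1, g = 0.3)
  expect_length(bins1, 1)
  expect_length(bins1[[1]]$members, 101)
  # zero range handled with a warning
  flat <- cbind(x, 0.5)
  expect_warning(b2 <- build_cover(flat, R = 3, g = 0.3), "zero range")
  expect_true(all(vapply(b2, function(b) length(b$index) == 2, logical(1))))
})

test_that("every patient lands in at least one cover bin", {
  set.seed(14)
  lens <- matrix(runif(400), 200, 2, dimnames = list(sprintf("p%03d", 1:200), NULL))
  for (g in c(0.2, 0.35)) {
    bins <- build_cover(lens, R = 10, g = g)
    expect_setequal(unique(unlist(lapply(bins, `[[`, "members"))), rownames(lens))
  }
})

test_that("bin clustering follows the single-linkage gap heuristic", {
  ids <- c("a", "b", "c", "d")
  d <- matrix(0.1, 4, 4, dimnames = list(ids, ids))
  d[1:2, 3:4] <- 1; d[3:4, 1:2] <- 1; diag(d) <- 0
  d["a", "b"] <- d["b", "a"] <- 0.1; d["c", "d"] <- d["d", "c"] <- 0.1
  out <- cluster_bin(ids, d)
  expect_length(out, 2)                             # two tight pairs split
  expect_setequal(out[[which(vapply(out, function(x) "a" %in% x, logical(1)))]],
                  c("a", "b"))
  expect_equal(cluster_bin("a", d), list("a"))      # singleton
  dd <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(dd) <- 0
  expect_length(cluster_bin(ids, dd), 1)            # all-equal distances: no gap
})

test_that("graph assembly matches constructed covers", {
  # 1-D lens values {0,1,2,10,11,12}, R = 2, g = 0.3: two nodes, no edge
  ids <- sprintf("p%d", 1:6)
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1, dimnames = list(ids, NULL))
  d <- as.matrix(dist(x)); dimnames(d) <- list(ids, ids)
  bins <- build_cover(x, R = 2, g = 0.3)
  bc <- lapply(bins, function(b) list(index = b$index,
                                      clusters = cluster_bin(b$members, d)))
  g1 <- build_graph(bc)
  expect_equal(nrow(g1$nodes), 2L)
  expect_equal(nrow(g1$edges), 0L)
  expect_setequal(unlist(g1$nodes$patients), ids)

  # larger gain shares the middle patient between bins: one edge, count 1
  x2 <- matrix(c(0, 1, 2, 5, 8, 9, 10), ncol = 1,
               dimnames = list(sprintf("p%d", 1:7), NULL))
  d2 <- as.matrix(dist(x2))
  bins2 <- build_cover(x2, R = 2, g = 0.5)
  bc2 <- lapply(bins2, function(b) list(index = b$index,
                                        clusters = list(b$members)))
  g2 <- build_graph(bc2)
  expect_equal(nrow(g2$edges), 1L)
  expect_equal(g2$edges$shared, 1)

  # nodes below min_node_size are dropped; an all-dropped graph is an error
  expect_error(build_graph(bc, min_node_size = 4), "empty mapper graph")
})

test_that("group extraction separates components and honours the sharing cap", {
  mk_graph <- function(bin_clusters) build_graph(bin_clusters, min_node_size = 2)
  # two components -> two groups, nothing shared
  bc <- list(list(index = 1, clusters = list(c("a", "b"))),
             list(index = 2, clusters = list(c("c", "d"))))
  gr <- extract_groups(mk_graph(bc), mapper_config())
  expect_length(gr$groups, 2)
  expect_equal(gr$shared_fraction, 0)

  # barbell: two 5-node cliques over 100 patients joined by one shared patient
  ids <- sprintf("q%03d", 1:100)
  cliqueA <- lapply(1:5, function(i) ids[1:50])
  cliqueB <- lapply(1:5, function(i) ids[50:100])   # q050 shared
  bc2 <- c(lapply(seq_along(cliqueA), function(i) list(index = i, clusters = cliqueA[i])),
           lapply(seq_along(cliqueB), function(i) list(index = 5 + i, clusters = cliqueB[i])))
  gr2 <- extract_groups(mk_graph(bc2), mapper_config())
  expect_length(gr2$groups, 2)
  expect_equal(gr2$shared_fraction, 0.01)
  expect_equal(unname(gr2$exclusive["q050"]), "shared")
})

test_that("low-mortality groups merge pairwise and conserve patients", {
  ids <- sprintf("p%03d", 1:60)
  sets <- list(t1 = ids[1:20], t2 = ids[20:35], t3 = ids[36:60])
  death <- c(rep(1, 12), rep(0, 8),          # t1: 12 deaths
             rep(1, 3), rep(0, 12),          # t2: 3 deaths (incl shared p020)
             rep(c(1, 0, 0, 0, 0), 5))       # t3: 5 deaths
  cohort <- tibble::tibble(patient_id = ids, death28 = death)
  graph <- structure(list(
    nodes = tibble::tibble(node = c("n1", "n2", "n3"), bin = "1",
                           size = lengths(sets), patients = unname(sets)),
    edges = tibble::tibble(from = character(), to = character(), shared = numeric())),
    class = "mapper_graph")
  groups <- structure(list(groups = sets,
                           exclusive = stats::setNames(rep("t1", 0), character()),
                           shared_fraction = 1 / 60,
                           node_community = stats::setNames(1:3, c("n1", "n2", "n3")),
                           graph = graph, overlap_cap = 0.1),
                      class = "endotype_groups")
  # t2 (3 deaths) and t3 (5 deaths) are both low; they share no patients and no
  # edges -> no merge candidate, identity apart from relabelling
  out_none <- merge_low_mortality(groups, cohort, min_deaths = 10)
  expect_length(out_none$groups, 3)

  # make t2 and t3 share a patient: they merge
  sets2 <- sets; sets2$t3 <- c(sets$t3, ids[35])
  groups$groups <- sets2
  out <- merge_low_mortality(groups, cohort, min_deaths = 10)
  expect_length(out$groups, 2)
  expect_setequal(unlist(out$groups), ids)         # patient conservation
  merged <- out$merged_from[[which(lengths(out$merged_from) == 2)]]
  expect_setequal(merged, c("t2", "t3"))

  # all groups at or above the threshold: identity
  cohort_hi <- cohort; cohort_hi$death28 <- 1
  out_hi <- merge_low_mortality(groups, cohort_hi, min_deaths = 10)
  expect_length(out_hi$groups, 3)
})

test_that("the full mapper stage is deterministic and recovers planted endotypes", {
  sim <- simulate_cohort(sim_config(seed = 1))
  prep <- prep_of(sim)
  cfg <- mapper_config()
  g1 <- mapper_endotypes(prep$expr, cfg, sim$cohort)
  g2 <- mapper_endotypes(prep$expr, cfg, sim$cohort)
  expect_identical(g1$membership, g2$membership)
  expect_identical(g1$exclusive, g2$exclusive)
  expect_lte(g1$shared_fraction, cfg$overlap_cap)
  # conservation: every patient in a node appears in a group
  expect_setequal(unique(unlist(g1$graph$nodes$patients)), names(g1$exclusive))
  # groups labelled by descending mortality
  expect_true(all(diff(g1$mortality) <= 1e-12))
  skip_if_not_installed("mclust")
  excl <- exclusive_members(g1)
  ari <- mclust::adjustedRandIndex(excl, sim$truth$endotype[names(excl)])
  expect_gte(ari, 0.6)
})
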