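test_that("auroc matches pair enumeration, including ties", {
  expect_equal(auroc(c(3, 2, 1), c(1, 1, 0)), 1)
  expect_equal(auroc(c(1, 2, 3), c(1, 1, 0)), 0)
  expect_equal(auroc(c(0.9, 0.8, 0.8, 0.1), c(1, 1, 0, 0)), 0.875)
  expect_error(auroc(c(1, 2), c(1, 1)), "both outcome classes")
  set.seed(19)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # plenty of ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    expect_equal(auroc(scores, labels), auroc_brute(scores, labels))
  }
  # antisymmetry without ties
  s <- rnorm(40); y <- rbinom(40, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(auroc(-s, y), 1 - auroc(s, y))
})

test_that("mRMR ranks relevance first and penalizes exact copies", {
  set.seed(31)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  x1 <- y + rnorm(n, 0, 1.0)           # most informative
  x2 <- x1                              # exact copy: redundancy 1 once x1 is in
  x3 <- y + rnorm(n, 0, 1.1)           # a bit less informative, independent
  X <- cbind(g1 = x1, g2 = x2, g3 = x3,
             matrix(rnorm(n * 7), n, 7, dimnames = list(NULL, sprintf("n%d", 1:7))))
  rownames(X) <- sprintf("p%03d", 1:n)
  r <- mrmr_rank(X, y, m = 3)
  expect_equal(r$gene_id[1], "g1")      # max relevance first (id tiebreak on g2)

  # independent oracle: exhaustive score arithmetic for the second pick
  f_of <- function(v) summary(stats::aov(v ~ factor(y)))[[1]][["F value"]][1]
  f_all <- apply(X, 2, f_of)
  z <- (f_all - mean(f_all)) / sd(f_all)
  red <- abs(cor(X, X[, "g1"]))[, 1]
  score2 <- z - red
  score2 <- score2[setdiff(colnames(X), "g1")]
  expect_equal(r$gene_id[2], names(score2)[which.max(score2)])
  expect_equal(r$gene_id[2], "g3")      # copy fully penalized, g3 next

  expect_equal(mrmr_rank(X, y, m = 1)$gene_id, "g1")
  # constant columns dropped with a warning
  X2 <- cbind(X, zz = rep(1, n))
  expect_warning(r2 <- mrmr_rank(X2, y, m = 5), "constant")
  expect_false("zz" %in% r2$gene_id)
})

test_that("ridge logistic matches glm in the unpenalized limit", {
  set.seed(29)
  n <- 300
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(0.5 + X %*% c(1, -0.5, 0.2)))
  beta <- ridge_logistic(X, y, lambda = 1e-8)
  ref <- unname(coef(glm(y ~ X, family = binomial())))
  expect_equal(beta, ref, tolerance = 1e-5)
})

test_that("cv_auroc is deterministic, order-invariant, and sane at the limits", {
  set.seed(33)
  n <- 200
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(sprintf("p%03d", 1:n), c("a", "b")))
  y <- rbinom(n, 1, 0.5); y[1:20] <- 1; y[21:40] <- 0
  X[, "a"] <- y * 10 + rnorm(n, 0, 0.01)          # perfectly separable feature
  cv <- cv_auroc(X, y, "a", repeats = 3, folds = 5, seed = 4)
  expect_gte(cv$mean, 0.99)
  expect_length(cv$fold_scores, 15)
  cv2 <- cv_auroc(X, y, "a", repeats = 3, folds = 5, seed = 4)
  expect_identical(cv$fold_scores, cv2$fold_scores)
  # permuting the rows leaves the fold scores unchanged (hash-keyed folds)
  perm <- sample(n)
  cv3 <- cv_auroc(X[perm, ], y[perm], "a", repeats = 3, folds = 5, seed = 4)
  expect_equal(cv$fold_scores, cv3$fold_scores)
  # stratification guard
  y_rare <- c(rep(1, 3), rep(0, n - 3))
  expect_error(cv_auroc(X, y_rare, "a", folds = 10), "below the number of folds")
})

test_that("step-up selection finds small planted panels and handles edge cases", {
  ns <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 300
    z <- matrix(rnorm(n * 3), n, 3)
    y <- rbinom(n, 1, plogis(-1 + z %*% c(1.2, 1, 0.8)))
    X <- cbind(z, matrix(rnorm(n * 27), n, 27))
    dimnames(X) <- list(sprintf("p%03d", 1:n), sprintf("g%02d", 1:30))
    stepup_select(X, y, colnames(X), max_n = 15, repeats = 5, folds = 5,
                  seed = s)$n_star
  }, numeric(1))
  expect_lte(median(ns), 5)
  # single candidate
  set.seed(1)
  X1 <- matrix(rnorm(100), 100, 1, dimnames = list(sprintf("p%03d", 1:100), "g1"))
  y1 <- rbinom(100, 1, 0.5); y1[1:10] <- 1; y1[11:20] <- 0
  s1 <- stepup_select(X1, y1, "g1", repeats = 2, folds = 5, seed = 1)
  expect_equal(s1$n_star, 1L)
  # all-null candidates: the one-standard-error rule collapses to small panels
  null_ns <- vapply(1:5, function(s) {
    set.seed(200 + s)
    X <- matrix(rnorm(200 * 15), 200, 15,
                dimnames = list(sprintf("p%03d", 1:200), sprintf("g%02d", 1:15)))
    y <- rbinom(200, 1, 0.3)
    stepup_select(X, y, colnames(X), max_n = 15, repeats = 10, folds = 10,
                  seed = s)$n_star
  }, numeric(1))
  expect_lte(median(null_ns), 3)
})

test_that("clinical comparison shares folds and is bounded by a perfect score", {
  set.seed(41)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("p%03d", 1:n), sprintf("g%d", 1:4)))
  y <- rbinom(n, 1, 0.4); y[1:15] <- 1; y[16:30] <- 0
  X[, 1] <- y + rnorm(n, 0, 1)
  clinical <- as.numeric(y)              # deterministic function of the outcome
  rep <- compare_with_clinical_score(X, y, c("g1", "g2"), clinical,
                                     repeats = 3, folds = 5, seed = 2)
  expect_equal(rep$comparator_auroc_mean, 1)
  expect_gte(rep$comparator_auroc_mean, rep$auroc_mean)
  expect_length(rep$fold_scores, 15)
  expect_length(rep$comparator_fold_scores, 15)
  # identical fold assignments across the two runs (hash-keyed by patient id)
  cvp <- cv_auroc(X, y, "g1", repeats = 3, folds = 5, seed = 2)
  cs <- matrix(clinical, ncol = 1, dimnames = list(rownames(X), "clinical_score"))
  cvc <- cv_auroc(cs, y, "clinical_score", repeats = 3, folds = 5, seed = 2)
  expect_identical(cvp$fold_ids, cvc$fold_ids)
  # missing clinical scores restrict the comparison to the matched subset
  clinical2 <- clinical; clinical2[1:50] <- NA
  rep2 <- compare_with_clinical_score(X, y, c("g1", "g2"), clinical2,
                                      repeats = 2, folds = 5, seed = 2)
  expect_equal(rep2$n, n - 50)
})

test_that("stratified models reduce to the unstratified path and skip tiny groups", {
  set.seed(47)
  n <- 160
  ids <- sprintf("p%03d", 1:n)
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(ids, sprintf("g%02d", 1:10)))
  y <- rbinom(n, 1, 0.4); y[1:10] <- 1; y[11:20] <- 0
  X[, 1] <- y * 1.5 + rnorm(n)
  all_in_one <- structure(list(
    groups = list(t1 = ids),
    exclusive = stats::setNames(rep("t1", n), ids),
    shared_fraction = 0), class = "endotype_groups")
  out <- stratified_models(X, y, all_in_one, colnames(X), max_n = 5,
                           repeats = 2, folds = 5, seed = 3)
  direct <- stepup_select(X, y, colnames(X), max_n = 5, repeats = 2, folds = 5,
                          seed = 3)
  expect_equal(out$reports$t1$feature_set, direct$features)
  expect_equal(out$reports$t1$auroc_mean,
               cv_auroc(X, y, direct$features, 2, 5, 3)$mean)
  # a group with a single death is skipped with a reason
  two <- structure(list(
    groups = list(t1 = ids[1:140], t2 = ids[141:160]),
    exclusive = stats::setNames(c(rep("t1", 140), rep("t2", 20)), ids),
    shared_fraction = 0), class = "endotype_groups")
  y2 <- y; y2[141:160] <- 0; y2[141] <- 1
  out2 <- stratified_models(X, y2, two, colnames(X), max_n = 3,
                            repeats = 2, folds = 5, seed = 3)
  expect_named(out2$reports, "t1")
  expect_match(out2$skipped$reason, "smallest class")
  expect_true(all(out2$union_features %in% colnames(X)))
})
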