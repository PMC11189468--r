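test_that("welch_test matches the closed form and t.test", {
  out <- welch_test(c(1, 2, 3), c(2, 4, 6))
  expect_equal(out$t_stat, -1.549193, tolerance = 1e-6)
  expect_equal(out$df, 2.941176, tolerance = 1e-6)
  # identical samples: t = 0, p = 1
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)
  # antisymmetry
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(welch_test(a, b)$t_stat, -welch_test(b, a)$t_stat)
  expect_equal(welch_test(a, b)$p_value, welch_test(b, a)$p_value)
  # agreement with stats::t.test across random draws
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(sample(3:15, 1)); y <- rnorm(sample(3:15, 1), sd = runif(1, 0.5, 2))
    ref <- stats::t.test(x, y)
    got <- welch_test(x, y)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  }
  # zero pooled SE
  expect_warning(z <- welch_test(c(2, 2, 2), c(2, 2)), "zero pooled")
  expect_equal(z$p_value, 1)
})

test_that("welch p-values are uniform under the null", {
  set.seed(77)
  n <- 10000; na_ <- 8; nb_ <- 12
  A <- matrix(rnorm(n * na_), n); B <- matrix(rnorm(n * nb_), n)
  w <- welch_stats(rowMeans(A), apply(A, 1, var), na_,
                   rowMeans(B), apply(B, 1, var), nb_)
  ks <- stats::ks.test(w$p_value, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("bh_adjust reproduces the step-up formula and rejects NaN", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)), c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.1, NaN)), "missing")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:200) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("de_table is invariant to patient order and fixes the sign convention", {
  set.seed(8)
  n <- 60
  expr <- named_matrix(rnorm(100 * n, 8, 0.5), 100, n)
  y <- rep(c(TRUE, FALSE), each = n / 2)
  expr["g001", y] <- expr["g001", y] + 2      # planted up in the case class
  tab <- de_table(expr, y)
  perm <- sample(n)
  tab2 <- de_table(expr[, perm], y[perm])
  expect_equal(tab, tab2)
  expect_gt(tab$l2fc[tab$gene_id == "g001"], 0)  # positive = higher in cases
  expect_equal(tab$gene_id[1], "g001")
  expect_true(all(tab$p_adjusted >= tab$p_value))
})

test_that("planted effects are recovered with controlled error rates", {
  sens <- c(); fpr <- c()
  for (s in 1:3) {
    set.seed(s)
    n <- 500; n_g <- 600; n_de <- 25
    expr <- named_matrix(rnorm(n_g * n, 8, 0.45), n_g, n)
    y <- rep(c(TRUE, FALSE), length.out = n)
    de_ids <- sprintf("g%03d", 1:n_de)
    expr[de_ids, y] <- expr[de_ids, y] + 1.0
    tab <- de_table(expr, y)
    hits <- tab$gene_id[tab$p_adjusted <= 0.05]
    sens <- c(sens, mean(de_ids %in% hits))
    null_tab <- tab[!tab$gene_id %in% de_ids, ]
    fpr <- c(fpr, mean(null_tab$p_value <= 0.05))
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fpr), 0.07)
  expect_gte(mean(fpr), 0.03)
})

test_that("shuffled labels give a calibrated rejection fraction", {
  set.seed(12)
  n <- 200
  expr <- named_matrix(rnorm(2000 * n, 8, 0.5), 2000, n)
  y <- sample(rep(c(TRUE, FALSE), each = n / 2))
  tab <- de_table(expr, y)
  frac <- mean(tab$p_value <= 0.05)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("between-group contrasts drop shared patients and count unions", {
  set.seed(4)
  expr <- named_matrix(rnorm(50 * 12, 8, 0.5), 50, 12)
  ids <- colnames(expr)
  groups <- structure(list(
    groups = list(t1 = ids[1:5], t2 = ids[5:9], t3 = ids[10:12]),
    exclusive = stats::setNames(c(rep("t1", 4), "shared", rep("t2", 4),
                                  rep("t3", 3)), ids),
    shared_fraction = 1 / 12), class = "endotype_groups")
  tab <- contrast_between_groups(expr, groups, "t1", "t2")
  expect_equal(unique(tab$n_case), 4L)       # shared patient absent from both sides
  expect_equal(unique(tab$n_control), 4L)
  tab_u <- contrast_between_groups(expr, groups, c("t1", "t2"), "t3")
  expect_equal(unique(tab_u$n_case), 8L)     # union uses summed exclusive members
  expect_error(contrast_between_groups(expr, groups, "t1", "missing"), "fewer than 2")
})

test_that("clinical comparisons respect availability rules and null calibration", {
  ids <- sprintf("p%03d", 1:30)
  groups <- structure(list(
    groups = list(t1 = ids[1:10], t2 = ids[11:20], t3 = ids[21:30]),
    exclusive = stats::setNames(rep(c("t1", "t2", "t3"), each = 10), ids),
    shared_fraction = 0), class = "endotype_groups")
  set.seed(6)
  cohort <- tibble::tibble(patient_id = ids, death28 = rbinom(30, 1, 0.2),
                           lactate = rnorm(30, 2), sparse = c(rnorm(1), rep(NA, 9),
                                                              rnorm(20)),
                           label = sample(letters, 30, TRUE))
  out <- clinical_compare(cohort, groups, features = c("lactate", "sparse", "label"))
  expect_equal(out$skipped_reason[out$feature == "sparse"],
               "fewer than 2 observations in a group")
  expect_equal(out$skipped_reason[out$feature == "label"], "non-numeric")
  expect_true(is.na(out$anova_p[out$feature == "sparse"]))
  lact <- out[out$feature == "lactate", ]
  expect_false(is.na(lact$anova_p))
  expect_equal(nrow(lact$pairwise[[1]]), 3L)   # all group pairs
  # merged-union contrast
  un <- clinical_compare(cohort, groups, features = "lactate",
                         pairs = list(list(a = c("t1", "t2"), b = "t3")))
  expect_equal(un$pairwise[[1]]$contrast, "t1+t2 vs t3")

  # ANOVA p-values calibrated under the null
  set.seed(9)
  rej <- mean(vapply(1:400, function(i) {
    cohort$feat <- rnorm(30)
    clinical_compare(cohort, groups, features = "feat")$anova_p[1] <= 0.05
  }, logical(1)))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
})
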