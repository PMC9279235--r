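test_that("AUC matches the pair-counting oracle", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)

  set.seed(14)
  for (r in 1:100) {
    n <- sample(6:30, 1)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
  }
  expect_error(auc(1:4, c(1, 1, 1, 1)), "Both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  for (r in 1:10) {
    scores <- rnorm(60)
    labels <- rbinom(60, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels),
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("identical paired scores give a degenerate bootstrap and p = 1", {
  set.seed(3)
  s <- runif(40); lab <- rep(c(0, 1), 20)
  bt <- bootstrap_auc_difference(s, s, lab, n_boot = 200, seed = 1)
  expect_equal(bt$diff, 0)
  expect_equal(bt$ci95, c(0, 0))
  pt <- permutation_test_auc(s, s, lab, n_perm = 200, seed = 1)
  expect_equal(pt$p_value, 1.0)
})

test_that("a large paired effect yields a CI excluding zero", {
  set.seed(6)
  n <- 200
  lab <- rbinom(n, 1, 0.5)
  good <- lab + rnorm(n, 0, 0.3)   # strongly separating
  rand <- rnorm(n)                 # uninformative
  bt <- bootstrap_auc_difference(good, rand, lab, n_boot = 2000, seed = 2)
  expect_gt(bt$ci95[1], 0)
  # deterministic under a fixed seed
  bt2 <- bootstrap_auc_difference(good, rand, lab, n_boot = 2000, seed = 2)
  expect_identical(bt$ci95, bt2$ci95)
  pt <- permutation_test_auc(good, rand, lab, n_perm = 500, seed = 3)
  expect_lt(pt$p_value, 0.05)
  expect_gte(pt$p_value, 1 / 501)
})

test_that("participant-level resampling keeps correlated nodules together", {
  set.seed(9)
  n <- 120
  gid <- rep(sprintf("P%02d", 1:40), each = 3)
  lab <- rep(rbinom(40, 1, 0.4), each = 3)
  a <- lab + rnorm(n); b <- rnorm(n)
  bt <- bootstrap_auc_difference(a, b, lab, group_ids = gid,
                                 n_boot = 300, seed = 4)
  expect_length(bt$draws, 300)
  expect_true(all(is.finite(bt$draws)))
})

test_that("bootstrap CI width shrinks with sample size", {
  widths <- sapply(c(100, 400, 1600), function(n) {
    mean(sapply(1:20, function(s) {
      set.seed(1000 + 17 * s + n)
      lab <- rep(c(0, 1), n / 2)
      a <- lab + rnorm(n, 0, 1.5)
      b <- lab + rnorm(n, 0, 3)
      bt <- bootstrap_auc_difference(a, b, lab, n_boot = 200, seed = s)
      diff(bt$ci95)
    }))
  })
  expect_true(all(diff(widths) < 0))
})

test_that("p-values never fall below the add-one floor", {
  set.seed(10)
  lab <- rep(c(0, 1), 30)
  a <- lab + rnorm(60, 0, 0.1)
  b <- -a
  pt <- permutation_test_auc(a, b, lab, n_perm = 99, seed = 5)
  expect_gte(pt$p_value, 1 / 100)
})

test_that("compare_auc bundles the paired machinery with tidiers", {
  set.seed(12)
  n <- 80
  lab <- rep(c(0, 1), n / 2)
  a <- lab + rnorm(n); b <- rnorm(n)
  cmp <- compare_auc(a, b, lab, n_boot = 200, n_perm = 200, seed = 1,
                     name_a = "esd", name_b = "axial")
  expect_s3_class(cmp, "model_comparison")
  expect_equal(cmp$diff, cmp$auc_a - cmp$auc_b)
  expect_true(cmp$ci95[1] <= cmp$ci95[2])
  td <- tidy(cmp)
  expect_equal(td$model, c("esd", "axial"))
  gl <- glance(cmp)
  expect_equal(gl$diff, cmp$diff)
  expect_equal(gl$resampling_unit, "nodule")
  p <- autoplot(cmp)
  expect_s3_class(p, "ggplot")
})

test_that("subgroup comparisons equal filtered direct computation", {
  set.seed(13)
  n <- 120
  tab <- tibble::tibble(
    participant_id = sprintf("P%03d", rep(1:60, each = 2)),
    nodule_type = rep(c("solid", "part_solid"), c(84, 36)),
    label = rbinom(n, 1, 0.4),
    score_a = NA_real_, score_b = rnorm(n))
  tab$score_a <- tab$label + rnorm(n)
  res <- subgroup_compare(tab, "nodule_type", n_boot = 100, n_perm = 100, seed = 2)
  expect_setequal(names(res), c("solid", "part_solid"))
  for (level in names(res)) {
    sub <- tab[tab$nodule_type == level, ]
    expect_equal(res[[level]]$auc_a, auc(sub$score_a, sub$label))
    expect_equal(res[[level]]$auc_b, auc(sub$score_b, sub$label))
  }

  # constant stratifier reproduces the unstratified comparison
  tab1 <- tab; tab1$nodule_type <- "solid"
  res1 <- subgroup_compare(tab1, "nodule_type", n_boot = 100, n_perm = 100, seed = 2)
  direct <- compare_auc(tab1$score_a, tab1$score_b, tab1$label,
                        tab1$participant_id, n_boot = 100, n_perm = 100, seed = 2)
  expect_equal(res1$solid$auc_a, direct$auc_a)
  expect_equal(res1$solid$ci95, direct$ci95)
  expect_equal(res1$solid$p_value, direct$p_value)

  # single-class stratum is skipped with a warning
  tab2 <- tab
  tab2$label[tab2$nodule_type == "part_solid"] <- 0
  expect_warning(res2 <- subgroup_compare(tab2, "nodule_type",
                                          n_boot = 50, n_perm = 50, seed = 2),
                 "skipped")
  expect_false("part_solid" %in% names(res2))
})

test_that("roc_points traces a monotone staircase from (0,0) to (1,1)", {
  set.seed(16)
  scores <- rnorm(30); labels <- rbinom(30, 1, 0.5)
  pts <- roc_points(scores, labels)
  expect_equal(pts$tpr[1], 0); expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1); expect_equal(pts$fpr[nrow(pts)], 1)
  expect_true(all(diff(pts$tpr) >= 0))
  expect_true(all(diff(pts$fpr) >= 0))
})
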