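test_that("placement AUC reproduces hand-checkable orderings", {
  # concordant 3 of the 4 event/non-event pairs
  expect_equal(auc_delong(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))$auc, 0.75)
  expect_equal(auc_delong(c(5, 4, 2, 1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc_delong(c(1, 1, 1, 1), c(1, 0, 1, 0))$auc, 0.5)
  set.seed(1)
  null <- auc_delong(runif(4000), rbinom(4000, 1, 0.3))
  expect_lt(abs(null$auc - 0.5), 0.03)
})

test_that("placement AUC equals brute-force pairwise concordance, with ties", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(10:200, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # heavy ties
    y <- rbinom(n, 1, 0.35)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(auc_delong(scores, y)$auc, oracle_auc_pairs(scores, y))
  }
})

test_that("AUC and DeLong interval agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  scores <- rnorm(120)
  y <- rbinom(120, 1, plogis(scores))
  ours <- auc_delong(scores, y)
  ref <- pROC::roc(y, scores, quiet = TRUE, direction = "<")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)))
  ref_ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(ours$ci, ref_ci[c(1, 3)], tolerance = 1e-8)
})

test_that("ROC points trace the empirical operating characteristics", {
  pts <- roc_curve_points(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0))
  expect_equal(pts$fpr, c(0, 0, 0.5, 0.5, 1, 1))
  expect_equal(pts$tpr, c(0, 0.5, 0.5, 1, 1, 1))
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
})

test_that("paired AUC comparison detects identical, opposite and reference cases", {
  y <- rep(c(1, 0), 10)
  s <- seq_len(20)
  same <- compare_auc(s, s, y)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  perfect <- ifelse(y == 1, 1, 0) + runif(20, 0, 0.1)
  opp <- compare_auc(perfect, -perfect, y)
  expect_equal(opp$difference, 1)
  expect_lt(opp$p, 0.01)
  expect_error(compare_auc(1:5, 1:4, c(1, 0, 1, 0, 1)), "paired")
})

test_that("paired DeLong p-value matches an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(47)
  x1 <- rnorm(150)
  x2 <- 0.5 * x1 + rnorm(150)
  y <- rbinom(150, 1, plogis(x1))
  ours <- compare_auc(x1, x2, y)
  ra <- pROC::roc(y, x1, quiet = TRUE, direction = "<")
  rb <- pROC::roc(y, x2, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$p, as.numeric(ref$p.value), tolerance = 1e-8)
})

test_that("bootstrap sensitivity interval brackets the DeLong difference", {
  set.seed(53)
  x1 <- rnorm(100)
  x2 <- rnorm(100)
  y <- rbinom(100, 1, plogis(x1))
  cmp <- compare_auc(x1, x2, y, bootstrap = 500, seed = 9)
  expect_true(cmp$boot_ci[1] <= cmp$difference &&
                cmp$difference <= cmp$boot_ci[2])
  cmp2 <- compare_auc(x1, x2, y, bootstrap = 500, seed = 9)
  expect_equal(cmp$boot_ci, cmp2$boot_ci)
})
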