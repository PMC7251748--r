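# helper: balanced feature matrix with a given class separation (in
# within-class SDs) on every column
sep_data <- function(n_per_class, p, delta, seed) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * p, delta), n_per_class),
             matrix(stats::rnorm(n_per_class * p, 0), n_per_class))
  labels <- rep(c("PF", "NS"), each = n_per_class)
  list(x = x, labels = labels)
}

test_that("a separable problem is learned perfectly", {
  d <- sep_data(30, 1, 10, seed = 61)     # PF >> NS on one feature
  model <- fit_bagging(d$x, d$labels, n_trees = 30, seed = 1)
  out <- predict(model, d$x)
  expect_equal(out$label, d$labels)
  expect_true(all(out$vote_pf >= 0 & out$vote_pf <= 1))
})

test_that("bagging is deterministic given the seed", {
  d <- sep_data(25, 4, 1, seed = 62)
  test <- sep_data(10, 4, 1, seed = 63)
  m1 <- fit_bagging(d$x, d$labels, n_trees = 15, seed = 9)
  m2 <- fit_bagging(d$x, d$labels, n_trees = 15, seed = 9)
  expect_identical(predict(m1, test$x), predict(m2, test$x))
})

test_that("T = 1 without bootstrap equals the single tree", {
  d <- sep_data(20, 3, 2, seed = 64)
  m <- fit_bagging(d$x, d$labels, n_trees = 1, seed = 1, bootstrap = FALSE)
  out <- predict(m, d$x)
  expect_true(all(out$vote_pf %in% c(0, 1)))
  expect_equal(out$label, d$labels)       # a full tree separates training
})

test_that("even split votes break toward NS", {
  leaf_pf <- matrix(c(0, 0, 0, 0, 1), 1,
                    dimnames = list(NULL, c("feature", "threshold", "left",
                                            "right", "pred")))
  leaf_ns <- leaf_pf; leaf_ns[1, "pred"] <- 0
  model <- structure(list(trees = list(leaf_pf, leaf_ns), n_trees = 2L,
                          p = 1L), class = "pf_bagging")
  out <- predict(model, matrix(0, 1, 1))
  expect_equal(out$vote_pf, 0.5)
  expect_equal(out$label, "NS")
})

test_that("degenerate inputs raise the documented errors", {
  d <- sep_data(10, 2, 1, seed = 65)
  expect_error(fit_bagging(d$x[1:10, ], d$labels[1:10]),
               "degenerate-training")
  m <- fit_bagging(d$x, d$labels, n_trees = 3, seed = 1)
  expect_error(predict(m, matrix(0, 2, 5)), "shape error")
  expect_error(cross_validate(d$x[1:12, ], d$labels[c(1:6, 11:16)], k = 10),
               "config error")
})

test_that("AUC has the right anchors and tie handling", {
  labels <- rep(c("PF", "NS"), each = 10)
  expect_equal(auc_score(c(rep(1, 10), rep(0, 10)), labels), 100)
  expect_equal(auc_score(rep(0.4, 20), labels), 50)
  expect_equal(auc_score(c(rep(0, 10), rep(1, 10)), labels), 0)
})

test_that("cross-validation metrics match a confusion-matrix oracle", {
  d <- sep_data(20, 2, 8, seed = 66)
  cv <- cross_validate(d$x, d$labels, k = 5, repeats = 2, n_trees = 10,
                       seed = 3)
  expect_equal(unname(cv$accuracy["mean"]), 100)
  expect_equal(unname(cv$sensitivity["mean"]), 100)
  expect_equal(unname(cv$specificity["mean"]), 100)
  expect_equal(unname(cv$auc["mean"]), 100)
})

test_that("repeat-1 metrics do not depend on the number of repeats", {
  d <- sep_data(15, 3, 0.8, seed = 67)
  cv1 <- cross_validate(d$x, d$labels, k = 5, repeats = 1, n_trees = 10,
                        seed = 4)
  cv3 <- cross_validate(d$x, d$labels, k = 5, repeats = 3, n_trees = 10,
                        seed = 4)
  expect_equal(cv1$per_repeat[1, ], cv3$per_repeat[1, ])
})

test_that("per-consonant metrics are produced for every stratum", {
  d <- sep_data(18, 2, 6, seed = 68)
  cons <- rep(rep(c("s", "sh", "x"), each = 6), 2)
  cv <- cross_validate(d$x, d$labels, consonants = cons, k = 3,
                       repeats = 2, n_trees = 10, seed = 5)
  expect_setequal(unique(cv$per_consonant$consonant), c("s", "sh", "x"))
  expect_true(all(cv$per_consonant$mean >= 0 & cv$per_consonant$mean <= 100))
})

test_that("feature significance flags shifted classes and not identical ones", {
  set.seed(69)
  x_same <- matrix(stats::rnorm(400), 40)
  labels <- rep(c("PF", "NS"), each = 20)
  same <- feature_significance(x_same[c(1:20, 1:20), ],
                               labels)   # identical class distributions
  expect_equal(same$H[same$consonant == "all"], 0L)
  d <- sep_data(50, 5, 3, seed = 70)     # 3 pooled-SD shift
  shifted <- feature_significance(d$x, d$labels)
  expect_equal(shifted$H[shifted$consonant == "all"], 1L)
  expect_lt(shifted$p[shifted$consonant == "all"], 0.01)
  expect_true(all(shifted$p >= 0 & shifted$p <= 1))
})

test_that("combining feature blocks concatenates dimensions", {
  feats <- data.frame(source_id = "a", consonant = "s", label = "PF")
  feats[paste0("p_", 1:10)] <- as.list(runif(10))
  feats[paste0("df_", 1:10)] <- as.list(runif(10))
  expect_equal(ncol(feature_matrix(feats, "csifs")$x) +
                 ncol(feature_matrix(feats, "ospp")$x),
               ncol(feature_matrix(feats, "both")$x))
  expect_equal(ncol(feature_matrix(feats, "both")$x), 20L)
})
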