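separable_toy <- function(n = 20) {
  # two features, positives shifted far from negatives
  withr::with_seed(3, tibble::tibble(
    f1 = c(rnorm(n / 2, 5), rnorm(n / 2, -5)),
    f2 = c(rnorm(n / 2, -5), rnorm(n / 2, 5))
  ))
}

test_that("set balancing cuts to the smaller size without replacement", {
  pos <- tibble::tibble(x = 1:100)
  neg <- tibble::tibble(x = 101:160)
  bal <- balance_sets(pos, neg, seed = 1)
  expect_equal(nrow(bal$pos), 60)
  expect_equal(nrow(bal$neg), 60)
  expect_identical(bal$neg, neg)                 # smaller passes through
  expect_equal(length(unique(bal$pos$x)), 60)    # no replacement
  bal2 <- balance_sets(pos, neg, seed = 1)
  expect_identical(bal, bal2)                    # seeded determinism
  eq <- balance_sets(pos[1:60, ], neg, seed = 2)
  expect_identical(eq$pos, pos[1:60, ])          # equal sizes: identity
  expect_error(balance_sets(pos[0, ], neg, seed = 1), "nonempty")
})

test_that("the forest separates a separable toy set and is deterministic", {
  X <- separable_toy()
  y <- rep(1:0, each = 10)
  m <- train_forest(X, y, seed = 7)
  s <- predict_scores(m, X)
  expect_gt(min(s[y == 1]), max(s[y == 0]))      # trees split perfectly
  m2 <- train_forest(X, y, seed = 7)
  Xnew <- separable_toy(40)
  expect_identical(predict_scores(m, Xnew), predict_scores(m2, Xnew))
  expect_error(train_forest(X, rep(1, 20), seed = 1), "both classes")
})

test_that("scores are voting fractions aligned by column name", {
  X <- separable_toy()
  y <- rep(1:0, each = 10)
  m <- train_forest(X, y, n_trees = 100, seed = 7)
  s <- predict_scores(m, X)
  expect_true(all(abs(s * 100 - round(s * 100)) < 1e-9))  # multiples of 1/100
  expect_true(all(s >= 0 & s <= 1))
  # shuffled columns give identical scores
  expect_identical(predict_scores(m, X[, c("f2", "f1")]), s)
  expect_error(predict_scores(m, X["f1"]), "lacks")
})

test_that("AUC matches hand examples and the pairwise-concordance oracle", {
  expect_equal(compute_auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_equal(compute_auc(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1.0)
  expect_equal(compute_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_error(compute_auc(c(0.1, 0.2), c(1, 1)), "both classes")
  withr::with_seed(21, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      scores <- round(runif(n), 2)  # rounded to force ties sometimes
      labels <- sample(0:1, n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      expect_equal(compute_auc(scores, labels),
                   oracle_auc(scores, labels))
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(22, {
    scores <- runif(200)
    labels <- rbinom(200, 1, plogis(3 * (scores - 0.5)))
    expect_equal(
      compute_auc(scores, labels),
      as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                     direction = "<")))
    )
  })
})

test_that("cross-validation is seeded, stratified and near-chance on noise", {
  withr::with_seed(30, {
    X <- tibble::as_tibble(matrix(rnorm(200 * 10), 200,
                                  dimnames = list(NULL, paste0("f", 1:10))))
  })
  y <- rep(1:0, each = 100)
  cv <- cross_validate(X, y, n_folds = 5, n_rounds = 3, n_trees = 50,
                       seed = 31)
  expect_length(cv$auc, 3)
  expect_gt(cv$mean_auc, 0.40)
  expect_lt(cv$mean_auc, 0.60)
  cv2 <- cross_validate(X, y, n_folds = 5, n_rounds = 3, n_trees = 50,
                        seed = 31)
  expect_identical(cv$auc, cv2$auc)
  expect_equal(nrow(cv$fold_auc), 15)
  expect_error(cross_validate(X[1:12, ], y[c(1:10, 101:102)], n_folds = 5,
                              seed = 1),
               "at least")
})

test_that("tidy/glance/autoplot methods summarize CV reports", {
  withr::with_seed(33, {
    X <- tibble::as_tibble(matrix(rnorm(60 * 4), 60,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  })
  cv <- cross_validate(X, rep(1:0, each = 30), n_folds = 3, n_rounds = 2,
                       n_trees = 20, seed = 5)
  td <- generics::tidy(cv)
  expect_equal(names(td), c("round", "auc"))
  gl <- generics::glance(cv)
  expect_equal(gl$mean_auc, cv$mean_auc)
  expect_s3_class(ggplot2::autoplot(cv), "ggplot")
})

test_that("the AUC-difference z-test follows the Hanley-McNeil SE formula", {
  # z = 0 when the AUCs agree
  expect_equal(auc_difference_test(0.9, 0.9, 100, 100)$p_value, 1.0)
  # monotone decrease of p with sample size
  ps <- vapply(c(100, 1000, 10000), function(n) {
    auc_difference_test(0.910, 0.894, n, n)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  # near-symmetry for close AUCs (SE is evaluated at the expected AUC)
  p_ab <- auc_difference_test(0.910, 0.894, 500, 500)$p_value
  p_ba <- auc_difference_test(0.894, 0.910, 500, 500)$p_value
  expect_equal(p_ab, p_ba, tolerance = 0.1)
  # hand check of the SE at A = 0.8, n_pos = n_neg = 2
  A <- 0.8; q1 <- A / (2 - A); q2 <- 2 * A^2 / (1 + A)
  se <- sqrt((A * (1 - A) + (q1 - A^2) + (q2 - A^2)) / 4)
  expect_equal(auc_difference_test(0.7, 0.8, 2, 2)$se, se)
})
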