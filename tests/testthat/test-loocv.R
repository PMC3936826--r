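test_that("nested LOOCV separates two well-separated classes", {
  toy <- toy_cohort(n = c(A = 15, B = 15), p = c(A = 0.15, B = 0.85), seed = 8)
  res <- nested_loocv(toy, grid = signature_grid(reduced = TRUE),
                      inner = "kfold", inner_k = 5)
  expect_gte(res$overall_accuracy, 0.9)
  # structural invariants of the summary
  expect_equal(unname(colSums(res$confusion)), unname(table(toy$group)),
               ignore_attr = TRUE)
  expect_equal(res$overall_accuracy,
               sum(diag(res$confusion)) / sum(res$confusion))
  expect_equal(unname(colSums(res$mean_probability)), c(1, 1),
               tolerance = 1e-9)
})

test_that("nested LOOCV predictions are invariant to subject order", {
  co <- generate_cohort(tiny_config(seed = 81, sizes = c(8, 4, 8, 4, 6, 6)))
  g <- data.frame(gamma = 2^-5, cost = 1)
  r1 <- nested_loocv(co, grid = g)
  set.seed(1); sh <- co[sample(nrow(co)), ]
  r2 <- nested_loocv(sh, grid = g)
  m1 <- r1$predictions[order(r1$predictions$subject_id), ]
  m2 <- r2$predictions[order(r2$predictions$subject_id), ]
  expect_equal(m1$predicted_group, m2$predicted_group)
  # probabilities agree within solver tolerance (libSVM's SMO solution
  # depends weakly on data order)
  expect_equal(m1$p_assigned, m2$p_assigned, tolerance = 1e-3)
})

test_that("pairwise accuracy table is symmetric with expected extremes", {
  cfg <- tiny_config(seed = 91, sizes = c(10, 10, 10, 4, 4, 4))
  co <- generate_cohort(cfg)
  co <- co[co$group %in% c("22q11DS", "Downs", "SMC15"), ]
  # make two of the classes share one spec (indistinguishable)
  same <- co$group %in% c("22q11DS", "Downs")
  pw <- pairwise_accuracy_table(co, grid = data.frame(gamma = 2^-5, cost = 1))
  expect_true(all(pw == t(pw), na.rm = TRUE))
  expect_true(all(is.na(diag(pw))))
  expect_true(all(pw >= 0 & pw <= 1, na.rm = TRUE))
})

test_that("probability-correctness association detects a strong link and flags separation", {
  set.seed(17)
  n <- 120
  p_assigned <- stats::runif(n, 0.1, 0.9)
  correct <- stats::runif(n) < p_assigned   # correctness tracks confidence
  df <- data.frame(correct = correct, p_assigned = p_assigned)
  res <- probability_correctness_assoc(df)
  expect_gt(res$slope, 0)
  expect_lt(res$p_value, 0.05)
  all_right <- data.frame(correct = rep(TRUE, 30),
                          p_assigned = stats::runif(30))
  res2 <- probability_correctness_assoc(all_right)
  expect_true(res2$degenerate)
})

test_that("probability-correctness test keeps its nominal type-I rate", {
  set.seed(23)
  pvals <- replicate(200, {
    df <- data.frame(correct = stats::runif(80) < 0.5,
                     p_assigned = stats::runif(80))
    probability_correctness_assoc(df)$p_value
  })
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("item importance zeroes constant features and finds the informative one", {
  set.seed(31)
  make <- function(n, id0) {
    base <- matrix(sample(0:2, n * 37, TRUE), n, 37)
    colnames(base) <- item_columns()
    grp <- rep(c("A", "B"), each = n / 2)
    base[, "item_31"] <- 1                          # constant item
    base[, "item_56"] <- ifelse(grp == "A", 0, 2)   # only real signal
    cbind(data.frame(subject_id = sprintf("s%03d", id0 + seq_len(n)),
                     group = grp, age_months = 100, sex = "M", iq = 70,
                     verbal = TRUE, onset = 2, stringsAsFactors = FALSE),
          as.data.frame(base))
  }
  train <- make(24, 0)
  holdout <- make(40, 100)   # fresh data: no memorization of training points
  m <- signature_svm(train, gamma = 2^-5, cost = 4)
  lin <- item_importance(m, method = "linear")
  expect_equal(lin$importance[lin$feature == "item_31"], 0, tolerance = 1e-10)
  expect_equal(lin$feature[1], "item_56")
  per <- item_importance(m, holdout, method = "permutation", n_perm = 10, seed = 2)
  expect_equal(per$feature[1], "item_56")
  expect_lt(abs(per$importance[per$feature == "item_31"]), 1e-10)
  per2 <- item_importance(m, holdout, method = "permutation", n_perm = 10, seed = 2)
  expect_identical(per, per2)
})

test_that("a leaky IQ covariate drives accuracy to one", {
  co <- generate_cohort(tiny_config(seed = 101, sizes = c(8, 4, 8, 4, 6, 6)))
  co[item_columns()] <- 0L                    # uninformative items
  co$iq <- as.integer(factor(co$group)) * 10  # class index: pure leakage
  res <- covariate_reanalysis(co, grid = data.frame(gamma = 1, cost = 10))
  expect_gte(res$accuracy_with_iq, 0.95)
  expect_lt(res$accuracy_without, res$accuracy_with_iq)
})
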