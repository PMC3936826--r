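test_that("allocation is exhaustive, deterministic and consistent", {
  cfg <- tiny_config(seed = 111)
  co <- generate_cohort(cfg)
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  blind <- generate_blind_cohort(tiny_config(seed = 112), 40)
  a1 <- allocate(m, blind)
  a2 <- allocate(m, blind)
  expect_identical(a1$summary, a2$summary)
  expect_equal(sum(a1$summary$n_assigned), 40)
  expect_equal(a1$summary$pct_assigned,
               100 * a1$summary$n_assigned / 40)
  expect_equal(sum(a1$summary$pct_assigned), 100)
  # copies of a single training subject all land in its predicted class
  one <- co[rep(3, 10), ]; one$subject_id <- sprintf("c%02d", 1:10)
  cls <- as.character(predict(m, co[3, , drop = FALSE], type = "class"))
  aa <- allocate(m, one)
  expect_equal(sum(aa$summary$n_assigned[aa$summary$group == cls]), 10)
})

test_that("a missing item column is reported by name", {
  cfg <- tiny_config(seed = 113)
  co <- generate_cohort(cfg)
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  blind <- generate_blind_cohort(cfg, 10)
  blind$item_56 <- NULL
  expect_error(allocate(m, blind), "item_56")
})

test_that("training-set accuracy dominates the nested-LOOCV estimate", {
  co <- generate_cohort(tiny_config(seed = 121, sizes = c(10, 5, 10, 5, 7, 7)))
  g <- data.frame(gamma = 2^-5, cost = 1)
  m <- signature_svm(co, gamma = g$gamma, cost = g$cost)
  train_acc <- mean(as.character(predict(m, co, type = "class")) == co$group)
  cv_acc <- nested_loocv(co, grid = g)$overall_accuracy
  expect_gte(train_acc, cv_acc)
})

test_that("probability comparison behaves on identical and shifted samples", {
  set.seed(7)
  a <- stats::runif(60, 0.3, 0.9)
  same <- compare_probability_distributions(a, a)
  expect_gte(same$mann_whitney_p, 0.99)
  b <- a - 0.25
  shift <- compare_probability_distributions(a, b)
  expect_lt(shift$mann_whitney_p, 0.01)
  expect_error(compare_probability_distributions(a[1:3], a), "at least 5")
})

test_that("structured blind probabilities beat the item-permuted copy", {
  cfg <- tiny_config(seed = 131, sizes = c(20, 8, 20, 8, 14, 14))
  co <- generate_cohort(cfg)
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  blind <- generate_blind_cohort(tiny_config(seed = 132), 150)
  permd <- permute_items(blind, seed = 5)
  pa <- allocate(m, blind)$assignments$p_assigned
  pb <- allocate(m, permd)$assignments$p_assigned
  res <- compare_probability_distributions(pa, pb)
  expect_lt(res$mann_whitney_p, 0.05)
  expect_gt(res$median_a, res$median_b)
})

test_that("label-permutation null is reproducible and favors the largest groups", {
  cfg <- tiny_config(seed = 141, sizes = c(40, 4, 4, 4, 4, 4))
  co <- generate_cohort(cfg)
  blind <- generate_blind_cohort(tiny_config(seed = 142), 50,
                                 weights = stats::setNames(rep(1 / 6, 6),
                                                           cfg$groups))
  n1 <- permuted_label_null(co, blind, n_rep = 3, seed = 9, reselect = FALSE,
                            gamma = 2^-5, cost = 1)
  n2 <- permuted_label_null(co, blind, n_rep = 3, seed = 9, reselect = FALSE,
                            gamma = 2^-5, cost = 1)
  expect_identical(n1$counts, n2$counts)
  expect_equal(rowSums(n1$counts), rep(50, 3), ignore_attr = TRUE)
  # the dominant training group should soak up most null allocations
  expect_equal(names(which.max(colMeans(n1$counts))), "22q11DS")
})
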