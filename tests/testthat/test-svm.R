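test_that("one-vs-one ensemble has k(k-1)/2 binaries and separates clean data", {
  co <- generate_cohort(tiny_config(seed = 61, sizes = rep(6, 6)))
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  expect_s3_class(m, "signature_svm")
  expect_length(m$classifiers, 15)

  toy <- toy_cohort(n = c(A = 12, B = 12), p = c(A = 0.1, B = 0.9))
  fit <- signature_svm(toy, gamma = 2^-5, cost = 4)
  pr <- predict(fit, toy, type = "class")
  expect_equal(mean(as.character(pr) == toy$group), 1.0)
})

test_that("a class with fewer than two members is rejected by name", {
  toy <- toy_cohort(n = c(A = 10, B = 1), p = c(A = 0.2, B = 0.8))
  expect_error(signature_svm(toy, gamma = 0.1, cost = 1), "B")
})

test_that("duplicating every training point leaves the decision function alone", {
  toy <- toy_cohort(n = c(A = 10, B = 10), p = c(A = 0.15, B = 0.85), seed = 3)
  x <- adirsig:::cohort_features(toy)
  y <- factor(toy$group)
  f1 <- fit_ovo_svm(x, y, gamma = 2^-5, cost = 10)
  f2 <- fit_ovo_svm(rbind(x, x), factor(c(as.character(y), as.character(y))),
                    gamma = 2^-5, cost = 10)
  d1 <- adirsig:::ovo_decision_values(f1, x)
  d2 <- adirsig:::ovo_decision_values(f2, x)
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("one-vs-one voting matches a brute-force vote counter", {
  classes <- c("A", "B", "C")
  pair_names <- c("A/B", "A/C", "B/C")
  set.seed(99)
  for (i in 1:200) {
    d <- stats::setNames(round(stats::rnorm(3), 1), pair_names)  # ties likely
    expect_equal(as.character(ovo_vote(d, classes)), brute_vote(d, classes))
  }
  # all pairwise decisions favoring one class
  expect_equal(as.character(ovo_vote(stats::setNames(c(2, 3, 1), pair_names),
                                     classes)), "A")
  # k = 2: vote equals the sign of the single decision value
  expect_equal(as.character(ovo_vote(stats::setNames(-0.3, "A/B"), c("A", "B"))), "B")
  expect_equal(as.character(ovo_vote(stats::setNames(0.3, "A/B"), c("A", "B"))), "A")
})

test_that("predicted probabilities are a proper distribution", {
  co <- generate_cohort(tiny_config(seed = 71))
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  p <- predict(m, co, type = "prob")
  expect_true(all(p >= 0))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
})

test_that("inner selection returns the single grid point trivially", {
  toy <- toy_cohort()
  x <- adirsig:::cohort_features(toy); y <- factor(toy$group)
  g <- data.frame(gamma = 0.2, cost = 4)
  sel <- inner_loocv_select(x, y, g, inner = "kfold", inner_k = 5)
  expect_equal(sel$gamma, 0.2)
  expect_equal(sel$cost, 4)
})

test_that("inner selection prefers the grid point with higher inner accuracy", {
  # a vanishing gamma makes the RBF kernel constant: majority prediction
  toy <- toy_cohort(n = c(A = 14, B = 10), p = c(A = 0.1, B = 0.9), seed = 5)
  x <- adirsig:::cohort_features(toy); y <- factor(toy$group)
  g <- data.frame(gamma = c(1e-9, 0.05), cost = c(1, 1))
  sel <- inner_loocv_select(x, y, g, inner = "loocv")
  expect_equal(sel$gamma, 0.05)
})

test_that("accuracy ties break to the smallest cost, then smallest gamma", {
  toy <- toy_cohort(n = c(A = 10, B = 10), p = c(A = 0.05, B = 0.95), seed = 6)
  x <- adirsig:::cohort_features(toy); y <- factor(toy$group)
  # all points separate this data perfectly -> tie on accuracy
  g <- expand.grid(gamma = c(0.3, 0.02), cost = c(16, 2))
  sel <- inner_loocv_select(x, y, g, inner = "kfold", inner_k = 4)
  expect_equal(sel$cost, 2)
  expect_equal(sel$gamma, 0.02)
})
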