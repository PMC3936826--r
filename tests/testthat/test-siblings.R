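test_that("concordance chi-square has df (k-1)^2 and matches chisq.test when dense", {
  pr <- fake_pairs(400, seed = 3, groups = LETTERS[1:4])
  res <- suppressWarnings(concordance_test(pr, classes = LETTERS[1:6]))
  expect_equal(res$df, 25)
  # dual route on a dense 4x4 table
  res4 <- suppressWarnings(concordance_test(pr, classes = LETTERS[1:4]))
  ref <- suppressWarnings(stats::chisq.test(table(pr$group1, pr$group2),
                                            correct = FALSE))
  expect_equal(res4$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res4$df, unname(ref$parameter))
  expect_equal(res4$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("perfect concordance produces an extreme chi-square", {
  pr <- fake_pairs(200, seed = 5, groups = LETTERS[1:4], concordant_frac = 1)
  res <- suppressWarnings(concordance_test(pr))
  expect_gt(res$statistic, stats::qchisq(0.999, res$df))
  one <- pr; one$group1 <- "A"; one$group2 <- "A"
  expect_error(concordance_test(one), "2 distinct")
})

test_that("probability correlation is exact in the degenerate limits", {
  pr <- fake_pairs(100, seed = 7)
  pr$prob2 <- pr$prob1
  expect_equal(probability_correlation(pr)$r, 1)
  pr$prob2 <- rep(0.5, 100)
  expect_true(probability_correlation(pr)$zero_variance)
  expect_error(probability_correlation(fake_pairs(5)), "at least 10")
})

test_that("correlations are symmetric under swapping the sibling labels", {
  pr <- fake_pairs(150, r_prob = 0.8, seed = 9)
  sw <- pr
  sw[c("group1", "group2", "prob1", "prob2", "pc1_1", "pc1_2")] <-
    pr[c("group2", "group1", "prob2", "prob1", "pc1_2", "pc1_1")]
  expect_equal(probability_correlation(pr)$r, probability_correlation(sw)$r)
  expect_equal(pc1_similarity(pr)$r_all, pc1_similarity(sw)$r_all)
})

test_that("Fisher z comparison is null for identical strata", {
  expect_equal(fisher_z_compare(0.4, 50, 0.4, 50),
               list(z = 0, p_value = 1))
  pr <- fake_pairs(60, seed = 11)
  # duplicate the concordant stratum into the discordant one
  conc <- pr[pr$concordant, ]
  disc <- conc; disc$group2 <- "ZZ"; disc$concordant <- FALSE
  disc$family_id <- paste0(disc$family_id, "d")
  both <- rbind(conc, disc); class(both) <- class(pr)
  sp <- split_correlation(both)
  expect_equal(sp$r_concordant, sp$r_discordant)
  expect_equal(sp$p_value, 1, tolerance = 1e-12)
  # all-concordant: discordant stratum unavailable
  sponly <- split_correlation(conc)
  expect_true(is.na(sponly$r_discordant))
})

test_that("variance-equality F-test detects shrunken concordant differences", {
  pr <- fake_pairs(200, seed = 13)
  d <- pr$prob1 - pr$prob2
  pr$prob2[pr$concordant] <- pr$prob1[pr$concordant] -
    0.1 * d[pr$concordant]
  res <- variance_equality_test(pr)
  expect_gt(res$F, 1)
  expect_lt(res$p_value, 0.05)
  # reciprocal identity under swapping strata
  swapped <- pr; swapped$concordant <- !swapped$concordant
  expect_equal(variance_equality_test(swapped)$F, 1 / res$F, tolerance = 1e-12)
})

test_that("severity-vs-specificity regressions recover the generating pattern", {
  set.seed(15)
  n <- 200
  pr <- fake_pairs(n, seed = 15)
  # specificity-only signal: prob2 tracks prob1, severities are noise
  pr$prob2 <- 0.6 * pr$prob1 + stats::rnorm(n, 0, 0.1)
  res <- severity_vs_specificity(pr)
  spec <- res[res$direction == "sib1_predicts_sib2", ]
  expect_lt(spec$p_value[spec$predictor == "probability"], 0.01)
  expect_gt(spec$p_value[spec$predictor == "mean_items"], 0.05)
  expect_error(severity_vs_specificity(fake_pairs(3)), "at least 20")
})

test_that("PC1 similarity is exact for duplicated profiles", {
  pr <- fake_pairs(120, seed = 17)
  pr$pc1_2 <- pr$pc1_1
  res <- pc1_similarity(pr)
  expect_equal(res$r_all, 1)
})

test_that("pair table aligns families and flags concordance", {
  cfg <- tiny_config(seed = 151)
  co <- generate_cohort(cfg)
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  sibs <- generate_sib_pairs(tiny_config(seed = 152), 30)
  tab <- sib_pair_table(sibs, m)
  expect_equal(nrow(tab), 30)
  expect_equal(tab$concordant, tab$group1 == tab$group2)
  expect_false(any(duplicated(tab$family_id)))
})

test_that("partial class sharing yields a concordant-vs-discordant PC1 contrast", {
  co <- generate_cohort(default_generator_config(seed = 1,
                                                 sizes = c(30, 10, 30, 10, 20, 20)))
  m <- signature_svm(co, gamma = 2^-5, cost = 1)
  uniform <- stats::setNames(rep(1 / 6, 6), m$classes)
  sibs <- generate_sib_pairs(default_generator_config(seed = 411), 300,
                             sib_icc = 0.5, class_share = 0.5,
                             weights = uniform)
  pr <- sib_pair_table(sibs, m)
  p1 <- pc1_similarity(pr)
  expect_gt(p1$r_concordant, p1$r_discordant)
  expect_gt(p1$z, 0)
  expect_lt(p1$p_compare, 0.05)
})

test_that("sibling tests hold their type-I rate under independent sibs", {
  # direct null simulation at the statistics level: independent pair members
  set.seed(19)
  nrep <- 300
  rej <- matrix(FALSE, nrep, 3,
                dimnames = list(NULL, c("prob_cor", "var_F", "pc1_z")))
  for (r in seq_len(nrep)) {
    pr <- fake_pairs(120, r_prob = 0, seed = 1000 + r)
    rej[r, "prob_cor"] <- probability_correlation(pr)$p_value < 0.05
    rej[r, "var_F"] <- variance_equality_test(pr)$p_value < 0.05
    rej[r, "pc1_z"] <- {
      z <- split_correlation(pr, "pc1_1", "pc1_2")
      !is.na(z$p_value) && z$p_value < 0.05
    }
  }
  rates <- colMeans(rej)
  expect_true(all(rates > 0.02 & rates < 0.08))
})
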