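test_that("generation is reproducible from the seed and seed-sensitive", {
  a <- generate_cohort(tiny_config(seed = 11))
  b <- generate_cohort(tiny_config(seed = 11))
  c <- generate_cohort(tiny_config(seed = 12))
  expect_identical(a, b)
  expect_false(identical(a[item_columns()], c[item_columns()]))
})

test_that("very large negative shifts floor all item codes at zero", {
  cfg <- tiny_config(seed = 2, sizes = rep(5, 6))
  for (g in seq_along(cfg$specs)) cfg$specs[[g]]$item_shift[] <- -20
  expect_warning(co <- generate_cohort(cfg), "degenerate")
  expect_true(all(cohort_item_matrix(co) == 0))
})

test_that("ordered-threshold marginals match the closed-form probit", {
  cfg <- tiny_config(seed = 3, sizes = c(4000, 5, 5, 5, 5, 5))
  shift <- 0.4
  cfg$specs[[1]]$item_shift[] <- shift
  co <- generate_cohort(cfg)
  m <- cohort_item_matrix(co[co$group == cfg$groups[1], ])
  s <- sqrt(1 + cfg$severity_sd^2)
  p1 <- pnorm((shift - cfg$cutpoints[1]) / s)
  p2 <- pnorm((shift - cfg$cutpoints[2]) / s)
  expect_equal(mean(m >= 1), p1, tolerance = 0.02)
  expect_equal(mean(m >= 2), p2, tolerance = 0.05)
})

test_that("calibration reproduces the published group domain means", {
  cfg <- default_generator_config(seed = 9,
                                  sizes = c(5, 5, 5, 10000, 5, 5))
  co <- generate_cohort(cfg)
  sm <- co[co$group == "SMC15", ]
  ds <- domain_scores(sm)
  target <- c(15.6, 13.6, 6.5)
  got <- c(mean(ds$dI), mean(ds$dII), mean(ds$dIII))
  expect_true(all(abs(got - target) / target < 0.10))
})

test_that("calibration residuals shrink with calibration sample size", {
  err_at <- function(n) {
    cfg <- default_generator_config(seed = 13, sizes = c(5, 5, 5, n, 5, 5))
    ds <- domain_scores(generate_cohort(cfg))
    grp <- generate_cohort(cfg)$group  # same seed: same cohort
    i <- grp == "SMC15"
    mean(abs(c(mean(ds$dI[i]) - 15.6, mean(ds$dII[i]) - 13.6,
               mean(ds$dIII[i]) - 6.5)))
  }
  expect_lt(err_at(8000), err_at(300) + 0.3)
})

test_that("infeasible calibration targets name the domain and ceiling", {
  expect_error(
    calibrate_specs(data.frame(group = "G", dI = 35, dII = 5, dIII = 2)),
    "domain I.*ceiling 30")
})

test_that("item permutation preserves marginals and destroys correlation", {
  cfg <- tiny_config(seed = 21, sizes = c(60, 10, 60, 10, 30, 30))
  co <- generate_cohort(cfg)
  pe <- permute_items(co, seed = 99)
  for (cc in sample(item_columns(), 8))
    expect_equal(table(co[[cc]]), table(pe[[cc]]))
  offdiag <- function(x) { cm <- suppressWarnings(cor(cohort_item_matrix(x)))
    mean(abs(cm[upper.tri(cm)]), na.rm = TRUE) }
  expect_lt(offdiag(pe), offdiag(co) / 2)
  one <- co[1, , drop = FALSE]
  expect_identical(permute_items(one, seed = 1), one)
})

test_that("label permutation preserves the label multiset and profiles", {
  co <- generate_cohort(tiny_config(seed = 31))
  pe <- permute_labels(co, seed = 7)
  expect_equal(sort(pe$group), sort(co$group))
  expect_identical(pe[item_columns()], co[item_columns()])
  same <- co; same$group <- "only"
  expect_identical(permute_labels(same, seed = 1)$group, same$group)
})

test_that("sibling generator respects mixture, sharing and independence limits", {
  cfg <- tiny_config(seed = 41)
  w <- stats::setNames(c(0, 0, 0, 0, 1, 0), cfg$groups)
  s <- generate_sib_pairs(cfg, 30, weights = w)
  expect_true(all(s$latent_class == "TSC"))
  expect_equal(nrow(s), 60)
  expect_error(generate_sib_pairs(cfg, 0), "positive")

  # independence limit: near-zero PC1 correlation between sibs
  ind <- generate_sib_pairs(tiny_config(seed = 42), 400, sib_icc = 0,
                            class_share = 0)
  pca <- pca_fit(ind, m = 1)
  pc1 <- pca_project(pca, ind)[, 1]
  s1 <- ind$sib_role == "sib1"
  expect_lt(abs(cor(pc1[s1], pc1[!s1])), 0.12)

  # full-sharing limit: strong PC1 correlation
  shr <- generate_sib_pairs(tiny_config(seed = 43), 400, sib_icc = 1,
                            class_share = 1)
  pca2 <- pca_fit(shr, m = 1)
  q1 <- pca_project(pca2, shr)[, 1]
  t1 <- shr$sib_role == "sib1"
  expect_gt(cor(q1[t1], q1[!t1]), 0.8)
})

test_that("pooled synthetic total score is close to the published average", {
  # expected value check at a large pooled n with the published group mix
  cfg <- default_generator_config(seed = 51,
                                  sizes = c(90, 21, 88, 22, 50, 51) * 10)
  ds <- domain_scores(generate_cohort(cfg))
  expect_equal(mean(ds$total), 20.6, tolerance = 0.03)
})
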