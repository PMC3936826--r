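#' Build the sibling-pair analysis table
#'
#' Aligns the classifier output for affected sibling pairs: for each family
#' the two siblings' assigned classes, assigned-class probabilities, mean
#' item scores (severity) and first-principal-component scores (profile
#' summary). Families with more than two affected siblings contribute their
#' first two by id order (logged); a pair is *concordant* when both sibs are
#' assigned the same class.
#'
#' @param cohort Sibling cohort with `family_id` and `sib_role` columns.
#' @param model A `signature_svm` trained on the labeled cohort.
#' @param pca Optional `signature_pca` for the PC1 scores; by default a PCA
#'   is fitted on the pooled sibling cohort's item scores.
#' @return Data frame of class `sib_pair_table`, one row per family.
#' @export
sib_pair_table <- function(cohort, model, pca = NULL) {
  stopifnot(all(c("family_id", "sib_role") %in% names(cohort)))
  cohort <- cohort[!is.na(cohort$family_id), , drop = FALSE]
  if (is.null(pca)) pca <- pca_fit(cohort, m = 2)
  pred <- predict.signature_svm(model, cohort, type = "response")
  pc1 <- pca_project(pca, cohort)[, 1]
  sev <- rowMeans(cohort_item_matrix(cohort))
  fams <- split(seq_len(nrow(cohort)), cohort$family_id)
  extra <- sum(vapply(fams, length, integer(1)) > 2)
  if (extra > 0)
    message(extra, " family(ies) with >2 affected sibs; first two by id order used")
  rows <- lapply(names(fams), function(f) {
    i <- fams[[f]]
    if (length(i) < 2) return(NULL)
    i <- i[order(cohort$subject_id[i])][1:2]
    data.frame(family_id = f,
               group1 = as.character(pred$predicted_group[i[1]]),
               group2 = as.character(pred$predicted_group[i[2]]),
               prob1 = pred$p_assigned[i[1]], prob2 = pred$p_assigned[i[2]],
               mean_items1 = sev[i[1]], mean_items2 = sev[i[2]],
               pc1_1 = pc1[i[1]], pc1_2 = pc1[i[2]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$concordant <- out$group1 == out$group2
  class(out) <- c("sib_pair_table", "data.frame")
  out
}

#' Sibling class-assignment concordance test
#'
#' Pearson chi-square test of independence on the `k x k` cross-tabulation
#' of sibling 1 versus sibling 2 assigned classes, with `df = (k - 1)^2` and
#' no continuity correction. Cells whose expected count is zero (classes
#' never assigned to one sibling set) contribute nothing to the statistic;
#' sparse tables are flagged with a warning because the chi-square
#' approximation degrades there.
#'
#' @param pairs A `sib_pair_table`.
#' @param classes Character vector of all k class names (fixes the table
#'   dimension); defaults to the classes observed.
#' @return List with `statistic`, `df`, `p_value` and the cross-tabulation.
#' @export
concordance_test <- function(pairs, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(pairs$group1, pairs$group2)))
  if (length(unique(c(pairs$group1, pairs$group2))) < 2)
    stop("need at least 2 distinct assigned classes", call. = FALSE)
  tab <- table(factor(pairs$group1, levels = classes),
               factor(pairs$group2, levels = classes))
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  use <- expected > 0
  stat <- sum((tab[use] - expected[use])^2 / expected[use])
  df <- (length(classes) - 1)^2
  if (any(expected[use] < 5))
    warning("sparse cells (expected < 5); chi-square approximation is rough")
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), table = tab)
}

#' Correlation of sibling assigned-class probabilities
#'
#' Pearson correlation between sibling 1 and sibling 2 assigned-class
#' probabilities, with the two-sided test.
#'
#' @param pairs A `sib_pair_table`.
#' @return List with `r`, `p_value`, `n` and a `zero_variance` flag.
#' @export
probability_correlation <- function(pairs) {
  if (nrow(pairs) < 10) stop("need at least 10 pairs", call. = FALSE)
  if (stats::sd(pairs$prob1) == 0 || stats::sd(pairs$prob2) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = nrow(pairs),
                zero_variance = TRUE))
  ct <- stats::cor.test(pairs$prob1, pairs$prob2)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs),
       zero_variance = FALSE)
}

#' Compare two correlations by Fisher's z
#'
#' @param r1,n1 Correlation and sample size in stratum 1.
#' @param r2,n2 Correlation and sample size in stratum 2.
#' @return List with `z` and two-sided `p_value`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (n1 < 4 || n2 < 4) return(list(z = NA_real_, p_value = NA_real_))
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Probability correlation split by concordance
#'
#' Pearson correlation of the sibling assigned-class probabilities within
#' concordant and discordant pairs separately, with a Fisher-z comparison
#' of the two strata. A stratum with fewer than 5 pairs is reported as
#' unavailable.
#'
#' @param pairs A `sib_pair_table`.
#' @param var1,var2 Column names of the per-sib quantities to correlate
#'   (defaults: the assigned-class probabilities).
#' @return List with `r_concordant`, `r_discordant`, stratum sizes, `z`
#'   and `p_value`.
#' @export
split_correlation <- function(pairs, var1 = "prob1", var2 = "prob2") {
  strat <- function(i) {
    if (sum(i) < 5) return(list(r = NA_real_, n = sum(i)))
    list(r = stats::cor(pairs[[var1]][i], pairs[[var2]][i]), n = sum(i))
  }
  co <- strat(pairs$concordant)
  di <- strat(!pairs$concordant)
  fz <- if (is.na(co$r) || is.na(di$r)) list(z = NA_real_, p_value = NA_real_)
  else fisher_z_compare(co$r, co$n, di$r, di$n)
  list(r_concordant = co$r, n_concordant = co$n,
       r_discordant = di$r, n_discordant = di$n,
       z = fz$z, p_value = fz$p_value)
}

#' Variance-equality test of sibling probability differences
#'
#' F-test for equality of variances of the within-pair probability
#' difference between discordant and concordant pairs:
#' `F = var(diff | discordant) / var(diff | concordant)` with the two-sided
#' p-value from the F distribution. A larger variance among discordant
#' pairs indicates that concordant pairs track each other's prediction
#' confidence more closely.
#'
#' @param pairs A `sib_pair_table`.
#' @return List with `F`, `df1`, `df2` and `p_value`.
#' @export
variance_equality_test <- function(pairs) {
  d <- pairs$prob1 - pairs$prob2
  dc <- d[!pairs$concordant]; cc <- d[pairs$concordant]
  if (length(dc) < 5 || length(cc) < 5)
    stop("need at least 5 pairs per stratum", call. = FALSE)
  vt <- stats::var.test(dc, cc)
  list(F = unname(vt$statistic), df1 = unname(vt$parameter[1]),
       df2 = unname(vt$parameter[2]), p_value = vt$p.value)
}

#' Severity versus specificity regressions
#'
#' Does a sibling's prediction confidence reflect profile *specificity*
#' rather than overall *severity*? For each direction, the other sibling's
#' assigned-class probability is regressed jointly on this sibling's mean
#' item score (severity) and assigned-class probability (specificity);
#' each predictor's coefficient and p-value are reported for both
#' directions.
#'
#' @param pairs A `sib_pair_table` with at least 20 pairs.
#' @return Data frame with one row per direction x predictor:
#'   `direction`, `predictor`, `estimate`, `p_value`; plus a `collinear`
#'   attribute flag when severity and probability correlate above 0.99.
#' @export
severity_vs_specificity <- function(pairs) {
  if (nrow(pairs) < 20) stop("need at least 20 pairs", call. = FALSE)
  run <- function(resp, sev, prob, label) {
    fit <- stats::lm(pairs[[resp]] ~ pairs[[sev]] + pairs[[prob]])
    co <- summary(fit)$coefficients
    data.frame(direction = label,
               predictor = c("mean_items", "probability"),
               estimate = co[2:3, "Estimate"],
               p_value = co[2:3, "Pr(>|t|)"],
               stringsAsFactors = FALSE)
  }
  out <- rbind(run("prob2", "mean_items1", "prob1", "sib1_predicts_sib2"),
               run("prob1", "mean_items2", "prob2", "sib2_predicts_sib1"))
  rownames(out) <- NULL
  collinear <- abs(stats::cor(pairs$mean_items1, pairs$prob1)) > 0.99 ||
    abs(stats::cor(pairs$mean_items2, pairs$prob2)) > 0.99
  if (collinear) warning("severity and probability nearly collinear (r > 0.99)")
  attr(out, "collinear") <- collinear
  out
}

#' PC1 similarity of sibling profiles
#'
#' Uses the first principal component of the 37 item scores as a profile
#' summary: Pearson correlation of the siblings' PC1 scores overall and
#' within concordance strata, with a Fisher-z comparison of the strata.
#'
#' @param pairs A `sib_pair_table` (carries the PC1 scores).
#' @return List with `r_all`, `p_all`, `r_concordant`, `r_discordant`,
#'   stratum sizes, and the Fisher-z `z`/`p_compare`.
#' @export
pc1_similarity <- function(pairs) {
  ct <- stats::cor.test(pairs$pc1_1, pairs$pc1_2)
  sp <- split_correlation(pairs, "pc1_1", "pc1_2")
  list(r_all = unname(ct$estimate), p_all = ct$p.value,
       r_concordant = sp$r_concordant, n_concordant = sp$n_concordant,
       r_discordant = sp$r_discordant, n_discordant = sp$n_discordant,
       z = sp$z, p_compare = sp$p_value)
}

#' Run the full sibling familiality suite
#'
#' Convenience wrapper producing one tidy report: concordance chi-square,
#' probability correlation (overall and split by concordance), the
#' variance-equality F-test, the severity-versus-specificity regressions
#' and the PC1 similarity analysis.
#'
#' @param pairs A `sib_pair_table`.
#' @param classes All class names for the concordance table.
#' @return Data frame with columns `analysis`, `statistic`, `value`, `p_value`.
#' @export
sibling_suite <- function(pairs, classes = NULL) {
  rows <- list()
  add <- function(analysis, statistic, value, p = NA_real_)
    rows[[length(rows) + 1]] <<- data.frame(analysis = analysis,
                                            statistic = statistic,
                                            value = value, p_value = p,
                                            stringsAsFactors = FALSE)
  ct <- concordance_test(pairs, classes)
  add("concordance", "chi_square", ct$statistic, ct$p_value)
  add("concordance", "df", ct$df)
  add("concordance", "n_concordant", sum(pairs$concordant))
  pc <- probability_correlation(pairs)
  add("probability_correlation", "r", pc$r, pc$p_value)
  sp <- split_correlation(pairs)
  add("probability_split", "r_concordant", sp$r_concordant)
  add("probability_split", "r_discordant", sp$r_discordant)
  add("probability_split", "fisher_z", sp$z, sp$p_value)
  vt <- variance_equality_test(pairs)
  add("variance_equality", "F", vt$F, vt$p_value)
  sv <- severity_vs_specificity(pairs)
  for (i in seq_len(nrow(sv)))
    add(sv$direction[i], sv$predictor[i], sv$estimate[i], sv$p_value[i])
  p1 <- pc1_similarity(pairs)
  add("pc1_similarity", "r_all", p1$r_all, p1$p_all)
  add("pc1_similarity", "r_concordant", p1$r_concordant)
  add("pc1_similarity", "r_discordant", p1$r_discordant)
  add("pc1_similarity", "fisher_z", p1$z, p1$p_compare)
  do.call(rbind, rows)
}
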