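#' Group-specific item signature pattern
#'
#' Deterministic per-group offsets added to the latent item locations so that
#' groups differ in their item *profiles*, not only in their domain means.
#' Group `g` gets offset `amp * cos(2 * pi * g * j / 37)` on the `j`-th item
#' (items in [adir_items()] order); distinct groups use distinct frequencies,
#' giving near-orthogonal signature patterns of equal strength.
#'
#' @param n_groups Number of groups.
#' @param amp Signature amplitude on the latent (probit) scale; 0 gives
#'   groups that differ only in domain-level severity.
#' @return `n_groups x 37` matrix of offsets with item-column names.
#' @export
signature_pattern <- function(n_groups, amp = 1) {
  j <- seq_len(37)
  pat <- outer(seq_len(n_groups), j, function(g, j) amp * cos(2 * pi * g * j / 37))
  colnames(pat) <- item_columns()
  pat
}

# Expected algorithm score of a single item with latent location `shift`,
# latent severity SD `ssd` and cut-points `cut`: closed form via the probit
# marginal (total latent SD sqrt(1 + ssd^2)).
expected_item_score <- function(shift, ssd, cut) {
  s <- sqrt(1 + ssd^2)
  stats::pnorm((shift - cut[1]) / s) + stats::pnorm((shift - cut[2]) / s)
}

# Expected score of a max-composite of two items (shifts sa, sb) sharing the
# latent severity t; integrates over t on a fixed quadrature grid.
expected_pair_max <- function(sa, sb, ssd, cut, ngrid = 241) {
  t <- seq(-6, 6, length.out = ngrid) * max(ssd, 1e-8)
  w <- stats::dnorm(t, 0, max(ssd, 1e-8)); w <- w / sum(w)
  if (ssd < 1e-8) { t <- 0; w <- 1 }
  pa1 <- stats::pnorm(t + sa - cut[1]); pa2 <- stats::pnorm(t + sa - cut[2])
  pb1 <- stats::pnorm(t + sb - cut[1]); pb2 <- stats::pnorm(t + sb - cut[2])
  emax <- (1 - (1 - pa1) * (1 - pb1)) + (pa2 + pb2 - pa2 * pb2)
  sum(w * emax)
}

# Expected domain score for a base shift plus per-item pattern offsets.
# `p_young` weights the item 64 vs 65 branch of domain I.
expected_domain_score <- function(domain, base, offsets, ssd, cut, p_young = 0.5) {
  items <- adir_items()
  off <- function(it) offsets[paste0("item_", it)]
  if (domain == "I") {
    plain <- setdiff(items$item[items$domain == "I"], c(64, 65))
    sum(expected_item_score(base + offsets[paste0("item_", plain)], ssd, cut)) +
      p_young * expected_item_score(base + off(64), ssd, cut) +
      (1 - p_young) * expected_item_score(base + off(65), ssd, cut)
  } else if (domain == "II") {
    d2 <- items$item[items$domain == "II"]
    sum(expected_item_score(base + offsets[paste0("item_", d2)], ssd, cut))
  } else {
    plain <- c(33, 39, 67, 68, 70)
    sum(expected_item_score(base + offsets[paste0("item_", plain)], ssd, cut)) +
      expected_pair_max(base + off(69), base + off(71), ssd, cut) +
      expected_pair_max(base + off(77), base + off(78), ssd, cut)
  }
}

#' Calibrate signature specifications to domain-mean targets
#'
#' Moment-matches the latent item-location shifts of the ordered-threshold
#' generator so that the expected domain scores of each group equal the given
#' targets. For each group and domain a common base shift is solved by root
#' finding on the exact expected-score function (probit marginals; numeric
#' quadrature for the max-composites), on top of which the per-item signature
#' `pattern` offsets are laid.
#'
#' @param domain_targets Data frame or matrix with one row per group and
#'   columns `dI`, `dII`, `dIII` holding target domain means; row names or a
#'   `group` column give group names.
#' @param pattern Per-group item offsets as from [signature_pattern()]
#'   (or `NULL` for none).
#' @param severity_sd SD of the shared latent severity trait.
#' @param cutpoints The two ordered thresholds on the latent scale.
#' @param p_young Per-group probability that a subject is under 120 months
#'   (weights the item 64/65 branch of domain I); recycled.
#' @return List of signature specs, each a list with `group`, `item_shift`
#'   (named length-37 vector), `severity_sd` and `cutpoints`.
#' @export
calibrate_specs <- function(domain_targets, pattern = NULL, severity_sd = 1,
                            cutpoints = c(0, 1.2), p_young = 0.5) {
  dt <- as.data.frame(domain_targets)
  groups <- if ("group" %in% names(dt)) as.character(dt$group) else rownames(dt)
  ngr <- nrow(dt)
  if (is.null(pattern)) pattern <- matrix(0, ngr, 37, dimnames = list(NULL, item_columns()))
  p_young <- rep_len(p_young, ngr)
  items <- adir_items()
  n_scored <- c(I = 15, II = 12, III = 7)
  specs <- vector("list", ngr)
  for (g in seq_len(ngr)) {
    shift <- stats::setNames(numeric(37), item_columns())
    offs <- pattern[g, item_columns()]
    for (dom in c("I", "II", "III")) {
      target <- dt[[paste0("d", dom)]][g]
      ceiling_d <- 2 * n_scored[[dom]]
      if (target < 0 || target >= ceiling_d)
        stop(sprintf("infeasible target %.2f for domain %s (ceiling %d)",
                     target, dom, ceiling_d), call. = FALSE)
      f <- function(s) expected_domain_score(dom, s, offs, severity_sd,
                                             cutpoints, p_young[g]) - target
      base <- if (target == 0) -Inf else
        stats::uniroot(f, c(-15, 15), tol = 1e-8)$root
      dom_items <- items$item[items$domain == dom]
      shift[paste0("item_", dom_items)] <-
        base + offs[paste0("item_", dom_items)]
    }
    specs[[g]] <- list(group = groups[g], item_shift = shift,
                       severity_sd = severity_sd, cutpoints = cutpoints)
  }
  specs
}

#' Default generator configuration
#'
#' Builds the configuration of the synthetic-cohort generator calibrated to
#' the published per-group summaries ([adir_reference()]): the six groups
#' with sizes 90, 21, 88, 22, 50 and 51, domain-mean targets, age/sex/IQ
#' distributions, the signature pattern, and the defaults for sibling and
#' idiopathic-mixture simulations (TSC-heavy mixture so that blind allocation
#' has a dominant class to recover).
#'
#' @param seed Integer seed stored in the config; every generator call is
#'   reproducible from it.
#' @param sizes Per-group sample sizes.
#' @param amp Signature amplitude, see [signature_pattern()].
#' @param severity_sd,cutpoints Latent-trait model parameters.
#' @param sib_icc Intraclass correlation of the latent severity between
#'   siblings of one family.
#' @param class_share Probability that the two siblings of a family share
#'   the same latent signature class.
#' @param mixture_weights Named class weights of the idiopathic mixture.
#' @return A `generator_config` list.
#' @export
default_generator_config <- function(seed = 1,
                                     sizes = c(90, 21, 88, 22, 50, 51),
                                     amp = 1, severity_sd = 1,
                                     cutpoints = c(0, 1.2),
                                     sib_icc = 0.5, class_share = 0.5,
                                     mixture_weights = c("22q11DS" = 0.10,
                                                         "Downs" = 0.01,
                                                         "PWS" = 0.01,
                                                         "SMC15" = 0.08,
                                                         "TSC" = 0.60,
                                                         "XXY" = 0.20)) {
  ref <- adir_reference()$table1
  stopifnot(length(sizes) == nrow(ref))
  targets <- data.frame(group = ref$group, dI = ref$dI_mean,
                        dII = ref$dII_mean, dIII = ref$dIII_mean)
  p_young <- stats::pnorm((120 - ref$age_mean) / ref$age_sd)
  pat <- signature_pattern(nrow(ref), amp)
  specs <- calibrate_specs(targets, pat, severity_sd, cutpoints, p_young)
  cfg <- list(groups = ref$group, group_sizes = stats::setNames(sizes, ref$group),
              specs = stats::setNames(specs, ref$group),
              severity_sd = severity_sd, cutpoints = cutpoints,
              age_mean = stats::setNames(ref$age_mean, ref$group),
              age_sd = stats::setNames(ref$age_sd, ref$group),
              p_female = stats::setNames(ref$female / ref$n, ref$group),
              iq_mean = stats::setNames(ref$iq_mean, ref$group),
              iq_sd = stats::setNames(ref$iq_sd, ref$group),
              sib_icc = sib_icc, class_share = class_share,
              mixture_weights = mixture_weights, seed = seed)
  w <- cfg$mixture_weights
  if (abs(sum(w) - 1) > 1e-6) stop("mixture_weights must sum to 1")
  class(cfg) <- "generator_config"
  cfg
}

# Draw the 37 item codes for subjects with latent severities `t` and spec
# index `cls` (into config$specs): ordered-threshold model.
draw_items <- function(cls, t, config) {
  n <- length(t)
  shifts <- do.call(rbind, lapply(config$specs[cls], `[[`, "item_shift"))
  lat <- t + shifts + matrix(stats::rnorm(n * 37), n, 37)
  codes <- (lat >= config$cutpoints[1]) + (lat >= config$cutpoints[2])
  colnames(codes) <- item_columns()
  codes
}

# Shared demographics + assembly for generated subjects.
assemble_cohort <- function(ids, group_label, cls, t, config,
                            family_id = NA, sib_role = NA) {
  n <- length(t)
  grp <- config$groups[cls]
  age <- pmax(stats::rnorm(n, config$age_mean[grp], config$age_sd[grp]), 50)
  sex <- ifelse(stats::runif(n) < config$p_female[grp], "F", "M")
  iq <- round(stats::rnorm(n, config$iq_mean[grp], config$iq_sd[grp]))
  onset <- pmax(0, pmin(5, round(1.2 + 0.8 * t + stats::rnorm(n, 0, 0.8))))
  df <- data.frame(subject_id = ids, group = group_label,
                   age_months = round(age, 1), sex = sex, iq = iq,
                   verbal = TRUE, family_id = family_id, sib_role = sib_role,
                   onset = onset, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(draw_items(cls, t, config)))
  df
}

#' Generate a labeled synthetic cohort
#'
#' Draws, for each group, subjects whose 37 item codes follow the
#' latent-severity ordered-threshold model: subject severity
#' `t ~ Normal(0, severity_sd)`, item `j` of group `g` scored by thresholding
#' `t + item_shift[g][j] + noise` at the two cut-points. Ages, sex, IQ and
#' onset scores are drawn from the per-group distributions in the config.
#' Fully reproducible from `config$seed`.
#'
#' @param config A `generator_config`, see [default_generator_config()].
#' @return A labeled cohort data frame (class `adir_cohort`).
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  sh <- vapply(config$specs, function(s) s$item_shift, numeric(37))
  if (length(config$specs) > 1 && max(apply(sh, 1, stats::sd)) < 1e-12)
    warning("degenerate specs: identical item shifts across all groups")
  parts <- lapply(seq_along(config$groups), function(g) {
    n <- config$group_sizes[[g]]
    t <- stats::rnorm(n, 0, config$severity_sd)
    ids <- sprintf("%s_%03d", config$groups[g], seq_len(n))
    assemble_cohort(ids, config$groups[g], rep(g, n), t, config)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  validate_cohort(out, require_group = TRUE)
  out
}

#' Generate a blind (idiopathic) cohort
#'
#' Subjects are a mixture over the signature classes with weights
#' `config$mixture_weights`; the group label is a blind label and the latent
#' class is retained in a `latent_class` column for diagnostics only.
#'
#' @param config A `generator_config`.
#' @param n Number of subjects.
#' @param weights Optional override of the mixture weights.
#' @param label Blind group label.
#' @return Cohort data frame with an extra `latent_class` column.
#' @export
generate_blind_cohort <- function(config, n, weights = NULL,
                                  label = "idiopathic") {
  set.seed(config$seed)
  if (is.null(weights)) weights <- config$mixture_weights
  w <- weights[config$groups]
  cls <- sample(seq_along(config$groups), n, replace = TRUE, prob = w)
  t <- stats::rnorm(n, 0, config$severity_sd)
  out <- assemble_cohort(sprintf("%s_%04d", label, seq_len(n)), label,
                         cls, t, config)
  out$latent_class <- config$groups[cls]
  rownames(out) <- NULL
  validate_cohort(out)
  out
}

#' Generate affected sibling pairs
#'
#' Each family draws a latent signature class from the mixture weights and a
#' family severity component; siblings share the family severity with
#' intraclass correlation `sib_icc` and share the latent class with
#' probability `class_share` (otherwise the second sibling draws an
#' independent class).
#'
#' @param config A `generator_config`.
#' @param n_pairs Number of families (two siblings each).
#' @param sib_icc,class_share Override the config defaults.
#' @param weights Optional override of the mixture weights.
#' @return Cohort data frame with `family_id`, `sib_role` (`sib1`/`sib2`)
#'   and `latent_class` columns.
#' @export
generate_sib_pairs <- function(config, n_pairs, sib_icc = config$sib_icc,
                               class_share = config$class_share,
                               weights = NULL) {
  if (n_pairs <= 0) stop("n_pairs must be positive", call. = FALSE)
  stopifnot(sib_icc >= 0, sib_icc <= 1, class_share >= 0, class_share <= 1)
  set.seed(config$seed)
  if (is.null(weights)) weights <- config$mixture_weights
  w <- weights[config$groups]
  k <- length(config$groups)
  cls1 <- sample(k, n_pairs, replace = TRUE, prob = w)
  share <- stats::runif(n_pairs) < class_share
  cls2 <- ifelse(share, cls1, sample(k, n_pairs, replace = TRUE, prob = w))
  ssd <- config$severity_sd
  t_fam <- stats::rnorm(n_pairs, 0, ssd * sqrt(sib_icc))
  t1 <- t_fam + stats::rnorm(n_pairs, 0, ssd * sqrt(1 - sib_icc))
  t2 <- t_fam + stats::rnorm(n_pairs, 0, ssd * sqrt(1 - sib_icc))
  fam <- sprintf("fam%04d", seq_len(n_pairs))
  s1 <- assemble_cohort(paste0(fam, "_s1"), "idiopathic", cls1, t1, config,
                        family_id = fam, sib_role = "sib1")
  s2 <- assemble_cohort(paste0(fam, "_s2"), "idiopathic", cls2, t2, config,
                        family_id = fam, sib_role = "sib2")
  s1$latent_class <- config$groups[cls1]
  s2$latent_class <- config$groups[cls2]
  out <- rbind(s1, s2)
  out <- out[order(out$family_id, out$sib_role), ]
  rownames(out) <- NULL
  validate_cohort(out)
  out
}

#' Permute item columns independently across subjects
#'
#' Destroys inter-item correlation and profile patterns while preserving the
#' marginal distribution of every item exactly — the construction used for
#' the item-permutation null of the blind-allocation analysis.
#'
#' @param cohort Cohort data frame.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Cohort with each `item_*` column independently permuted.
#' @export
permute_items <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  for (cc in item_columns()) cohort[[cc]] <- cohort[[cc]][sample.int(n)]
  cohort
}

#' Permute group labels
#'
#' Shuffles the group labels as a block, preserving label frequencies and
#' leaving profiles untouched — the construction used for the
#' label-permutation null.
#'
#' @inheritParams permute_items
#' @return Cohort with shuffled `group` column.
#' @export
permute_labels <- function(cohort, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cohort$group <- sample(cohort$group)
  cohort
}
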