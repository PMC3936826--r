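#' The 37 ADI-R diagnostic-algorithm items
#'
#' Returns the item table used throughout the package: the 37 algorithm items
#' of the Autism Diagnostic Interview-Revised (verbal algorithm), the domain
#' each contributes to, composite pairings, and the age-dependent choice
#' between items 64 and 65.
#'
#' Domains: `I` reciprocal social interaction, `II` communication (verbal),
#' `III` restricted/repetitive behavior. Items 69/71 and 77/78 enter domain
#' III as the pairwise maximum of each pair; exactly one of items 64 ("group
#' play with peers", age under 10 years) and 65 ("friendships", age 10 years
#' or older) counts toward domain I for a given subject. The domain mapping is
#' exposed as data so that alternative algorithm versions can be swapped in
#' without touching code.
#'
#' @return A data frame with columns `item` (integer item number),
#'   `description`, `domain` (`"I"`, `"II"` or `"III"`), `composite_with`
#'   (partner item number for max-composites, `NA` otherwise) and `age_rule`
#'   (`"under10"`, `"over10"` or `NA`).
#' @examples
#' table(adir_items()$domain)
#' @export
adir_items <- function() {
  df <- data.frame(
    item = c(31L, 33L, 34L, 35L, 36L, 37L, 38L, 39L, 42L, 43L, 44L, 45L,
             47L, 48L, 49L, 50L, 51L, 52L, 53L, 54L, 55L, 56L, 57L, 58L,
             59L, 61L, 62L, 63L, 64L, 65L, 67L, 68L, 69L, 70L, 71L, 77L, 78L),
    description = c(
      "Use of other's body to communicate",
      "Stereotyped utterances and delayed echolalia",
      "Social verbalization/chat",
      "Reciprocal conversation",
      "Inappropriate questions or statements",
      "Pronominal reversal",
      "Neologisms/idiosyncratic language",
      "Verbal rituals",
      "Pointing to express interest",
      "Nodding",
      "Head shaking",
      "Conventional/instrumental gestures",
      "Spontaneous imitation of actions",
      "Imaginative play",
      "Imaginative play with peers",
      "Direct gaze",
      "Social smiling",
      "Showing and directing attention",
      "Offering to share",
      "Seeking to share enjoyment with others",
      "Offering comfort",
      "Quality of social overtures",
      "Range of facial expressions used to communicate",
      "Inappropriate facial expressions",
      "Appropriateness of social responses",
      "Imitative social play",
      "Interest in children",
      "Response to approaches of other children",
      "Group play with peers (age <10.0 years)",
      "Friendships (age >10.0 years)",
      "Unusual preoccupations",
      "Circumscribed interests",
      "Repetitive use of objects or interest in parts of objects",
      "Compulsions/rituals",
      "Unusual sensory interests",
      "Hand and finger mannerisms",
      "Other complex mannerisms or stereotyped body movements"),
    stringsAsFactors = FALSE)
  dom1 <- c(31, 49, 50, 51, 52, 53, 54, 55, 56, 57, 58, 59, 62, 63, 64, 65)
  dom3 <- c(33, 39, 67, 68, 69, 70, 71, 77, 78)
  df$domain <- ifelse(df$item %in% dom1, "I", ifelse(df$item %in% dom3, "III", "II"))
  df$composite_with <- NA_integer_
  df$composite_with[df$item == 69] <- 71L
  df$composite_with[df$item == 71] <- 69L
  df$composite_with[df$item == 77] <- 78L
  df$composite_with[df$item == 78] <- 77L
  df$age_rule <- NA_character_
  df$age_rule[df$item == 64] <- "under10"
  df$age_rule[df$item == 65] <- "over10"
  df
}

#' Names of the 37 item columns in a cohort table
#'
#' @return Character vector `item_31`, `item_33`, ..., `item_78`.
#' @export
item_columns <- function() paste0("item_", adir_items()$item)

#' Recode raw ADI-R codes to algorithm scores
#'
#' Raw codes 0, 1 and 2 are kept; a code 3 ("behavior disrupts family life")
#' is recoded as 2 so that all items carry equal weight; the conventional
#' not-applicable/untestable codes 7, 8 and 9 score 0, following the standard
#' algorithm convention. Any other code is a validation error.
#'
#' @param raw Integer vector of raw item codes.
#' @param context Optional string (e.g. subject/item) prepended to error
#'   messages.
#' @return Integer vector of algorithm scores in `{0, 1, 2}`.
#' @examples
#' recode_item(c(0, 1, 2, 3, 8))
#' @export
recode_item <- function(raw, context = NULL) {
  raw <- as.integer(raw)
  bad <- !is.na(raw) & !(raw %in% c(0L, 1L, 2L, 3L, 7L, 8L, 9L))
  if (any(bad)) {
    stop(sprintf("%sunrecognized ADI-R code(s): %s",
                 if (is.null(context)) "" else paste0(context, ": "),
                 paste(unique(raw[bad]), collapse = ", ")), call. = FALSE)
  }
  out <- raw
  out[!is.na(out) & out == 3L] <- 2L
  out[!is.na(out) & out >= 7L] <- 0L
  out
}

#' ADI-R algorithm domain cut-offs
#'
#' The standard algorithm cut-offs for verbal subjects: reciprocal social
#' interaction (domain I) >= 10, communication verbal (domain II) >= 8,
#' restricted/repetitive behavior (domain III) >= 3, and age-of-onset score
#' >= 1. These are the package defaults and can be overridden wherever a
#' `thresholds` argument is accepted.
#'
#' @return Named list with elements `dI`, `dII`, `dIII`, `onset`.
#' @export
adir_thresholds <- function() list(dI = 10, dII = 8, dIII = 3, onset = 1)

# Extract the 37-item score matrix from a cohort-shaped data frame.
cohort_item_matrix <- function(cohort) {
  cols <- item_columns()
  missing <- setdiff(cols, names(cohort))
  if (length(missing) > 0)
    stop("cohort is missing item column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  m <- as.matrix(cohort[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("missing item codes are not supported; impute or drop subjects first",
                     call. = FALSE)
  if (any(m < 0 | m > 2)) stop("item codes outside {0,1,2}; run recode_item()/read_cohort() first",
                               call. = FALSE)
  m
}

#' ADI-R algorithm domain scores
#'
#' Computes the three algorithm domain scores and their total for each subject.
#' Domain I sums its items with exactly one of items 64/65 chosen by age
#' (64 below 120.0 months, 65 at or above 120.0 months); domain III sums items
#' 33, 39, 67, 68, 70 plus the composites `max(69, 71)` and `max(77, 78)`.
#' Ceilings are 30 (I), 24 (II) and 14 (III).
#'
#' @param profile A cohort data frame with the 37 `item_*` columns (and an
#'   `age_months` column unless `age_months` is supplied), or a named numeric
#'   vector of the 37 item scores for a single subject.
#' @param age_months Age(s) in months; overrides the cohort column.
#' @return Data frame with columns `dI`, `dII`, `dIII`, `total`.
#' @examples
#' prof <- stats::setNames(rep(2, 37), item_columns())
#' domain_scores(prof, age_months = 96)
#' @export
domain_scores <- function(profile, age_months = NULL) {
  if (is.numeric(profile) && !is.null(names(profile)))
    profile <- as.data.frame(as.list(profile))
  m <- cohort_item_matrix(profile)
  if (is.null(age_months)) {
    if (!"age_months" %in% names(profile))
      stop("supply age_months or include an age_months column", call. = FALSE)
    age_months <- profile$age_months
  }
  age_months <- rep_len(age_months, nrow(m))
  items <- adir_items()
  col <- function(it) m[, paste0("item_", it)]
  d1_items <- items$item[items$domain == "I"]
  dI <- rowSums(m[, paste0("item_", d1_items), drop = FALSE])
  # exactly one of 64/65 counts: drop the branch not matching the subject's age
  use64 <- age_months < 120
  dI <- dI - ifelse(use64, col(65), col(64))
  d2_items <- items$item[items$domain == "II"]
  dII <- rowSums(m[, paste0("item_", d2_items), drop = FALSE])
  dIII <- col(33) + col(39) + col(67) + col(68) + col(70) +
    pmax(col(69), col(71)) + pmax(col(77), col(78))
  data.frame(dI = dI, dII = dII, dIII = dIII, total = dI + dII + dIII)
}

#' ASD classification from domain scores
#'
#' Applies the ASD rule used in genetic studies: ASD is classified when all
#' three core domains meet their cut-offs, or when exactly two core domains
#' are met and the remaining domain is within one point of its cut-off; in
#' either case the age-of-onset criterion must also be met.
#'
#' @param scores Data frame with `dI`, `dII`, `dIII` columns (as returned by
#'   [domain_scores()]).
#' @param onset_score Numeric onset-domain score(s); `NA` values are treated
#'   as meeting the onset criterion, with a warning.
#' @param thresholds List of cut-offs, see [adir_thresholds()].
#' @return Logical vector, `TRUE` for subjects classified as ASD.
#' @export
classify_asd <- function(scores, onset_score = NULL,
                         thresholds = adir_thresholds()) {
  thr <- c(thresholds$dI, thresholds$dII, thresholds$dIII)
  sc <- as.matrix(scores[, c("dI", "dII", "dIII")])
  met <- sweep(sc, 2, thr, ">=")
  near <- sweep(sc, 2, thr - 1, ">=")
  n_met <- rowSums(met)
  core_ok <- n_met == 3 | (n_met == 2 & rowSums(near) == 3)
  if (is.null(onset_score)) onset_score <- rep(NA_real_, nrow(sc))
  onset_score <- rep_len(onset_score, nrow(sc))
  if (anyNA(onset_score)) {
    warning(sum(is.na(onset_score)),
            " subject(s) without an onset score; onset criterion treated as met")
    onset_score[is.na(onset_score)] <- thresholds$onset
  }
  core_ok & onset_score >= thresholds$onset
}
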