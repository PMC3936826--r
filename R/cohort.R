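#' Validate a cohort table
#'
#' Checks the structural invariants a cohort must satisfy before analysis:
#' the 37 item columns present with codes in `{0,1,2}`, unique subject ids,
#' and (when `require_group = TRUE`) a nonempty group for every subject.
#'
#' @param cohort Data frame in the cohort layout (see [read_cohort()]).
#' @param require_group Require a usable `group` column.
#' @return The cohort, invisibly, with class `adir_cohort` attached.
#' @export
validate_cohort <- function(cohort, require_group = FALSE) {
  if (!"subject_id" %in% names(cohort))
    stop("cohort must have a subject_id column", call. = FALSE)
  dup <- duplicated(cohort$subject_id)
  if (any(dup))
    stop("duplicate subject_id(s): ",
         paste(unique(cohort$subject_id[dup]), collapse = ", "), call. = FALSE)
  cohort_item_matrix(cohort)
  if (require_group) {
    if (!"group" %in% names(cohort) || anyNA(cohort$group) ||
        any(!nzchar(as.character(cohort$group))))
      stop("every subject needs a nonempty group label", call. = FALSE)
  }
  if ("verbal" %in% names(cohort) && any(!cohort$verbal, na.rm = TRUE))
    warning("cohort contains nonverbal subjects; the verbal algorithm assumes verbal subjects")
  class(cohort) <- unique(c("adir_cohort", class(cohort)))
  invisible(cohort)
}

#' Read a cohort TSV file
#'
#' Reads the tab-separated cohort dialect: one header row with columns
#' `subject_id, group, age_months, sex, iq, verbal, family_id, sib_role,
#' onset` and the 37 item columns `item_31 ... item_78`. Raw item codes are
#' recoded on read ([recode_item()]: 3 becomes 2; 7/8/9 become 0) and the
#' number of recoded cells is reported. Missing numerics are empty fields.
#'
#' @param path File path.
#' @param quiet Suppress the recoding message.
#' @return A validated cohort data frame (class `adir_cohort`).
#' @export
read_cohort <- function(path, quiet = FALSE) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  cols <- item_columns()
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("file ", path, " is missing item column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  n_recoded <- 0L
  for (cc in cols) {
    raw <- df[[cc]]
    rec <- recode_item(raw, context = cc)
    n_recoded <- n_recoded + sum(rec != raw, na.rm = TRUE)
    df[[cc]] <- rec
  }
  if (n_recoded > 0 && !quiet)
    message(n_recoded, " item code(s) recoded on read (3 -> 2, 7/8/9 -> 0)")
  if ("verbal" %in% names(df)) df$verbal <- as.logical(df$verbal)
  validate_cohort(df)
  df
}

#' Write a cohort TSV file
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.adir_cohort <- function(x, ...) {
  cat("ADI-R cohort:", nrow(x), "subjects\n")
  if ("group" %in% names(x)) {
    tab <- table(x$group)
    cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Published reference tables
#'
#' The published summary tables for the six-genetic-disorder study sample
#' that this package's analyses are designed around, entered from print:
#'
#' * `table1` — per-group sample characteristics: n, sex counts, age,
#'   ASD-classification counts, domain and total ADI-R means and SDs, IQ.
#' * `table3` — one-by-one (pairwise) SVM accuracies.
#' * `table4_confusion` — leave-one-out confusion counts, rows = predicted
#'   class, columns = true class.
#' * `table4_probability` — mean predicted probability for each class (rows)
#'   among subjects of each true class (columns).
#' * `table6` — allocation of the blind idiopathic samples (AGRE0 singleton
#'   probands; AGRE1/AGRE2 sibling sets): assigned counts, percents and
#'   assigned-class probability summaries.
#'
#' These are inputs for arithmetic checks and for calibrating the synthetic
#' generator; they are not recomputable from raw data (the clinical cohorts
#' are not deposited).
#'
#' @return Named list of data frames / matrices described above.
#' @export
adir_reference <- function() {
  groups <- c("22q11DS", "Downs", "PWS", "SMC15", "TSC", "XXY")
  table1 <- data.frame(
    group = groups,
    n = c(90L, 21L, 88L, 22L, 50L, 51L),
    female = c(42L, 16L, 48L, 8L, 31L, 0L),
    male = c(48L, 5L, 40L, 14L, 19L, 51L),
    age_mean = c(162.5, 169.1, 191.9, 161.4, 126.2, 145.4),
    age_sd = c(33.6, 32.6, 141.0, 103.6, 74.0, 41.4),
    asd_yes = c(40L, 6L, 20L, 19L, 22L, 16L),
    asd_no = c(50L, 15L, 68L, 3L, 28L, 35L),
    dI_mean = c(9.8, 7.2, 7.9, 15.6, 12.0, 8.5),
    dI_sd = c(6.4, 4.4, 5.1, 6.0, 9.0, 6.0),
    dII_mean = c(7.7, 6.8, 5.7, 13.6, 9.6, 8.8),
    dII_sd = c(4.8, 3.8, 4.5, 5.5, 6.8, 5.4),
    dIII_mean = c(2.5, 3.2, 2.8, 6.5, 3.7, 2.3),
    dIII_sd = c(2.2, 2.0, 2.0, 2.4, 3.3, 2.1),
    total_mean = c(20.0, 17.2, 16.3, 35.7, 25.2, 19.6),
    total_sd = c(12.0, 8.6, 10.1, 12.2, 17.9, 12.0),
    iq_mean = c(67.0, 49.5, 70.9, 51.0, 69.3, 80.4),
    iq_sd = c(14.1, 11.9, 16.3, 19.0, 27.4, 13.9),
    stringsAsFactors = FALSE)
  table3 <- matrix(c(
    NA,   0.89, 0.91, 0.97, 0.90, 0.82,
    0.89, NA,   0.77, 0.84, 0.82, 0.87,
    0.91, 0.77, NA,   0.84, 0.86, 0.86,
    0.97, 0.84, 0.84, NA,   0.94, 0.88,
    0.90, 0.82, 0.86, 0.94, NA,   0.72,
    0.82, 0.87, 0.86, 0.88, 0.72, NA),
    nrow = 6, byrow = TRUE, dimnames = list(groups, groups))
  table4_confusion <- matrix(c(
    74, 1, 7, 0, 6, 14,
    0, 1, 1, 0, 0, 0,
    7, 18, 68, 9, 7, 6,
    0, 0, 4, 10, 0, 2,
    2, 0, 3, 0, 30, 9,
    7, 1, 5, 3, 7, 20),
    nrow = 6, byrow = TRUE,
    dimnames = list(predicted = groups, true = groups))
  table4_probability <- matrix(c(
    0.602, 0.092, 0.095, 0.032, 0.150, 0.215,
    0.027, 0.166, 0.103, 0.097, 0.030, 0.047,
    0.099, 0.485, 0.537, 0.301, 0.120, 0.167,
    0.020, 0.110, 0.089, 0.326, 0.050, 0.067,
    0.103, 0.044, 0.068, 0.064, 0.430, 0.185,
    0.149, 0.103, 0.108, 0.179, 0.220, 0.319),
    nrow = 6, byrow = TRUE,
    dimnames = list(predicted = groups, true = groups))
  table6 <- data.frame(
    group = rep(groups, 3),
    dataset = rep(c("AGRE0", "AGRE1", "AGRE2"), each = 6),
    n_assigned = c(26L, 1L, 1L, 24L, 255L, 68L,
                   23L, 1L, 5L, 28L, 302L, 84L,
                   28L, 1L, 5L, 32L, 283L, 94L),
    pct_assigned = c(6.9, 0.3, 0.3, 6.4, 68, 18.1,
                     5.2, 0.2, 1.1, 6.3, 68.2, 19,
                     6.3, 0.2, 1.1, 7.2, 63.9, 21.2),
    mean_probability = c(0.44, 0.25, 0.34, 0.40, 0.61, 0.41,
                         0.44, 0.28, 0.30, 0.40, 0.62, 0.41,
                         0.48, 0.27, 0.33, 0.41, 0.60, 0.42),
    sd_probability = c(0.154, NA, NA, 0.086, 0.139, 0.092,
                       0.143, NA, 0.131, 0.102, 0.134, 0.071,
                       0.189, NA, 0.072, 0.093, 0.140, 0.095),
    stringsAsFactors = FALSE)
  list(table1 = table1, table3 = table3, table4_confusion = table4_confusion,
       table4_probability = table4_probability, table6 = table6)
}

#' Chance accuracy of frequency-matched random assignment
#'
#' Expected accuracy when each subject is assigned a class at random with
#' probabilities proportional to class sizes: `sum(p_i^2)` where `p_i` are
#' the class frequencies. For the study's group sizes this is the quoted
#' ~21% baseline.
#'
#' @param sizes Class sizes (or frequencies).
#' @return Expected accuracy as a proportion in (0, 1].
#' @examples
#' chance_accuracy(c(90, 21, 88, 22, 50, 51))
#' @export
chance_accuracy <- function(sizes) {
  p <- sizes / sum(sizes)
  sum(p^2)
}

#' Accuracy summaries from a confusion matrix
#'
#' @param confusion Square count matrix, rows = predicted class, columns =
#'   true class.
#' @return List with `overall` (trace over total) and `per_class`
#'   (diagonal over column sums).
#' @export
confusion_accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  list(overall = sum(diag(confusion)) / sum(confusion),
       per_class = diag(confusion) / colSums(confusion))
}

#' Per-group cohort summary
#'
#' Summarizes a labeled cohort in the layout of a sample-characteristics
#' table: per group the sample size, sex counts, age, ASD classification
#' counts (via [classify_asd()]), domain and total score means and SDs, and
#' IQ; plus a case-weighted pooled row.
#'
#' @param cohort Labeled cohort data frame.
#' @param thresholds ASD cut-offs, see [adir_thresholds()].
#' @return Data frame of class `cohort_summary`, one row per group plus a
#'   pooled `Average` row.
#' @export
summarize_cohort <- function(cohort, thresholds = adir_thresholds()) {
  validate_cohort(cohort, require_group = TRUE)
  ds <- domain_scores(cohort)
  onset <- if ("onset" %in% names(cohort)) cohort$onset else NULL
  asd <- classify_asd(ds, onset, thresholds)
  grp <- as.character(cohort$group)
  gl <- sort(unique(grp))
  one <- function(g) {
    i <- grp == g
    data.frame(
      group = g, n = sum(i),
      female = sum(cohort$sex[i] == "F", na.rm = TRUE),
      male = sum(cohort$sex[i] == "M", na.rm = TRUE),
      age_mean = mean(cohort$age_months[i]), age_sd = stats::sd(cohort$age_months[i]),
      asd_yes = sum(asd[i]), asd_no = sum(!asd[i]),
      dI_mean = mean(ds$dI[i]), dI_sd = stats::sd(ds$dI[i]),
      dII_mean = mean(ds$dII[i]), dII_sd = stats::sd(ds$dII[i]),
      dIII_mean = mean(ds$dIII[i]), dIII_sd = stats::sd(ds$dIII[i]),
      total_mean = mean(ds$total[i]), total_sd = stats::sd(ds$total[i]),
      iq_mean = if ("iq" %in% names(cohort)) mean(cohort$iq[i], na.rm = TRUE) else NA,
      iq_sd = if ("iq" %in% names(cohort)) stats::sd(cohort$iq[i], na.rm = TRUE) else NA,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(gl, one))
  pooled <- data.frame(
    group = "Average", n = nrow(cohort),
    female = sum(out$female), male = sum(out$male),
    age_mean = mean(cohort$age_months), age_sd = stats::sd(cohort$age_months),
    asd_yes = sum(out$asd_yes), asd_no = sum(out$asd_no),
    dI_mean = mean(ds$dI), dI_sd = stats::sd(ds$dI),
    dII_mean = mean(ds$dII), dII_sd = stats::sd(ds$dII),
    dIII_mean = mean(ds$dIII), dIII_sd = stats::sd(ds$dIII),
    total_mean = mean(ds$total), total_sd = stats::sd(ds$total),
    iq_mean = if ("iq" %in% names(cohort)) mean(cohort$iq, na.rm = TRUE) else NA,
    iq_sd = if ("iq" %in% names(cohort)) stats::sd(cohort$iq, na.rm = TRUE) else NA,
    stringsAsFactors = FALSE)
  out <- rbind(out, pooled)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
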