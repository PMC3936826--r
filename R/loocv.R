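# Deterministic, order-invariant stratified fold assignment: within each
# class, subjects are ranked by id and dealt round-robin into k folds.
make_folds <- function(y, k, ids) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    i <- which(y == cl)
    i <- i[order(ids[i])]
    fold[i] <- (seq_along(i) - 1L) %% k + 1L
  }
  fold
}

# Cross-validated multiclass accuracy for one (gamma, cost) point.
# Fold models are plain libSVM one-vs-one fits (internal voting), which is
# all the selection step needs.
cv_accuracy <- function(x, y, gamma, cost, fold) {
  correct <- 0L
  for (f in unique(fold)) {
    tr <- fold != f
    ytr <- droplevels(y[tr])
    m <- e1071::svm(x[tr, , drop = FALSE], ytr, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
    pred <- stats::predict(m, x[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
  }
  correct / length(y)
}

#' Inner-loop hyperparameter selection
#'
#' Selects the `(gamma, cost)` grid point maximizing inner cross-validated
#' accuracy on a training set: exact leave-one-out by default, or the
#' stratified k-fold approximation. Accuracy ties are broken by the smallest
#' cost, then the smallest gamma (preferring the smoother model).
#'
#' @param x Feature matrix.
#' @param y Class factor.
#' @param grid Data frame of `gamma`/`cost` candidates.
#' @param inner `"loocv"` or `"kfold"`.
#' @param inner_k Folds when `inner = "kfold"`.
#' @param ids Subject ids used for deterministic fold assignment (defaults
#'   to row order).
#' @return List with `gamma`, `cost`, `accuracy`, `method` and the per-point
#'   `grid_accuracy`.
#' @export
inner_loocv_select <- function(x, y, grid, inner = c("loocv", "kfold"),
                               inner_k = 10, ids = NULL) {
  inner <- match.arg(inner)
  y <- factor(y)
  if (is.null(ids)) ids <- seq_along(y)
  grid <- grid[order(grid$cost, grid$gamma), , drop = FALSE]
  fold <- if (inner == "loocv") seq_along(y)
  else make_folds(y, min(inner_k, length(y)), ids)
  acc <- vapply(seq_len(nrow(grid)), function(i)
    cv_accuracy(x, y, grid$gamma[i], grid$cost[i], fold), numeric(1))
  best <- which.max(acc)  # first max: smallest cost, then smallest gamma
  list(gamma = grid$gamma[best], cost = grid$cost[best],
       accuracy = acc[best],
       method = if (inner == "loocv") "LOOCV" else sprintf("%d-fold CV", inner_k),
       grid_accuracy = cbind(grid, accuracy = acc))
}

#' Nested leave-one-out cross-validation of the signature classifier
#'
#' The unbiased accuracy-estimation procedure: each subject in turn is held
#' out; `gamma` and `cost` are selected by an inner cross-validation loop on
#' the remaining `n - 1` subjects; a one-vs-one ensemble is fitted on those
#' `n - 1` and the held-out subject is predicted with a class and a coupled
#' class-probability vector. Summaries are assembled in the confusion-table
#' layout (rows = predicted class, columns = true class) together with the
#' mean predicted probability of each class among subjects of each true
#' class.
#'
#' @inheritParams signature_svm
#' @param verbose Print per-fold progress.
#' @return An object of class `signature_loocv` with elements
#'   `predictions` (per-subject data frame), `confusion`,
#'   `per_class_accuracy`, `overall_accuracy`, `mean_probability`, `hyper`
#'   (per-fold selected hyperparameters) and `classes`.
#' @export
nested_loocv <- function(cohort, grid = signature_grid(), with_iq = FALSE,
                         inner = c("loocv", "kfold"), inner_k = 10,
                         verbose = FALSE) {
  inner <- match.arg(inner)
  validate_cohort(cohort, require_group = TRUE)
  y <- factor(cohort$group)
  if (any(table(y) < 2)) stop("every class needs >= 2 subjects", call. = FALSE)
  n <- nrow(cohort)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  classes <- levels(y)
  k <- length(classes)
  xraw <- cohort_item_matrix(cohort)
  rownames(xraw) <- cohort$subject_id
  preds <- character(n); pmat <- matrix(NA_real_, n, k,
                                        dimnames = list(cohort$subject_id, classes))
  hyper <- data.frame(gamma = numeric(n), cost = numeric(n))
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    if (with_iq) {
      ctr <- mean(cohort$iq[tr]); scl <- stats::sd(cohort$iq[tr])
      x <- cbind(xraw, iq = (cohort$iq - ctr) / scl)
    } else x <- xraw
    if (nrow(grid) > 1) {
      sel <- inner_loocv_select(x[tr, , drop = FALSE], y[tr], grid,
                                inner = inner, inner_k = inner_k,
                                ids = cohort$subject_id[tr])
      g <- sel$gamma; cst <- sel$cost
    } else { g <- grid$gamma[1]; cst <- grid$cost[1] }
    hyper$gamma[i] <- g; hyper$cost[i] <- cst
    fit <- fit_ovo_svm(x[tr, , drop = FALSE], y[tr], g, cst, min_class = 1)
    res <- predict.signature_svm(fit, x[i, , drop = FALSE], type = "prob")
    d <- ovo_decision_values(fit, x[i, , drop = FALSE])
    preds[i] <- as.character(ovo_vote(d, classes))
    pmat[i, ] <- res[1, classes]
    if (verbose && i %% 25 == 0) message("outer fold ", i, "/", n)
  }
  predicted <- factor(preds, levels = classes)
  predictions <- data.frame(subject_id = cohort$subject_id,
                            true_group = y, predicted_group = predicted,
                            stringsAsFactors = FALSE)
  pp <- as.data.frame(pmat); names(pp) <- paste0("p_", classes)
  predictions <- cbind(predictions, pp)
  predictions$p_assigned <- pmat[cbind(seq_len(n), as.integer(predicted))]
  predictions$correct <- predictions$predicted_group == predictions$true_group
  rownames(predictions) <- NULL
  confusion <- table(predicted = predicted, true = y)
  acc <- confusion_accuracy(confusion)
  mean_probability <- vapply(classes, function(tc)
    colMeans(pmat[y == tc, , drop = FALSE]), numeric(k))
  # rows = predicted-for class, columns = true class
  dimnames(mean_probability) <- list(predicted = classes, true = classes)
  structure(list(predictions = predictions, confusion = confusion,
                 per_class_accuracy = acc$per_class,
                 overall_accuracy = acc$overall,
                 mean_probability = mean_probability,
                 hyper = hyper, classes = classes, n = n,
                 inner = inner, with_iq = with_iq),
            class = "signature_loocv")
}

#' @export
print.signature_loocv <- function(x, ...) {
  cat("Nested leave-one-out cross-validation,", x$n, "subjects,",
      length(x$classes), "classes\n\n")
  cat("Confusion (rows = predicted, columns = true):\n")
  print(x$confusion)
  cat("\nPer-class accuracy:\n")
  print(round(x$per_class_accuracy, 3))
  cat(sprintf("\nOverall accuracy: %d/%d (%.1f%%)\n",
              sum(diag(x$confusion)), x$n, 100 * x$overall_accuracy))
  invisible(x)
}

#' @export
summary.signature_loocv <- function(object, ...) {
  print(object)
  cat("\nMean predicted probability (rows = class, columns = true class):\n")
  print(round(object$mean_probability, 3))
  cat("\nSelected hyperparameters (outer folds):\n")
  print(table(gamma = object$hyper$gamma, cost = object$hyper$cost))
  invisible(object)
}

#' Pairwise (one-by-one) accuracy table
#'
#' Nested-LOOCV accuracy of every two-class subproblem: entry `(g, h)` is
#' the accuracy of the classifier restricted to subjects of groups `g` and
#' `h` only. The matrix is symmetric with an undefined diagonal.
#'
#' @inheritParams nested_loocv
#' @return `k x k` symmetric matrix of accuracies, `NA` diagonal.
#' @export
pairwise_accuracy_table <- function(cohort, grid = signature_grid(),
                                    inner = c("loocv", "kfold"),
                                    inner_k = 10) {
  inner <- match.arg(inner)
  groups <- sort(unique(as.character(cohort$group)))
  k <- length(groups)
  out <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (a in seq_len(k - 1)) for (b in seq((a + 1), k)) {
    sub <- cohort[cohort$group %in% groups[c(a, b)], , drop = FALSE]
    res <- nested_loocv(sub, grid, inner = inner, inner_k = inner_k)
    out[a, b] <- out[b, a] <- res$overall_accuracy
  }
  out
}

#' Association between predicted probability and correctness
#'
#' Tests whether higher assigned-class probabilities go with a higher chance
#' of correct classification: logistic regression of correctness (0/1) on
#' the assigned-class probability, reporting the slope and its Wald p-value,
#' with the point-biserial correlation alongside. Complete separation (e.g.
#' all predictions correct) is reported with a flag rather than an error.
#'
#' @param result A `signature_loocv` object (or its `predictions` frame).
#' @return List with `slope`, `p_value`, `r_pointbiserial`, `n` and
#'   `degenerate`.
#' @export
probability_correctness_assoc <- function(result) {
  df <- if (inherits(result, "signature_loocv")) result$predictions else result
  if (nrow(df) < 10) stop("need at least 10 subjects", call. = FALSE)
  degenerate <- FALSE
  if (length(unique(df$correct)) < 2 ||
      stats::sd(df$p_assigned) == 0) degenerate <- TRUE
  fit <- withCallingHandlers(
    stats::glm(correct ~ p_assigned, data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        degenerate <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  slope <- if ("p_assigned" %in% rownames(co)) co["p_assigned", "Estimate"] else NA
  p <- if ("p_assigned" %in% rownames(co)) co["p_assigned", "Pr(>|z|)"] else NA
  r_pb <- if (degenerate && length(unique(df$correct)) < 2) NA_real_
  else stats::cor(as.numeric(df$correct), df$p_assigned)
  list(slope = slope, p_value = p, r_pointbiserial = r_pb,
       n = nrow(df), degenerate = degenerate)
}

#' Item importance for the fitted ensemble
#'
#' Default (`"linear"`): for each binary classifier the linear primal
#' approximation `w = |sum_i alpha_i y_i x_i|` is computed from the support
#' coefficients, and each feature's weight is averaged over the binary
#' classifiers — the importance the support-coefficient workflow affords for
#' RBF models, heuristic but fast. `"permutation"`: the drop in whole-model
#' accuracy when one feature column is shuffled, averaged over `n_perm`
#' shuffles (requires a labeled cohort).
#'
#' @param model A `signature_svm`.
#' @param cohort Labeled cohort (required for `method = "permutation"`).
#' @param method `"linear"` or `"permutation"`.
#' @param n_perm Shuffles per feature for the permutation method.
#' @param seed Optional seed for the permutation method.
#' @return Data frame `feature`, `importance`, sorted descending.
#' @export
item_importance <- function(model, cohort = NULL,
                            method = c("linear", "permutation"),
                            n_perm = 20, seed = NULL) {
  method <- match.arg(method)
  feats <- model$features
  if (method == "linear") {
    W <- vapply(model$classifiers, function(cl) {
      abs(colSums(cl$model$coefs[, 1] * cl$model$SV))
    }, numeric(length(feats)))
    imp <- rowMeans(matrix(W, nrow = length(feats)))
  } else {
    if (is.null(cohort)) stop("permutation importance needs a labeled cohort",
                              call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    x <- cohort_features(cohort, with_iq = isTRUE(model$with_iq),
                         iq_center = model$iq_center, iq_scale = model$iq_scale)
    y <- as.character(cohort$group)
    base <- mean(as.character(predict.signature_svm(model, x, type = "class")) == y)
    imp <- vapply(seq_along(feats), function(j) {
      accs <- vapply(seq_len(n_perm), function(r) {
        xp <- x; xp[, j] <- xp[sample.int(nrow(xp)), j]
        mean(as.character(predict.signature_svm(model, xp, type = "class")) == y)
      }, numeric(1))
      base - mean(accs)
    }, numeric(1))
  }
  out <- data.frame(feature = feats, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Re-analysis with IQ as an additional predictor
#'
#' Runs the nested cross-validation once on the 37 items alone and once with
#' standardized IQ appended as a 38th feature, to check whether general
#' intellectual ability confounds the signature classification. Subjects
#' with missing IQ are dropped (with a warning and count).
#'
#' @inheritParams nested_loocv
#' @return List with `accuracy_without`, `accuracy_with_iq`, `n_used`,
#'   `n_dropped` and both `signature_loocv` results.
#' @export
covariate_reanalysis <- function(cohort, grid = signature_grid(),
                                 inner = c("loocv", "kfold"), inner_k = 10) {
  inner <- match.arg(inner)
  has_iq <- !is.na(cohort$iq)
  n_dropped <- sum(!has_iq)
  if (n_dropped > 0) {
    warning(n_dropped, " subject(s) without IQ dropped from the re-analysis")
    cohort <- cohort[has_iq, , drop = FALSE]
  }
  without <- nested_loocv(cohort, grid, with_iq = FALSE,
                          inner = inner, inner_k = inner_k)
  with_iq <- nested_loocv(cohort, grid, with_iq = TRUE,
                          inner = inner, inner_k = inner_k)
  list(accuracy_without = without$overall_accuracy,
       accuracy_with_iq = with_iq$overall_accuracy,
       n_used = nrow(cohort), n_dropped = n_dropped,
       loocv_without = without, loocv_with_iq = with_iq)
}
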