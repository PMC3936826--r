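#' Default hyperparameter grid
#'
#' The grid of RBF-kernel `gamma` and soft-margin `cost` values searched by
#' the inner cross-validation loop. The full grid spans `gamma` in
#' `2^-7 ... 2^3` and `cost` in `2^-3 ... 2^7` on log2 steps of 2; the
#' reduced grid is the coarse 2 x 2 subset `gamma in {2^-5, 2^-2}`,
#' `cost in {1, 8}` used for the larger simulation suites, bracketing the
#' conventional `gamma = 1/p` default for 37 items.
#'
#' @param reduced Return the coarse grid.
#' @return Data frame with columns `gamma` and `cost`, sorted by cost then
#'   gamma (the tie-break preference order).
#' @export
signature_grid <- function(reduced = FALSE) {
  g <- if (reduced) expand.grid(gamma = 2^c(-5, -2), cost = 2^c(0, 3))
  else expand.grid(gamma = 2^seq(-7, 3, 2), cost = 2^seq(-3, 7, 2))
  g <- g[order(g$cost, g$gamma), , drop = FALSE]
  rownames(g) <- NULL
  g
}

# Platt sigmoid fit: P(first class | decision value d) = 1/(1+exp(A*d+B)),
# maximum likelihood with the prior-smoothed targets of Platt (1999) so the
# fit is well defined even under complete separation.
platt_fit <- function(d, is_first) {
  np <- sum(is_first); nn <- sum(!is_first)
  t <- ifelse(is_first, (np + 1) / (np + 2), 1 / (nn + 2))
  nll <- function(par) {
    f <- par[1] * d + par[2]
    lse <- ifelse(f > 30, f, log1p(exp(f)))   # log(1 + exp(f)), overflow-safe
    sum(t * lse + (1 - t) * (lse - f))
  }
  init <- c(A = 0, B = log((nn + 1) / (np + 1)))
  fit <- stats::optim(init, nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  c(A = unname(fit$par[1]), B = unname(fit$par[2]))
}

platt_prob <- function(d, params) 1 / (1 + exp(params["A"] * d + params["B"]))

# Build the feature matrix: raw 0-2 item codes, optionally plus IQ
# standardized with the supplied (training-set) center/scale.
cohort_features <- function(cohort, with_iq = FALSE,
                            iq_center = NULL, iq_scale = NULL) {
  x <- cohort_item_matrix(cohort)
  rownames(x) <- cohort$subject_id
  if (with_iq) {
    if (!"iq" %in% names(cohort) || anyNA(cohort$iq))
      stop("with_iq = TRUE requires a complete iq column", call. = FALSE)
    if (is.null(iq_center)) iq_center <- mean(cohort$iq)
    if (is.null(iq_scale)) iq_scale <- stats::sd(cohort$iq)
    x <- cbind(x, iq = (cohort$iq - iq_center) / iq_scale)
    attr(x, "iq_center") <- iq_center
    attr(x, "iq_scale") <- iq_scale
  }
  x
}

#' Fit a one-vs-one RBF-SVM ensemble
#'
#' Trains the `k(k-1)/2` binary radial-basis-function support vector
#' machines of the one-against-one multiclass scheme (each binary problem
#' solved by libSVM via \pkg{e1071}), and fits a Platt sigmoid to each
#' binary's training decision values so that pairwise class probabilities
#' can be coupled into a k-class probability vector at prediction time.
#' Features are used unscaled (items share the common 0-2 scale).
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Class labels (coerced to factor); every class needs >= 2
#'   members.
#' @param gamma RBF kernel width, `K(u, v) = exp(-gamma * |u - v|^2)`.
#' @param cost Soft-margin cost.
#' @param min_class Minimum class size (the outer cross-validation loop
#'   trains with a singleton left in a 2-member class and lowers this to 1).
#' @return An object of class `signature_svm`.
#' @seealso [signature_svm()] for the cohort-level interface with
#'   hyperparameter selection, [predict.signature_svm()].
#' @export
fit_ovo_svm <- function(x, y, gamma, cost, min_class = 2) {
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  k <- length(classes)
  if (k < 2) stop("need at least 2 classes", call. = FALSE)
  small <- table(y) < min_class
  if (any(small))
    stop("class(es) with fewer than 2 members: ",
         paste(names(small)[small], collapse = ", "), call. = FALSE)
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  classifiers <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    idx <- y %in% pr
    yi <- factor(as.character(y[idx]), levels = pr)
    m <- e1071::svm(x[idx, , drop = FALSE], yi, type = "C-classification",
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE, fitted = TRUE)
    d <- m$decision.values[, 1]
    # orient decision values so positive favors class `a` (libSVM orders the
    # pair by first occurrence in the data, not by factor level)
    flip <- colnames(m$decision.values)[1] != paste(a, b, sep = "/")
    if (flip) d <- -d
    list(a = a, b = b, model = m, flip = flip,
         platt = platt_fit(d, yi == a))
  })
  structure(list(classifiers = classifiers, classes = classes,
                 gamma = gamma, cost = cost, n = nrow(x),
                 features = colnames(x)),
            class = "signature_svm")
}

# Oriented decision-value matrix (n x n_pairs) for new data.
ovo_decision_values <- function(object, x) {
  d <- vapply(object$classifiers, function(cl) {
    prd <- stats::predict(cl$model, x, decision.values = TRUE)
    dv <- attr(prd, "decision.values")[, 1]
    if (cl$flip) -dv else dv
  }, numeric(nrow(x)))
  d <- matrix(d, nrow = nrow(x))
  colnames(d) <- vapply(object$classifiers, function(cl)
    paste(cl$a, cl$b, sep = "/"), character(1))
  d
}

#' One-vs-one majority vote
#'
#' Aggregates oriented pairwise decision values into a predicted class: each
#' binary classifier votes for the class its decision value favors, and the
#' class with the most votes wins. Vote ties are broken by the largest
#' summed signed decision margin in the tied class's favor, then by the
#' lowest class index.
#'
#' @param decision Matrix (or vector for one subject) of decision values,
#'   one column per unordered class pair named `"a/b"`, positive favoring
#'   `a`.
#' @param classes Character vector of class names fixing the class order.
#' @return Factor of predicted classes.
#' @export
ovo_vote <- function(decision, classes) {
  if (is.null(dim(decision))) decision <- matrix(decision, nrow = 1,
                                                 dimnames = list(NULL, names(decision)))
  pair_names <- strsplit(colnames(decision), "/", fixed = TRUE)
  k <- length(classes)
  n <- nrow(decision)
  votes <- matrix(0L, n, k, dimnames = list(NULL, classes))
  margin <- matrix(0, n, k, dimnames = list(NULL, classes))
  for (j in seq_along(pair_names)) {
    a <- pair_names[[j]][1]; b <- pair_names[[j]][2]
    wa <- decision[, j] > 0
    votes[, a] <- votes[, a] + wa
    votes[, b] <- votes[, b] + !wa
    margin[, a] <- margin[, a] + decision[, j]
    margin[, b] <- margin[, b] - decision[, j]
  }
  pick <- vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1) top <- top[margin[i, top] == max(margin[i, top])]
    top[1]
  }, integer(1))
  factor(classes[pick], levels = classes)
}

#' Couple pairwise probabilities into class probabilities
#'
#' Solves the second pairwise-coupling problem of Wu, Lin and Weng (the
#' method used by libSVM): given pairwise class-conditional probabilities
#' `r[i, j] = P(class i | class i or j, x)`, find the probability vector `p`
#' minimizing `sum_i sum_{j != i} (r[j,i] p_i - r[i,j] p_j)^2` subject to
#' `p >= 0`, `sum(p) = 1`, by the fixed-point iteration of the libSVM
#' reference algorithm.
#'
#' @param r Square matrix of pairwise probabilities with `r[i,j] + r[j,i]
#'   = 1` off the diagonal (the diagonal is ignored). Row/column names give
#'   class names.
#' @param eps Convergence tolerance on the stationarity residual.
#' @param max_iter Iteration cap.
#' @return Named probability vector summing to 1.
#' @export
couple_probabilities <- function(r, eps = 1e-12, max_iter = 500) {
  r <- as.matrix(r)
  k <- nrow(r)
  if (any(!is.finite(r[row(r) != col(r)])))
    stop("non-finite pairwise probabilities", call. = FALSE)
  if (k == 1) return(stats::setNames(1, rownames(r)))
  Q <- matrix(0, k, k)
  for (t in seq_len(k)) {
    Q[t, t] <- sum(r[-t, t]^2)
    for (j in seq_len(k)) if (j != t) Q[t, j] <- -r[j, t] * r[t, j]
  }
  p <- rep(1 / k, k)
  Qp <- as.vector(Q %*% p)
  pQp <- sum(p * Qp)
  for (it in seq_len(max_iter)) {
    if (max(abs(Qp - pQp)) < eps) break
    for (t in seq_len(k)) {
      diff <- (-Qp[t] + pQp) / Q[t, t]
      p[t] <- p[t] + diff
      pQp <- (pQp + diff * (diff * Q[t, t] + 2 * Qp[t])) / (1 + diff)^2
      Qp <- (Qp + diff * Q[, t]) / (1 + diff)
      p <- p / (1 + diff)
    }
  }
  p <- pmax(p, 0); p <- p / sum(p)
  stats::setNames(p, rownames(r))
}

#' Predict classes and coupled probabilities
#'
#' Predicted class is the one-vs-one majority vote over the binary decision
#' values ([ovo_vote()]); the k-class probability vector is obtained by
#' Platt-transforming each binary decision value and coupling the pairwise
#' probabilities ([couple_probabilities()]). The probability reported for
#' the assigned class (`p_assigned`) quantifies prediction confidence.
#'
#' @param object A `signature_svm`.
#' @param newdata Cohort data frame or feature matrix.
#' @param type `"class"` for the vote-assigned factor, `"prob"` for the
#'   probability matrix, `"response"` for a per-subject data frame with
#'   class, probabilities and `p_assigned`.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.signature_svm <- function(object, newdata,
                                  type = c("response", "class", "prob"), ...) {
  type <- match.arg(type)
  x <- if (is.matrix(newdata)) newdata else
    cohort_features(newdata, with_iq = "iq" %in% object$features,
                    iq_center = object$iq_center, iq_scale = object$iq_scale)
  if (!identical(colnames(x), object$features))
    x <- x[, object$features, drop = FALSE]
  d <- ovo_decision_values(object, x)
  cls <- ovo_vote(d, object$classes)
  k <- length(object$classes)
  prob <- matrix(NA_real_, nrow(x), k,
                 dimnames = list(rownames(x), object$classes))
  rmat <- matrix(0.5, k, k, dimnames = list(object$classes, object$classes))
  for (i in seq_len(nrow(x))) {
    for (j in seq_along(object$classifiers)) {
      cl <- object$classifiers[[j]]
      pa <- platt_prob(d[i, j], cl$platt)
      pa <- min(max(pa, 1e-7), 1 - 1e-7)
      rmat[cl$a, cl$b] <- pa
      rmat[cl$b, cl$a] <- 1 - pa
    }
    prob[i, ] <- couple_probabilities(rmat)
  }
  stopifnot(all(abs(rowSums(prob) - 1) < 1e-9), all(prob >= 0))
  if (type == "class") return(cls)
  if (type == "prob") return(prob)
  out <- data.frame(subject_id = if (is.null(rownames(x)))
    seq_len(nrow(x)) else rownames(x),
    predicted_group = cls, stringsAsFactors = FALSE)
  pp <- as.data.frame(prob)
  names(pp) <- paste0("p_", object$classes)
  out <- cbind(out, pp)
  out$p_assigned <- prob[cbind(seq_len(nrow(prob)), as.integer(cls))]
  rownames(out) <- NULL
  out
}

#' @export
print.signature_svm <- function(x, ...) {
  k <- length(x$classes)
  cat("One-vs-one RBF-SVM signature classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  %d binary classifiers (k(k-1)/2, k = %d), trained on n = %d\n",
              k * (k - 1) / 2, k, x$n))
  cat(sprintf("  gamma = %g, cost = %g, features: %d\n",
              x$gamma, x$cost, length(x$features)))
  if (!is.null(x$selection))
    cat(sprintf("  hyperparameters selected by inner %s (accuracy %.3f)\n",
                x$selection$method, x$selection$accuracy))
  invisible(x)
}

#' @export
summary.signature_svm <- function(object, ...) {
  print(object)
  nsv <- vapply(object$classifiers, function(cl) cl$model$tot.nSV, numeric(1))
  cat(sprintf("  support vectors per binary: median %d (range %d-%d)\n",
              round(stats::median(nsv)), min(nsv), max(nsv)))
  invisible(object)
}

#' Fit the signature classifier to a labeled cohort
#'
#' The central model-fitting function: builds the feature matrix (37 raw
#' item codes, optionally plus standardized IQ), selects `gamma` and `cost`
#' by the inner cross-validation loop over `grid` (unless both are given
#' explicitly), and fits the final one-vs-one ensemble on the full cohort.
#' This is the "train on everything" step used before allocating blind
#' samples; for unbiased accuracy estimation use [nested_loocv()].
#'
#' @param cohort Labeled cohort data frame.
#' @param grid Hyperparameter grid, see [signature_grid()].
#' @param gamma,cost Fixed hyperparameters; if both given, no selection.
#' @param with_iq Append standardized IQ as a 38th feature.
#' @param inner `"loocv"` for exact leave-one-out selection (the default),
#'   `"kfold"` for the faster stratified k-fold approximation.
#' @param inner_k Folds for `inner = "kfold"`.
#' @return A `signature_svm` with a `$selection` record.
#' @export
signature_svm <- function(cohort, grid = signature_grid(),
                          gamma = NULL, cost = NULL, with_iq = FALSE,
                          inner = c("loocv", "kfold"), inner_k = 10) {
  inner <- match.arg(inner)
  validate_cohort(cohort, require_group = TRUE)
  x <- cohort_features(cohort, with_iq)
  y <- factor(cohort$group)
  if (is.null(gamma) || is.null(cost)) {
    sel <- inner_loocv_select(x, y, grid, inner = inner, inner_k = inner_k,
                              ids = cohort$subject_id)
    gamma <- sel$gamma; cost <- sel$cost
  } else sel <- list(gamma = gamma, cost = cost, accuracy = NA_real_,
                     method = "fixed")
  fit <- fit_ovo_svm(x, y, gamma, cost)
  fit$selection <- sel
  fit$with_iq <- with_iq
  if (with_iq) {
    fit$iq_center <- attr(x, "iq_center")
    fit$iq_scale <- attr(x, "iq_scale")
  }
  fit
}
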