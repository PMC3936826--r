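#' Principal component analysis of item profiles
#'
#' Centered, unscaled (covariance-matrix) PCA of the 37 item scores — the
#' items share the common 0-2 scale, so the covariance convention keeps
#' loadings in score units. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible.
#'
#' @param cohort Cohort data frame or numeric matrix of item scores.
#' @param m Number of components to retain (default all).
#' @param scale. Use the correlation matrix instead (flagged alternative).
#' @return Object of class `signature_pca`: `center`, `loadings` (p x m,
#'   orthonormal columns), `sdev`, `explained_variance` (proportions) and
#'   the training `scores`.
#' @export
pca_fit <- function(cohort, m = NULL, scale. = FALSE) {
  x <- if (is.matrix(cohort)) cohort else cohort_item_matrix(cohort)
  if (is.null(m)) m <- min(nrow(x) - 1, ncol(x))
  stopifnot(m >= 1, nrow(x) > m)
  if (any(apply(x, 2, stats::sd) == 0)) {
    if (scale.) stop("constant columns cannot be scaled", call. = FALSE)
    warning("constant item(s) retained with zero loading")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  keep <- seq_len(min(m, ncol(pc$rotation)))
  load <- pc$rotation[, keep, drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pc$x[, keep, drop = FALSE], 2, flip, `*`)
  structure(list(center = pc$center,
                 scale = if (scale.) pc$scale else NULL,
                 loadings = load, sdev = pc$sdev[keep],
                 explained_variance = pc$sdev[keep]^2 / sum(pc$sdev^2),
                 scores = scores),
            class = "signature_pca")
}

#' Project new profiles onto a fitted PCA
#'
#' Centers the new profiles by the *model's* item means (no refit, no data
#' leakage) and projects them on the model's loadings — how blind samples
#' are inserted into the training-sample component space.
#'
#' @param model A `signature_pca`.
#' @param cohort Cohort data frame or item-score matrix.
#' @return Score matrix (subjects x components).
#' @export
pca_project <- function(model, cohort) {
  x <- if (is.matrix(cohort)) cohort else cohort_item_matrix(cohort)
  x <- sweep(x, 2, model$center)
  if (!is.null(model$scale)) x <- sweep(x, 2, model$scale, `/`)
  x %*% model$loadings
}

#' @export
print.signature_pca <- function(x, ...) {
  cat("PCA of item profiles:", nrow(x$loadings), "items,",
      ncol(x$loadings), "components\n")
  cat("explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.signature_pca <- function(x, groups = NULL, newdata = NULL,
                               new_label = "blind", ...) {
  sc <- x$scores[, 1:2, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(sc, col = col, pch = 16,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained_variance[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained_variance[2]),
                 ...)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     col = seq_along(levels(factor(groups))), pch = 16, cex = 0.7)
  if (!is.null(newdata)) {
    pr <- pca_project(x, newdata)
    graphics::points(pr[, 1:2, drop = FALSE], pch = 4, col = "grey40")
  }
  invisible(x)
}

# Mean silhouette width from a distance matrix and cluster labels;
# singleton clusters score 0 by convention.
mean_silhouette <- function(d, cluster) {
  d <- as.matrix(d)
  n <- length(cluster)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(cl) mean(d[i, cluster == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' k-means cluster-structure screen
#'
#' Runs standard k-means (multiple restarts) over a range of k and reports
#' quality metrics only — total within-cluster inertia and the mean
#' silhouette width. A flat silhouette profile (< ~0.3 everywhere) indicates
#' no relevant cluster structure; cluster labels are never used downstream.
#'
#' @param cohort Cohort data frame or item-score matrix.
#' @param k_range Values of k to screen.
#' @param nstart Random restarts per k.
#' @param seed Seed for the restarts.
#' @return Data frame with columns `k`, `inertia`, `mean_silhouette`.
#' @export
kmeans_screen <- function(cohort, k_range = 2:8, nstart = 25, seed = 1) {
  x <- if (is.matrix(cohort)) cohort else cohort_item_matrix(cohort)
  stopifnot(all(k_range >= 2), all(k_range <= nrow(x) - 1))
  set.seed(seed)
  d <- stats::dist(x)
  out <- lapply(k_range, function(k) {
    km <- stats::kmeans(x, centers = k, nstart = nstart, iter.max = 50)
    data.frame(k = k, inertia = km$tot.withinss,
               mean_silhouette = mean_silhouette(d, km$cluster))
  })
  do.call(rbind, out)
}
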