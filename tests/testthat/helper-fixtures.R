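# Shared fixtures and independent oracles used across the suite.

# A small calibrated 6-group config for quick end-to-end runs.
tiny_config <- function(seed = 1, sizes = c(20, 8, 20, 8, 14, 14), ...) {
  default_generator_config(seed = seed, sizes = sizes, ...)
}

# Hand-built two-class cohort: items drawn Binomial(2, p_class); classes are
# well separated when the p's differ strongly.
toy_cohort <- function(n = c(A = 15, B = 15), p = c(A = 0.15, B = 0.85),
                       seed = 1) {
  set.seed(seed)
  rows <- lapply(names(n), function(g) {
    items <- matrix(stats::rbinom(n[[g]] * 37, 2, p[[g]]), n[[g]], 37)
    colnames(items) <- item_columns()
    cbind(data.frame(subject_id = sprintf("%s%03d", g, seq_len(n[[g]])),
                     group = g, age_months = 120, sex = "M", iq = 70,
                     verbal = TRUE, onset = 2, stringsAsFactors = FALSE),
          as.data.frame(items))
  })
  do.call(rbind, rows)
}

# Brute-force simplex-grid minimizer of the pairwise-coupling objective:
# coarse pass at `step`, then a local refinement at step/10 around the best
# point. Independent of the fixed-point implementation.
coupling_objective <- function(p, r) {
  k <- length(p)
  obj <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (j != i)
    obj <- obj + (r[j, i] * p[i] - r[i, j] * p[j])^2
  obj
}

simplex_grid <- function(k, step) {
  m <- round(1 / step)
  if (k == 2) {
    a <- 0:m
    cbind(a, m - a) / m
  } else if (k == 3) {
    g <- expand.grid(a = 0:m, b = 0:m)
    g <- g[g$a + g$b <= m, ]
    cbind(g$a, g$b, m - g$a - g$b) / m
  } else {
    g <- expand.grid(a = 0:m, b = 0:m, c = 0:m)
    g <- g[g$a + g$b + g$c <= m, ]
    cbind(g$a, g$b, g$c, m - g$a - g$b - g$c) / m
  }
}

# Vectorized objective over a candidate matrix (rows = simplex points).
grid_objective <- function(P, r) {
  k <- ncol(P)
  obj <- numeric(nrow(P))
  for (i in seq_len(k)) for (j in seq_len(k)) if (j != i)
    obj <- obj + (r[j, i] * P[, i] - r[i, j] * P[, j])^2
  obj
}

grid_couple <- function(r, step = 0.01) {
  k <- nrow(r)
  cand <- simplex_grid(k, step)
  best <- cand[which.min(grid_objective(cand, r)), ]
  # local refinement at step/10 in a box around the coarse optimum
  axes <- lapply(seq_len(k - 1), function(i) {
    v <- seq(best[i] - step, best[i] + step, by = step / 10)
    v[v >= -1e-12 & v <= 1 + 1e-12]
  })
  g <- as.matrix(expand.grid(axes))
  last <- 1 - rowSums(g)
  keep <- last >= -1e-12 & last <= 1 + 1e-12
  cand2 <- pmax(cbind(g, last)[keep, , drop = FALSE], 0)
  unname(cand2[which.min(grid_objective(cand2, r)), ])
}

# Random valid pairwise-probability matrix.
random_r_matrix <- function(k) {
  r <- matrix(0.5, k, k)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    v <- stats::runif(1, 0.05, 0.95)
    r[i, j] <- v; r[j, i] <- 1 - v
  }
  rownames(r) <- colnames(r) <- paste0("C", seq_len(k))
  r
}

# Brute-force one-vs-one vote counter with the package's documented
# tie-break (max votes, then max summed signed margin, then lowest index),
# written independently for cross-checking ovo_vote().
brute_vote <- function(d, classes) {
  pairs <- strsplit(names(d), "/", fixed = TRUE)
  votes <- stats::setNames(rep(0, length(classes)), classes)
  margin <- stats::setNames(rep(0, length(classes)), classes)
  for (j in seq_along(pairs)) {
    a <- pairs[[j]][1]; b <- pairs[[j]][2]
    if (d[j] > 0) votes[a] <- votes[a] + 1 else votes[b] <- votes[b] + 1
    margin[a] <- margin[a] + d[j]; margin[b] <- margin[b] - d[j]
  }
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    mm <- margin[top]
    top <- top[mm == max(mm)]
  }
  top[1]
}

# Directly assembled sibling-pair tables (bypassing the classifier) for
# unit tests of the statistics.
fake_pairs <- function(n, r_prob = 0, seed = 1, groups = LETTERS[1:4],
                       concordant_frac = 0.5) {
  set.seed(seed)
  z <- stats::rnorm(n)
  clamp <- function(p) pmin(pmax(p, 0.01), 0.99)
  p1 <- clamp(0.5 + 0.15 * (sqrt(r_prob) * z +
                              sqrt(1 - r_prob) * stats::rnorm(n)))
  p2 <- clamp(0.5 + 0.15 * (sqrt(r_prob) * z +
                              sqrt(1 - r_prob) * stats::rnorm(n)))
  g1 <- sample(groups, n, TRUE)
  conc <- stats::runif(n) < concordant_frac
  g2 <- ifelse(conc, g1, sample(groups, n, TRUE))
  out <- data.frame(family_id = sprintf("f%04d", seq_len(n)),
                    group1 = g1, group2 = g2,
                    prob1 = p1, prob2 = p2,
                    mean_items1 = stats::runif(n, 0, 2),
                    mean_items2 = stats::runif(n, 0, 2),
                    pc1_1 = stats::rnorm(n), pc1_2 = stats::rnorm(n),
                    stringsAsFactors = FALSE)
  out$concordant <- out$group1 == out$group2
  class(out) <- c("sib_pair_table", "data.frame")
  out
}
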