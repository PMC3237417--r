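# Relationship statistics between origin-mode sets: Monte Carlo
# intersection test (exact analog: hypergeometric tail) and
# classification-accuracy similarity with a six-classifier suite, plus the
# shared chi-square and Welch t utilities.

#' Monte Carlo intersection test between two gene sets
#'
#' Given M genes of which m are in set 1, n in set 2 and N in both, draws
#' an m-subset and an n-subset without replacement `reps` times and counts
#' their intersection. The default empirical P is the standard one-sided
#' tail: P(sim >= N) when N exceeds the expectation mn/M (enrichment),
#' P(sim <= N) otherwise (depletion). `mode = "paper-literal"` uses strict
#' inequalities (P(sim > N) / P(sim < N)), the tail excluding ties at N.
#' The analytic P is the exact hypergeometric tail in the same direction.
#' Reported empirical P floors at 1/reps.
#'
#' @param M,m,n,N set sizes and observed intersection
#' @param reps simulation count (default 100000)
#' @param seed optional seed applied locally
#' @param mode tail convention, see above
#' @return list of class `intersection_test`: M, m, n, N, expected,
#'   mean_sim, reps, p_empirical, p_analytic, direction
#' @export
monte_carlo_intersection <- function(M, m, n, N, reps = 100000L,
                                     seed = NULL,
                                     mode = c("standard", "paper-literal")) {
  mode <- match.arg(mode)
  if (m < 0 || n < 0 || m > M || n > M) stop("need 0 <= m, n <= M")
  if (N > min(m, n) || N < max(0, m + n - M)) {
    stop("infeasible intersection N for these set sizes")
  }
  run <- function() mc_intersection_sample(as.integer(M), as.integer(m),
                                           as.integer(n), as.integer(reps))
  sims <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  expected <- m * n / M
  enriched <- N > expected
  p_emp <- if (mode == "standard") {
    if (enriched) mean(sims >= N) else mean(sims <= N)
  } else {
    if (enriched) mean(sims > N) else mean(sims < N)
  }
  p_emp <- max(p_emp, 1 / reps)
  p_an <- if (enriched) {
    stats::phyper(N - 1, m, M - m, n, lower.tail = FALSE)
  } else {
    stats::phyper(N, m, M - m, n)
  }
  structure(list(M = M, m = m, n = n, N = N, expected = expected,
                 mean_sim = mean(sims), reps = reps, p_empirical = p_emp,
                 p_analytic = p_an,
                 direction = if (enriched) "enriched" else "depleted"),
            class = "intersection_test")
}

#' Chi-square test on a 2x2 table (no continuity correction)
#'
#' @param a,b,c,d cell counts, rows (a, b) and (c, d)
#' @return list(statistic, p)
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  o <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  n <- sum(o)
  e <- outer(rowSums(o), colSums(o)) / n
  if (any(e == 0)) return(list(statistic = NA_real_, p = NA_real_))
  stat <- sum((o - e)^2 / e)
  list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                           lower.tail = FALSE))
}

#' Welch two-sample t-test
#'
#' Standard Welch statistic with Satterthwaite degrees of freedom;
#' identical groups (zero pooled standard error) give t = 0, p = 1.
#'
#' @param x,y numeric vectors
#' @return list(statistic, df, p)
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p = NA_real_))
  }
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  se2 <- vx + vy
  if (se2 == 0) return(list(statistic = 0, df = Inf, p = 1))
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(statistic = t, df = df,
       p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

# --- classifier suite ----------------------------------------------------
# Six discriminative learners at fixed defaults. The named six-model suite
# (naive Bayes, kNN, decision tree, C4.5, SVM, random forest) is realised
# with the learners available offline: Gaussian naive Bayes, kNN (k = 5),
# two variance-reduction binary trees (gini- and entropy-split, the latter
# standing in for C4.5), ridge-regularised logistic regression (linear
# margin classifier standing in for the linear SVM), and bagged randomized
# trees (standing in for the random forest).

nb_train_predict <- function(xtr, ytr, xte) {
  stats_by <- lapply(c(FALSE, TRUE), function(cl) {
    xx <- xtr[ytr == cl, , drop = FALSE]
    list(mu = colMeans(xx), sd = pmax(apply(xx, 2, stats::sd), 1e-6),
         prior = nrow(xx) / nrow(xtr))
  })
  ll <- vapply(stats_by, function(s) {
    rowSums(vapply(seq_len(ncol(xte)), function(j) {
      stats::dnorm(xte[, j], s$mu[j], s$sd[j], log = TRUE)
    }, numeric(nrow(xte)))) + log(s$prior)
  }, numeric(nrow(xte)))
  if (nrow(xte) == 1) ll <- matrix(ll, nrow = 1)
  c(FALSE, TRUE)[max.col(ll, ties.method = "first")]
}

knn_train_predict <- function(xtr, ytr, xte, k = 5L) {
  k <- min(k, nrow(xtr))
  vapply(seq_len(nrow(xte)), function(i) {
    d <- colSums((t(xtr) - xte[i, ])^2)
    nb <- ytr[order(d)[seq_len(k)]]
    mean(nb) > 0.5
  }, TRUE)
}

# small recursive binary tree on numeric features
tree_fit <- function(x, y, depth = 3L, min_split = 8L,
                     split = c("gini", "info"), mtry = NULL) {
  split <- match.arg(split)
  impurity <- function(p) {
    if (split == "gini") 2 * p * (1 - p) else {
      if (p <= 0 || p >= 1) 0 else -p * log2(p) - (1 - p) * log2(1 - p)
    }
  }
  grow <- function(idx, d) {
    p <- mean(y[idx])
    node <- list(pred = p > 0.5)
    if (d == 0 || length(idx) < min_split || p == 0 || p == 1) return(node)
    cols <- seq_len(ncol(x))
    if (!is.null(mtry)) cols <- sample(cols, min(mtry, length(cols)))
    best <- list(gain = 1e-9)
    base <- impurity(p)
    for (j in cols) {
      v <- x[idx, j]
      for (cut in stats::quantile(v, c(.25, .5, .75), names = FALSE)) {
        l <- idx[v <= cut]; r <- idx[v > cut]
        if (length(l) == 0 || length(r) == 0) next
        g <- base - (length(l) * impurity(mean(y[l])) +
                       length(r) * impurity(mean(y[r]))) / length(idx)
        if (g > best$gain) best <- list(gain = g, j = j, cut = cut,
                                        l = l, r = r)
      }
    }
    if (is.null(best$j)) return(node)
    node$j <- best$j; node$cut <- best$cut
    node$left <- grow(best$l, d - 1L)
    node$right <- grow(best$r, d - 1L)
    node
  }
  grow(seq_len(nrow(x)), depth)
}

tree_predict <- function(node, xte) {
  vapply(seq_len(nrow(xte)), function(i) {
    nd <- node
    while (!is.null(nd$j)) {
      nd <- if (xte[i, nd$j] <= nd$cut) nd$left else nd$right
    }
    nd$pred
  }, TRUE)
}

glmnet_train_predict <- function(xtr, ytr, xte) {
  fit <- glmnet::glmnet(xtr, factor(ytr), family = "binomial", alpha = 0,
                        lambda = 0.05, standardize = TRUE)
  as.logical(stats::predict(fit, xte, type = "class"))
}

bagged_trees_predict <- function(xtr, ytr, xte, n_trees = 15L) {
  mtry <- max(1L, floor(sqrt(ncol(xtr))))
  votes <- vapply(seq_len(n_trees), function(b) {
    idx <- sample(nrow(xtr), replace = TRUE)
    tr <- tree_fit(xtr[idx, , drop = FALSE], ytr[idx], split = "gini",
                   mtry = mtry)
    tree_predict(tr, xte)
  }, logical(nrow(xte)))
  if (nrow(xte) == 1) votes <- matrix(votes, nrow = 1)
  rowMeans(votes) > 0.5
}

classifier_suite <- function() {
  list(
    naive_bayes = nb_train_predict,
    knn = knn_train_predict,
    tree_gini = function(xtr, ytr, xte) {
      tree_predict(tree_fit(xtr, ytr, split = "gini"), xte)
    },
    tree_info = function(xtr, ytr, xte) {
      tree_predict(tree_fit(xtr, ytr, split = "info"), xte)
    },
    logistic_ridge = glmnet_train_predict,
    bagged_trees = bagged_trees_predict)
}

#' Classification-accuracy similarity of two feature sets
#'
#' Labels the union by set membership, runs stratified 5-fold
#' cross-validation with the six-classifier suite and returns per-classifier
#' accuracies and their mean (the similarity readout: high accuracy means
#' the sets are easily separable, hence dissimilar).
#'
#' @param features_set1,features_set2 numeric data.frames or matrices with
#'   identical columns, one row per miRNA; both need >= 10 rows (and >= 5
#'   to stratify the folds)
#' @param seed seed for fold assignment and the randomized learners
#' @param folds number of CV folds (default 5)
#' @return list of class `similarity_result`: accuracy_per_classifier,
#'   mean_accuracy, folds
#' @export
cv_similarity <- function(features_set1, features_set2, seed = 1L,
                          folds = 5L) {
  x1 <- as.matrix(features_set1)
  x2 <- as.matrix(features_set2)
  if (nrow(x1) < folds || nrow(x2) < folds) {
    stop("each set needs at least ", folds, " members to stratify ",
         folds, "-fold CV")
  }
  x <- rbind(x1, x2)
  x[is.na(x)] <- 0
  keep <- apply(x, 2, function(v) stats::sd(v) > 0)
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stop("no informative feature columns")
  x <- scale(x)
  y <- c(rep(TRUE, nrow(x1)), rep(FALSE, nrow(x2)))
  suite <- classifier_suite()
  withr::with_seed(seed, {
    fold_of <- integer(length(y))
    fold_of[y] <- sample(rep_len(seq_len(folds), sum(y)))
    fold_of[!y] <- sample(rep_len(seq_len(folds), sum(!y)))
    acc <- vapply(suite, function(clf) {
      correct <- 0L
      for (f in seq_len(folds)) {
        te <- fold_of == f
        pred <- clf(x[!te, , drop = FALSE], y[!te], x[te, , drop = FALSE])
        correct <- correct + sum(pred == y[te])
      }
      correct / length(y)
    }, 0)
  })
  structure(list(accuracy_per_classifier = acc,
                 mean_accuracy = mean(acc), folds = folds),
            class = "similarity_result")
}
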