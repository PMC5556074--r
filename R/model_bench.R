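# The methodology engine: capability-tag clustering of candidate
# algorithms (Jaccard distance, complete linkage), repeated stratified
# cross-validated benchmarking over the preprocessing variants,
# per-cluster champion selection, and MANOVA comparison of clusters.

#' Shipped algorithm capability-tag matrix
#'
#' Binary capability tags for the 51 candidate classification
#' algorithms, over the published tag vocabulary (Accepts Case Weights
#' ... Two Class Only). Shipped as editable CSV package data.
#'
#' @param path Optional path to an alternative tag CSV.
#' @return Integer matrix, rows = algorithms, columns = tags.
#' @export
algorithm_tags <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "algorithm_tags.csv", package = "hotspotr")
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Jaccard distance between binary tag vectors
#'
#' d(a, b) = 1 - |intersection| / |union| over the positive tags. Two
#' all-zero rows are assigned distance 0 (identical emptiness) with a
#' warning.
#'
#' @param tags Binary matrix, rows = items.
#' @return A symmetric `dist`-compatible matrix with zero diagonal.
#' @export
jaccard_distance <- function(tags) {
  tags <- as.matrix(tags)
  if (!all(tags %in% c(0, 1))) {
    hs_error("hs_validation_error", "tag matrix must be binary")
  }
  inter <- tcrossprod(tags)
  tot <- rowSums(tags)
  uni <- outer(tot, tot, "+") - inter
  if (any(uni[upper.tri(uni)] == 0)) {
    hs_warn("hs_empty_tags", "all-zero tag pair: distance defined as 0")
  }
  d <- ifelse(uni == 0, 0, 1 - inter / uni)
  diag(d) <- 0
  dimnames(d) <- list(rownames(tags), rownames(tags))
  d
}

#' Cluster algorithms by capability tags
#'
#' Agglomerative hierarchical clustering with complete linkage on a
#' distance matrix, cut at `k` clusters. Rows are ordered
#' lexicographically by name before clustering so merge-order ties
#' resolve deterministically; clusters are numbered by first appearance
#' in that order.
#'
#' @param dist_matrix Square symmetric distance matrix with row names.
#' @param k Number of clusters.
#' @return Named integer vector: algorithm -> cluster (1..k).
#' @export
cluster_algorithms <- function(dist_matrix, k = 5) {
  n <- nrow(dist_matrix)
  if (k > n) hs_error("hs_validation_error", "k exceeds number of algorithms")
  ord <- order(rownames(dist_matrix))
  dm <- dist_matrix[ord, ord]
  hc <- stats::hclust(stats::as.dist(dm), method = "complete")
  cl <- stats::cutree(hc, k = k)
  relabel <- match(cl, unique(cl))
  setNames(relabel, names(cl))[rownames(dist_matrix)]
}

# ---- model registry -------------------------------------------------------

# Ridge-shrunk Gaussian discriminant with pooled covariance
# (S + lambda * I): the package's penalized discriminant analysis.
fit_pda <- function(x, y, lambda = 1) {
  cls <- levels(y)
  mu <- lapply(cls, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  n <- nrow(x)
  s <- matrix(0, ncol(x), ncol(x))
  for (i in seq_along(cls)) {
    xc <- sweep(x[y == cls[i], , drop = FALSE], 2, mu[[i]], "-")
    s <- s + crossprod(xc)
  }
  s <- s / (n - length(cls)) + lambda * diag(ncol(x))
  structure(list(classes = cls, mu = mu, sinv = solve(s),
                 prior = as.numeric(table(y)[cls]) / n),
            class = "hs_pda")
}

predict_pda <- function(object, x) {
  scores <- vapply(seq_along(object$classes), function(i) {
    d <- sweep(x, 2, object$mu[[i]], "-")
    -0.5 * rowSums((d %*% object$sinv) * d) + log(object$prior[i])
  }, numeric(nrow(x)))
  p <- exp(scores - apply(scores, 1, max))
  p <- p / rowSums(p)
  p[, match("HS", object$classes)]
}

#' Classifier registry
#'
#' A representative set of classifiers spanning all five capability
#' clusters, each exposed through a uniform fit / predict-probability
#' interface (positive class HS). Entries: rf, ranger (random forests);
#' ada (gradient-boosted shallow trees); glm, plr (plain and
#' L2-penalized logistic regression), multinom; svmPoly, svmRadial
#' (kernel SVMs with Platt probability models); knn, lda, qda, nb, pda
#' (distance- and discriminant-family models, pda being the in-package
#' ridge-shrunk Gaussian discriminant).
#'
#' @param names Optional subset of registry entries to return.
#' @return Named list of model specs (`fit(x, y)`, `predict_prob(fit,
#'   x)`).
#' @export
model_registry <- function(names = NULL) {
  reg <- list(
    rf = list(
      fit = function(x, y) randomForest::randomForest(x, y, ntree = 300),
      predict_prob = function(m, x) stats::predict(m, x, type = "prob")[, "HS"]),
    ranger = list(
      fit = function(x, y) {
        d <- data.frame(x, .class = y, check.names = FALSE)
        ranger::ranger(dependent.variable.name = ".class", data = d,
                       probability = TRUE, num.trees = 300, num.threads = 1,
                       seed = sample.int(1e6, 1))
      },
      predict_prob = function(m, x) {
        stats::predict(m, data.frame(x, check.names = FALSE),
                       num.threads = 1)$predictions[, "HS"]
      }),
    ada = list(
      fit = function(x, y) {
        xgboost::xgboost(data = as.matrix(x),
                         label = as.numeric(y == "HS"),
                         nrounds = 50, max_depth = 2, eta = 0.3,
                         objective = "binary:logistic", verbose = 0,
                         nthread = 1)
      },
      predict_prob = function(m, x) stats::predict(m, as.matrix(x))),
    glm = list(
      fit = function(x, y) {
        d <- data.frame(x, check.names = FALSE)
        d$.y <- as.numeric(y == "HS")
        stats::glm(.y ~ ., data = d, family = stats::binomial())
      },
      predict_prob = function(m, x) {
        stats::predict(m, data.frame(x, check.names = FALSE), type = "response")
      }),
    plr = list(
      fit = function(x, y) {
        glmnet::glmnet(as.matrix(x), factor(y, c("NS", "HS")),
                       family = "binomial", alpha = 0, lambda = 0.05)
      },
      predict_prob = function(m, x) {
        as.numeric(stats::predict(m, as.matrix(x), type = "response"))
      }),
    multinom = list(
      fit = function(x, y) {
        d <- data.frame(x, .class = factor(y, c("NS", "HS")), check.names = FALSE)
        nnet::multinom(.class ~ ., data = d, trace = FALSE, MaxNWts = 20000)
      },
      predict_prob = function(m, x) {
        as.numeric(stats::predict(m, data.frame(x, check.names = FALSE),
                                  type = "probs"))
      }),
    svmPoly = list(
      fit = function(x, y) {
        kernlab::ksvm(as.matrix(x), factor(y, c("HS", "NS")),
                      kernel = "polydot",
                      kpar = list(degree = 2, scale = 0.1, offset = 1),
                      C = 1, prob.model = TRUE)
      },
      predict_prob = function(m, x) {
        kernlab::predict(m, as.matrix(x), type = "probabilities")[, "HS"]
      }),
    svmRadial = list(
      fit = function(x, y) {
        kernlab::ksvm(as.matrix(x), factor(y, c("HS", "NS")),
                      kernel = "rbfdot", C = 1, prob.model = TRUE)
      },
      predict_prob = function(m, x) {
        kernlab::predict(m, as.matrix(x), type = "probabilities")[, "HS"]
      }),
    knn = list(
      fit = function(x, y) list(x = as.matrix(x), y = y, k = 7),
      predict_prob = function(m, x) {
        pr <- class::knn(m$x, as.matrix(x), m$y, k = m$k, prob = TRUE)
        p <- attr(pr, "prob")
        ifelse(pr == "HS", p, 1 - p)
      }),
    lda = list(
      fit = function(x, y) MASS::lda(x, grouping = y),
      predict_prob = function(m, x) stats::predict(m, x)$posterior[, "HS"]),
    qda = list(
      fit = function(x, y) MASS::qda(x, grouping = y),
      predict_prob = function(m, x) stats::predict(m, x)$posterior[, "HS"]),
    nb = list(
      fit = function(x, y) e1071::naiveBayes(x, y),
      predict_prob = function(m, x) {
        stats::predict(m, x, type = "raw")[, "HS"]
      }),
    pda = list(
      fit = function(x, y) fit_pda(as.matrix(x), y),
      predict_prob = function(m, x) predict_pda(m, as.matrix(x)))
  )
  if (!is.null(names)) {
    missing <- setdiff(names, names(reg))
    if (length(missing) > 0) {
      hs_error("hs_validation_error",
               paste("unknown registry entries:", paste(missing, collapse = ", ")))
    }
    reg <- reg[names]
  }
  reg
}

#' Coin-flip null learner
#'
#' A base learner that ignores the features and emits uniform random
#' scores, deterministic per fitted instance. Useful for null
#' calibration: a stacked meta-model should assign it no weight, and
#' stepwise selection should remove it.
#'
#' @return A model spec usable alongside [model_registry()] entries.
#' @export
null_learner <- function() {
  list(
    fit = function(x, y) list(key = sample.int(1e9, 1)),
    predict_prob = function(m, x) {
      old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
      set.seed(m$key)
      stats::runif(nrow(x))
    })
}

# Stratified fold assignment: per class, shuffled indices dealt round-robin.
stratified_folds <- function(class_labels, folds) {
  assignment <- integer(length(class_labels))
  for (cl in unique(class_labels)) {
    idx <- sample(which(class_labels == cl))
    assignment[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assignment
}

feature_matrix <- function(table) {
  as.matrix(table[, feature_columns(table), drop = FALSE])
}

apply_resample <- function(table, resample, seed) {
  switch(resample,
         none = table,
         up = upsample_minor(table, seed),
         down = downsample_major(table, seed))
}

#' Cross-validated benchmark of classifiers over dataset variants
#'
#' For every model x variant, runs `repeats` rounds of stratified
#' `folds`-fold cross-validation on the variant's training data and
#' averages the per-fold metrics. Up/down-sampling is applied inside
#' each training fold only (never before fold assignment, which would
#' leak duplicated minority rows across folds). Models that fail to fit
#' on every fold are reported as non-converged. Deterministic under
#' `seed`.
#'
#' @param variants Output of [build_variants()] (or a subset).
#' @param models Model registry (default [model_registry()]).
#' @param folds,repeats Cross-validation geometry.
#' @param seed Master seed.
#' @return Data.frame: `algorithm`, `variant`, `converged`, and mean
#'   AUROC, Accuracy, TPR, TNR, PPV, NPV, FDR, FNR, F1, MCC.
#' @export
benchmark_models <- function(variants, models = model_registry(),
                             folds = 10, repeats = 10, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  out <- list()
  for (vn in names(variants)) {
    v <- variants[[vn]]
    tab <- v$cv_train
    y_all <- tab$class
    fold_sets <- lapply(seq_len(repeats), function(r) {
      set.seed((seed * 1009 + r * 101) %% 2147483647)
      stratified_folds(y_all, folds)
    })
    for (mn in names(models)) {
      spec <- models[[mn]]
      reports <- list()
      for (r in seq_len(repeats)) {
        fa <- fold_sets[[r]]
        for (f in seq_len(folds)) {
          tr <- tab[fa != f, , drop = FALSE]
          te <- tab[fa == f, , drop = FALSE]
          if (length(unique(te$class)) == 0 || nrow(te) == 0) next
          fit_seed <- (seed * 7919 + r * 613 + f * 31 +
                         match(mn, names(models))) %% 2147483647
          set.seed(fit_seed)
          tr <- apply_resample(tr, v$resample, fit_seed)
          rep_i <- tryCatch({
            set.seed(fit_seed)
            m <- spec$fit(feature_matrix(tr), factor(tr$class, c("HS", "NS")))
            p <- spec$predict_prob(m, feature_matrix(te))
            metrics_report(ifelse(p >= 0.5, "HS", "NS"), te$class, p)
          }, error = function(e) NULL)
          reports[[length(reports) + 1]] <- rep_i
        }
      }
      ok <- !vapply(reports, is.null, logical(1))
      if (!any(ok)) {
        row <- as.list(setNames(rep(NA_real_, 10),
                                c("AUROC", "Accuracy", "TPR", "TNR", "PPV",
                                  "NPV", "FDR", "FNR", "F1", "MCC")))
        converged <- FALSE
      } else {
        mat <- do.call(rbind, reports[ok])
        row <- as.list(colMeans(mat, na.rm = TRUE))
        converged <- TRUE
      }
      out[[length(out) + 1]] <- cbind(
        data.frame(algorithm = mn, variant = vn, converged = converged,
                   stringsAsFactors = FALSE),
        as.data.frame(row))
    }
  }
  do.call(rbind, out)
}

#' Per-cluster champion selection
#'
#' Within each capability cluster, picks the converged algorithm
#' maximizing the selection score (by default the sum of AUROC, TPR and
#' TNR) on one variant's benchmark results. Ties break lexicographically
#' by algorithm name; clusters with no converged member are skipped with
#' a warning.
#'
#' @param results Benchmark results from [benchmark_models()].
#' @param clusters Named cluster assignment from [cluster_algorithms()].
#' @param variant Variant name to rank on.
#' @param score_metrics Metric columns summed into the selection score.
#' @return Named character vector: cluster id -> champion algorithm.
#' @export
select_champions <- function(results, clusters, variant = "ScaledUp",
                             score_metrics = c("AUROC", "TPR", "TNR")) {
  res <- results[results$variant == variant & results$converged, , drop = FALSE]
  if (nrow(res) == 0) {
    hs_error("hs_validation_error", paste("no converged results for variant", variant))
  }
  res$score <- rowSums(res[, score_metrics, drop = FALSE])
  champions <- character(0)
  for (cl in sort(unique(clusters[res$algorithm]))) {
    members <- res[clusters[res$algorithm] == cl, , drop = FALSE]
    if (nrow(members) == 0) {
      hs_warn("hs_empty_cluster", paste("cluster", cl, "has no converged member"))
      next
    }
    members <- members[order(-members$score, members$algorithm), , drop = FALSE]
    champions[as.character(cl)] <- members$algorithm[1]
  }
  champions
}

#' One-way MANOVA with the Pillai trace
#'
#' Computes the between-group (H) and within-group (E) scatter matrices
#' of a multivariate response, the eigenvalues of H E^-1, the Pillai
#' trace V = sum(lambda / (1 + lambda)), and its standard F
#' approximation.
#'
#' @param x Numeric matrix, rows = observations, columns = responses
#'   (>= 2).
#' @param groups Group labels (>= 2 groups, each with >= 2 members).
#' @return List: `statistic` (V), `f`, `df1`, `df2`, `p_value`,
#'   `eigenvalues`.
#' @export
manova_pillai <- function(x, groups) {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) < 2) || ncol(x) < 1) {
    hs_error("hs_validation_error",
             "need >= 2 groups with >= 2 members and >= 1 response metric")
  }
  p <- ncol(x); g <- nlevels(groups); n <- nrow(x)
  grand <- colMeans(x)
  h <- matrix(0, p, p); e <- matrix(0, p, p)
  for (lv in levels(groups)) {
    xg <- x[groups == lv, , drop = FALSE]
    mg <- colMeans(xg)
    h <- h + nrow(xg) * tcrossprod(mg - grand)
    e <- e + crossprod(sweep(xg, 2, mg, "-"))
  }
  a <- tryCatch(h %*% solve(e), error = function(err) {
    hs_error("hs_singular_error",
             "within-group scatter is singular; reduce the response metrics")
  })
  lambda <- Re(eigen(a, only.values = TRUE)$values)
  lambda[lambda < 0] <- 0
  v <- sum(lambda / (1 + lambda))
  s <- min(p, g - 1)
  m <- (abs(p - g + 1) - 1) / 2
  nn <- (n - g - p - 1) / 2
  f <- ((2 * nn + s + 1) / (2 * m + s + 1)) * (v / s) / (1 - v / s)
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  list(statistic = v, f = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       eigenvalues = lambda)
}
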