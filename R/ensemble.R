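# The final classifier: champion base learners stacked by a logistic
# meta-model. The meta-model is always trained on out-of-fold base
# classifications (cross-fitting), never on in-fold predictions, so it
# cannot learn the bases' overfit; every meta input row carries a fold
# provenance tag that tests can assert on.

#' Fit champion base learners with out-of-fold predictions
#'
#' Fits each champion on resampled training data and collects, for the
#' meta-model, its out-of-fold classification of every training
#' observation: the data is split into stratified folds, each base is
#' refitted without the held-out fold (resampling applied inside the
#' retained folds only) and predicts the held-out rows. Champions that
#' fail to fit are excluded with a warning.
#'
#' @param train Preprocessed (scaled, unresampled) feature table.
#' @param champions Registry names of the base learners.
#' @param registry Model registry.
#' @param folds Number of cross-fitting folds.
#' @param resample Resampling regime inside folds ("up", "down",
#'   "none").
#' @param seed Integer seed.
#' @param use_probabilities Stack base probabilities instead of binary
#'   classifications.
#' @return List: `fits` (base models refitted on the full resampled
#'   train), `oof` (n x champions matrix of out-of-fold outputs),
#'   `fold_id` (provenance tag per row), `champions`.
#' @export
fit_base <- function(train, champions = c("rf", "svmPoly", "pda"),
                     registry = model_registry(), folds = 5,
                     resample = "up", seed = 1, use_probabilities = FALSE) {
  if (length(unique(train$class)) < 2) {
    hs_error("hs_validation_error", "training data must contain both classes")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold_id <- stratified_folds(train$class, folds)
  oof <- matrix(NA_real_, nrow(train), length(champions),
                dimnames = list(NULL, champions))
  failed <- character(0)
  for (j in seq_along(champions)) {
    spec <- registry[[champions[j]]]
    if (is.null(spec)) {
      hs_error("hs_validation_error", paste("unknown champion:", champions[j]))
    }
    ok <- TRUE
    for (f in seq_len(folds)) {
      fit_seed <- (seed * 7919 + f * 31 + j) %% 2147483647
      tr <- train[fold_id != f, , drop = FALSE]
      set.seed(fit_seed)
      tr <- apply_resample(tr, resample, fit_seed)
      p <- tryCatch({
        set.seed(fit_seed)
        m <- spec$fit(feature_matrix(tr), factor(tr$class, c("HS", "NS")))
        spec$predict_prob(m, feature_matrix(train[fold_id == f, , drop = FALSE]))
      }, error = function(e) NULL)
      if (is.null(p)) { ok <- FALSE; break }
      oof[fold_id == f, j] <- p
    }
    if (!ok) failed <- c(failed, champions[j])
  }
  if (length(failed) > 0) {
    hs_warn("hs_base_failed",
            paste("base learner(s) failed to converge and were excluded:",
                  paste(failed, collapse = ", ")))
    champions <- setdiff(champions, failed)
    oof <- oof[, champions, drop = FALSE]
  }
  if (length(champions) == 0) {
    hs_error("hs_validation_error", "no base learner converged")
  }
  if (!use_probabilities) oof <- (oof >= 0.5) * 1

  # Final base fits on the full resampled training table.
  fits <- list()
  for (j in seq_along(champions)) {
    fit_seed <- (seed * 104729 + j) %% 2147483647
    set.seed(fit_seed)
    tr <- apply_resample(train, resample, fit_seed)
    set.seed(fit_seed)
    fits[[champions[j]]] <- registry[[champions[j]]]$fit(
      feature_matrix(tr), factor(tr$class, c("HS", "NS")))
  }
  list(fits = fits, oof = oof, fold_id = fold_id, champions = champions)
}

#' Fit the logistic meta-model on base outputs
#'
#' Maximum-likelihood logistic regression of the HS label on the base
#' learners' out-of-fold outputs: logit(pi) = b0 + sum(b_j X_j). Under
#' perfect separation the fit falls back to a ridge-penalized logistic
#' model and is flagged (`penalized = TRUE`).
#'
#' @param base_outputs n x k matrix of base outputs (binary or
#'   probability).
#' @param labels HS/NS labels of length n.
#' @return A `meta_model` list: `coefficients` (intercept first),
#'   `penalized`, `data` (for stepwise refits), `variables`.
#' @export
fit_meta <- function(base_outputs, labels) {
  y <- as.numeric(check_labels(labels) == "HS")
  df <- as.data.frame(base_outputs)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = cbind(df, y = y), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  co <- stats::coef(fit)
  if ((sep || !fit$converged) && ncol(df) >= 2) {
    gf <- glmnet::glmnet(as.matrix(base_outputs), y, family = "binomial",
                         alpha = 0, lambda = 0.01)
    co <- c(as.numeric(gf$a0), as.numeric(gf$beta))
    names(co) <- c("(Intercept)", colnames(base_outputs))
    structure(list(coefficients = co, penalized = TRUE, glm = NULL,
                   data = cbind(df, y = y), variables = colnames(base_outputs)),
              class = "meta_model")
  } else {
    co[is.na(co)] <- 0
    structure(list(coefficients = co, penalized = FALSE, glm = fit,
                   data = cbind(df, y = y), variables = colnames(base_outputs)),
              class = "meta_model")
  }
}

# Wald p-values of the non-intercept terms of a glm; aliased terms get 1.
wald_p <- function(fit, vars) {
  sm <- summary(fit)$coefficients
  p <- setNames(rep(1, length(vars)), vars)
  rows <- intersect(rownames(sm), paste0("`", vars, "`"))
  clean <- gsub("`", "", rownames(sm))
  for (v in vars) {
    i <- match(v, clean)
    if (!is.na(i)) p[v] <- sm[i, 4]
  }
  p
}

#' Bidirectional stepwise selection of base learners
#'
#' Starting from the full meta-model, repeatedly removes the variable
#' with the largest Wald p-value above `alpha`, then reconsiders removed
#' variables whose p-value would fall below `alpha` when re-added.
#' Variable order ties resolve lexicographically. If every variable is
#' removed, the intercept-only model is kept and flagged. Penalized
#' (separation-fallback) meta-models are returned unchanged: their
#' coefficients carry no Wald statistics.
#'
#' @param meta A `meta_model` from [fit_meta()].
#' @param alpha Retention threshold on the Wald p-value.
#' @return A reduced `meta_model` with elements `selected` and
#'   `intercept_only`.
#' @export
stepwise_select <- function(meta, alpha = 0.05) {
  if (meta$penalized) {
    meta$selected <- meta$variables
    meta$intercept_only <- FALSE
    return(meta)
  }
  df <- meta$data
  all_vars <- sort(meta$variables)
  current <- all_vars
  refit <- function(vars) {
    fml <- if (length(vars) == 0) "y ~ 1" else {
      paste("y ~", paste(sprintf("`%s`", vars), collapse = " + "))
    }
    suppressWarnings(stats::glm(stats::as.formula(fml), data = df,
                                family = stats::binomial()))
  }
  repeat {
    changed <- FALSE
    if (length(current) > 0) {
      fit <- refit(current)
      p <- wald_p(fit, current)
      worst <- max(p)
      if (worst > alpha) {
        drop <- sort(names(p)[p == worst])[1]
        current <- setdiff(current, drop)
        changed <- TRUE
      }
    }
    for (v in setdiff(all_vars, current)) {
      fit_v <- refit(c(current, v))
      if (wald_p(fit_v, v)[[v]] < alpha) {
        current <- sort(c(current, v))
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  fit <- refit(current)
  co <- stats::coef(fit)
  names(co) <- gsub("`", "", names(co))
  co[is.na(co)] <- 0
  meta$coefficients <- co
  meta$glm <- fit
  meta$selected <- current
  meta$intercept_only <- length(current) == 0
  if (meta$intercept_only) {
    hs_warn("hs_intercept_only", "stepwise removed every base learner")
  }
  meta
}

#' Train the full stacked ensemble
#'
#' End-to-end training on a raw (unscaled) labelled feature table:
#' z-score scaling fitted on the data, champion bases with out-of-fold
#' cross-fitting (up-sampling of the minority class inside folds, the
#' ScaledUp-style regime), logistic meta-model on the out-of-fold binary
#' classifications, and bidirectional stepwise reduction.
#'
#' @param train Raw labelled feature table.
#' @param champions Base learner registry names.
#' @param registry Model registry.
#' @param folds Cross-fitting folds for the meta inputs.
#' @param resample Resampling regime ("up", "down", "none").
#' @param threshold Decision threshold on the meta probability.
#' @param alpha Stepwise retention threshold.
#' @param seed Integer seed (end-to-end deterministic).
#' @param use_probabilities Stack probabilities instead of binary votes.
#' @return An `ensemble_model`.
#' @export
fit_ensemble <- function(train, champions = c("rf", "svmPoly", "pda"),
                         registry = model_registry(), folds = 5,
                         resample = "up", threshold = 0.5, alpha = 0.05,
                         seed = 1, use_probabilities = FALSE) {
  state <- fit_scaler(train)
  train_sc <- apply_scaler(state, train)
  base <- fit_base(train_sc, champions, registry, folds, resample, seed,
                   use_probabilities)
  meta <- fit_meta(base$oof, train_sc$class)
  meta <- stepwise_select(meta, alpha)
  structure(list(
    state = state, base_fits = base$fits, champions = base$champions,
    registry = registry[base$champions],
    meta = meta, threshold = threshold,
    use_probabilities = use_probabilities,
    metadata = list(seed = seed, folds = folds, resample = resample,
                    alpha = alpha, n_train = nrow(train),
                    trained = format(Sys.time(), tz = "UTC"))),
    class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model: bases {%s}, selected {%s}, threshold %.2f>\n",
              paste(x$champions, collapse = ", "),
              paste(x$meta$selected, collapse = ", "), x$threshold))
  invisible(x)
}

# Meta probability from base outputs using the selected coefficients.
meta_probability <- function(model, base_out) {
  co <- model$meta$coefficients
  eta <- rep(co[["(Intercept)"]], nrow(base_out))
  for (v in setdiff(names(co), "(Intercept)")) {
    eta <- eta + co[[v]] * base_out[, v]
  }
  stats::plogis(eta)
}

#' Classify residues with a fitted ensemble
#'
#' Applies the model's stored preprocessing state to a raw feature
#' table, obtains each base learner's classification, and combines them
#' through the logistic meta-model. A residue is called HS when its
#' meta probability reaches the decision threshold (boundary
#' inclusive).
#'
#' @param model An `ensemble_model`.
#' @param features Raw feature table (schema must match training).
#' @return Data.frame: identity columns present in `features`, plus
#'   `probability` and `classification` (HS/NS).
#' @export
predict_residues <- function(model, features) {
  missing <- setdiff(model$state$features, names(features))
  extra <- setdiff(feature_columns(features),
                   c(model$state$features, model$state$dropped))
  if (length(missing) > 0 || length(extra) > 0) {
    hs_error("hs_schema_error",
             sprintf("feature schema mismatch; missing: [%s]; extra: [%s]",
                     paste(missing, collapse = ", "),
                     paste(extra, collapse = ", ")))
  }
  x <- feature_matrix(apply_scaler(model$state, features))
  base_out <- vapply(model$champions, function(ch) {
    p <- model$registry[[ch]]$predict_prob(model$base_fits[[ch]], x)
    if (model$use_probabilities) p else (p >= 0.5) * 1
  }, numeric(nrow(x)))
  base_out <- matrix(base_out, nrow = nrow(x),
                     dimnames = list(NULL, model$champions))
  prob <- meta_probability(model, base_out)
  out <- features[, intersect(ID_COLUMNS, names(features)), drop = FALSE]
  out$probability <- prob
  out$classification <- ifelse(prob >= model$threshold, "HS", "NS")
  out
}

#' Save / load a fitted ensemble
#'
#' The archive is a single RDS bundle embedding the preprocessing state
#' and a schema version; loading a bundle of a different version fails
#' explicitly.
#'
#' @param model An `ensemble_model`.
#' @param path Archive path.
#' @return `path` invisibly ([save_model()]); the restored
#'   `ensemble_model` ([load_model()]).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "hotspotr_ensemble", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e) {
    hs_error("hs_archive_error", paste("cannot read model archive:",
                                       conditionMessage(e)))
  })
  if (!is.list(bundle) || !identical(bundle$format, "hotspotr_ensemble")) {
    hs_error("hs_archive_error", "not a hotspotr ensemble archive")
  }
  if (!identical(bundle$version, 1L)) {
    hs_error("hs_version_error",
             sprintf("archive version %s not supported", bundle$version))
  }
  bundle$model
}
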