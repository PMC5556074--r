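# Labelling, splitting, scaling, PCA and class resampling: the six
# training-set variants used throughout benchmarking and ensemble
# training. Scaling and PCA states are always fitted on training data
# and re-applied to test data.

#' Hot-spot label from experimental ddG
#'
#' A residue is a Hot-Spot when its alanine-scanning binding free energy
#' change is at least 2.0 kcal/mol (boundary inclusive), a Null-Spot
#' otherwise.
#'
#' @param ddg Numeric ddG values, kcal/mol.
#' @param threshold Label threshold, kcal/mol.
#' @return Character vector over \{"HS","NS"\} (NA ddG gives NA).
#' @export
label_from_ddg <- function(ddg, threshold = 2.0) {
  ifelse(is.na(ddg), NA_character_, ifelse(ddg >= threshold, "HS", "NS"))
}

#' Load a labelled feature table from CSV
#'
#' Reads an observations x features CSV. When a `ddg` column is present
#' and `class` is absent, labels are derived with [label_from_ddg()];
#' observations with missing ddG or any missing feature are dropped with
#' a warning (count logged).
#'
#' @param path CSV path.
#' @return A feature table data.frame with a `class` column.
#' @export
load_feature_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"class" %in% names(tab)) {
    if (!"ddg" %in% names(tab)) {
      hs_error("hs_validation_error", "table has neither 'class' nor 'ddg' column")
    }
    tab$class <- label_from_ddg(tab$ddg)
  }
  keep <- stats::complete.cases(tab[, c(feature_columns(tab), "class")])
  if (any(!keep)) {
    hs_warn("hs_rows_dropped",
            sprintf("%d observation(s) with missing values dropped", sum(!keep)))
    tab <- tab[keep, , drop = FALSE]
  }
  tab$class <- check_labels(tab$class)
  tab
}

#' Stratified train/test split
#'
#' Splits per class with round-to-nearest training sizes, so 127 HS +
#' 407 NS at fraction 0.7 gives exactly 374 train / 160 test.
#' Deterministic under `seed`.
#'
#' @param table Feature table with a `class` column.
#' @param train_fraction Fraction assigned to training, per class.
#' @param seed Integer seed.
#' @return List with `train` and `test` data.frames (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(table, train_fraction = 0.7, seed = 1) {
  cls <- table$class
  sizes <- table(cls)
  if (length(sizes) < 2 || any(sizes < 2)) {
    hs_error("hs_validation_error", "both classes must have at least 2 members")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train_idx <- unlist(lapply(names(sizes), function(cl) {
    idx <- which(cls == cl)
    sample(idx, round(train_fraction * length(idx)))
  }), use.names = FALSE)
  list(train = table[sort(train_idx), , drop = FALSE],
       test = table[sort(setdiff(seq_len(nrow(table)), train_idx)), , drop = FALSE])
}

# Preserve the caller's RNG stream around seeded operations.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit a z-score scaler on training data
#'
#' Records per-feature mean and sample standard deviation (n - 1) of the
#' training table. Zero-variance features are dropped and recorded.
#'
#' @param train Training feature table.
#' @return A `preprocess_state` with `center`, `scale`, `dropped`.
#' @export
fit_scaler <- function(train) {
  fc <- feature_columns(train)
  if (length(fc) == 0 || nrow(train) == 0) {
    hs_error("hs_validation_error", "empty training table")
  }
  x <- as.matrix(train[, fc, drop = FALSE])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  dropped <- fc[scl < 1e-12 | is.na(scl)]
  if (length(dropped) == length(fc)) {
    hs_error("hs_validation_error", "all feature columns have zero variance")
  }
  keep <- setdiff(fc, dropped)
  structure(list(center = ctr[keep], scale = scl[keep], dropped = dropped,
                 features = keep, pca = NULL),
            class = "preprocess_state")
}

#' Apply a fitted scaler (and PCA basis, if present)
#'
#' Transforms a table with the training-derived statistics stored in
#' `state`; test data is never used to refit anything.
#'
#' @param state A `preprocess_state` from [fit_scaler()] /
#'   [fit_pca()].
#' @param table Feature table to transform.
#' @return Transformed table (identity columns preserved).
#' @export
apply_scaler <- function(state, table) {
  missing <- setdiff(state$features, names(table))
  if (length(missing) > 0) {
    hs_error("hs_schema_error",
             paste("features missing from table:", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(table[, state$features, drop = FALSE])
  x <- sweep(sweep(x, 2, state$center, "-"), 2, state$scale, "/")
  if (!is.null(state$pca)) {
    x <- x %*% state$pca$rotation[, seq_len(state$pca$d), drop = FALSE]
    colnames(x) <- paste0("PC", seq_len(ncol(x)))
  }
  cbind(table[, intersect(ID_COLUMNS, names(table)), drop = FALSE],
        as.data.frame(x, optional = TRUE))
}

#' Fit PCA on scaled training data
#'
#' Principal components of the (already z-scored) training features,
#' retaining the smallest number of components whose cumulative variance
#' ratio reaches `threshold`.
#'
#' @param state Scaler state from [fit_scaler()].
#' @param train_scaled Output of `apply_scaler(state, train)`.
#' @param threshold Cumulative variance ratio in (0, 1].
#' @return The state with a `pca` element (`rotation`, eigenvalues
#'   `lambda`, retained count `d`).
#' @export
fit_pca <- function(state, train_scaled, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) {
    hs_error("hs_validation_error", "threshold must be in (0, 1]")
  }
  x <- as.matrix(train_scaled[, state$features, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  lambda <- pc$sdev^2
  cum <- cumsum(lambda) / sum(lambda)
  d <- which(cum >= threshold)[1]
  state$pca <- list(rotation = pc$rotation, lambda = lambda, d = d,
                    threshold = threshold)
  state
}

#' Up-sample the minority class
#'
#' Draws the minority class with replacement until its size matches the
#' majority class. Every majority row is kept exactly once; the added
#' rows are drawn only from original minority rows.
#'
#' @param train Feature table.
#' @param seed Integer seed.
#' @return Balanced feature table.
#' @export
upsample_minor <- function(train, seed = 1) {
  sizes <- table(train$class)
  if (length(sizes) < 2) hs_error("hs_validation_error", "need two classes")
  minor <- names(sizes)[which.min(sizes)]
  need <- max(sizes) - min(sizes)
  if (need == 0) return(train)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  extra <- sample(which(train$class == minor), need, replace = TRUE)
  out <- rbind(train, train[extra, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Down-sample to the minority class size
#'
#' Subsamples every class without replacement to the size of the least
#' prevalent class.
#'
#' @inheritParams upsample_minor
#' @return Balanced feature table (rows are a subset of the input).
#' @export
downsample_major <- function(train, seed = 1) {
  sizes <- table(train$class)
  if (length(sizes) < 2) hs_error("hs_validation_error", "need two classes")
  n_min <- min(sizes)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  keep <- unlist(lapply(names(sizes), function(cl) {
    idx <- which(train$class == cl)
    if (length(idx) > n_min) sample(idx, n_min) else idx
  }), use.names = FALSE)
  train[sort(keep), , drop = FALSE]
}

#' Build the six preprocessing variants
#'
#' Scaled, ScaledUp, ScaledDown, PCA, PCAUp, PCADown: z-scoring, then
#' optionally PCA (95% cumulative variance), then optionally up- or
#' down-sampling of the training classes. Each variant carries the
#' resampled training table (`train`), the unresampled one (`cv_train`,
#' for cross-validation where resampling must happen inside folds), the
#' transformed test table, the fitted `state` and its `resample` tag.
#'
#' @param train,test Feature tables (raw, unscaled).
#' @param pca_threshold Cumulative variance ratio for the PCA variants.
#' @param seed Integer seed for the resampling draws.
#' @return Named list of six variants.
#' @export
build_variants <- function(train, test, pca_threshold = 0.95, seed = 1) {
  sc <- fit_scaler(train)
  train_sc <- apply_scaler(sc, train)
  test_sc <- apply_scaler(sc, test)
  pc <- fit_pca(sc, train_sc, pca_threshold)
  train_pc <- apply_scaler(pc, train)
  test_pc <- apply_scaler(pc, test)

  make <- function(tr, te, state, resample) {
    tr_rs <- switch(resample,
                    none = tr,
                    up = upsample_minor(tr, seed),
                    down = downsample_major(tr, seed))
    list(train = tr_rs, cv_train = tr, test = te, state = state,
         resample = resample)
  }
  list(
    Scaled = make(train_sc, test_sc, sc, "none"),
    ScaledUp = make(train_sc, test_sc, sc, "up"),
    ScaledDown = make(train_sc, test_sc, sc, "down"),
    PCA = make(train_pc, test_pc, pc, "none"),
    PCAUp = make(train_pc, test_pc, pc, "up"),
    PCADown = make(train_pc, test_pc, pc, "down")
  )
}

#' Serialize a preprocess state to JSON
#'
#' @param state A `preprocess_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_preprocess_state <- function(state, path) {
  doc <- list(version = 1L,
              center = as.list(state$center), scale = as.list(state$scale),
              dropped = state$dropped, features = state$features)
  if (!is.null(state$pca)) {
    doc$pca <- list(rotation = state$pca$rotation, lambda = state$pca$lambda,
                    d = state$pca$d, threshold = state$pca$threshold)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized preprocess state
#'
#' @param path JSON path written by [save_preprocess_state()].
#' @return A `preprocess_state`.
#' @export
read_preprocess_state <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$version) || doc$version != 1L) {
    hs_error("hs_version_error", "unsupported preprocess state version")
  }
  state <- structure(list(center = unlist(doc$center), scale = unlist(doc$scale),
                          dropped = doc$dropped, features = doc$features,
                          pca = NULL),
                     class = "preprocess_state")
  if (!is.null(doc$pca)) {
    rot <- as.matrix(doc$pca$rotation)
    rownames(rot) <- state$features
    state$pca <- list(rotation = rot, lambda = doc$pca$lambda,
                      d = doc$pca$d, threshold = doc$pca$threshold)
  }
  state
}
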