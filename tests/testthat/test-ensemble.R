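# Stacked ensemble: cross-fitted bases, logistic meta-model, stepwise
# reduction, prediction and archiving.

sep_table <- function(seed, n = 200, effect = 2.5) {
  make_synthetic_table(n_obs = n, n_features = 10, n_informative = 5,
                       effect_size = effect, seed = seed)
}

test_that("bases train accurately on separable data and cross-fit cleanly", {
  tab <- sep_table(41)
  st <- fit_scaler(tab)
  train <- apply_scaler(st, tab)
  base <- fit_base(train, champions = c("rf", "pda"), folds = 4, seed = 1)
  expect_setequal(colnames(base$oof), c("rf", "pda"))
  expect_false(anyNA(base$oof))
  expect_true(all(base$oof %in% c(0, 1)))
  # Fold provenance tag: every row belongs to exactly one of 4 folds.
  expect_equal(sort(unique(base$fold_id)), 1:4)
  expect_length(base$fold_id, nrow(train))
  # Training accuracy of the refitted bases on separable data.
  for (ch in c("rf", "pda")) {
    p <- model_registry(ch)[[ch]]$predict_prob(base$fits[[ch]],
                                               feature_matrix(train))
    acc <- mean(ifelse(p >= 0.5, "HS", "NS") == train$class)
    expect_gt(acc, 0.95)
  }
})

test_that("single-class training data and failing bases are rejected", {
  tab <- sep_table(42)
  tab$class <- "NS"
  expect_error(fit_base(tab), class = "hs_validation_error")

  tab2 <- sep_table(43)
  reg <- c(model_registry("pda"),
           list(broken = list(fit = function(x, y) stop("nope"),
                              predict_prob = function(m, x) NULL)))
  expect_warning(
    base <- fit_base(tab2, champions = c("pda", "broken"), registry = reg,
                     folds = 3, seed = 1),
    class = "hs_base_failed")
  expect_equal(base$champions, "pda")
})

test_that("ensemble training is deterministic under one master seed", {
  tab <- sep_table(44)
  sp <- stratified_split(tab, 0.7, seed = 2)
  m1 <- fit_ensemble(sp$train, champions = c("rf", "pda"), seed = 7)
  m2 <- fit_ensemble(sp$train, champions = c("rf", "pda"), seed = 7)
  p1 <- predict_residues(m1, sp$test)
  p2 <- predict_residues(m2, sp$test)
  expect_identical(p1$probability, p2$probability)
  expect_equal(m1$meta$coefficients, m2$meta$coefficients)
})

test_that("meta-model learns a truth-telling base and ignores noise bases", {
  set.seed(45)
  n <- 400
  y <- sample(c("HS", "NS"), n, replace = TRUE, prob = c(0.3, 0.7))
  truth_teller <- (y == "HS") * 1
  flawed <- truth_teller; flip <- sample(n, 80); flawed[flip] <- 1 - flawed[flip]
  noise <- rbinom(n, 1, 0.5)
  meta <- fit_meta(cbind(good = flawed, noise = noise), y)
  expect_false(meta$penalized)
  expect_gt(meta$coefficients[["good"]], 1)
  expect_lt(abs(meta$coefficients[["noise"]]), 1)
  # Logit identity: predicted pi back-transforms exactly.
  eta <- meta$coefficients[["(Intercept)"]] + meta$coefficients[["good"]] * flawed +
    meta$coefficients[["noise"]] * noise
  expect_equal(qlogis(plogis(eta)), eta, tolerance = 1e-9)

  # Pure-noise bases alone carry no signal: AUROC ~ 0.5.
  noise2 <- cbind(n1 = rbinom(n, 1, 0.5), n2 = rbinom(n, 1, 0.5))
  meta_null <- fit_meta(noise2, y)
  p_null <- plogis(meta_null$coefficients[["(Intercept)"]] +
                     noise2 %*% meta_null$coefficients[c("n1", "n2")])
  expect_lt(abs(auroc(as.numeric(p_null), y) - 0.5), 0.1)
})

test_that("stepwise keeps significant bases, drops noise, flags empty models", {
  set.seed(46)
  n <- 300
  y <- sample(c("HS", "NS"), n, replace = TRUE)
  good <- (y == "HS") * 1; flip <- sample(n, 45); good[flip] <- 1 - good[flip]
  noise <- rbinom(n, 1, 0.5)
  meta <- fit_meta(cbind(good = good, noise = noise), y)
  red <- stepwise_select(meta, alpha = 0.05)
  expect_equal(red$selected, "good")
  expect_false(red$intercept_only)

  only_noise <- fit_meta(cbind(n1 = rbinom(n, 1, 0.5)), y)
  expect_warning(red2 <- stepwise_select(only_noise, alpha = 0.05),
                 class = "hs_intercept_only")
  expect_true(red2$intercept_only)
})

test_that("full and reduced models give near-identical predictions", {
  tab <- sep_table(47, n = 300, effect = 1.2)
  sp <- stratified_split(tab, 0.7, seed = 3)
  reg <- c(model_registry(c("rf", "svmPoly", "pda")),
           list(noise1 = null_learner(), noise2 = null_learner()))
  full <- fit_ensemble(sp$train, champions = names(reg), registry = reg,
                       seed = 4, alpha = 1)       # alpha 1: keep everything
  reduced <- fit_ensemble(sp$train, champions = names(reg), registry = reg,
                          seed = 4, alpha = 0.05)
  pf <- predict_residues(full, sp$test)
  pr <- predict_residues(reduced, sp$test)
  expect_gt(mean(pf$classification == pr$classification), 0.9)
})

test_that("prediction applies threshold boundary-inclusively", {
  tab <- sep_table(48)
  sp <- stratified_split(tab, 0.7, seed = 5)
  m <- fit_ensemble(sp$train, champions = c("rf", "pda"), seed = 6)
  # Zeroed coefficients: pi = plogis(0) = 0.5 exactly, at the threshold.
  m$meta$coefficients[] <- 0
  p <- predict_residues(m, sp$test)
  expect_equal(unique(p$probability), 0.5)
  expect_equal(unique(p$classification), "HS")
  # All-zero base votes: pi = plogis(intercept).
  m$meta$coefficients <- c("(Intercept)" = -1.3, rf = 2, pda = 2)
  base_out <- matrix(0, 3, 2, dimnames = list(NULL, c("rf", "pda")))
  expect_equal(hotspotr:::meta_probability(m, base_out), rep(plogis(-1.3), 3))
})

test_that("probability is monotone in agreeing positive votes", {
  m <- list(meta = list(coefficients = c("(Intercept)" = -2, a = 1.5,
                                         b = 2.0, c = 0.7)))
  votes <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  p <- hotspotr:::meta_probability(m, as.matrix(votes))
  for (i in seq_len(nrow(votes))) for (j in seq_len(nrow(votes))) {
    if (all(votes[i, ] >= votes[j, ])) expect_gte(p[i], p[j])
  }
})

test_that("schema mismatches are reported with missing and extra names", {
  tab <- sep_table(49)
  sp <- stratified_split(tab, 0.7, seed = 7)
  m <- suppressWarnings(fit_ensemble(sp$train, champions = "pda", seed = 8))
  bad <- sp$test
  names(bad)[names(bad) == "f001"] <- "f999"
  err <- expect_error(predict_residues(m, bad), class = "hs_schema_error")
  expect_match(conditionMessage(err), "f001")
  expect_match(conditionMessage(err), "f999")
})

test_that("model archives round-trip bitwise and reject corruption", {
  tab <- sep_table(50)
  sp <- stratified_split(tab, 0.7, seed = 9)
  m <- suppressWarnings(fit_ensemble(sp$train, champions = c("rf", "pda"),
                                     seed = 10))
  f <- tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_residues(m, sp$test)$probability,
                   predict_residues(m2, sp$test)$probability)

  corrupt <- tempfile(fileext = ".rds")
  writeLines("not an archive", corrupt)
  expect_error(load_model(corrupt), class = "hs_archive_error")

  wrong <- tempfile(fileext = ".rds")
  saveRDS(list(format = "hotspotr_ensemble", version = 99L, model = NULL), wrong)
  expect_error(load_model(wrong), class = "hs_version_error")
})
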