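# Tag clustering, cross-validated benchmarking, champions, MANOVA.

test_that("Jaccard distance matches hand values and the dist() oracle", {
  m <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(1, 1, 0), d = c(0, 1, 1))
  d <- jaccard_distance(m)
  expect_equal(d["a", "b"], 2 / 3)
  expect_equal(d["a", "c"], 0)
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d))
  expect_equal(as.matrix(dist(m, method = "binary")), d, ignore_attr = TRUE)

  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(jaccard_distance(disjoint)["a", "b"], 1)
  expect_warning(dz <- jaccard_distance(rbind(a = c(0, 0), b = c(0, 0))),
                 class = "hs_empty_tags")
  expect_equal(dz["a", "b"], 0)
  expect_error(jaccard_distance(rbind(c(1, 2))), class = "hs_validation_error")
})

test_that("Jaccard distance satisfies the triangle inequality on random triples", {
  set.seed(31)
  tags <- matrix(rbinom(30 * 8, 1, 0.4), 30, 8,
                 dimnames = list(paste0("alg", 1:30), NULL))
  tags[rowSums(tags) == 0, 1] <- 1
  d <- jaccard_distance(tags)
  for (i in 1:50) {
    t3 <- sample(30, 3)
    expect_lte(d[t3[1], t3[2]], d[t3[1], t3[3]] + d[t3[3], t3[2]] + 1e-12)
  }
})

test_that("complete-linkage clustering recovers planted tag blocks", {
  block <- rbind(
    matrix(rep(c(1, 1, 1, 0, 0, 0), 4), 4, byrow = TRUE),
    matrix(rep(c(0, 0, 0, 1, 1, 1), 3), 3, byrow = TRUE))
  rownames(block) <- paste0("m", 1:7)
  cl <- cluster_algorithms(jaccard_distance(block), k = 2)
  expect_equal(length(unique(cl[1:4])), 1)
  expect_equal(length(unique(cl[5:7])), 1)
  expect_false(cl[1] == cl[5])

  d <- jaccard_distance(block)
  expect_equal(length(unique(cluster_algorithms(d, k = 1))), 1)
  expect_equal(length(unique(cluster_algorithms(d, k = 7))), 7)
  expect_error(cluster_algorithms(d, k = 8), class = "hs_validation_error")
})

test_that("the shipped tag table covers the 51 algorithms and clusters to 5", {
  tags <- algorithm_tags()
  expect_equal(nrow(tags), 51)
  expect_equal(ncol(tags), 55)
  expect_true(all(tags %in% c(0L, 1L)))
  expect_true(all(rowSums(tags) > 0))
  expect_true(all(c("rf", "svmPoly", "pda", "plr", "ORFsvm") %in% rownames(tags)))
  cl <- cluster_algorithms(jaccard_distance(tags), k = 5)
  expect_equal(sort(unique(unname(cl))), 1:5)
})

test_that("benchmark reports sane metrics for dummy and competent models", {
  tab <- make_synthetic_table(n_obs = 120, n_features = 8, n_informative = 4,
                              effect_size = 3, seed = 32)
  sp <- stratified_split(tab, 0.7, seed = 1)
  v <- build_variants(sp$train, sp$test, seed = 1)

  majority <- list(fit = function(x, y) NULL,
                   predict_prob = function(m, x) rep(0, nrow(x)))
  failing <- list(fit = function(x, y) stop("no convergence"),
                  predict_prob = function(m, x) NULL)
  reg <- c(model_registry(c("rf", "pda")),
           list(majority = majority, failing = failing))
  res <- benchmark_models(v["Scaled"], reg, folds = 3, repeats = 1, seed = 2)

  maj <- res[res$algorithm == "majority", ]
  expect_equal(maj$TPR, 0)
  expect_equal(maj$TNR, 1)
  expect_false(res$converged[res$algorithm == "failing"])
  expect_true(all(is.na(res[res$algorithm == "failing",
                            c("AUROC", "Accuracy")])))
  # Strongly separated classes: competent models reach AUROC ~ 1.
  expect_gt(res$AUROC[res$algorithm == "rf"], 0.95)
  expect_gt(res$AUROC[res$algorithm == "pda"], 0.95)
})

test_that("benchmark is reproducible under a fixed master seed", {
  tab <- make_synthetic_table(n_obs = 80, n_features = 6, seed = 33)
  sp <- stratified_split(tab, 0.7, seed = 1)
  v <- build_variants(sp$train, sp$test, seed = 1)
  reg <- model_registry(c("rf", "plr"))
  r1 <- benchmark_models(v["ScaledUp"], reg, folds = 3, repeats = 2, seed = 9)
  r2 <- benchmark_models(v["ScaledUp"], reg, folds = 3, repeats = 2, seed = 9)
  expect_identical(r1, r2)
  r3 <- benchmark_models(v["ScaledUp"], reg, folds = 3, repeats = 2, seed = 10)
  expect_false(identical(r1$AUROC, r3$AUROC))
})

test_that("champion selection maximizes the score within each cluster", {
  res <- data.frame(
    algorithm = c("alpha", "beta", "gamma", "delta"),
    variant = "ScaledUp", converged = TRUE,
    AUROC = c(0.9, 0.8, 0.7, 0.7), TPR = c(0.9, 0.95, 0.6, 0.6),
    TNR = c(0.9, 0.9, 0.8, 0.8))
  clusters <- c(alpha = 1, beta = 1, gamma = 2, delta = 2)
  ch <- select_champions(res, clusters, "ScaledUp")
  expect_equal(unname(ch["1"]), "alpha")   # planted maximum
  expect_equal(unname(ch["2"]), "delta")   # tie -> lexicographically...
  # gamma and delta tie exactly: lexicographically smaller name wins.
  expect_equal(unname(ch["2"]), sort(c("gamma", "delta"))[1])

  one_per <- res[c(1, 3), ]
  ch2 <- select_champions(one_per, clusters, "ScaledUp")
  expect_equal(unname(ch2), c("alpha", "gamma"))
})

test_that("Pillai MANOVA matches stats::manova and the ANOVA identity", {
  set.seed(34)
  x <- matrix(rnorm(90), 30, 3)
  g <- rep(c("a", "b", "c"), each = 10)
  x[g == "b", ] <- x[g == "b", ] + 0.8
  got <- manova_pillai(x, g)
  fit <- summary(stats::manova(x ~ factor(g)), test = "Pillai")$stats
  expect_equal(got$statistic, fit[1, "Pillai"], tolerance = 1e-9)
  expect_equal(got$f, fit[1, "approx F"], tolerance = 1e-9)
  expect_equal(got$p_value, fit[1, "Pr(>F)"], tolerance = 1e-9)
  expect_true(got$statistic >= 0 &&
                got$statistic <= min(length(unique(g)) - 1, ncol(x)))

  # One response: Pillai V reduces to SSB / (SSB + SSW).
  y <- matrix(c(1, 2, 3, 7, 8, 9), ncol = 1)
  g2 <- rep(c("a", "b"), each = 3)
  got1 <- manova_pillai(y, g2)
  ssb <- 2 * sum(3 * (c(2, 8) - 5)^2) / 2
  ssw <- sum((y - rep(c(2, 8), each = 3))^2)
  expect_equal(got1$statistic, ssb / (ssb + ssw))
})

test_that("Pillai p-value agrees with a permutation oracle", {
  set.seed(35)
  x <- matrix(rnorm(48), 24, 2)
  g <- rep(c("a", "b"), each = 12)
  x[g == "b", 1] <- x[g == "b", 1] + 1.1
  got <- manova_pillai(x, g)
  perm <- replicate(400, manova_pillai(x, sample(g))$statistic)
  p_perm <- mean(perm >= got$statistic)
  expect_lt(abs(p_perm - got$p_value), 0.08)
})
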