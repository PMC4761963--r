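# Best-subset search, bootstrap RC distributions, significance and
# classification.

test_that("fit_linear reproduces exact and oracle least squares", {
  x <- toy_features(n = 30, m = 3, seed = 1, ids = c("m1", "m2", "m3"))
  y <- 1 + 2 * x[, "m1"]
  fm <- feature_matrix(x, y)
  f <- fit_linear(fm, "m1")
  expect_equal(unname(f$coefficients), c(1, 2), tolerance = 1e-9)

  f0 <- fit_linear(fm, character())
  expect_equal(unname(f0$coefficients[1]), mean(y), tolerance = 1e-12)

  set.seed(77)
  x2 <- matrix(rnorm(60), 20, 3, dimnames = list(paste0("g", 1:20),
                                                 c("a", "b", "c")))
  y2 <- rnorm(20)
  f2 <- fit_linear(feature_matrix(abs(x2), y2), c("a", "b", "c"))
  X <- cbind(1, abs(x2))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% y2)[, 1]
  expect_equal(unname(f2$coefficients), unname(beta_oracle), tolerance = 1e-9)

  dup <- cbind(x, m4 = x[, "m1"])
  expect_error(fit_linear(feature_matrix(dup, y), c("m1", "m4")), "collinear")
  expect_error(fit_linear(fm, "nope"), "unknown TFBS")
})

test_that("exhaustive search equals the subset-enumeration oracle", {
  for (r in 1:50) {
    set.seed(2000 + r)
    m <- sample(4:7, 1)
    n <- sample(25:40, 1)
    ids <- sprintf("M%02d", 1:m)
    x <- matrix(rpois(n * m, 1.2), n, m, dimnames = list(NULL, ids))
    rownames(x) <- sprintf("g%03d", 1:n)
    k_true <- sample(0:3, 1)
    beta <- numeric(m)
    if (k_true) beta[sample(m, k_true)] <- runif(k_true, -2, 2)
    y <- 1 + x %*% beta + rnorm(n, sd = 1)
    fit <- search_models(feature_matrix(x, y[, 1]), max_model_size = 3)
    want <- oracle_best_subset(x, y[, 1], 3)
    expect_identical(fit$selected_tfbs, want$sel)
    expect_equal(fit$fit_criterion, want$crit, tolerance = 1e-8)
  }
})

test_that("a noiseless single-cause response selects exactly its TFBS", {
  x <- toy_features(n = 40, m = 5, seed = 3)
  y <- 0.5 + 1.7 * x[, "M02"]
  fit <- search_models(feature_matrix(x, y), max_model_size = 3)
  expect_identical(fit$selected_tfbs, "M02")
})

test_that("forward selection matches exhaustive search on orthogonal designs", {
  set.seed(9)
  n <- 64
  # orthogonal +/-1 contrasts scaled to nonnegative features
  h <- cbind(rep(c(1, -1), 32), rep(c(1, 1, -1, -1), 16),
             rep(c(rep(1, 4), rep(-1, 4)), 8))
  x <- h + 1
  colnames(x) <- c("A", "B", "C"); rownames(x) <- paste0("g", 1:n)
  y <- 2 + 1.5 * x[, "A"] - 2 * x[, "C"] + rnorm(n, sd = 0.4)
  fm <- feature_matrix(x, y)
  ex <- search_models(fm, max_model_size = 3, mode = "exhaustive")
  fw <- search_models(fm, max_model_size = 3, mode = "forward")
  expect_identical(sort(ex$selected_tfbs), sort(fw$selected_tfbs))
  expect_equal(ex$fit_criterion, fw$fit_criterion, tolerance = 1e-9)
})

test_that("the exhaustive budget is enforced with a pointer to forward mode", {
  x <- toy_features(n = 50, m = 25, seed = 4, ids = sprintf("M%02d", 1:25))
  fm <- feature_matrix(x, rnorm(50))
  expect_error(search_models(fm, max_model_size = 12, budget = 1000),
               "forward")
})

test_that("bootstrap RC distributions have exactly B entries and are seeded", {
  x <- toy_features(n = 50, m = 4, seed = 5)
  y <- 1 + 2 * x[, "M01"] + rnorm(50, sd = 0.5)
  fm <- feature_matrix(x, y)
  d1 <- bootstrap_rcs(fm, max_model_size = 3, B = 40, seed = 11)
  expect_equal(dim(d1$rc), c(40, 4))
  expect_equal(colnames(d1$rc), sprintf("M%02d", 1:4))
  d2 <- bootstrap_rcs(fm, max_model_size = 3, B = 40, seed = 11)
  expect_identical(d1$rc, d2$rc)
  d3 <- bootstrap_rcs(fm, max_model_size = 3, B = 40, seed = 12)
  expect_false(identical(d1$rc, d3$rc))
  # absent-from-model replicates contribute exactly 0
  expect_true(all(d1$rc[!d1$selected] == 0))
  # the alternative subset scheme obeys the same contracts
  ds <- bootstrap_rcs(fm, max_model_size = 3, B = 40, seed = 11,
                      scheme = "subsets")
  expect_equal(dim(ds$rc), c(40, 4))
  expect_identical(ds$rc,
                   bootstrap_rcs(fm, max_model_size = 3, B = 40, seed = 11,
                                 scheme = "subsets")$rc)
  expect_error(bootstrap_rcs(fm, B = 1), "B must be")
})

test_that("RC significance testing follows the stated conventions", {
  all_zero <- test_rcs(rep(0, 100), n_tfbs_tested = 10)
  expect_false(all_zero$significant)
  expect_equal(all_zero$sign, 0)

  const <- test_rcs(rep(1.5, 100), n_tfbs_tested = 10)
  expect_true(const$significant)
  expect_equal(const$sign, 1)
  expect_equal(const$p_bonferroni, 0)

  set.seed(8)
  rcs <- rnorm(1000, mean = 0.5, sd = 0.5)
  r <- test_rcs(rcs, n_tfbs_tested = 100, alpha = 0.01)
  expect_equal(r$mean_rc, mean(rcs), tolerance = 1e-12)
  expect_equal(r$p_bonferroni, min(1, r$p * 100))
  expect_true(r$significant)
})

test_that("null RC distributions keep the Bonferroni false-positive rate", {
  set.seed(303)
  reps <- 40; n_tfbs <- 100
  fp <- 0
  for (r in seq_len(reps)) {
    rcs <- rnorm(1000)
    if (test_rcs(rcs, n_tfbs_tested = n_tfbs, alpha = 0.01)$significant) {
      fp <- fp + 1
    }
  }
  expect_lte(fp / reps, 0.01 + 0.02)  # binomial slack around the nominal rate
})

test_that("TFBS classification maps sign patterns to statuses", {
  tab <- function(ids, sig, sgn) {
    data.frame(tfbs_id = ids, significant = sig, sign = sgn)
  }
  a <- tab(c("m1", "m2", "m3", "m4", "m5"),
           c(TRUE, TRUE, TRUE, FALSE, FALSE), c(1, 1, -1, 0, 0))
  b <- tab(c("m1", "m2", "m3", "m4", "m5"),
           c(TRUE, TRUE, FALSE, TRUE, FALSE), c(1, -1, 0, -1, 0))
  cl <- classify_tfbs(a, b)
  got <- setNames(cl$status, cl$tfbs_id)
  expect_equal(unname(got["m1"]), "identical")
  expect_equal(unname(got["m2"]), "opposite")
  expect_equal(unname(got["m3"]), "unique_to_A")
  expect_equal(unname(got["m4"]), "unique_to_B")
  expect_equal(unname(got["m5"]), "not_significant")
  expect_error(classify_tfbs(a, b[1:3, ]), "universe")
})

test_that("promoter_lm recovers a planted coefficient and its methods work", {
  set.seed(21)
  x <- toy_features(n = 120, m = 5, seed = 21)
  y <- 2 + 2 * x[, "M01"] - 1.5 * x[, "M04"] + rnorm(120, sd = 0.5)
  fm <- feature_matrix(x, y)
  fit <- promoter_lm(fm, B = 120, seed = 3, max_model_size = 4)
  tab <- summary(fit)
  expect_s3_class(tab, "data.frame")
  expect_true(tab$significant[tab$tfbs_id == "M01"])
  expect_equal(tab$sign[tab$tfbs_id == "M01"], 1)
  expect_true(tab$significant[tab$tfbs_id == "M04"])
  expect_equal(tab$sign[tab$tfbs_id == "M04"], -1)
  expect_equal(tab$mean_rc, unname(colMeans(fit$dist$rc[, tab$tfbs_id])),
               tolerance = 1e-12)
  # methods
  expect_output(print(fit), "promoter_lm")
  expect_equal(unname(coef(fit)), tab$mean_rc)
  expect_length(predict(fit), 120)
  expect_equal(unname(residuals(fit)),
               unname(y - predict(fit)), tolerance = 1e-9)
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
})

test_that("refitting without exclusions reproduces the original fit", {
  x <- toy_features(n = 60, m = 3, seed = 31)
  y <- 1 + 1.5 * x[, "M02"] + rnorm(60, sd = 0.4)
  fit <- promoter_lm(feature_matrix(x, y), B = 60, seed = 5)
  re <- refit_excluding(fit, character(0))
  expect_identical(re$fit$dist$rc, fit$dist$rc)
  expect_true(all(re$shift$shift == 0))
  expect_error(refit_excluding(fit, rownames(x)[1:55]), "remain")
})

test_that("excluding the only carriers of a TFBS removes it from models", {
  set.seed(41)
  n <- 80
  x <- toy_features(n = n, m = 3, seed = 41)
  x[, "M03"] <- 0
  carriers <- rownames(x)[1:15]
  x[carriers, "M03"] <- rpois(15, 2) + 1
  y <- 1 + 2 * x[, "M03"] + 0.8 * x[, "M01"] + rnorm(n, sd = 0.4)
  fit <- promoter_lm(feature_matrix(x, y), B = 80, seed = 7)
  expect_gt(fit$table$selection_frequency[fit$table$tfbs_id == "M03"], 0.5)
  re <- refit_excluding(fit, carriers)
  expect_lte(re$fit$table$selection_frequency[re$fit$table$tfbs_id == "M03"],
             0.05)
})

test_that("a subpopulation-driven positive RC flips sign when the subset is removed", {
  # two-population construction: a small "keratin-like" block carries high
  # counts of M01 with strongly positive effect; in the remaining genes the
  # same site acts negatively
  set.seed(51)
  n_drv <- 60; n_rest <- 140
  genes <- sprintf("g%03d", 1:(n_drv + n_rest))
  driver <- genes[seq_len(n_drv)]
  m1 <- c(sample(2:4, n_drv, TRUE), sample(0:1, n_rest, TRUE))
  m2 <- rpois(n_drv + n_rest, 1)
  x <- cbind(M01 = m1, M02 = m2)
  rownames(x) <- genes
  effect <- ifelse(genes %in% driver, 3, -1.2)
  y <- 2 + effect * x[, "M01"] + 0.5 * x[, "M02"] + rnorm(length(genes), sd = 0.4)
  fit <- promoter_lm(feature_matrix(x, y), B = 100, seed = 9)
  before <- fit$table$mean_rc[fit$table$tfbs_id == "M01"]
  expect_gt(before, 0)
  re <- refit_excluding(fit, driver)
  after <- re$fit$table$mean_rc[re$fit$table$tfbs_id == "M01"]
  expect_lt(after, 0)
  expect_lt(re$shift$shift[re$shift$tfbs_id == "M01"], 0)
})
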