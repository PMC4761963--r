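# Up-regulation calling, partitioning, overlap and enrichment tests.

make_expr <- function(treated, control, genes = paste0("g", seq_len(nrow(treated)))) {
  vals <- cbind(control, treated)
  colnames(vals) <- c(paste0("ctrl_", seq_len(ncol(control))),
                      paste0("trt_", seq_len(ncol(treated))))
  rownames(vals) <- genes
  expression_matrix(vals)
}

test_that("fold change follows the pseudocount formula", {
  em <- make_expr(treated = rbind(c(8, 8), c(30, 34)),
                  control = rbind(c(8, 8), c(3, 5)))
  de <- suppressMessages(call_upregulated(em, "ctrl", "trt"))
  expect_equal(de$fc[1], 1)            # (8+1)/(8+1)
  expect_false(de$up[1])
  expect_equal(de$fc[2], 33 / 5)       # (32+1)/(4+1) = 6.6
  expect_gt(de$fc[2], 2)
})

test_that("zero-variance genes get p = 1 by convention", {
  em <- make_expr(treated = rbind(c(5, 5), c(9, 11)),
                  control = rbind(c(5, 5), c(2, 3)))
  expect_message(de <- call_upregulated(em, "ctrl", "trt"), "zero variance")
  expect_equal(de$p[1], 1)
  expect_true(all(de$q >= de$p - 1e-15))
  expect_true(all(de$p >= 0 & de$q <= 1))
})

test_that("unknown or under-replicated conditions are rejected", {
  em <- make_expr(treated = rbind(c(5, 6)), control = rbind(c(2, 3)))
  expect_error(call_upregulated(em, "nope", "trt"), "unknown condition")
  vals <- matrix(c(1, 2, 3), 1, dimnames = list("g1", c("a_1", "a_2", "b_1")))
  em2 <- expression_matrix(vals)
  expect_error(call_upregulated(em2, "a", "b"), "fewer than 2")
})

test_that("planted 4-fold shifts are recovered with few false flags", {
  reps <- 20
  sens <- fdrN <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    n_pos <- 50; n_null <- 450; n <- n_pos + n_null
    base <- 2.5  # log2 control level
    mu <- matrix(base, n, 8)
    mu[seq_len(n_pos), 5:8] <- base + 2   # true 4-fold shift, log2 scale
    vals <- 2^(mu + rnorm(n * 8, sd = 0.3)) - 1
    vals[vals < 0] <- 0
    colnames(vals) <- c(paste0("ctrl_", 1:4), paste0("trt_", 1:4))
    rownames(vals) <- paste0("g", seq_len(n))
    de <- call_upregulated(expression_matrix(vals), "ctrl", "trt")
    flagged <- which(de$up)
    sens[r] <- mean(seq_len(n_pos) %in% flagged)
    fdrN[r] <- if (length(flagged)) mean(flagged > n_pos) else 0
  }
  expect_gte(mean(sens), 0.9)
  expect_lte(mean(fdrN), 0.10)
})

test_that("expressed-gene detection applies the condition-mean threshold", {
  vals <- rbind(g1 = c(0, 0, 0, 0), g2 = c(0.1, 0.1, 5, 5),
                g3 = c(0.5, 0.5, 0.9, 0.9))
  colnames(vals) <- c("a_1", "a_2", "b_1", "b_2")
  em <- expression_matrix(vals)
  expect_identical(detect_expressed(em), "g2")
  zero <- expression_matrix(matrix(0, 2, 4,
                                   dimnames = list(c("x", "y"), colnames(vals))))
  expect_length(detect_expressed(zero), 0)
})

test_that("partition splits shared, unique and DUG sets correctly", {
  # equal means in both treatments: all shared, no DUGs
  vals2 <- sweep(cbind(matrix(2, 3, 2), matrix(40, 3, 2), matrix(40, 3, 2)),
                 2, c(0.98, 1.02, 0.98, 1.02, 0.98, 1.02), `*`)
  colnames(vals2) <- c("c_1", "c_2", "A_1", "A_2", "B_1", "B_2")
  rownames(vals2) <- c("g1", "g2", "g3")
  em <- expression_matrix(vals2)
  deA <- call_upregulated(em, "c", "A")
  deB <- call_upregulated(em, "c", "B")
  part <- partition_upregulated(deA, deB)
  expect_setequal(part$shared, c("g1", "g2", "g3"))
  expect_length(part$dug_A, 0)
  expect_length(part$dug_B, 0)
})

test_that("disjoint up-regulation lands in the unique sets", {
  vals <- rbind(g1 = c(2, 2, 40, 41, 2, 2),
                g2 = c(2, 2, 2, 2, 40, 41))
  colnames(vals) <- c("c_1", "c_2", "A_1", "A_2", "B_1", "B_2")
  em <- expression_matrix(vals)
  deA <- suppressMessages(call_upregulated(em, "c", "A"))
  deB <- suppressMessages(call_upregulated(em, "c", "B"))
  part <- partition_upregulated(deA, deB)
  expect_identical(part$unique_to_A, "g1")
  expect_identical(part$unique_to_B, "g2")
  expect_length(part$shared, 0)
  expect_error(partition_upregulated(deA, deB[c(2, 1), ]), "universe")
})

test_that("partition identity holds on random inputs and DUGs are up-regulated", {
  for (r in 1:10) {
    set.seed(500 + r)
    n <- 60
    mu <- cbind(ctrl = rep(2, n),
                A = sample(c(2, 8, 30), n, TRUE),
                B = sample(c(2, 8, 30), n, TRUE))
    vals <- do.call(cbind, lapply(colnames(mu), function(cn) {
      m <- sapply(1:3, function(j) mu[, cn] * 2^rnorm(n, sd = 0.1))
      colnames(m) <- paste(cn, 1:3, sep = "_")
      m
    }))
    rownames(vals) <- paste0("g", 1:n)
    em <- expression_matrix(vals)
    deA <- suppressMessages(call_upregulated(em, "ctrl", "A"))
    deB <- suppressMessages(call_upregulated(em, "ctrl", "B"))
    part <- partition_upregulated(deA, deB)
    expect_equal(length(part$shared) + length(part$unique_to_A) +
                   length(part$unique_to_B), length(part$up_all))
    expect_length(intersect(part$dug_A, part$dug_B), 0)
    expect_true(all(c(part$dug_A, part$dug_B) %in% part$up_all))
    # BH monotonicity on the sorted p-values
    o <- order(deA$p)
    expect_true(all(diff(deA$q[o]) >= -1e-12))
  }
})

test_that("the printed study counts reproduce from the partition fixture", {
  em <- partition_count_fixture()
  deA <- suppressMessages(call_upregulated(em, "ctrl", "A"))
  deB <- suppressMessages(call_upregulated(em, "ctrl", "B"))
  part <- partition_upregulated(deA, deB)
  expect_length(part$up_all, 1570)
  expect_length(part$shared, 875)
  expect_equal(length(part$unique_to_A) + length(part$unique_to_B), 695)
  expect_length(part$dug_A, 162)
  expect_length(part$dug_B, 220)
  expect_equal(round(100 * (length(part$dug_A) + length(part$dug_B)) /
                       length(part$up_all)), 24)
})

test_that("hypergeometric overlap test matches closed forms and the oracle", {
  u <- paste0("g", 1:10)
  res <- overlap_test(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)  # 1/252
  degenerate <- overlap_test(u, u, u)
  expect_equal(degenerate$p, 1)
  none <- overlap_test(u[1:3], u[4:6], u)
  expect_equal(none$p, brute_hyper_tail(0, 3, 3, 10), tolerance = 1e-12)
  adj <- overlap_test(u[1:5], u[1:5], u, n_tests = 300)
  expect_equal(adj$p_adjusted, min(1, res$p * 300))
  expect_error(overlap_test("g1", "g1", character(0)), "empty universe")
  expect_error(overlap_test("zz", u[1], u), "subset")
})

test_that("overlap test equals exhaustive enumeration on all small universes", {
  for (N in 2:12) {
    u <- paste0("g", seq_len(N))
    for (a in 0:N) for (b in 0:N) {
      setA <- utils::head(u, a)
      setB <- utils::tail(u, b)
      k <- length(intersect(setA, setB))
      got <- overlap_test(setA, setB, u)$p
      want <- brute_hyper_tail(k, a, b, N)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("correlation matches the textbook formula", {
  x <- c(1, 2, 3, 4); y <- c(2, 4, 5, 9)
  got <- correlate(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(2 / (1 - r_hand^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  expect_equal(correlate(x, x)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(correlate(1:2, 1:2), "at least 3")
})

test_that("category enrichment applies hypergeometric + Bonferroni", {
  u <- paste0("g", 1:20)
  cats <- list(half = u[1:10], other = u[11:20], tiny = u[1:2])
  res <- enrich_categories(u[1:10], u, cats, alpha = 0.01)
  expect_equal(res$p[res$category == "half"],
               brute_hyper_tail(10, 10, 10, 20), tolerance = 1e-12)
  expect_equal(res$p_adjusted, pmin(1, res$p * 3))
  # disjoint category: upper tail at overlap 0 is 1
  expect_equal(res$p[res$category == "other"], 1)
  expect_false(res$significant[res$category == "other"])
  one <- enrich_categories(u[1:10], u, cats["half"])
  expect_equal(one$p_adjusted, one$p)
  empty <- enrich_categories(character(0), u, cats)
  expect_true(all(empty$p == 1))
  expect_error(enrich_categories(u[1:2], u[1:5], list(bad = u[6:8])), "subset")
})
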