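# Best-subset linear modelling of promoter features. The search enumerates
# TFBS subsets (or grows one greedily), scores each ordinary-least-squares fit
# by an information criterion, and the bootstrap wrapper turns the winning
# coefficients of B resamples into per-TFBS regression-coefficient (RC)
# distributions.

#' Ordinary least squares on a TFBS subset
#'
#' Fits the response on the given feature columns plus an intercept and
#' records the model-search criterion.
#'
#' @param features A [feature_matrix()] with a response set, or a plain
#'   numeric matrix when `response` is supplied.
#' @param subset Character vector of TFBS ids (may be empty: intercept-only
#'   model).
#' @param response Per-gene response; taken from `features` when `NULL`.
#' @param criterion `"bic"` (default) or `"adjr2"`; both are reported as
#'   smaller-is-better values (`adjr2` negated).
#' @return List of class `"model_fit"`: `selected_tfbs`, `coefficients`
#'   (intercept first), `fit_criterion`, `n_genes`, `residuals`, `fitted`.
#'   A rank-deficient (collinear) subset is an error.
#' @export
fit_linear <- function(features, subset = character(), response = NULL,
                       criterion = c("bic", "adjr2")) {
  criterion <- match.arg(criterion)
  xy <- resolve_xy(features, response)
  subset <- as.character(subset)
  missing_cols <- setdiff(subset, colnames(xy$x))
  if (length(missing_cols)) {
    stop("unknown TFBS ids: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(xy$x)
  if (n <= length(subset) + 1L) {
    stop("need more genes (", n, ") than parameters (", length(subset) + 1L, ")")
  }
  X <- cbind(`(Intercept)` = 1, xy$x[, subset, drop = FALSE])
  fit <- stats::lm.fit(X, xy$y)
  if (fit$rank < ncol(X)) {
    stop("collinear TFBS subset (design rank ", fit$rank, " < ", ncol(X), ")")
  }
  rss <- sum(fit$residuals^2)
  structure(list(selected_tfbs = subset,
                 coefficients = fit$coefficients,
                 fit_criterion = criterion_value(rss, n, length(subset),
                                                 sum((xy$y - mean(xy$y))^2),
                                                 criterion),
                 criterion = criterion, n_genes = n,
                 residuals = fit$residuals, fitted = fit$fitted.values),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("model_fit:", length(x$selected_tfbs), "TFBS(s) on", x$n_genes,
      "genes;", x$criterion, "=", format(x$fit_criterion, digits = 6), "\n")
  if (length(x$selected_tfbs)) {
    print(x$coefficients)
  } else {
    cat("  intercept-only:", format(x$coefficients[1], digits = 6), "\n")
  }
  invisible(x)
}

resolve_xy <- function(features, response) {
  if (inherits(features, "feature_matrix")) {
    x <- features$values
    y <- response %||% features$response
  } else {
    x <- as.matrix(features)
    y <- response
  }
  if (is.null(y)) stop("no response: supply `response` or use set_response()")
  if (length(y) != nrow(x)) stop("response length != number of genes")
  list(x = x, y = as.numeric(y))
}

# Smaller is better for both criteria. RSS is floored at a relative epsilon
# so that numerically perfect fits share one criterion value and the
# size-then-lexicographic tie-break decides between them.
criterion_value <- function(rss, n, k, tss, criterion) {
  rss <- max(rss, 1e-12 * max(tss, .Machine$double.eps))
  if (criterion == "bic") {
    n * log(rss / n) + (k + 1) * log(n)
  } else {
    if (n - k - 1 <= 0) return(Inf)
    -(1 - (rss / (n - k - 1)) / (tss / (n - 1)))
  }
}

# All subsets of ids up to max_size, in size-then-lexicographic order.
enumerate_subsets <- function(ids, max_size) {
  m <- length(ids)
  out <- list(integer(0))
  for (k in seq_len(min(max_size, m))) {
    cmb <- utils::combn(m, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

n_subsets <- function(m, max_size) {
  sum(choose(m, 0:min(max_size, m)))
}

# Criterion of one subset from precomputed Gram quantities; NA when the
# normal equations are singular (collinear subset).
subset_criterion <- function(G, Xy, yy, n, idx, tss, criterion) {
  cols <- c(1L, idx + 1L)
  beta <- tryCatch({
    R <- chol(G[cols, cols, drop = FALSE])
    backsolve(R, forwardsolve(t(R), Xy[cols]))
  }, error = function(e) NULL)
  if (is.null(beta)) return(list(crit = NA_real_, beta = NULL))
  rss <- max(yy - sum(beta * Xy[cols]), 0)
  list(crit = criterion_value(rss, n, length(idx), tss, criterion), beta = beta)
}

# Core search on a plain x/y pair. `subsets` may be precomputed (bootstrap
# reuses one enumeration across replicates).
search_xy <- function(x, y, max_size, mode, criterion, budget = 1e6,
                      subsets = NULL) {
  m <- ncol(x)
  n <- length(y)
  X <- cbind(1, x)
  G <- crossprod(X)
  Xy <- crossprod(X, y)[, 1]
  yy <- sum(y * y)
  tss <- sum((y - mean(y))^2)
  best <- list(crit = Inf, idx = integer(0), beta = mean(y))
  consider <- function(idx) {
    if (n <= length(idx) + 1L) return()
    r <- subset_criterion(G, Xy, yy, n, idx, tss, criterion)
    # strict improvement: ties keep the earlier (smaller, lexicographically
    # first) subset
    if (!is.na(r$crit) && r$crit < best$crit - 1e-10) {
      best <<- list(crit = r$crit, idx = idx, beta = r$beta)
    }
  }
  if (mode == "exhaustive") {
    if (n_subsets(m, max_size) > budget) {
      stop("exhaustive search over ", format(n_subsets(m, max_size)),
           " subsets exceeds the budget (", format(budget),
           "); use mode = \"forward\"")
    }
    if (is.null(subsets)) subsets <- enumerate_subsets(seq_len(m), max_size)
    for (idx in subsets) consider(idx)
  } else {
    consider(integer(0))
    current <- integer(0)
    repeat {
      if (length(current) >= min(max_size, m)) break
      prev <- best$crit
      prev_idx <- best$idx
      for (j in setdiff(seq_len(m), current)) consider(sort(c(current, j)))
      if (best$crit >= prev - 1e-10 && identical(best$idx, prev_idx)) break
      current <- best$idx
    }
  }
  coefs <- stats::setNames(as.numeric(best$beta),
                           c("(Intercept)", colnames(x)[best$idx]))
  list(selected = colnames(x)[best$idx], coefficients = coefs,
       fit_criterion = best$crit)
}

#' Search for the best-fitting TFBS subset model
#'
#' Exhaustive mode enumerates every subset up to `max_model_size` (subject to
#' a subset-count budget) and returns the one optimizing the criterion, ties
#' broken by smaller subset then lexicographic TFBS order; forward mode is
#' greedy stepwise with the same criterion, for problems whose enumeration
#' exceeds the budget.
#'
#' @inheritParams fit_linear
#' @param max_model_size Largest subset considered (default 10).
#' @param mode `"exhaustive"` (default) or `"forward"`.
#' @param budget Maximum number of subsets enumerable in exhaustive mode
#'   (default `1e6`); exceeding it is an error directing to forward mode.
#' @return A `"model_fit"` (see [fit_linear()]) for the winning subset.
#' @export
search_models <- function(features, max_model_size = 10L,
                          mode = c("exhaustive", "forward"),
                          response = NULL, criterion = c("bic", "adjr2"),
                          budget = 1e6) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  xy <- resolve_xy(features, response)
  res <- search_xy(xy$x, xy$y, max_model_size, mode, criterion, budget)
  fit <- stats::lm.fit(cbind(1, xy$x[, res$selected, drop = FALSE]), xy$y)
  structure(list(selected_tfbs = res$selected,
                 coefficients = res$coefficients,
                 fit_criterion = res$fit_criterion,
                 criterion = criterion, n_genes = nrow(xy$x),
                 residuals = fit$residuals, fitted = fit$fitted.values),
            class = "model_fit")
}

#' Bootstrap distributions of TFBS regression coefficients
#'
#' Draws `B` gene-level bootstrap resamples, runs the best-subset model
#' search on each, and records every TFBS's coefficient; a TFBS absent from
#' a replicate's winning model contributes RC 0 for that replicate, so every
#' distribution has exactly `B` entries. The alternative scheme fits `B`
#' random feature subsets on the full data behind the same interface.
#'
#' @inheritParams search_models
#' @param B Number of replicates (default 1000).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param scheme `"bootstrap"` (gene resampling, default) or `"subsets"`
#'   (random subset fits on the full gene set).
#' @return List of class `"rc_distributions"`: `rc` (a `B` x TFBS matrix),
#'   `selected` (logical `B` x TFBS inclusion matrix), `tfbs_ids`, `B`,
#'   `n_redraws` (degenerate resamples redrawn), plus the search settings.
#' @export
bootstrap_rcs <- function(features, max_model_size = 10L, B = 1000L,
                          seed = 1L, response = NULL,
                          mode = c("exhaustive", "forward"),
                          criterion = c("bic", "adjr2"),
                          scheme = c("bootstrap", "subsets"), budget = 1e6) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  scheme <- match.arg(scheme)
  if (B < 2) stop("B must be >= 2")
  xy <- resolve_xy(features, response)
  x <- xy$x; y <- xy$y
  n <- nrow(x); m <- ncol(x)
  tfbs_ids <- colnames(x)
  subsets <- if (mode == "exhaustive") {
    if (n_subsets(m, max_model_size) > budget) {
      stop("exhaustive search over ", format(n_subsets(m, max_model_size)),
           " subsets exceeds the budget (", format(budget),
           "); use mode = \"forward\"")
    }
    enumerate_subsets(seq_len(m), max_model_size)
  } else NULL
  rc <- matrix(0, nrow = B, ncol = m, dimnames = list(NULL, tfbs_ids))
  sel <- matrix(FALSE, nrow = B, ncol = m, dimnames = list(NULL, tfbs_ids))
  n_redraws <- 0L
  with_local_seed(derive_seed(seed, 505L), {
    for (b in seq_len(B)) {
      if (scheme == "bootstrap") {
        attempts <- 0L
        repeat {
          idx <- sample.int(n, n, replace = TRUE)
          if (stats::var(y[idx]) > 0) break
          attempts <- attempts + 1L
          n_redraws <- n_redraws + 1L
          if (attempts >= 10L * B) {
            stop("could not draw a non-degenerate resample in ", 10L * B,
                 " attempts")
          }
        }
        res <- search_xy(x[idx, , drop = FALSE], y[idx], max_model_size,
                         mode, criterion, budget, subsets = subsets)
        chosen <- res$selected
        coefs <- res$coefficients[chosen]
      } else {
        k <- sample.int(min(max_model_size, m, n - 2L), 1L)
        chosen <- tfbs_ids[sort(sample.int(m, k))]
        f <- tryCatch(fit_linear(x, chosen, response = y, criterion = criterion),
                      error = function(e) NULL)
        if (is.null(f)) { chosen <- character(0); coefs <- numeric(0) }
        else coefs <- f$coefficients[chosen]
      }
      if (length(chosen)) {
        rc[b, chosen] <- coefs
        sel[b, chosen] <- TRUE
      }
    }
  })
  structure(list(rc = rc, selected = sel, tfbs_ids = tfbs_ids, B = B,
                 n_redraws = n_redraws, max_model_size = max_model_size,
                 mode = mode, criterion = criterion, scheme = scheme,
                 seed = seed),
            class = "rc_distributions")
}

#' @export
print.rc_distributions <- function(x, ...) {
  cat("rc_distributions:", x$B, "replicates x", length(x$tfbs_ids),
      "TFBSs (", x$scheme, "scheme,", x$mode, "search )\n")
  invisible(x)
}

#' One-sample t-test of an RC distribution against zero
#'
#' Significance of a TFBS's `B` regression coefficients under Bonferroni
#' control: significant when `min(1, p * n_tfbs_tested) < alpha`. The
#' degenerate zero-variance case follows the stated convention: a constant
#' nonzero RC is significant, a constant zero RC is not.
#'
#' @param rcs Numeric vector of regression coefficients (`length >= 2`).
#' @param n_tfbs_tested Size of the Bonferroni family.
#' @param alpha Significance level (default 0.01).
#' @return List with `mean_rc`, `t`, `p`, `p_bonferroni`, `significant`,
#'   and `sign` (`+1`/`-1` when significant, else `0`).
#' @export
test_rcs <- function(rcs, n_tfbs_tested, alpha = 0.01) {
  if (length(rcs) < 2) stop("need at least 2 regression coefficients")
  if (n_tfbs_tested < 1) stop("n_tfbs_tested must be >= 1")
  m <- mean(rcs)
  if (stats::var(rcs) == 0) {
    tstat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    tt <- stats::t.test(rcs, mu = 0)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
  }
  pb <- min(1, p * n_tfbs_tested)
  sig <- pb < alpha
  list(mean_rc = m, t = tstat, p = p, p_bonferroni = pb,
       significant = sig, sign = if (sig) sign(m) else 0)
}

# Summary table for a full rc_distributions object.
rc_table <- function(dist, alpha = 0.01) {
  stopifnot(inherits(dist, "rc_distributions"))
  ids <- sort(dist$tfbs_ids)
  rows <- lapply(ids, function(id) {
    r <- test_rcs(dist$rc[, id], n_tfbs_tested = length(dist$tfbs_ids),
                  alpha = alpha)
    data.frame(tfbs_id = id, mean_rc = r$mean_rc, t = r$t, p_raw = r$p,
               p_bonferroni = r$p_bonferroni,
               selection_frequency = mean(dist$selected[, id]),
               significant = r$significant, sign = r$sign,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify TFBS behaviour between two conditions
#'
#' Per TFBS over a shared universe: `identical` when significant in both
#' conditions with equal signs, `opposite` when significant in both with
#' unequal signs, `unique_to_A`/`unique_to_B` when significant in exactly
#' one, else `not_significant`.
#'
#' @param resA,resB Per-TFBS significance tables (from [summary.promoter_lm()]
#'   or [promoter_lm()]'s `table` element) with columns `tfbs_id`,
#'   `significant`, `sign`.
#' @return Data frame of class `"tfbs_classification"` with columns
#'   `tfbs_id`, `sign_A`, `sign_B`, `status`; per-status counts are available
#'   via `table(x$status)` and shown by the print method.
#' @export
classify_tfbs <- function(resA, resB) {
  a <- as.data.frame(resA); b <- as.data.frame(resB)
  if (!setequal(a$tfbs_id, b$tfbs_id)) {
    stop("the two conditions test different TFBS universes")
  }
  b <- b[match(a$tfbs_id, b$tfbs_id), ]
  status <- ifelse(a$significant & b$significant,
                   ifelse(a$sign == b$sign, "identical", "opposite"),
            ifelse(a$significant, "unique_to_A",
            ifelse(b$significant, "unique_to_B", "not_significant")))
  out <- data.frame(tfbs_id = a$tfbs_id,
                    sign_A = a$sign, sign_B = b$sign,
                    status = status, stringsAsFactors = FALSE)
  class(out) <- c("tfbs_classification", "data.frame")
  out
}

#' @export
print.tfbs_classification <- function(x, ...) {
  counts <- table(factor(x$status, levels = c("identical", "opposite",
                                              "unique_to_A", "unique_to_B",
                                              "not_significant")))
  cat("tfbs_classification over", nrow(x), "TFBSs:\n")
  print(counts)
  invisible(x)
}
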