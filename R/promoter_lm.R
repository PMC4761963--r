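#' Promoter regression model of TFBS activity
#'
#' The package's central fit: models per-gene expression (mean log2
#' abundance of one condition) as a linear function of promoter binding-site
#' counts, searching TFBS subsets for the best-fitting model and
#' bootstrapping the search to obtain a `B`-member regression-coefficient
#' (RC) distribution per TFBS. Each distribution is tested against zero by a
#' one-sample t-test under Bonferroni control over the TFBS universe.
#'
#' @param features A [feature_matrix()]; its response must be set unless
#'   `response` is supplied.
#' @param response Optional per-gene response overriding the one stored in
#'   `features`.
#' @param max_model_size Largest TFBS subset considered per fit (default 10).
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap stream.
#' @param mode Subset search: `"exhaustive"` enumeration (default, subject
#'   to `budget`) or greedy `"forward"` selection.
#' @param criterion Fit criterion: `"bic"` (default) or `"adjr2"`.
#' @param scheme RC-generation scheme: `"bootstrap"` (gene resampling,
#'   default) or `"subsets"` (random feature-subset fits).
#' @param alpha Bonferroni-adjusted significance level (default 0.01).
#' @param budget Exhaustive-mode subset budget (default `1e6`).
#' @return An object of class `"promoter_lm"` with elements `table` (per-TFBS
#'   data frame: `tfbs_id`, `mean_rc`, `t`, `p_raw`, `p_bonferroni`,
#'   `selection_frequency`, `significant`, `sign`), `dist` (the
#'   [bootstrap_rcs()] object), `best_fit` (full-data [search_models()] fit),
#'   `alpha`, `n_genes`, and the call. Methods: `print`, `summary`, `coef`
#'   (mean RCs), `predict`, `residuals`, `plot` (RC quantile plot).
#' @examples
#' x <- matrix(rpois(600, 1), 200, 3, dimnames = list(NULL, c("M1", "M2", "M3")))
#' rownames(x) <- sprintf("g%03d", 1:200)
#' y <- 1 + 2 * x[, "M1"] + rnorm(200, sd = 0.5)
#' fm <- feature_matrix(x, response = y)
#' fit <- promoter_lm(fm, B = 50, seed = 1)
#' summary(fit)
#' coef(fit)
#' @export
promoter_lm <- function(features, response = NULL, max_model_size = 10L,
                        B = 1000L, seed = 1L,
                        mode = c("exhaustive", "forward"),
                        criterion = c("bic", "adjr2"),
                        scheme = c("bootstrap", "subsets"),
                        alpha = 0.01, budget = 1e6) {
  mode <- match.arg(mode)
  criterion <- match.arg(criterion)
  scheme <- match.arg(scheme)
  xy <- resolve_xy(features, response)
  fm <- feature_matrix(xy$x, xy$y)
  dist <- bootstrap_rcs(fm, max_model_size = max_model_size, B = B,
                        seed = seed, mode = mode, criterion = criterion,
                        scheme = scheme, budget = budget)
  best <- search_models(fm, max_model_size = max_model_size, mode = mode,
                        criterion = criterion, budget = budget)
  structure(list(table = rc_table(dist, alpha = alpha), dist = dist,
                 best_fit = best, alpha = alpha, n_genes = nrow(fm$values),
                 features = fm, call = match.call()),
            class = "promoter_lm")
}

#' @export
print.promoter_lm <- function(x, ...) {
  cat("promoter_lm:", x$n_genes, "genes,", length(x$dist$tfbs_ids),
      "TFBSs,", x$dist$B, "bootstrap replicates\n")
  sig <- x$table[x$table$significant, ]
  cat("  significant TFBSs (Bonferroni <", x$alpha, "):", nrow(sig), "\n")
  if (nrow(sig)) {
    cat(" ", paste(sprintf("%s(%s)", sig$tfbs_id,
                           ifelse(sig$sign > 0, "+", "-")), collapse = " "), "\n")
  }
  cat("  best full-data model:",
      if (length(x$best_fit$selected_tfbs))
        paste(x$best_fit$selected_tfbs, collapse = " + ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' Per-TFBS significance table of a promoter regression model
#'
#' @param object A [promoter_lm()] fit.
#' @param ... Unused.
#' @return The per-TFBS data frame (see [promoter_lm()]), ordered by
#'   `tfbs_id`.
#' @export
summary.promoter_lm <- function(object, ...) {
  out <- object$table
  class(out) <- c("summary.promoter_lm", "data.frame")
  out
}

#' @export
print.summary.promoter_lm <- function(x, ...) {
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.promoter_lm <- function(object, which = c("mean_rc", "best_fit"), ...) {
  which <- match.arg(which)
  if (which == "mean_rc") {
    stats::setNames(object$table$mean_rc, object$table$tfbs_id)
  } else {
    object$best_fit$coefficients
  }
}

#' @export
predict.promoter_lm <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$features$values
       else if (inherits(newdata, "feature_matrix")) newdata$values
       else as.matrix(newdata)
  sel <- object$best_fit$selected_tfbs
  beta <- object$best_fit$coefficients
  pred <- rep(unname(beta[1]), nrow(x))
  if (length(sel)) pred <- pred + as.vector(x[, sel, drop = FALSE] %*% beta[sel])
  pred
}

#' @export
residuals.promoter_lm <- function(object, ...) {
  object$features$response - stats::predict(object)
}

#' RC quantile plot
#'
#' Draws the per-TFBS bootstrap RC distributions as quantile boxes (2.5, 25,
#' 50, 75, 97.5 percentiles), significant TFBSs filled, mirroring the usual
#' presentation of promoter-model coefficient distributions.
#'
#' @param x A [promoter_lm()] fit.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.promoter_lm <- function(x, ...) {
  ids <- x$table$tfbs_id
  rc <- x$dist$rc[, ids, drop = FALSE]
  qs <- apply(rc, 2L, stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  bx <- list(stats = qs, n = rep(x$dist$B, ncol(qs)),
             conf = qs[c(2, 4), , drop = FALSE], out = numeric(0),
             group = numeric(0), names = ids)
  graphics::bxp(bx, boxfill = ifelse(x$table$significant, "grey55", "white"),
                las = 2, ylab = "regression coefficient (RC)", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Refit the promoter model after excluding a gene subset
#'
#' Reruns the identical bootstrap pipeline (same seed and settings) on the
#' reduced gene set and reports the per-TFBS mean-RC shift, the device used
#' to probe which gene subpopulation drives a coefficient (e.g. removing
#' keratin genes from the modelled set).
#'
#' @param fit A [promoter_lm()] object.
#' @param excluded_genes Character vector of gene ids to drop; must leave at
#'   least `max_model_size + 2` genes.
#' @return List of class `"promoter_lm_refit"`: `fit` (the reduced-set
#'   [promoter_lm()]), `excluded`, and `shift` (data frame `tfbs_id`,
#'   `mean_rc_before`, `mean_rc_after`, `shift`).
#' @export
refit_excluding <- function(fit, excluded_genes) {
  stopifnot(inherits(fit, "promoter_lm"))
  genes <- rownames(fit$features$values)
  excluded_genes <- unique(excluded_genes)
  stray <- setdiff(excluded_genes, genes)
  if (length(stray)) {
    stop("excluded genes not in the model: ", paste(utils::head(stray, 5),
                                                    collapse = ", "))
  }
  keep <- setdiff(genes, excluded_genes)
  if (length(keep) < fit$dist$max_model_size + 2L) {
    stop("only ", length(keep), " genes would remain; need at least ",
         fit$dist$max_model_size + 2L)
  }
  sub <- feature_matrix(fit$features$values[keep, , drop = FALSE],
                        fit$features$response[keep])
  refit <- promoter_lm(sub, max_model_size = fit$dist$max_model_size,
                       B = fit$dist$B, seed = fit$dist$seed,
                       mode = fit$dist$mode, criterion = fit$dist$criterion,
                       scheme = fit$dist$scheme, alpha = fit$alpha)
  shift <- data.frame(tfbs_id = fit$table$tfbs_id,
                      mean_rc_before = fit$table$mean_rc,
                      mean_rc_after = refit$table$mean_rc,
                      shift = refit$table$mean_rc - fit$table$mean_rc,
                      stringsAsFactors = FALSE)
  structure(list(fit = refit, excluded = excluded_genes, shift = shift),
            class = "promoter_lm_refit")
}

#' @export
print.promoter_lm_refit <- function(x, ...) {
  cat("promoter_lm_refit:", length(x$excluded), "genes excluded\n")
  moved <- x$shift[order(-abs(x$shift$shift)), ]
  print(utils::head(moved, 5), digits = 4, row.names = FALSE)
  invisible(x)
}
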