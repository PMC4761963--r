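# Differential up-regulation calling, partitioning between two treatments,
# and the hypergeometric overlap/enrichment utilities.

#' Call up-regulated genes against a control condition
#'
#' Per gene: fold change \eqn{(mean_{treated} + \epsilon)/(mean_{control} +
#' \epsilon)} on the abundance scale, and a Welch two-sample t-test on
#' `log2(x + 1)` replicate values, with Benjamini-Hochberg q-values over all
#' tested genes. A gene is flagged up-regulated when `FC > fc_threshold` and
#' `q < fdr_threshold`.
#'
#' @param expr An [expression_matrix()].
#' @param control,treated Condition ids present in the design, each with at
#'   least 2 replicates.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold on q-values (default 0.05).
#' @param pseudocount \eqn{\epsilon} added to both means in the ratio
#'   (default 1), guarding division by zero on FPKM-scale data.
#' @return A data frame of class `"de_result"` with columns `gene_id`,
#'   `mean_control`, `mean_treated`, `fc`, `p`, `q`, `up`. Genes with zero
#'   variance in both groups get `p = 1` by convention (a message reports how
#'   many).
#' @export
call_upregulated <- function(expr, control, treated, fc_threshold = 2,
                             fdr_threshold = 0.05, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  for (cn in c(control, treated)) {
    k <- sum(expr$design$condition == cn)
    if (k == 0) stop("unknown condition '", cn, "'")
    if (k < 2) stop("condition '", cn, "' has fewer than 2 replicates")
  }
  xc <- log2p1(expr$values[, samples_of(expr, control), drop = FALSE])
  xt <- log2p1(expr$values[, samples_of(expr, treated), drop = FALSE])
  mc <- condition_means(expr, control)
  mt <- condition_means(expr, treated)
  n_flat <- 0L
  p <- vapply(seq_len(nrow(xc)), function(i) {
    a <- xt[i, ]; b <- xc[i, ]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      n_flat <<- n_flat + 1L
      return(1)
    }
    stats::t.test(a, b)$p.value
  }, numeric(1))
  if (n_flat > 0) {
    message(n_flat, " gene(s) with zero variance in both groups: p = 1 by convention")
  }
  q <- stats::p.adjust(p, method = "BH")
  fc <- (mt + pseudocount) / (mc + pseudocount)
  out <- data.frame(gene_id = rownames(expr$values),
                    mean_control = mc, mean_treated = mt,
                    fc = fc, p = p, q = q,
                    up = fc > fc_threshold & q < fdr_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "control") <- control
  attr(out, "treated") <- treated
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("de_result", "data.frame")
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat("de_result:", attr(x, "treated"), "vs", attr(x, "control"), "-",
      sum(x$up), "of", nrow(x), "genes up-regulated (FC >",
      attr(x, "fc_threshold"), ", q <", attr(x, "fdr_threshold"), ")\n")
  invisible(x)
}

#' Genes expressed in at least one condition
#'
#' @param expr An [expression_matrix()].
#' @param min_abundance A gene is expressed when its mean abundance exceeds
#'   this value in at least one condition (default 1, FPKM-like scale).
#' @return Character vector of gene ids.
#' @export
detect_expressed <- function(expr, min_abundance = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  means <- vapply(conditions_of(expr), function(cn) condition_means(expr, cn),
                  numeric(nrow(expr$values)))
  rownames(expr$values)[apply(as.matrix(means), 1L, max) > min_abundance]
}

#' Partition up-regulated genes between two treatments
#'
#' Splits the union of up-regulated genes into shared and condition-unique
#' sets, and calls differentially up-regulated genes (DUGs): genes whose
#' between-treatment condition-mean ratio (with the pseudocount of `deA`)
#' exceeds `dug_fc_threshold` in favour of a treatment in which they are
#' up-regulated versus control.
#'
#' @param deA,deB [call_upregulated()] results for the two treatments over
#'   the same gene universe.
#' @param dug_fc_threshold Between-treatment fold-change threshold
#'   (default 2).
#' @return An object of class `"gene_partition"`: a list with character-vector
#'   elements `shared`, `unique_to_A`, `unique_to_B`, `dug_A`, `dug_B`, and
#'   `up_all` (the union).
#' @export
partition_upregulated <- function(deA, deB, dug_fc_threshold = 2) {
  stopifnot(inherits(deA, "de_result"), inherits(deB, "de_result"))
  if (!identical(deA$gene_id, deB$gene_id)) {
    stop("the two DE results cover different gene universes")
  }
  eps <- attr(deA, "pseudocount") %||% 1
  upA <- deA$gene_id[deA$up]
  upB <- deB$gene_id[deB$up]
  fc_ab <- (deA$mean_treated + eps) / (deB$mean_treated + eps)
  names(fc_ab) <- deA$gene_id
  structure(list(
    shared = intersect(upA, upB),
    unique_to_A = setdiff(upA, upB),
    unique_to_B = setdiff(upB, upA),
    dug_A = intersect(upA, deA$gene_id[fc_ab > dug_fc_threshold]),
    dug_B = intersect(upB, deA$gene_id[1 / fc_ab > dug_fc_threshold]),
    up_all = union(upA, upB)
  ), class = "gene_partition")
}

#' @export
print.gene_partition <- function(x, ...) {
  cat("gene_partition:", length(x$up_all), "up-regulated genes\n",
      " shared:", length(x$shared),
      " unique A:", length(x$unique_to_A),
      " unique B:", length(x$unique_to_B), "\n",
      " DUGs:", length(x$dug_A) + length(x$dug_B),
      sprintf("(%d A, %d B)", length(x$dug_A), length(x$dug_B)), "\n")
  invisible(x)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the realized overlap when
#' `setA` is drawn from the universe and compared against `setB`, with a
#' Bonferroni adjustment for `n_tests` comparisons.
#'
#' @param setA,setB Character vectors, both subsets of `universe`.
#' @param universe Character vector of all eligible genes (non-empty).
#' @param n_tests Number of tests in the family (`>= 1`).
#' @return List with `overlap`, `p` (raw) and `p_adjusted`
#'   (`min(1, p * n_tests)`).
#' @export
overlap_test <- function(setA, setB, universe, n_tests = 1L) {
  if (!length(universe)) stop("empty universe")
  if (n_tests < 1) stop("n_tests must be >= 1")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (length(setdiff(setA, universe)) || length(setdiff(setB, universe))) {
    stop("both sets must be subsets of the universe")
  }
  k <- length(intersect(setA, setB))
  p <- stats::phyper(k - 1, length(setA), length(universe) - length(setA),
                     length(setB), lower.tail = FALSE)
  list(overlap = k, p = p, p_adjusted = min(1, p * n_tests))
}

#' Pearson correlation with a t-transform p-value
#'
#' @param x,y Numeric vectors of equal length `>= 3`; constant input is an
#'   error (the coefficient is undefined), never a silent `NaN`.
#' @return List with `r` and two-sided `p`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for zero-variance input")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Hypergeometric category enrichment with Bonferroni control
#'
#' Generic gene-set enrichment: per category, the upper-tail hypergeometric
#' probability of the query/category overlap within the universe, Bonferroni-
#' adjusted over the number of categories tested.
#'
#' @param query Character vector of genes of interest (subset of `universe`);
#'   an empty query yields `p = 1` for every category.
#' @param universe All eligible genes.
#' @param categories Named list of character vectors, each a subset of
#'   `universe`.
#' @param alpha Significance level on adjusted p-values (default 0.01).
#' @return Data frame with columns `category`, `size`, `overlap`, `p`,
#'   `p_adjusted`, `significant`.
#' @export
enrich_categories <- function(query, universe, categories, alpha = 0.01) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  if (length(setdiff(unlist(categories), universe))) {
    stop("category gene sets must be subsets of the universe")
  }
  n <- length(categories)
  rows <- lapply(names(categories), function(cn) {
    cat_set <- unique(categories[[cn]])
    k <- length(intersect(query, cat_set))
    p <- if (!length(query)) 1 else
      stats::phyper(k - 1, length(cat_set),
                    length(universe) - length(cat_set),
                    length(query), lower.tail = FALSE)
    data.frame(category = cn, size = length(cat_set), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- pmin(1, out$p * n)
  out$significant <- out$p_adjusted < alpha
  out
}
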