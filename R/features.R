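#' Gene x TFBS feature matrix
#'
#' Container pairing a genes x TFBS matrix of binding-site features (hit
#' counts by default) with an optional per-gene response (mean log2
#' expression of the modelled condition).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), TFBS
#'   ids in columns.
#' @param response Optional numeric vector, one value per gene, in row order
#'   (or named by gene id).
#' @return An object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(values, response = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene ids as rownames and TFBS ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (any(values < 0)) stop("feature values must be nonnegative")
  if (!is.null(response)) {
    if (!is.null(names(response))) {
      missing <- setdiff(rownames(values), names(response))
      if (length(missing)) {
        stop("response missing for genes: ", paste(utils::head(missing, 5), collapse = ", "))
      }
      response <- response[rownames(values)]
    }
    if (length(response) != nrow(values)) {
      stop("response length ", length(response), " != ", nrow(values), " genes")
    }
    response <- stats::setNames(as.numeric(response), rownames(values))
  }
  structure(list(values = values, response = response), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix:", nrow(x$values), "genes x", ncol(x$values), "TFBSs",
      if (is.null(x$response)) "(no response)" else "(with response)", "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' Attach a response vector to a feature matrix
#'
#' @param features A [feature_matrix()].
#' @param response Per-gene numeric response (named by gene id or in row order).
#' @return The feature matrix with the response set.
#' @export
set_response <- function(features, response) {
  stopifnot(inherits(features, "feature_matrix"))
  feature_matrix(features$values, response)
}

#' Build the gene x TFBS feature matrix from motif hits
#'
#' Each cell counts the hits of one PWM in one gene's promoter, both strands
#' combined. Genes without hits get zero rows; an optional binary encoding
#' records presence instead of counts.
#'
#' @param hits Hit table from [scan_promoters()].
#' @param genes Ordered character vector of gene ids (the modelled gene set);
#'   must contain every gene appearing in `hits` and no duplicates.
#' @param tfbs_ids Ordered character vector of PWM ids defining the columns.
#' @param encoding `"count"` (default) or `"presence"` (0/1).
#' @return A [feature_matrix()] (response unset).
#' @export
build_features <- function(hits, genes, tfbs_ids,
                           encoding = c("count", "presence")) {
  encoding <- match.arg(encoding)
  if (anyDuplicated(genes)) stop("duplicate gene ids in `genes`")
  stray <- setdiff(unique(hits$gene_id), genes)
  if (length(stray)) {
    stop("hits reference genes outside `genes`: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  m <- matrix(0, nrow = length(genes), ncol = length(tfbs_ids),
              dimnames = list(genes, tfbs_ids))
  if (nrow(hits)) {
    keep <- hits$pwm_id %in% tfbs_ids
    tab <- table(factor(hits$gene_id[keep], levels = genes),
                 factor(hits$pwm_id[keep], levels = tfbs_ids))
    m[] <- as.numeric(tab)
  }
  if (encoding == "presence") m[] <- as.numeric(m > 0)
  feature_matrix(m)
}

#' Scan promoters and assemble TFBS features in one step
#'
#' Convenience wrapper: scans every promoter with every PWM and tabulates hit
#' counts. Genes requested without a promoter record get an all-zero feature
#' row and a warning naming them.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param pwms List of [pwm()] objects.
#' @param genes Gene ids to model; defaults to `names(promoters)`.
#' @inheritParams scan_pwm
#' @inheritParams build_features
#' @return A [feature_matrix()].
#' @export
tfbs_features <- function(promoters, pwms, genes = names(promoters),
                          mss_cutoff = 0.85, css_cutoff = 0.90,
                          encoding = c("count", "presence")) {
  missing <- setdiff(genes, names(promoters))
  if (length(missing)) {
    warning(length(missing), " gene(s) without a promoter sequence get ",
            "all-zero features: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  present <- promoters[intersect(genes, names(promoters))]
  hits <- if (length(present)) {
    scan_promoters(pwms, present, mss_cutoff, css_cutoff)
  } else {
    data.frame(gene_id = character(), pwm_id = character())
  }
  tfbs_ids <- vapply(pwms, function(p) p$id, character(1))
  build_features(hits, genes, tfbs_ids, encoding = match.arg(encoding))
}
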