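#' Expression matrix with a condition/replicate design
#'
#' A genes x samples matrix of nonnegative FPKM-like abundances together with
#' a design mapping each sample to a condition and replicate index.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All values must be `>= 0` with no
#'   missing cells.
#' @param design Data frame with columns `sample`, `condition`, `replicate`;
#'   one row per column of `values`. If omitted, it is parsed from column
#'   names following the `<condition>_<replicate>` convention.
#' @return An object of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, design = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene ids as rownames and sample ids as colnames")
  }
  if (anyNA(values)) stop("expression values contain missing cells")
  if (any(values < 0)) stop("expression values must be nonnegative")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (is.null(design)) design <- parse_design(colnames(values))
  design <- as.data.frame(design)
  stopifnot(all(c("sample", "condition", "replicate") %in% names(design)))
  if (!identical(as.character(design$sample), colnames(values))) {
    stop("design samples must match value columns, in order")
  }
  structure(list(values = values, design = design), class = "expression_matrix")
}

# "<condition>_<replicate>" column-name convention; the last underscore splits.
parse_design <- function(sample_ids) {
  cond <- sub("_[^_]*$", "", sample_ids)
  repl <- sub("^.*_", "", sample_ids)
  if (any(cond == sample_ids)) {
    stop("sample names must follow the <condition>_<replicate> convention")
  }
  data.frame(sample = sample_ids, condition = cond, replicate = repl,
             stringsAsFactors = FALSE)
}

#' @export
print.expression_matrix <- function(x, ...) {
  tab <- table(x$design$condition)
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  conditions:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

conditions_of <- function(expr) unique(expr$design$condition)

samples_of <- function(expr, condition) {
  expr$design$sample[expr$design$condition == condition]
}

# per-gene mean abundance within one condition
condition_means <- function(expr, condition) {
  s <- samples_of(expr, condition)
  if (!length(s)) stop("unknown condition '", condition, "'")
  rowMeans(expr$values[, s, drop = FALSE])
}

log2p1 <- function(x) log2(x + 1)

#' Write / read the tab-delimited expression format
#'
#' First column `gene_id`, remaining columns one per sample named
#' `<condition>_<replicate>`.
#'
#' @param expr An [expression_matrix()].
#' @param file Path.
#' @return `read_expression()` returns an [expression_matrix()].
#' @export
write_expression <- function(expr, file) {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_expression
#' @export
read_expression <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  expression_matrix(vals)
}

#' Write / read promoters as FASTA
#'
#' One record per gene; the header is the bare gene id.
#'
#' @param promoters Named character vector of sequences.
#' @param file Path.
#' @return `read_promoters()` returns a named character vector.
#' @export
write_promoters <- function(promoters, file) {
  stopifnot(!is.null(names(promoters)))
  x <- Biostrings::DNAStringSet(unlist(promoters))
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(file) {
  x <- Biostrings::readDNAStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}
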