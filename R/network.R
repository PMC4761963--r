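# TF -> target network assembly and exchange formats.

#' Candidate transcription factors behind significant TFBSs
#'
#' Restricts the TFs bound to significant TFBSs to those whose coding genes
#' are themselves up-regulated. TF names without an entry in the map are
#' dropped with one warning reporting the count.
#'
#' @param pwms Named list of [pwm()] objects (their `tf_names` link matrices
#'   to factors).
#' @param tf_gene_map Named character vector: TF name -> coding-gene id.
#' @param upregulated Character vector of up-regulated gene ids.
#' @param significant_tfbs Character vector of significant PWM ids.
#' @return Character vector of TF names; the number of unmapped names is
#'   attached as attribute `"n_unmapped"`.
#' @export
candidate_tfs <- function(pwms, tf_gene_map, upregulated, significant_tfbs) {
  tf_names <- unique(unlist(lapply(pwms[names(pwms) %in% significant_tfbs],
                                   function(p) p$tf_names)))
  unmapped <- setdiff(tf_names, names(tf_gene_map))
  if (length(unmapped)) {
    warning(length(unmapped), " TF name(s) missing from tf_gene_map dropped: ",
            paste(utils::head(unmapped, 5), collapse = ", "))
  }
  mapped <- intersect(tf_names, names(tf_gene_map))
  out <- mapped[tf_gene_map[mapped] %in% upregulated]
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Build the TF -> DUG regulatory network
#'
#' Links a transcription factor to a differentially up-regulated gene when
#' any of the factor's PWMs has a positive feature value (at least one
#' binding site) in that gene's promoter. DUGs without any incoming edge are
#' kept as nodes and reported in `unlinked` — partial coverage is surfaced,
#' never dropped.
#'
#' @param tfs Character vector of TF names (e.g. from [candidate_tfs()]).
#' @param dugs Named character vector: gene id -> condition-dependency label
#'   (or a bare character vector of gene ids).
#' @param features A [feature_matrix()] whose rows include every DUG.
#' @param pwm_tf_links Data frame with columns `pwm_id`, `tf` linking
#'   matrices to factors (see [pwm_tf_table()]).
#' @return An object of class `"regulatory_network"`: list with `edges`
#'   (data frame `tf`, `gene`), `tf_nodes` (data frame `tf`, `out_degree`),
#'   `gene_nodes` (data frame `gene`, `label`) and `unlinked` (character).
#' @export
build_network <- function(tfs, dugs, features, pwm_tf_links) {
  stopifnot(inherits(features, "feature_matrix"))
  labels <- if (is.null(names(dugs))) {
    stats::setNames(rep("", length(dugs)), dugs)
  } else {
    stats::setNames(as.character(dugs), names(dugs))
  }
  genes <- names(labels)
  missing <- setdiff(genes, rownames(features$values))
  if (length(missing)) {
    stop("DUGs absent from the feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  vals <- features$values[genes, , drop = FALSE]
  edge_list <- list()
  for (tf in sort(unique(tfs))) {
    pids <- intersect(pwm_tf_links$pwm_id[pwm_tf_links$tf == tf],
                      colnames(vals))
    if (!length(pids)) next
    targets <- genes[rowSums(vals[, pids, drop = FALSE]) > 0]
    if (length(targets)) {
      edge_list[[tf]] <- data.frame(tf = tf, gene = targets,
                                    stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edge_list)) do.call(rbind, edge_list) else
    data.frame(tf = character(), gene = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new_network(edges, tfs = sort(unique(tfs)), gene_labels = labels)
}

# Internal constructor enforcing the degree/deduplication invariants.
new_network <- function(edges, tfs = character(), gene_labels = character()) {
  edges <- unique(edges[order(edges$tf, edges$gene), , drop = FALSE])
  rownames(edges) <- NULL
  tf_ids <- sort(union(tfs, edges$tf))
  gene_ids <- sort(union(names(gene_labels), edges$gene))
  deg <- table(factor(edges$tf, levels = tf_ids))
  labels <- stats::setNames(rep("", length(gene_ids)), gene_ids)
  labels[names(gene_labels)] <- gene_labels
  structure(list(
    edges = edges,
    tf_nodes = data.frame(tf = tf_ids, out_degree = as.integer(deg),
                          stringsAsFactors = FALSE),
    gene_nodes = data.frame(gene = gene_ids, label = unname(labels[gene_ids]),
                            stringsAsFactors = FALSE),
    unlinked = setdiff(gene_ids, edges$gene)
  ), class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$tf_nodes), "TFs ->",
      nrow(x$gene_nodes), "genes,", nrow(x$edges), "links\n")
  if (length(x$unlinked)) {
    cat("  unlinked genes:", length(x$unlinked), "\n")
  }
  invisible(x)
}

#' Merge two regulatory networks
#'
#' Node and edge union with deduplication; when the two networks label a
#' shared gene differently, the labels are concatenated with `";"`.
#'
#' @param a,b `"regulatory_network"` objects.
#' @return A merged `"regulatory_network"`.
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "regulatory_network"), inherits(b, "regulatory_network"))
  la <- stats::setNames(a$gene_nodes$label, a$gene_nodes$gene)
  lb <- stats::setNames(b$gene_nodes$label, b$gene_nodes$gene)
  genes <- union(names(la), names(lb))
  labels <- vapply(genes, function(g) {
    u <- unique(c(la[g], lb[g]))
    u <- u[!is.na(u) & nzchar(u)]
    paste(sort(u), collapse = ";")
  }, character(1))
  new_network(rbind(a$edges, b$edges),
              tfs = union(a$tf_nodes$tf, b$tf_nodes$tf),
              gene_labels = stats::setNames(labels, genes))
}

network_to_igraph <- function(net) {
  nodes <- data.frame(
    name = c(paste0("tf:", net$tf_nodes$tf), paste0("gene:", net$gene_nodes$gene)),
    node_id = c(net$tf_nodes$tf, net$gene_nodes$gene),
    role = c(rep("tf", nrow(net$tf_nodes)), rep("gene", nrow(net$gene_nodes))),
    out_degree = c(net$tf_nodes$out_degree, rep(0L, nrow(net$gene_nodes))),
    label = c(rep("", nrow(net$tf_nodes)), net$gene_nodes$label),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = paste0("tf:", net$edges$tf),
                      to = paste0("gene:", net$edges$gene),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

igraph_to_network <- function(g) {
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  tf_rows <- v$role == "tf"
  edges <- data.frame(tf = sub("^tf:", "", e$from),
                      gene = sub("^gene:", "", e$to), stringsAsFactors = FALSE)
  new_network(edges, tfs = v$node_id[tf_rows],
              gene_labels = stats::setNames(v$label[!tf_rows], v$node_id[!tf_rows]))
}

#' Export / read a regulatory network
#'
#' `"sif"` writes `tf regulates gene` lines (isolated nodes as single-token
#' lines; node attributes are not representable in SIF), `"edgelist"` a
#' 2-column table, `"graphml"` a GraphML document carrying node roles,
#' out-degrees and gene labels (via igraph). `read_network()` inverts each
#' format; a GraphML round trip preserves the network exactly.
#'
#' @param net A `"regulatory_network"`.
#' @param file Path.
#' @param format `"sif"`, `"graphml"` or `"edgelist"`.
#' @return `read_network()` returns a `"regulatory_network"`.
#' @export
export_network <- function(net, file, format = c("sif", "graphml", "edgelist")) {
  stopifnot(inherits(net, "regulatory_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\tregulates\t%s", net$edges$tf, net$edges$gene)
    iso <- c(setdiff(net$tf_nodes$tf, net$edges$tf),
             setdiff(net$gene_nodes$gene, net$edges$gene))
    writeLines(c(lines, iso), file)
  } else if (format == "edgelist") {
    utils::write.table(net$edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    igraph::write_graph(network_to_igraph(net), file, format = "graphml")
  }
  invisible(file)
}

#' @rdname export_network
#' @export
read_network <- function(file, format = c("sif", "graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    return(igraph_to_network(igraph::read_graph(file, format = "graphml")))
  }
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "edgelist") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- data.frame(tf = vapply(parts, `[`, "", 1L),
                        gene = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE)
    return(new_network(edges))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_edge <- lengths(parts) >= 3L
  edges <- data.frame(
    tf = vapply(parts[is_edge], `[`, "", 1L),
    gene = vapply(parts[is_edge], `[`, "", 3L), stringsAsFactors = FALSE)
  iso <- unlist(parts[!is_edge])
  # single-token SIF lines carry no role; treat unknown isolates as genes
  new_network(edges,
              gene_labels = stats::setNames(rep("", length(iso)), iso))
}

#' PWM -> TF link table
#'
#' Expands the `tf_names` of a PWM collection into the 2-column link table
#' consumed by [build_network()].
#'
#' @param pwms Named list of [pwm()] objects.
#' @return Data frame with columns `pwm_id`, `tf`.
#' @export
pwm_tf_table <- function(pwms) {
  rows <- lapply(pwms, function(p) {
    if (!length(p$tf_names)) return(NULL)
    data.frame(pwm_id = p$id, tf = p$tf_names, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out %||% data.frame(pwm_id = character(), tf = character())
}
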