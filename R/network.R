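#' Build the TF-target regulatory network
#'
#' Edges run from each significant TF (`p_adj <= alpha`) to every GOI gene in
#' that TF's target set — the regulatory wiring of the input list, restricted
#' to the genes the user supplied. Node attributes are computed on the
#' undirected projection: `degree` is the number of incident edges (a
#' self-regulating TF's loop counts once) and `neighborhood_connectivity` the
#' mean degree of a node's neighbors. GOI genes with no significant upstream
#' TF appear as isolated nodes (degree 0, connectivity 0) so the attribute
#' table covers the whole input set.
#'
#' @param result An `uptf_enrichment` computed against `db`.
#' @param goi `gene_set` used for the enrichment run.
#' @param db The `tf_target_db` used for the enrichment run.
#' @param alpha Significance threshold on `p_adj`.
#' @return List with `edges` (data.frame `source`, `interaction`, `target`)
#'   and `nodes` (data.frame `node`, `degree`, `neighborhood_connectivity`,
#'   `is_tf`).
#' @export
build_network <- function(result, goi, db, alpha = result$config$alpha) {
  stopifnot(inherits(result, "uptf_enrichment"), inherits(db, "tf_target_db"))
  goi <- unclass(goi)
  sig <- result$records$tf_id[result$records$p_adj <= alpha]
  sig <- sig[sig %in% names(db$entries)]
  if (!length(sig)) {
    warning("no significant TFs at alpha = ", alpha,
            "; network has no edges", call. = FALSE)
  }
  src <- character(0); tgt <- character(0)
  for (tf in sig) {
    hits <- intersect(goi, db$entries[[tf]])
    src <- c(src, rep(tf, length(hits)))
    tgt <- c(tgt, hits)
  }
  edges <- unique(data.frame(source = src,
                             interaction = rep("regulates", length(src)),
                             target = tgt))
  edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  nodes <- sort(unique(c(edges$source, edges$target, goi)), method = "radix")
  deg <- setNames(integer(length(nodes)), nodes)
  nbrs <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    deg[a] <- deg[a] + 1L
    if (b != a) deg[b] <- deg[b] + 1L
    nbrs[[a]] <- c(nbrs[[a]], b)
    if (b != a) nbrs[[b]] <- c(nbrs[[b]], a)
  }
  nc <- vapply(nodes, function(v) {
    nb <- setdiff(unique(nbrs[[v]]), v)
    if (!length(nb)) 0 else mean(deg[nb])
  }, numeric(1))
  attrs <- data.frame(node = nodes, degree = as.integer(deg),
                      neighborhood_connectivity = nc,
                      is_tf = nodes %in% sig, row.names = NULL)
  list(edges = edges, nodes = attrs)
}

#' Write network edges in Cytoscape SIF format
#'
#' One line per edge, `SOURCE<TAB>regulates<TAB>TARGET`, deduplicated and
#' sorted by (source, target) so output is byte-deterministic. The file loads
#' directly into Cytoscape via File > Import > Network.
#'
#' @param edges Edge data.frame from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(edges, path) {
  edges <- unique(edges[, c("source", "interaction", "target")])
  edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                 drop = FALSE]
  writeLines(if (nrow(edges)) paste(edges$source, edges$interaction,
                                    edges$target, sep = "\t") else character(0),
             path)
  invisible(path)
}

#' Write node attributes as TSV
#'
#' Header `node, degree, neighborhood_connectivity, is_tf`; rows sorted by
#' node ID. Imports into Cytoscape as a node attribute table for sizing nodes
#' by edge count and coloring by neighborhood connectivity.
#'
#' @param nodes Node data.frame from [build_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(nodes, path) {
  nodes <- nodes[order(nodes$node, method = "radix"), , drop = FALSE]
  utils::write.table(nodes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
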