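#' Read a lncRNA-miRNA or miRNA-mRNA interaction table
#'
#' @param path TSV with columns `source_id`, `target_id` and optionally
#'   `score`.
#' @param kind `"lnc_mirna"` or `"mirna_mrna"`.
#' @return data.frame with `source_id`, `target_id`, `kind` (and `score`).
#' @export
read_interactions <- function(path, kind = c("lnc_mirna", "mirna_mrna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) .fail("interaction table not found: %s", path)
  x <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  miss <- setdiff(c("source_id", "target_id"), names(x))
  if (length(miss)) .fail("interaction table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(x$source_id == x$target_id)) .fail("self-edges are not allowed")
  x$kind <- kind
  x
}

#' Build a lncRNA-miRNA-mRNA competing-endogenous-RNA network
#'
#' Starting from a focus lncRNA, keeps the miRNAs it interacts with, then
#' the mRNA targets of those miRNAs intersected with the supplied set of
#' upregulated differential protein-coding genes (matched by the caller to
#' the relevant tissue x timepoint). miRNAs left without any surviving mRNA
#' edge are pruned.
#'
#' @param lnc_mirna Interaction table (`source_id` = lncRNA,
#'   `target_id` = miRNA).
#' @param mirna_mrna Interaction table (`source_id` = miRNA,
#'   `target_id` = mRNA).
#' @param deg_up Character vector of upregulated differential coding genes.
#' @param focus_lnc The lncRNA at the center of the network.
#' @return A `cerna_network` list with `nodes` (id, type), `edges`
#'   (source_id, target_id, kind) and `focus_lnc`.
#' @export
build_cerna_network <- function(lnc_mirna, mirna_mrna, deg_up, focus_lnc) {
  if (!focus_lnc %in% lnc_mirna$source_id)
    .fail("focus lncRNA %s absent from the lncRNA-miRNA table", focus_lnc)
  mi <- unique(lnc_mirna$target_id[lnc_mirna$source_id == focus_lnc])
  mm <- mirna_mrna[mirna_mrna$source_id %in% mi &
                     mirna_mrna$target_id %in% deg_up, , drop = FALSE]
  mi_keep <- intersect(mi, unique(mm$source_id))
  edges <- rbind(
    if (length(mi_keep)) data.frame(source_id = focus_lnc, target_id = mi_keep,
                                    kind = "lnc_mirna", stringsAsFactors = FALSE),
    if (nrow(mm)) unique(data.frame(source_id = mm$source_id,
                                    target_id = mm$target_id,
                                    kind = "mirna_mrna", stringsAsFactors = FALSE))
  )
  if (is.null(edges)) edges <- data.frame(source_id = character(0),
                                          target_id = character(0),
                                          kind = character(0))
  nodes <- rbind(
    data.frame(id = focus_lnc, type = "lncRNA", stringsAsFactors = FALSE),
    if (length(mi_keep)) data.frame(id = sort(mi_keep), type = "miRNA"),
    if (nrow(mm)) data.frame(id = sort(unique(mm$target_id)), type = "mRNA")
  )
  structure(list(nodes = nodes, edges = edges, focus_lnc = focus_lnc),
            class = "cerna_network")
}

#' Summary statistics of a ceRNA network
#'
#' @param net A `cerna_network`.
#' @return List with node/edge counts by type, per-node degree table and
#'   the number of connected components.
#' @export
network_stats <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  deg <- table(factor(c(edges$source_id, edges$target_id), levels = nodes$id))
  n_comp <- if (!nrow(edges)) nrow(nodes) else {
    g <- igraph::graph_from_data_frame(edges[c("source_id", "target_id")],
                                       directed = FALSE,
                                       vertices = nodes$id)
    igraph::components(g)$no
  }
  list(
    n_nodes = nrow(nodes),
    n_edges = nrow(edges),
    nodes_by_type = table(nodes$type),
    degree = data.frame(id = names(deg), degree = as.integer(deg),
                        stringsAsFactors = FALSE),
    n_components = n_comp
  )
}

#' Write a ceRNA network as a TSV edge list plus JSON summary
#'
#' @param net A `cerna_network`.
#' @param edge_path,summary_path Output paths.
#' @return `edge_path`, invisibly.
#' @export
write_cerna_network <- function(net, edge_path, summary_path = NULL) {
  write.table(net$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    st <- network_stats(net)
    jsonlite::write_json(
      list(focus_lnc = net$focus_lnc, n_nodes = st$n_nodes,
           n_edges = st$n_edges, n_components = st$n_components,
           nodes_by_type = as.list(st$nodes_by_type)),
      summary_path, auto_unbox = TRUE)
  }
  invisible(edge_path)
}
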