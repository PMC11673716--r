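#' Flag biomarkers of exceptional relevance
#'
#' The default (`mode = "pooled"`) computes, within each requested hierarchy
#' level, the threshold `tau = mean + sd` over ALL pooled (node, prediction)
#' normalized relevance values of that level, and flags a node iff its
#' median relevance strictly exceeds `tau` and is positive. The
#' `"per_node"` variant applies the same rule node-wise (`tau_g = mean_g +
#' sd_g` over that node's own pooled values).
#'
#' @param agg an `xmn_agg` from [aggregate_global()].
#' @param level_filter levels to threshold (default genes, level `"D"`).
#' @param mode `"pooled"` or `"per_node"`.
#' @return an object of class `xmn_biomarkers`: list with `table`
#'   (data.frame: node_id, level, median_relevance, threshold, flagged,
#'   mode), `flagged` (character vector of flagged node ids), `mode`,
#'   `thresholds` (named per level, pooled mode only).
#' @export
threshold_biomarkers <- function(agg, level_filter = "D",
                                 mode = c("pooled", "per_node")) {
  stopifnot(inherits(agg, "xmn_agg"))
  mode <- match.arg(mode)
  tab <- agg$table[agg$table$level %in% level_filter, , drop = FALSE]
  if (!nrow(tab)) xmn_abort("no nodes at requested level(s)")

  if (mode == "pooled") {
    thresholds <- setNames(numeric(length(level_filter)), level_filter)
    tau_of <- numeric(nrow(tab))
    for (lv in level_filter) {
      cols <- tab$node_id[tab$level == lv]
      if (!length(cols)) next
      pooled <- as.vector(agg$values[, cols, drop = FALSE])
      if (length(pooled) < 2L) xmn_abort("fewer than 2 pooled values at level ", lv)
      thresholds[lv] <- mean(pooled) + sd(pooled)
      tau_of[tab$level == lv] <- thresholds[lv]
    }
  } else {
    if (tab$n[1] < 2L) xmn_abort("fewer than 2 pooled values per node")
    tau_of <- tab$mean + tab$std
    thresholds <- NULL
  }
  flagged <- tab$median > tau_of & tab$median > 0
  out <- data.frame(
    node_id = tab$node_id, level = tab$level,
    median_relevance = tab$median, threshold = tau_of,
    flagged = flagged, mode = mode,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(table = out, flagged = out$node_id[out$flagged],
         mode = mode, thresholds = thresholds),
    class = "xmn_biomarkers"
  )
}

#' @export
print.xmn_biomarkers <- function(x, ...) {
  cat("Biomarkers (", x$mode, " threshold): ", length(x$flagged), " of ",
      nrow(x$table), " nodes flagged\n", sep = "")
  if (length(x$flagged)) print(x$table[x$table$flagged, ], row.names = FALSE)
  invisible(x)
}

#' Write the biomarker table
#' @param bm an `xmn_biomarkers`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(bm, path) {
  write.table(bm$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the relevance network for graph viewers
#'
#' Writes (i) a SIF edge file `child<TAB>part_of<TAB>parent`, (ii) a node
#' attribute CSV (`node_id, level, median_relevance, flagged`) and (iii) a
#' GraphML file carrying the same attributes, suitable for Cytoscape-style
#' rendering of relevant genes and pathways. With `flagged_only = TRUE` the
#' export is restricted to the sub-network induced by the flagged nodes and
#' their ancestors (up to the output node).
#'
#' @param h an `xmn_hierarchy`.
#' @param agg an `xmn_agg` (median relevance per node; nodes without an
#'   aggregate, e.g. the output node, get relevance 0).
#' @param biomarkers an `xmn_biomarkers` (or NULL: nothing flagged).
#' @param dir output directory.
#' @param flagged_only restrict to flagged nodes + ancestors?
#' @return named character vector of the files written, invisibly.
#' @export
export_relevance_network <- function(h, agg, biomarkers = NULL, dir,
                                     flagged_only = FALSE) {
  validate_hierarchy(h)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flagged <- if (is.null(biomarkers)) character(0) else biomarkers$flagged

  nodes <- h$nodes
  edges <- h$edges
  if (flagged_only) {
    keep <- union(flagged, hierarchy_ancestors(h, flagged))
    keep <- union(keep, nodes$id[nodes$level == "O"])
    nodes <- nodes[nodes$id %in% keep, , drop = FALSE]
    edges <- edges[edges$child_id %in% keep & edges$parent_id %in% keep, , drop = FALSE]
  }
  med <- setNames(agg$table$median, agg$table$node_id)
  attrs <- data.frame(
    node_id = nodes$id,
    level = nodes$level,
    median_relevance = ifelse(nodes$id %in% names(med), med[nodes$id], 0),
    flagged = nodes$id %in% flagged,
    row.names = NULL, stringsAsFactors = FALSE
  )

  sif <- file.path(dir, "relevance_network.sif")
  writeLines(
    if (nrow(edges)) paste(edges$child_id, "part_of", edges$parent_id, sep = "\t") else character(0),
    sif
  )
  csv <- file.path(dir, "relevance_nodes.csv")
  utils::write.csv(attrs, csv, row.names = FALSE, quote = FALSE)

  g <- igraph::graph_from_data_frame(
    d = edges, directed = TRUE,
    vertices = attrs
  )
  gml <- file.path(dir, "relevance_network.graphml")
  igraph::write_graph(g, gml, format = "graphml")

  invisible(c(sif = sif, nodes = csv, graphml = gml))
}
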