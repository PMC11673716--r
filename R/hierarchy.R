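#' Functional hierarchies
#'
#' A functional hierarchy is a levelled DAG with five levels: genes at level
#' `D`, pathways at `C`, pathway groups at `B`, top categories at `A` and a
#' single output node at `O`. Edges connect adjacent levels only (D-C, C-B,
#' B-A, A-O) and always point from child (lower level) to parent (upper
#' level). The hierarchy defines the wiring of the modular network: every
#' C/B/A/O node becomes a neural module whose inputs are the outputs of its
#' children.
#'
#' @param nodes data.frame with columns `id`, `level`, `name`.
#' @param edges data.frame with columns `child_id`, `parent_id`.
#' @return An object of class `xmn_hierarchy`: a list with `nodes` (data.frame
#'   `id`, `level`, `name`), `edges` (data.frame `child_id`, `parent_id`) and
#'   precomputed adjacency lists `children` and `parents` (named lists of
#'   character vectors, one entry per node).
#' @export
hierarchy <- function(nodes, edges) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need <- setdiff(c("id", "level", "name"), names(nodes))
  if (length(need)) xmn_abort("node table misses column(s): ", paste(need, collapse = ", "))
  need <- setdiff(c("child_id", "parent_id"), names(edges))
  if (length(need)) xmn_abort("edge table misses column(s): ", paste(need, collapse = ", "))

  nodes <- data.frame(
    id = as.character(nodes$id),
    level = as.character(nodes$level),
    name = as.character(nodes$name),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    child_id = as.character(edges$child_id),
    parent_id = as.character(edges$parent_id),
    stringsAsFactors = FALSE
  )
  ## canonical order: by level, then id — file order must not matter
  nodes <- nodes[order(match(nodes$level, LEVELS), nodes$id), , drop = FALSE]
  edges <- unique(edges[order(edges$child_id, edges$parent_id), , drop = FALSE])
  rownames(nodes) <- rownames(edges) <- NULL

  h <- structure(list(nodes = nodes, edges = edges), class = "xmn_hierarchy")
  h <- xmn_index(h)
  validate_hierarchy(h)
  h
}

xmn_index <- function(h) {
  ids <- h$nodes$id
  ch <- pa <- setNames(vector("list", length(ids)), ids)
  for (i in seq_along(ids)) ch[[i]] <- pa[[i]] <- character(0)
  if (nrow(h$edges)) {
    ch_split <- split(h$edges$child_id, h$edges$parent_id)
    pa_split <- split(h$edges$parent_id, h$edges$child_id)
    ch[names(ch_split)] <- lapply(ch_split, sort)
    pa[names(pa_split)] <- lapply(pa_split, sort)
  }
  h$children <- ch
  h$parents <- pa
  h
}

#' Validate a functional hierarchy
#'
#' Checks all structural invariants: unique ids, known levels, edges between
#' adjacent levels only, exactly one output node, every non-output node with
#' at least one parent and every non-gene node with at least one child.
#'
#' @param h an `xmn_hierarchy`.
#' @return `h`, invisibly; errors describe the first violation found.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "xmn_hierarchy"))
  nodes <- h$nodes
  edges <- h$edges

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) xmn_abort("duplicate node id: ", dup[1])
  bad <- setdiff(unique(nodes$level), LEVELS)
  if (length(bad)) xmn_abort("unknown level '", bad[1], "' (expected D, C, B, A, O)")

  lvl <- setNames(nodes$level, nodes$id)
  miss <- setdiff(unique(c(edges$child_id, edges$parent_id)), nodes$id)
  if (length(miss)) xmn_abort("edge references unknown node id: ", miss[1])

  if (nrow(edges)) {
    ci <- match(lvl[edges$child_id], LEVELS)
    pi <- match(lvl[edges$parent_id], LEVELS)
    bad <- which(pi != ci + 1L)
    if (length(bad)) {
      b <- bad[1]
      xmn_abort(
        "edge between non-adjacent levels ", lvl[edges$child_id[b]], "→",
        lvl[edges$parent_id[b]], ": ", edges$child_id[b], " → ", edges$parent_id[b]
      )
    }
  }

  n_o <- sum(nodes$level == "O")
  if (n_o == 0L) xmn_abort("missing output node (level O)")
  if (n_o > 1L) xmn_abort("more than one output node (level O)")

  no_parent <- nodes$id[nodes$level != "O" & lengths(h$parents[nodes$id]) == 0L]
  if (length(no_parent)) xmn_abort("node without parent: ", no_parent[1])
  no_child <- nodes$id[nodes$level != "D" & lengths(h$children[nodes$id]) == 0L]
  if (length(no_child)) xmn_abort("non-gene node without children: ", no_child[1])
  invisible(h)
}

#' Load a hierarchy from node/edge TSV files or a single JSON file
#'
#' The TSV dialect is `nodes.tsv` with header `id  level  name` and
#' `edges.tsv` with header `child_id  parent_id` (tab-separated, UTF-8).
#' Alternatively a single JSON file `{"nodes": [...], "edges": [...]}` with
#' the same fields can be given as `node_path` (detected by the `.json`
#' extension or by leaving `edge_path` unset).
#'
#' @param node_path path to `nodes.tsv` or to a JSON hierarchy file.
#' @param edge_path path to `edges.tsv`; omit for JSON input.
#' @return an `xmn_hierarchy`.
#' @export
load_hierarchy <- function(node_path, edge_path = NULL) {
  if (is.null(edge_path) || grepl("\\.json$", node_path, ignore.case = TRUE)) {
    obj <- jsonlite::fromJSON(node_path, simplifyDataFrame = TRUE)
    return(hierarchy(as.data.frame(obj$nodes), as.data.frame(obj$edges)))
  }
  for (p in c(node_path, edge_path)) {
    if (!file.exists(p)) xmn_abort("file not found: ", p)
  }
  nodes <- read.delim(node_path, colClasses = "character")
  edges <- read.delim(edge_path, colClasses = "character")
  hierarchy(nodes, edges)
}

#' Write a hierarchy to TSV or JSON
#'
#' @param h an `xmn_hierarchy`.
#' @param node_path output path for `nodes.tsv`, or a `.json` path for the
#'   single-file form.
#' @param edge_path output path for `edges.tsv`; omit for JSON output.
#' @return the path(s) written, invisibly.
#' @export
write_hierarchy <- function(h, node_path, edge_path = NULL) {
  validate_hierarchy(h)
  if (is.null(edge_path) || grepl("\\.json$", node_path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(nodes = h$nodes, edges = h$edges), node_path,
      dataframe = "rows", auto_unbox = TRUE
    )
    return(invisible(node_path))
  }
  write.table(h$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(h$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' Gene (level-D) identifiers of a hierarchy, in canonical order
#' @param h an `xmn_hierarchy`.
#' @return character vector of gene ids, sorted.
#' @export
hierarchy_genes <- function(h) {
  sort(h$nodes$id[h$nodes$level == "D"])
}

#' Prune a hierarchy to the measured genes
#'
#' Gene nodes absent from `measured_genes` are removed; any pathway node left
#' without children is then removed, cascading upward through levels C, B and
#' A. The output node is never removed. The result is a valid hierarchy (the
#' operation is idempotent, and with the full gene set it is the identity).
#'
#' @param h an `xmn_hierarchy`.
#' @param measured_genes character vector of measured gene ids.
#' @return the pruned `xmn_hierarchy`.
#' @export
prune_to_genes <- function(h, measured_genes) {
  validate_hierarchy(h)
  measured_genes <- as.character(measured_genes)
  if (!length(measured_genes)) xmn_abort("measured_genes must be non-empty")
  genes <- h$nodes$id[h$nodes$level == "D"]
  keep <- intersect(genes, measured_genes)
  if (!length(keep)) xmn_abort("no measured genes in hierarchy")

  alive <- setNames(h$nodes$level %in% "O", h$nodes$id) # O always survives
  alive[keep] <- TRUE
  for (lv in c("C", "B", "A")) {
    ids <- h$nodes$id[h$nodes$level == lv]
    for (id in ids) alive[id] <- any(alive[h$children[[id]]])
  }
  nodes <- h$nodes[alive[h$nodes$id], , drop = FALSE]
  edges <- h$edges[alive[h$edges$child_id] & alive[h$edges$parent_id], , drop = FALSE]
  hierarchy(nodes, edges)
}

#' Summary statistics of a hierarchy
#'
#' @param h an `xmn_hierarchy`.
#' @return list with `n_nodes` (named count per level, all five levels),
#'   `n_edges`, and `fanout`: a summary of the number of children per
#'   non-gene node (min/median/mean/max).
#' @export
hierarchy_stats <- function(h) {
  validate_hierarchy(h)
  counts <- setNames(integer(length(LEVELS)), LEVELS)
  tab <- table(h$nodes$level)
  counts[names(tab)] <- as.integer(tab)
  mods <- h$nodes$id[h$nodes$level != "D"]
  fan <- lengths(h$children[mods])
  list(
    n_nodes = counts,
    n_edges = nrow(h$edges),
    fanout = c(
      min = as.numeric(min(fan)), median = as.numeric(median(fan)),
      mean = mean(fan), max = as.numeric(max(fan))
    )
  )
}

#' @export
print.xmn_hierarchy <- function(x, ...) {
  s <- hierarchy_stats(x)
  cat("Functional hierarchy:",
      paste(sprintf("%s=%d", names(s$n_nodes), s$n_nodes), collapse = " "),
      sprintf("| %d edges\n", s$n_edges))
  invisible(x)
}

#' Ancestors of a set of nodes (transitive parents, excluding the nodes)
#' @param h an `xmn_hierarchy`.
#' @param ids character vector of node ids.
#' @return character vector of ancestor ids (sorted, unique).
#' @export
hierarchy_ancestors <- function(h, ids) {
  out <- character(0)
  frontier <- unique(as.character(ids))
  while (length(frontier)) {
    up <- unique(unlist(h$parents[frontier], use.names = FALSE))
    up <- setdiff(up, out)
    out <- c(out, up)
    frontier <- up
  }
  sort(setdiff(out, ids))
}
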