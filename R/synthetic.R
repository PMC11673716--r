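#' Specification of a synthetic benchmark dataset
#'
#' Describes a two-class expression study with a known ground truth: a
#' functional hierarchy over `n_genes` genes, Gaussian log-scale background
#' expression, and a set of planted discriminative genes shifted by
#' `effect_size` noise standard deviations in the second class. The defaults
#' describe a 200-gene panel with 10 planted genes of effect 3 sigma and 100
#' samples per class; `n_per_class` accepts unequal counts to emulate class
#' imbalance. `membership_fanout` is the mean number of parents per node
#' (1 = a tree; 2 adds on average one extra pathway membership per gene).
#'
#' @param n_genes,n_C,n_B,n_A node counts per level.
#' @param membership_fanout mean parents per non-root node (>= 1).
#' @param n_per_class integer vector of per-class sample counts (length =
#'   number of classes, >= 2).
#' @param n_planted number of planted discriminative genes.
#' @param effect_size mean shift of planted genes in class 2, in units of
#'   `noise_sigma`.
#' @param noise_sigma standard deviation of the Gaussian background.
#' @param ar1_rho optional AR(1) correlation between genes within a C
#'   pathway (0 = independent background).
#' @param classes class labels.
#' @param seed RNG seed.
#' @return an object of class `xmn_synth_spec`.
#' @export
synthetic_spec <- function(n_genes = 200L, n_C = 20L, n_B = 6L, n_A = 2L,
                           membership_fanout = 1, n_per_class = c(100L, 100L),
                           n_planted = 10L, effect_size = 3, noise_sigma = 1,
                           ar1_rho = 0, classes = NULL, seed = 1L) {
  if (any(c(n_genes, n_C, n_B, n_A) < 1L)) xmn_abort("all level counts must be >= 1")
  if (n_genes < n_C || n_C < n_B || n_B < n_A) {
    xmn_abort("counts must be feasible: n_genes >= n_C >= n_B >= n_A")
  }
  if (membership_fanout < 1) xmn_abort("membership_fanout must be >= 1")
  if (length(n_per_class) < 2L) xmn_abort("need at least 2 classes")
  if (n_planted > n_genes) xmn_abort("n_planted exceeds n_genes")
  if (effect_size < 0 || noise_sigma <= 0) xmn_abort("effect_size >= 0, noise_sigma > 0")
  if (is.null(classes)) classes <- paste0("class", seq_along(n_per_class))
  structure(
    list(
      n_genes = as.integer(n_genes), n_C = as.integer(n_C),
      n_B = as.integer(n_B), n_A = as.integer(n_A),
      membership_fanout = membership_fanout,
      n_per_class = as.integer(n_per_class), n_planted = as.integer(n_planted),
      effect_size = effect_size, noise_sigma = noise_sigma,
      ar1_rho = ar1_rho, classes = classes, seed = as.integer(seed)
    ),
    class = "xmn_synth_spec"
  )
}

pad_ids <- function(prefix, n) sprintf("%s%0*d", prefix, max(2L, nchar(n)), seq_len(n))

## Assign each of n_child children to parents: one guaranteed parent
## (round-robin so every parent is non-empty), plus extra memberships with
## probability (fanout - 1) each, drawn uniformly among the other parents.
assign_parents <- function(child_ids, parent_ids, fanout) {
  n_p <- length(parent_ids)
  primary <- parent_ids[((seq_along(child_ids) - 1L) %% n_p) + 1L]
  edges <- data.frame(child_id = child_ids, parent_id = primary,
                      stringsAsFactors = FALSE)
  p_extra <- min(fanout - 1, 1)
  if (p_extra > 0 && n_p > 1L) {
    extra <- runif(length(child_ids)) < p_extra
    if (any(extra)) {
      others <- vapply(which(extra), function(i) {
        pool <- setdiff(parent_ids, primary[i])
        pool[sample.int(length(pool), 1L)]
      }, character(1))
      edges <- rbind(edges, data.frame(child_id = child_ids[extra],
                                       parent_id = others,
                                       stringsAsFactors = FALSE))
    }
  }
  edges
}

#' Generate a synthetic functional hierarchy
#'
#' Builds a valid hierarchy with the requested node counts: every gene
#' belongs to at least one C pathway, every C to at least one B group, every
#' B to at least one A category, every A to the single output node. With
#' `membership_fanout > 1` some nodes get additional parents
#' (multi-membership). Deterministic per seed.
#'
#' @param spec an [synthetic_spec()].
#' @return list with `hierarchy` (an `xmn_hierarchy`) and `truth`: planted
#'   gene ids and the C/B/A modules containing planted genes.
#' @export
make_hierarchy <- function(spec) {
  stopifnot(inherits(spec, "xmn_synth_spec"))
  set.seed(spec$seed)
  genes <- pad_ids("g", spec$n_genes)
  cs <- pad_ids("c", spec$n_C)
  bs <- pad_ids("b", spec$n_B)
  as_ <- pad_ids("a", spec$n_A)

  nodes <- data.frame(
    id = c(genes, cs, bs, as_, "output"),
    level = c(rep("D", spec$n_genes), rep("C", spec$n_C),
              rep("B", spec$n_B), rep("A", spec$n_A), "O"),
    name = c(genes, cs, bs, as_, "output"),
    stringsAsFactors = FALSE
  )
  edges <- rbind(
    assign_parents(genes, cs, spec$membership_fanout),
    assign_parents(cs, bs, spec$membership_fanout),
    assign_parents(bs, as_, spec$membership_fanout),
    data.frame(child_id = as_, parent_id = "output", stringsAsFactors = FALSE)
  )
  h <- hierarchy(nodes, edges)

  planted <- sort(sample(genes, spec$n_planted))
  anc <- hierarchy_ancestors(h, planted)
  lvl <- setNames(h$nodes$level, h$nodes$id)
  truth <- list(
    planted_genes = planted,
    planted_C = sort(anc[lvl[anc] == "C"]),
    planted_B = sort(anc[lvl[anc] == "B"]),
    planted_A = sort(anc[lvl[anc] == "A"])
  )
  list(hierarchy = h, truth = truth)
}

#' Generate a synthetic two-class expression dataset
#'
#' Background genes are i.i.d. Normal(0, sigma^2) in every class (optionally
#' AR(1)-correlated within each C pathway); planted genes get an additional
#' `+ effect_size * sigma` mean shift in the second class. Values emulate
#' already log-transformed expression. Class counts honour
#' `spec$n_per_class` exactly. Deterministic per seed.
#'
#' @param spec an [synthetic_spec()].
#' @param hgen result of [make_hierarchy()] (generated from `spec` if NULL).
#' @return list with `expression` (gene-by-sample matrix), `labels` (factor
#'   named by sample id), `hierarchy`, `truth`.
#' @export
make_expression <- function(spec, hgen = NULL) {
  stopifnot(inherits(spec, "xmn_synth_spec"))
  if (is.null(hgen)) hgen <- make_hierarchy(spec)
  h <- hgen$hierarchy
  truth <- hgen$truth
  genes <- pad_ids("g", spec$n_genes)

  n <- sum(spec$n_per_class)
  samples <- pad_ids("s", n)
  labels <- factor(rep(spec$classes, spec$n_per_class), levels = spec$classes)
  names(labels) <- samples

  set.seed(spec$seed + 1L)
  x <- matrix(rnorm(spec$n_genes * n, 0, spec$noise_sigma), spec$n_genes, n,
              dimnames = list(genes, samples))
  if (spec$ar1_rho > 0) {
    ## AR(1) dependence along the gene order within each C pathway
    rho <- spec$ar1_rho
    for (cid in h$nodes$id[h$nodes$level == "C"]) {
      g <- intersect(genes, h$children[[cid]])
      if (length(g) < 2L) next
      for (i in 2:length(g)) {
        x[g[i], ] <- rho * x[g[i - 1L], ] + sqrt(1 - rho^2) * x[g[i], ]
      }
    }
  }
  shift <- spec$effect_size * spec$noise_sigma
  x[truth$planted_genes, labels == spec$classes[2]] <-
    x[truth$planted_genes, labels == spec$classes[2], drop = FALSE] + shift

  list(expression = x, labels = labels, hierarchy = h, truth = truth)
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `nodes.tsv`, `edges.tsv`, `expression.tsv`, `labels.tsv` and
#' `truth.json`.
#'
#' @param spec an [synthetic_spec()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_synthetic <- function(spec, dir) {
  data <- make_expression(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    nodes = file.path(dir, "nodes.tsv"),
    edges = file.path(dir, "edges.tsv"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_hierarchy(data$hierarchy, paths[["nodes"]], paths[["edges"]])
  write_expression(data$expression, paths[["expression"]])
  write_labels(data$labels, paths[["labels"]])
  jsonlite::write_json(data$truth, paths[["truth"]], auto_unbox = FALSE)
  invisible(paths)
}
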