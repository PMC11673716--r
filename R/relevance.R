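#' Epsilon-rule relevance propagation through one linear layer
#'
#' Redistributes upper-layer relevance `R` to the layer inputs:
#' `R_j = sum_k a_j w_jk / (z_k + eps * sign(z_k)) * R_k` with
#' `z_k = sum_j a_j w_jk + b_k` and `sign(0) = +1`. With `epsilon = 0` and no
#' bias the redistribution is conservative (`sum R_j = sum R_k`); a positive
#' epsilon absorbs relevance at near-zero pre-activations, stabilising the
#' division. Nonlinear activations pass relevance through unchanged, so this
#' single rule covers the whole backward pass.
#'
#' @param a input activations: vector (one sample) or sample-by-input matrix.
#' @param w input-by-output weight matrix.
#' @param b optional bias vector (absorbs relevance).
#' @param R upper relevance: vector or sample-by-output matrix.
#' @param epsilon stabiliser, >= 0.
#' @return lower relevance, same shape as `a`.
#' @export
lrp_linear_epsilon <- function(a, w, b = NULL, R, epsilon = 0) {
  vec <- is.null(dim(a))
  if (vec) a <- matrix(a, 1L)
  if (is.null(dim(R))) R <- matrix(R, 1L)
  stopifnot(ncol(a) == nrow(w), ncol(R) == ncol(w), epsilon >= 0)
  Z <- a %*% w
  if (!is.null(b)) Z <- sweep(Z, 2L, b, "+")
  sgn <- ifelse(Z >= 0, 1, -1) # sign(0) treated as +1
  S <- R / (Z + epsilon * sgn)
  out <- a * (S %*% t(w))
  if (vec) out[1L, ] else out
}

#' Explain predictions by layer-wise relevance propagation
#'
#' Seeds relevance at the output-module head score of a start class (by
#' default each sample's predicted class) and propagates it backwards along
#' the forward wiring: through the output head, down every module's internal
#' layers with the epsilon rule, and from each module's input to its
#' children. At fan-out nodes relevance arriving from multiple parents is
#' summed. Auxiliary heads of non-output modules feed nothing forward and
#' therefore carry no relevance. Gene relevance is read at the input layer;
#' each module's relevance is the sum over its last internal layer's
#' neurons.
#'
#' @param net an `xmn_network`.
#' @param x sample-by-gene input matrix (or single named vector).
#' @param start_class `NULL` (predicted class per sample) or a single class
#'   label used for every sample.
#' @param epsilon stabiliser for [lrp_linear_epsilon()].
#' @param fwd optional precomputed [forward()] result.
#' @return an object of class `xmn_relevance`: list with `gene` (sample-by-
#'   gene relevance matrix), `module` (sample-by-module relevance matrix),
#'   `start_class` (factor per sample), `seed_score` (the propagated head
#'   scores), `epsilon`, `sample_ids`.
#' @export
lrp_explain <- function(net, x, start_class = NULL, epsilon = 1e-6, fwd = NULL) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  if (is.null(fwd)) fwd <- forward(net, x)
  n <- fwd$n
  L <- length(net$spec$layer_widths)
  lvl <- setNames(net$hierarchy$nodes$level, net$hierarchy$nodes$id)
  o_id <- net$hierarchy$nodes$id[lvl == "O"]

  if (is.null(start_class)) {
    cls <- predict_network(net, fwd = fwd)$class
  } else {
    if (!start_class %in% net$classes) xmn_abort("unknown start_class: ", start_class)
    cls <- factor(rep(start_class, n), levels = net$classes)
  }
  ci <- as.integer(cls)
  scores <- fwd$head_scores[[o_id]]
  seed_score <- scores[cbind(seq_len(n), ci)]

  ## relevance seeded at the head output: only the start class carries its score
  R_head <- matrix(0, n, net$spec$n_classes)
  R_head[cbind(seq_len(n), ci)] <- seed_score

  R_last <- setNames(vector("list", length(net$topo)), net$topo)
  gene_rel <- matrix(0, n, length(net$gene_ids),
                     dimnames = list(rownames(x), net$gene_ids))
  mod_rel <- matrix(0, n, length(net$topo),
                    dimnames = list(rownames(x), net$topo))

  for (id in rev(net$topo)) {
    m <- net$modules[[id]]
    a <- fwd$acts[[id]]
    R <- if (id == o_id) {
      lrp_linear_epsilon(a$layers[[L]], m$Wh, m$bh, R_head, epsilon)
    } else {
      R_last[[id]]
    }
    if (is.null(R)) R <- matrix(0, n, net$spec$layer_widths[L]) # unreachable module
    mod_rel[, id] <- rowSums(R)
    for (k in rev(seq_len(L))) {
      A_prev <- if (k > 1L) a$layers[[k - 1L]] else a$input
      R <- lrp_linear_epsilon(A_prev, m$W[[k]], m$b[[k]], R, epsilon)
    }
    for (cid in m$children) {
      seg <- R[, m$slices[[cid]], drop = FALSE]
      if (lvl[[cid]] == "D") {
        gene_rel[, cid] <- gene_rel[, cid] + seg[, 1L]
      } else {
        R_last[[cid]] <- if (is.null(R_last[[cid]])) seg else R_last[[cid]] + seg
      }
    }
  }
  structure(
    list(
      gene = gene_rel, module = mod_rel,
      start_class = cls, seed_score = seed_score, epsilon = epsilon,
      sample_ids = rownames(x)
    ),
    class = "xmn_relevance"
  )
}

#' Per-module scalar relevance of a relevance map
#'
#' The module relevance is the sum of relevance over the module's last
#' internal-layer neurons; [lrp_explain()] records it, this accessor returns
#' it (samples x modules).
#'
#' @param rmap an `xmn_relevance`.
#' @return numeric sample-by-module matrix.
#' @export
module_relevance <- function(rmap) {
  stopifnot(inherits(rmap, "xmn_relevance"))
  rmap$module
}

#' Normalize relevance within each hierarchy level
#'
#' Divides every node's relevance by the absolute sum over its level (genes
#' form level D; C, B, A are each one level), per sample, so that
#' `sum(|relevance|) = 1` within each level. Relative signs and ratios
#' inside a level are preserved, making values comparable across
#' cross-validation splits. An all-zero level is left as zeros (with a
#' warning). The operation is idempotent.
#'
#' @param values numeric matrix, samples in rows, nodes in columns.
#' @param levels character vector: the hierarchy level of each column.
#' @return the normalized matrix.
#' @export
normalize_layerwise <- function(values, levels) {
  if (is.null(dim(values))) values <- matrix(values, 1L, dimnames = list(NULL, names(values)))
  stopifnot(ncol(values) == length(levels))
  warned <- FALSE
  for (lv in unique(levels)) {
    cols <- which(levels == lv)
    denom <- rowSums(abs(values[, cols, drop = FALSE]))
    zero <- denom == 0
    if (any(zero) && !warned) {
      warning("all-zero relevance in level ", lv, " for ", sum(zero),
              " sample(s); left as zeros")
      warned <- TRUE
    }
    denom[zero] <- 1
    values[, cols] <- values[, cols, drop = FALSE] / denom
  }
  values
}

#' Explain all pooled test predictions of a cross-validation
#'
#' For every split, runs [lrp_explain()] with that split's selected model on
#' its held-out test fold (inputs centered with the split's stored gene
#' means), normalizes each sample's relevance per hierarchy level and pools
#' everything: the result covers each sample exactly once.
#'
#' @param cv an `xmn_cv` from [run_crossval()].
#' @param x the gene-by-sample expression matrix used for the CV.
#' @param start_class `NULL` (predicted class) or a fixed class label.
#' @param epsilon LRP stabiliser.
#' @param normalize normalize per level before pooling? (default TRUE)
#' @return an object of class `xmn_cohort_relevance`: list with `values`
#'   (pooled sample-by-node matrix over genes and modules), `node_levels`,
#'   `start_class`, `true_class`, `sample_ids`, `epsilon`.
#' @export
explain_crossval <- function(cv, x, start_class = NULL, epsilon = 1e-6,
                             normalize = TRUE) {
  stopifnot(inherits(cv, "xmn_cv"))
  h <- cv$hierarchy
  genes <- hierarchy_genes(h)
  x <- x[genes, , drop = FALSE]
  lvl <- setNames(h$nodes$level, h$nodes$id)

  out <- list()
  truth <- list()
  starts <- list()
  for (split in seq_len(cv$folds$k)) {
    model <- cv$models[[split]]
    id_te <- names(cv$folds$fold_of)[cv$folds$fold_of %in% cv$roles[[split]]$test]
    xt <- t(mean_center(x[, id_te, drop = FALSE], means = model$gene_means))
    rmap <- lrp_explain(model$net, xt, start_class = start_class, epsilon = epsilon)
    vals <- cbind(rmap$gene, rmap$module)
    if (normalize) {
      vals <- normalize_layerwise(vals, unname(lvl[colnames(vals)]))
    }
    out[[split]] <- vals
    truth[[split]] <- cv$predictions$true[match(id_te, cv$predictions$sample_id)]
    starts[[split]] <- as.character(rmap$start_class)
  }
  values <- do.call(rbind, out)
  structure(
    list(
      values = values,
      node_levels = setNames(unname(lvl[colnames(values)]), colnames(values)),
      start_class = factor(unlist(starts), levels = cv$classes),
      true_class = factor(unlist(truth), levels = cv$classes),
      sample_ids = rownames(values),
      epsilon = epsilon
    ),
    class = "xmn_cohort_relevance"
  )
}

#' Aggregate normalized relevance across pooled predictions
#'
#' Per node: median, mean and standard deviation of the normalized relevance
#' over all pooled test predictions, plus per-class medians.
#'
#' @param rel an `xmn_cohort_relevance` (or a bare sample-by-node matrix).
#' @param node_levels required if `rel` is a bare matrix.
#' @param by_class optional factor per row for per-class aggregates
#'   (defaults to `rel$true_class` when available).
#' @return an object of class `xmn_agg`: list with `table` (data.frame:
#'   node_id, level, median, mean, std, n, median_<class>...) and `values`
#'   (the pooled matrix, retained for thresholding).
#' @export
aggregate_global <- function(rel, node_levels = NULL, by_class = NULL) {
  if (inherits(rel, "xmn_cohort_relevance")) {
    values <- rel$values
    node_levels <- rel$node_levels
    if (is.null(by_class)) by_class <- rel$true_class
  } else {
    values <- rel
    if (is.null(node_levels)) xmn_abort("node_levels required for matrix input")
  }
  if (nrow(values) < 1L) xmn_abort("need at least one prediction to aggregate")
  tab <- data.frame(
    node_id = colnames(values),
    level = unname(node_levels[colnames(values)]),
    median = apply(values, 2L, median),
    mean = colMeans(values),
    std = apply(values, 2L, sd),
    n = nrow(values),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(by_class)) {
    for (cl in levels(as.factor(by_class))) {
      rows <- which(by_class == cl)
      tab[[paste0("median_", cl)]] <- if (length(rows)) {
        apply(values[rows, , drop = FALSE], 2L, median)
      } else {
        NA_real_
      }
    }
  }
  structure(list(table = tab, values = values), class = "xmn_agg")
}

#' @export
print.xmn_agg <- function(x, ...) {
  cat("Aggregated relevance over", x$table$n[1], "predictions,",
      nrow(x$table), "nodes\n")
  top <- x$table[order(-x$table$median), c("node_id", "level", "median")]
  print(head(top, 5), row.names = FALSE)
  invisible(x)
}

#' Write relevance tables as TSV
#'
#' `relevance_per_sample.tsv`: sample_id, node_id, level, relevance (long
#' format); `relevance_global.tsv`: node_id, level, median, mean, std, n.
#'
#' @param rel an `xmn_cohort_relevance`.
#' @param agg an `xmn_agg`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_relevance <- function(rel, agg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- data.frame(
    sample_id = rep(rel$sample_ids, times = ncol(rel$values)),
    node_id = rep(colnames(rel$values), each = nrow(rel$values)),
    level = rep(unname(rel$node_levels), each = nrow(rel$values)),
    relevance = as.vector(rel$values)
  )
  write.table(long, file.path(dir, "relevance_per_sample.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(agg$table, file.path(dir, "relevance_global.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
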