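#' Module architecture specification
#'
#' Every hierarchy node at levels C, B, A and O is realised as a small neural
#' module: a stack of internal layers (default three layers of three neurons)
#' fed by the concatenated outputs of the node's children, plus a linear
#' classifier head (the module-output layer) used only for the multi-loss.
#' Gene children contribute one input each; module children contribute their
#' last internal layer (so `tail(layer_widths, 1)` inputs). All internal
#' layers use `activation` except the last, which is the identity; heads are
#' linear, with softmax applied inside the loss.
#'
#' Bias placement follows the sparse-explanation design: the first internal
#' layer (the module-input layer carrying the L1-penalised inter-module
#' weights), the last internal layer and the head are bias-free by default;
#' intermediate layers carry biases.
#'
#' @param layer_widths integer vector of internal layer widths.
#' @param activation `"tanh"` (the only nonlinearity currently supported).
#' @param n_classes number of output classes (>= 2).
#' @param input_bias,hidden_bias,last_bias,head_bias logical bias flags for
#'   the first internal layer, intermediate layers, last internal layer and
#'   the classifier head.
#' @return an object of class `xmn_module_spec`.
#' @export
module_spec <- function(layer_widths = c(3L, 3L, 3L), activation = "tanh",
                        n_classes = 2L, input_bias = FALSE, hidden_bias = TRUE,
                        last_bias = FALSE, head_bias = FALSE) {
  layer_widths <- as.integer(layer_widths)
  if (!length(layer_widths) || any(layer_widths < 1L)) {
    xmn_abort("layer_widths must be non-empty positive integers")
  }
  if (!identical(activation, "tanh")) xmn_abort("unsupported activation: ", activation)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) xmn_abort("n_classes must be >= 2")
  L <- length(layer_widths)
  bias <- logical(L)
  bias[1] <- isTRUE(input_bias)
  if (L > 2L) bias[2:(L - 1L)] <- isTRUE(hidden_bias)
  bias[L] <- isTRUE(last_bias)
  structure(
    list(
      layer_widths = layer_widths, activation = activation,
      n_classes = n_classes, layer_bias = bias, head_bias = isTRUE(head_bias)
    ),
    class = "xmn_module_spec"
  )
}

xavier_init <- function(n_in, n_out) {
  ## normalized Xavier: uniform on +/- sqrt(6 / (fan_in + fan_out))
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Build a modular network from a hierarchy
#'
#' Creates one module per C/B/A/O node, wired so that each module's first
#' layer receives the concatenation of its children's outputs (genes as
#' scalars, child modules via their last internal layer). Weights are drawn
#' with normalized-Xavier initialisation; enabled biases start at zero. The
#' same seed always yields bit-identical parameters.
#'
#' @param h an `xmn_hierarchy`.
#' @param spec an [module_spec()].
#' @param seed integer RNG seed.
#' @param classes character vector of class labels (length `spec$n_classes`);
#'   defaults to `class1..classK`.
#' @return an object of class `xmn_network`: list with `hierarchy`, `spec`,
#'   `seed`, `classes`, `gene_ids` (input order), `topo` (module evaluation
#'   order) and `modules` (per module: `children`, per-child input slices,
#'   weight matrices `W[[k]]`, biases `b[[k]]` or NULL, head `Wh`/`bh`).
#' @export
build_network <- function(h, spec, seed = 1L, classes = NULL) {
  validate_hierarchy(h)
  stopifnot(inherits(spec, "xmn_module_spec"))
  if (!any(h$nodes$level == "C")) xmn_abort("hierarchy has no level-C modules")
  if (is.null(classes)) classes <- paste0("class", seq_len(spec$n_classes))
  if (length(classes) != spec$n_classes) xmn_abort("classes length must equal n_classes")

  gene_ids <- hierarchy_genes(h)
  ## deterministic evaluation order: C, then B, A, O; ids sorted within level
  topo <- unlist(lapply(MODULE_LEVELS, function(lv) {
    sort(h$nodes$id[h$nodes$level == lv])
  }), use.names = FALSE)

  widths <- spec$layer_widths
  L <- length(widths)
  out_w <- widths[L]
  lvl <- setNames(h$nodes$level, h$nodes$id)

  set.seed(as.integer(seed))
  modules <- setNames(vector("list", length(topo)), topo)
  for (id in topo) {
    children <- h$children[[id]] # sorted
    child_w <- ifelse(lvl[children] == "D", 1L, out_w)
    ends <- cumsum(child_w)
    slices <- Map(function(s, e) s:e, ends - child_w + 1L, ends)
    names(slices) <- children
    n_in <- sum(child_w)

    W <- vector("list", L)
    b <- vector("list", L)
    prev <- n_in
    for (k in seq_len(L)) {
      W[[k]] <- xavier_init(prev, widths[k])
      ## `b[k] <- list(...)`: plain [[<- NULL would drop the element
      b[k] <- list(if (spec$layer_bias[k]) numeric(widths[k]) else NULL)
      prev <- widths[k]
    }
    Wh <- xavier_init(out_w, spec$n_classes)
    bh <- if (spec$head_bias) numeric(spec$n_classes) else NULL
    modules[[id]] <- list(
      id = id, level = unname(lvl[id]), children = children,
      slices = slices, n_in = n_in, W = W, b = b, Wh = Wh, bh = bh
    )
  }
  structure(
    list(
      hierarchy = h, spec = spec, seed = as.integer(seed), classes = classes,
      gene_ids = gene_ids, topo = topo, modules = modules
    ),
    class = "xmn_network"
  )
}

#' Number of trainable parameters
#' @param net an `xmn_network`.
#' @param per_module return a named vector per module instead of the total?
#' @return integer count(s).
#' @export
count_parameters <- function(net, per_module = FALSE) {
  per <- vapply(net$modules, function(m) {
    sum(lengths(m$W)) + sum(lengths(m$b)) + length(m$Wh) + length(m$bh)
  }, integer(1))
  if (per_module) per else sum(per)
}

## Assemble a module's input matrix (samples x n_in) from gene inputs and
## child-module activations.
module_input <- function(m, X, acts, out_w) {
  parts <- lapply(m$children, function(cid) {
    if (is.null(acts[[cid]])) X[, cid, drop = FALSE] else acts[[cid]]
  })
  do.call(cbind, parts)
}

#' Forward pass through the modular network
#'
#' Evaluates every module in topological order (children before parents) and
#' returns all head scores and internal activations. The pass is a pure
#' function of (parameters, input).
#'
#' @param net an `xmn_network`.
#' @param x numeric sample-by-gene matrix (or a single named vector) whose
#'   columns cover `net$gene_ids`; extra columns are ignored.
#' @return an object of class `xmn_forward`: list with `head_scores` (list of
#'   sample-by-class score matrices per module id), `acts` (per module: the
#'   input matrix and every internal layer's output) and `n` (sample count).
#' @export
forward <- function(net, x) {
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  if (is.null(colnames(x))) {
    if (ncol(x) != length(net$gene_ids)) {
      xmn_abort("unnamed input must have exactly ", length(net$gene_ids), " columns")
    }
    colnames(x) <- net$gene_ids
  }
  miss <- setdiff(net$gene_ids, colnames(x))
  if (length(miss)) xmn_abort("input misses gene(s): ", miss[1])
  x <- x[, net$gene_ids, drop = FALSE]
  if (any(!is.finite(x))) xmn_abort("non-finite value in input")

  L <- length(net$spec$layer_widths)
  out_w <- net$spec$layer_widths[L]
  last <- setNames(vector("list", length(net$topo)), net$topo)
  acts <- setNames(vector("list", length(net$topo)), net$topo)
  scores <- setNames(vector("list", length(net$topo)), net$topo)

  for (id in net$topo) {
    m <- net$modules[[id]]
    A <- module_input(m, x, last, out_w)
    layer_out <- vector("list", L)
    inp <- A
    for (k in seq_len(L)) {
      Z <- A %*% m$W[[k]]
      if (!is.null(m$b[[k]])) Z <- sweep(Z, 2L, m$b[[k]], "+")
      A <- if (k < L) tanh(Z) else Z
      layer_out[[k]] <- A
    }
    S <- A %*% m$Wh
    if (!is.null(m$bh)) S <- sweep(S, 2L, m$bh, "+")
    colnames(S) <- net$classes
    last[[id]] <- A
    acts[[id]] <- list(input = inp, layers = layer_out)
    scores[[id]] <- S
  }
  structure(
    list(head_scores = scores, acts = acts, n = nrow(x)),
    class = "xmn_forward"
  )
}

softmax <- function(S) {
  ## row-wise, log-sum-exp stabilised
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Class probabilities and predictions from the output module
#'
#' @param net an `xmn_network`.
#' @param x input matrix as in [forward()].
#' @param fwd optional precomputed [forward()] result.
#' @return list with `prob` (sample-by-class softmax of the output-module
#'   head) and `class` (factor of argmax predictions; ties break to the
#'   first class).
#' @export
predict_network <- function(net, x = NULL, fwd = NULL) {
  if (is.null(fwd)) fwd <- forward(net, x)
  o_id <- net$hierarchy$nodes$id[net$hierarchy$nodes$level == "O"]
  P <- softmax(fwd$head_scores[[o_id]])
  cls <- factor(net$classes[max.col(P, ties.method = "first")], levels = net$classes)
  list(prob = P, class = cls)
}

#' @export
print.xmn_network <- function(x, ...) {
  cat(
    "Modular network:", length(x$modules), "modules over",
    length(x$gene_ids), "genes;", count_parameters(x), "parameters;",
    length(x$classes), "classes\n"
  )
  invisible(x)
}

## Deep-copy of module parameters (for checkpoints).
snapshot_params <- function(net) {
  lapply(net$modules, function(m) list(W = m$W, b = m$b, Wh = m$Wh, bh = m$bh))
}

restore_params <- function(net, snap) {
  for (id in names(snap)) {
    net$modules[[id]]$W <- snap[[id]]$W
    net$modules[[id]]$b <- snap[[id]]$b
    net$modules[[id]]$Wh <- snap[[id]]$Wh
    net$modules[[id]]$bh <- snap[[id]]$bh
  }
  net
}

## Weight matrices are stored as explicit {dim, data} pairs (column-major)
## so the JSON reader can rebuild them without shape guessing.
mat_out <- function(w) list(dim = dim(w), data = as.vector(w))
mat_in <- function(o) matrix(as.numeric(unlist(o$data)), unlist(o$dim)[1], unlist(o$dim)[2])

#' Save / load a network checkpoint
#'
#' The checkpoint is a single JSON file (format `xmodnn-checkpoint`,
#' version 1) carrying the hierarchy, the module spec, the seed, the class
#' labels and every parameter array keyed by module id and layer index.
#' Values round-trip at 15 significant digits.
#'
#' @param net an `xmn_network`.
#' @param path output path (`.json`).
#' @return `path` invisibly for `save_network`; an `xmn_network` for
#'   `load_network`.
#' @export
save_network <- function(net, path) {
  params <- lapply(net$modules, function(m) {
    list(
      W = lapply(m$W, mat_out),
      b = lapply(m$b, function(v) if (is.null(v)) NULL else as.vector(v)),
      Wh = mat_out(m$Wh),
      bh = if (is.null(m$bh)) NULL else as.vector(m$bh)
    )
  })
  obj <- list(
    format = "xmodnn-checkpoint", version = 1L,
    hierarchy = list(nodes = as.list(net$hierarchy$nodes),
                     edges = as.list(net$hierarchy$edges)),
    spec = unclass(net$spec), seed = net$seed, classes = net$classes,
    params = params
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(unlist(obj$format), "xmodnn-checkpoint")) {
    xmn_abort("not an xmodnn checkpoint: ", path)
  }
  col <- function(x) unlist(x, use.names = FALSE)
  h <- hierarchy(
    data.frame(id = col(obj$hierarchy$nodes$id),
               level = col(obj$hierarchy$nodes$level),
               name = col(obj$hierarchy$nodes$name)),
    data.frame(child_id = col(obj$hierarchy$edges$child_id),
               parent_id = col(obj$hierarchy$edges$parent_id))
  )
  bias <- as.logical(col(obj$spec$layer_bias))
  sp <- module_spec(
    layer_widths = col(obj$spec$layer_widths),
    activation = col(obj$spec$activation),
    n_classes = col(obj$spec$n_classes),
    input_bias = bias[1],
    hidden_bias = if (length(bias) > 2L) bias[2] else TRUE,
    last_bias = bias[length(bias)],
    head_bias = as.logical(col(obj$spec$head_bias))
  )
  net <- build_network(h, sp, seed = col(obj$seed), classes = col(obj$classes))
  for (id in names(net$modules)) {
    p <- obj$params[[id]]
    if (is.null(p)) xmn_abort("checkpoint misses parameters for module ", id)
    net$modules[[id]]$W <- lapply(p$W, mat_in)
    net$modules[[id]]$b <- lapply(p$b, function(v) {
      if (is.null(v) || !length(v)) NULL else as.numeric(unlist(v))
    })
    net$modules[[id]]$Wh <- mat_in(p$Wh)
    net$modules[[id]]["bh"] <- list(
      if (is.null(p$bh) || !length(p$bh)) NULL else as.numeric(unlist(p$bh))
    )
  }
  net
}
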