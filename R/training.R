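#' Training configuration
#'
#' Defaults follow the tuned hyperparameter set for the modular network:
#' learning rate 0.01, mini-batch 32, L1 penalty 0.01 on all weights and 0.1
#' on the first module-hidden (module-input) layer, multi-loss layer weights
#' C:1.3, B:1.2, A:1.1, O:1.0, and progressive inclusion of module layers at
#' epochs C:1, B:2, A:4, O:6 (1-indexed). Class weights for the weighted
#' cross-entropy are computed automatically from the class frequencies.
#'
#' @param learning_rate optimizer step size.
#' @param batch_size mini-batch size.
#' @param max_epochs number of epochs to run (model selection afterwards is
#'   by validation loss, see [select_best()]).
#' @param loss_weights named numeric, multi-loss weight per module level.
#' @param inclusion_epochs named integer, first epoch (1-indexed) at which
#'   each module level joins the objective; must be non-decreasing C..O.
#' @param l1_all L1 multiplier for all weight blocks except the first
#'   internal layer (biases never penalised).
#' @param l1_input L1 multiplier for first-internal-layer weight blocks.
#' @param class_weight_mode `"automatic"` (balanced: n/(K*n_c)) or
#'   `"manual"` (then `class_weights` must be given).
#' @param class_weights named numeric, used when mode is `"manual"`.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param layer_reduce aggregate module losses within a level by `"sum"`
#'   (default) or `"mean"` before applying the level weight.
#' @param center `"train_only"` (centering statistics from the training
#'   split, applied to held-out splits) or `"global"`.
#' @param seed RNG seed for initialisation and batch shuffling.
#' @return an object of class `xmn_train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 32L, max_epochs = 30L,
                         loss_weights = c(C = 1.3, B = 1.2, A = 1.1, O = 1.0),
                         inclusion_epochs = c(C = 1L, B = 2L, A = 4L, O = 6L),
                         l1_all = 0.01, l1_input = 0.1,
                         class_weight_mode = c("automatic", "manual"),
                         class_weights = NULL,
                         optimizer = c("adam", "sgd"),
                         layer_reduce = c("sum", "mean"),
                         center = c("train_only", "global"),
                         seed = 1L) {
  class_weight_mode <- match.arg(class_weight_mode)
  optimizer <- match.arg(optimizer)
  layer_reduce <- match.arg(layer_reduce)
  center <- match.arg(center)
  if (learning_rate <= 0 || l1_all < 0 || l1_input < 0) {
    xmn_abort("rates and penalties must be positive")
  }
  miss <- setdiff(MODULE_LEVELS, names(loss_weights))
  if (length(miss)) xmn_abort("loss_weights misses level(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(MODULE_LEVELS, names(inclusion_epochs))
  if (length(miss)) xmn_abort("inclusion_epochs misses level(s): ", paste(miss, collapse = ", "))
  inc <- as.integer(inclusion_epochs[MODULE_LEVELS])
  if (any(diff(inc) < 0L)) xmn_abort("inclusion_epochs must be non-decreasing C <= B <= A <= O")
  if (any(inc < 1L)) xmn_abort("inclusion_epochs are 1-indexed and must be >= 1")
  if (class_weight_mode == "manual" && is.null(class_weights)) {
    xmn_abort("manual class_weight_mode requires class_weights")
  }
  structure(
    list(
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs),
      loss_weights = loss_weights[MODULE_LEVELS],
      inclusion_epochs = setNames(inc, MODULE_LEVELS),
      l1_all = l1_all, l1_input = l1_input,
      class_weight_mode = class_weight_mode, class_weights = class_weights,
      optimizer = optimizer, layer_reduce = layer_reduce, center = center,
      seed = as.integer(seed)
    ),
    class = "xmn_train_config"
  )
}

#' Balanced class weights for the weighted cross-entropy
#'
#' `w_c = n_total / (n_classes * n_c)`: equal-frequency classes get weight 1,
#' minority classes get up-weighted proportionally.
#'
#' @param labels factor of class labels (its levels define the classes).
#' @return named numeric vector of weights, one per class.
#' @export
class_weights <- function(labels) {
  labels <- as.factor(labels)
  counts <- table(labels)
  if (length(counts) < 2L) xmn_abort("need at least 2 classes")
  if (any(counts == 0L)) {
    xmn_abort("class with zero samples: ", names(counts)[counts == 0][1])
  }
  n <- sum(counts)
  setNames(as.numeric(n / (length(counts) * counts)), names(counts))
}

log_softmax <- function(S) {
  m <- apply(S, 1L, max)
  S - m - log(rowSums(exp(S - m)))
}

#' Weighted cross-entropy loss
#'
#' `loss_i = -w_{y_i} * log softmax(scores_i)[y_i]`, averaged over samples.
#' Log-sum-exp stabilised.
#'
#' @param scores numeric class-score vector (one sample) or sample-by-class
#'   matrix.
#' @param y class labels: integer indices or factor/character matching the
#'   score columns / `classes`.
#' @param w named numeric class weights (default: all 1).
#' @param classes class labels ordering the score columns; defaults to the
#'   score matrix's colnames.
#' @return mean weighted negative log-likelihood (nats).
#' @export
weighted_cross_entropy <- function(scores, y, w = NULL, classes = NULL) {
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  if (is.null(classes)) classes <- colnames(scores)
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(scores)))
  yi <- if (is.numeric(y)) as.integer(y) else match(as.character(y), classes)
  if (any(is.na(yi)) || any(yi < 1L) || any(yi > ncol(scores))) {
    xmn_abort("labels do not match score columns")
  }
  if (is.null(w)) w <- setNames(rep(1, length(classes)), classes)
  wv <- if (is.null(names(w))) rep_len(w, length(classes)) else as.numeric(w[classes])
  LS <- log_softmax(scores)
  mean(-wv[yi] * LS[cbind(seq_len(nrow(scores)), yi)])
}

#' Module levels active in the progressive schedule at a given epoch
#'
#' @param epoch 1-indexed epoch.
#' @param cfg an [train_config()].
#' @return character vector of active levels (subset of C, B, A, O).
#' @export
active_layers <- function(epoch, cfg) {
  stopifnot(epoch >= 1)
  MODULE_LEVELS[epoch >= cfg$inclusion_epochs[MODULE_LEVELS]]
}

#' Weighted multi-loss over active module layers
#'
#' `total = sum over active levels l of loss_weights[l] * reduce(module
#' losses at l)` where `reduce` is a sum (default) or mean per
#' `cfg$layer_reduce`. Inactive levels contribute nothing.
#'
#' @param module_losses named numeric: per-module head loss.
#' @param h the `xmn_hierarchy` (for module levels).
#' @param cfg an [train_config()].
#' @param epoch 1-indexed epoch determining the active set.
#' @return total weighted multi-loss (scalar).
#' @export
multi_loss <- function(module_losses, h, cfg, epoch = Inf) {
  lvl <- setNames(h$nodes$level, h$nodes$id)
  act <- if (is.infinite(epoch)) MODULE_LEVELS else active_layers(epoch, cfg)
  total <- 0
  for (l in act) {
    ids <- intersect(names(module_losses), names(lvl)[lvl == l])
    if (!length(ids)) {
      if (any(lvl == l)) xmn_abort("missing module losses for active level ", l)
      next
    }
    red <- if (cfg$layer_reduce == "mean") mean(module_losses[ids]) else sum(module_losses[ids])
    total <- total + cfg$loss_weights[[l]] * red
  }
  total
}

#' L1 penalty over the network weights
#'
#' `l1_input * sum|W|` over first-internal-layer blocks plus `l1_all *
#' sum|W|` over every other weight block including heads; biases excluded.
#'
#' @param net an `xmn_network`.
#' @param cfg an [train_config()].
#' @param modules optional subset of module ids (default: all).
#' @return penalty value (scalar).
#' @export
l1_penalty <- function(net, cfg, modules = NULL) {
  ids <- if (is.null(modules)) names(net$modules) else modules
  p <- 0
  for (id in ids) {
    m <- net$modules[[id]]
    p <- p + cfg$l1_input * sum(abs(m$W[[1]]))
    for (k in seq_along(m$W)[-1]) p <- p + cfg$l1_all * sum(abs(m$W[[k]]))
    p <- p + cfg$l1_all * sum(abs(m$Wh))
  }
  unname(p)
}

## ---- backward pass ---------------------------------------------------------

## Per-module head losses for a forward pass (named numeric).
module_losses <- function(net, fwd, y, w) {
  vapply(net$topo, function(id) {
    weighted_cross_entropy(fwd$head_scores[[id]], y, w, classes = net$classes)
  }, numeric(1))
}

## Gradients of the training objective (weighted multi-loss over active
## modules + L1 on active modules' weights) w.r.t. all active-module
## parameters. Returns list per active module: W (list), b (list), Wh, bh.
backward <- function(net, fwd, x, y, w, cfg, active) {
  lvl <- setNames(net$hierarchy$nodes$level, net$hierarchy$nodes$id)
  yi <- if (is.numeric(y)) as.integer(y) else match(as.character(y), net$classes)
  n <- fwd$n
  L <- length(net$spec$layer_widths)
  wv <- as.numeric(w[net$classes])
  if (is.null(dim(x))) x <- matrix(x, 1L, dimnames = list(NULL, names(x)))
  x <- x[, net$gene_ids, drop = FALSE]

  ## count modules per active level once (for layer_reduce = "mean")
  n_per_level <- table(factor(lvl[net$topo], levels = MODULE_LEVELS))

  grads <- list()
  dlast <- setNames(vector("list", length(net$topo)), net$topo) # grad wrt last layer output
  for (id in rev(net$topo)) {
    m <- net$modules[[id]]
    l <- m$level
    if (!(l %in% active)) next
    a <- fwd$acts[[id]]
    A_last <- a$layers[[L]]

    scale <- cfg$loss_weights[[l]]
    if (cfg$layer_reduce == "mean") scale <- scale / as.numeric(n_per_level[[l]])

    ## head contribution
    P <- softmax(fwd$head_scores[[id]])
    dS <- P
    dS[cbind(seq_len(n), yi)] <- dS[cbind(seq_len(n), yi)] - 1
    dS <- dS * (wv[yi] / n) * scale
    gWh <- crossprod(A_last, dS) + cfg$l1_all * sign(m$Wh)
    gbh <- if (!is.null(m$bh)) colSums(dS) else NULL
    dA <- dS %*% t(m$Wh)
    if (!is.null(dlast[[id]])) dA <- dA + dlast[[id]]

    gW <- vector("list", L)
    gb <- vector("list", L)
    for (k in rev(seq_len(L))) {
      Ak <- a$layers[[k]]
      dZ <- if (k < L) dA * (1 - Ak * Ak) else dA # tanh' vs identity
      A_prev <- if (k > 1L) a$layers[[k - 1L]] else a$input
      mult <- if (k == 1L) cfg$l1_input else cfg$l1_all
      gW[[k]] <- crossprod(A_prev, dZ) + mult * sign(m$W[[k]])
      gb[k] <- list(if (!is.null(m$b[[k]])) colSums(dZ) else NULL)
      dA <- dZ %*% t(m$W[[k]])
    }
    ## dA is now the gradient w.r.t. the module input: route to module children
    for (cid in m$children) {
      if (lvl[[cid]] == "D") next
      seg <- dA[, m$slices[[cid]], drop = FALSE]
      dlast[[cid]] <- if (is.null(dlast[[cid]])) seg else dlast[[cid]] + seg
    }
    grads[[id]] <- list(W = gW, b = gb, Wh = gWh, bh = gbh)
  }
  grads
}

adam_init <- function(net) {
  lapply(net$modules, function(m) {
    zero <- function(p) if (is.null(p)) NULL else p * 0
    list(
      t = 0L,
      mW = lapply(m$W, zero), vW = lapply(m$W, zero),
      mb = lapply(m$b, zero), vb = lapply(m$b, zero),
      mWh = zero(m$Wh), vWh = zero(m$Wh),
      mbh = zero(m$bh), vbh = zero(m$bh)
    )
  })
}

## One optimizer step on the active modules.
apply_grads <- function(net, grads, state, cfg) {
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (id in names(grads)) {
    m <- net$modules[[id]]
    g <- grads[[id]]
    if (cfg$optimizer == "sgd") {
      for (k in seq_along(m$W)) {
        m$W[[k]] <- m$W[[k]] - lr * g$W[[k]]
        if (!is.null(m$b[[k]])) m$b[[k]] <- m$b[[k]] - lr * g$b[[k]]
      }
      m$Wh <- m$Wh - lr * g$Wh
      if (!is.null(m$bh)) m$bh <- m$bh - lr * g$bh
    } else {
      s <- state[[id]]
      s$t <- s$t + 1L
      corr <- lr * sqrt(1 - b2^s$t) / (1 - b1^s$t)
      upd <- function(p, gr, mm, vv) {
        mm <- b1 * mm + (1 - b1) * gr
        vv <- b2 * vv + (1 - b2) * gr * gr
        list(p = p - corr * mm / (sqrt(vv) + eps), m = mm, v = vv)
      }
      for (k in seq_along(m$W)) {
        u <- upd(m$W[[k]], g$W[[k]], s$mW[[k]], s$vW[[k]])
        m$W[[k]] <- u$p; s$mW[[k]] <- u$m; s$vW[[k]] <- u$v
        if (!is.null(m$b[[k]])) {
          u <- upd(m$b[[k]], g$b[[k]], s$mb[[k]], s$vb[[k]])
          m$b[[k]] <- u$p; s$mb[[k]] <- u$m; s$vb[[k]] <- u$v
        }
      }
      u <- upd(m$Wh, g$Wh, s$mWh, s$vWh)
      m$Wh <- u$p; s$mWh <- u$m; s$vWh <- u$v
      if (!is.null(m$bh)) {
        u <- upd(m$bh, g$bh, s$mbh, s$vbh)
        m$bh <- u$p; s$mbh <- u$m; s$vbh <- u$v
      }
      state[[id]] <- s
    }
    net$modules[[id]] <- m
  }
  list(net = net, state = state)
}

#' Train a modular network with weighted multi-loss progressive training
#'
#' Mini-batch optimisation of the weighted multi-loss plus L1 penalty.
#' Module layers join the objective at their inclusion epochs (C first);
#' modules of not-yet-included layers are fully frozen — they receive no
#' gradient from any source, so their parameters are bit-identical to their
#' initialisation until their level becomes active. Per epoch, the
#' validation loss (full multi-loss over all levels, plus L1) and the
#' validation macro-F1 of the output head are recorded together with a
#' parameter snapshot, for later model selection.
#'
#' @param net an `xmn_network`.
#' @param x_train,y_train training sample-by-gene matrix and labels (factor
#'   with levels matching `net$classes`).
#' @param x_val,y_val validation split (may be NULL: training loss is then
#'   used in place of validation loss).
#' @param cfg an [train_config()].
#' @return list with `net` (parameters after the final epoch) and `history`:
#'   an object of class `xmn_history` with a per-epoch data.frame (`epoch`,
#'   per-level summed losses, `train_objective`, `val_loss`, `val_f1`) and
#'   the per-epoch parameter snapshots.
#' @export
train_network <- function(net, x_train, y_train, x_val = NULL, y_val = NULL, cfg) {
  y_train <- factor(y_train, levels = net$classes)
  if (anyNA(y_train)) xmn_abort("training labels outside the network's classes")
  w <- if (cfg$class_weight_mode == "automatic") {
    class_weights(y_train)
  } else {
    cfg$class_weights
  }
  w <- w[net$classes]
  if (anyNA(w)) xmn_abort("class weights must cover all classes")
  x_train <- x_train[, net$gene_ids, drop = FALSE]
  has_val <- !is.null(x_val)
  if (has_val) {
    y_val <- factor(y_val, levels = net$classes)
    x_val <- x_val[, net$gene_ids, drop = FALSE]
  }
  lvl <- setNames(net$hierarchy$nodes$level, net$hierarchy$nodes$id)

  n <- nrow(x_train)
  state <- adam_init(net)
  records <- list()
  snaps <- list()
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    act <- active_layers(epoch, cfg)
    idx <- sample.int(n)
    starts <- seq(1L, n, by = cfg$batch_size)
    obj_sum <- 0
    for (s in starts) {
      b <- idx[s:min(s + cfg$batch_size - 1L, n)]
      xb <- x_train[b, , drop = FALSE]
      yb <- y_train[b]
      fwd <- forward(net, xb)
      ml <- module_losses(net, fwd, yb, w)
      if (any(!is.finite(ml))) {
        xmn_abort("non-finite loss in module ", names(ml)[!is.finite(ml)][1],
                  " at epoch ", epoch)
      }
      active_ids <- net$topo[lvl[net$topo] %in% act]
      obj <- multi_loss(ml, net$hierarchy, cfg, epoch) +
        l1_penalty(net, cfg, modules = active_ids)
      obj_sum <- obj_sum + obj * length(b)
      grads <- backward(net, fwd, xb, yb, w, cfg, act)
      up <- apply_grads(net, grads, state, cfg)
      net <- up$net
      state <- up$state
    }

    ## epoch bookkeeping: full-data losses per level + validation
    fwd_tr <- forward(net, x_train)
    ml_tr <- module_losses(net, fwd_tr, y_train, w)
    per_level <- vapply(MODULE_LEVELS, function(l) {
      ids <- net$topo[lvl[net$topo] == l]
      if (length(ids)) sum(ml_tr[ids]) else 0
    }, numeric(1))
    if (has_val) {
      fwd_v <- forward(net, x_val)
      ml_v <- module_losses(net, fwd_v, y_val, w)
      val_loss <- multi_loss(ml_v, net$hierarchy, cfg, epoch = Inf) +
        l1_penalty(net, cfg)
      pred_v <- predict_network(net, fwd = fwd_v)$class
      val_f1 <- compute_metrics(y_val, pred_v, net$classes)$f1_macro
    } else {
      val_loss <- multi_loss(ml_tr, net$hierarchy, cfg, epoch = Inf) +
        l1_penalty(net, cfg)
      val_f1 <- NA_real_
    }
    records[[epoch]] <- data.frame(
      epoch = epoch,
      loss_C = per_level[["C"]], loss_B = per_level[["B"]],
      loss_A = per_level[["A"]], loss_O = per_level[["O"]],
      train_objective = obj_sum / n, val_loss = val_loss, val_f1 = val_f1
    )
    snaps[[epoch]] <- snapshot_params(net)
  }
  history <- structure(
    list(log = do.call(rbind, records), snapshots = snaps),
    class = "xmn_history"
  )
  list(net = net, history = history)
}

#' Select the best checkpoint by validation loss
#'
#' Returns the network restored to the epoch with the lowest validation
#' loss; ties break to the earliest epoch.
#'
#' @param net an `xmn_network` (architecture carrier).
#' @param history an `xmn_history` from [train_network()].
#' @return list with `net` (restored parameters) and `epoch` (selected).
#' @export
select_best <- function(net, history) {
  stopifnot(inherits(history, "xmn_history"))
  losses <- history$log$val_loss
  if (!length(losses)) xmn_abort("empty training history")
  best <- which.min(losses) # which.min takes the first minimum: earliest epoch
  list(net = restore_params(net, history$snapshots[[best]]), epoch = best)
}

#' @export
print.xmn_history <- function(x, ...) {
  cat("Training history:", nrow(x$log), "epochs; final val_loss =",
      signif(x$log$val_loss[nrow(x$log)], 4), "\n")
  invisible(x)
}

#' Write a training log as TSV
#' @param history an `xmn_history`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(history, path) {
  write.table(history$log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
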