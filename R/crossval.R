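#' Stratified k-fold assignment
#'
#' Within each class, samples are shuffled (seeded) and dealt into k chunks
#' of size `ceiling(n_c/k)` or `floor(n_c/k)`, the larger chunks going to the
#' lowest-index folds; fold f is the union of chunk f over classes. Per-class
#' fold counts therefore differ by at most one, preserving the label
#' distribution in every fold.
#'
#' @param labels factor of class labels named by sample id.
#' @param k number of folds (>= 2, <= number of samples).
#' @param seed RNG seed for the within-class shuffles.
#' @return an object of class `xmn_folds`: list with `k`, `fold_of` (integer
#'   fold index 1..k named by sample id) and `seed`.
#' @export
stratified_folds <- function(labels, k = 10L, seed = 1L) {
  labels <- as.factor(labels)
  if (is.null(names(labels))) names(labels) <- paste0("s", seq_along(labels))
  k <- as.integer(k)
  n <- length(labels)
  if (k < 2L) xmn_abort("k must be >= 2")
  if (k > n) xmn_abort("k must not exceed the number of samples (", n, ")")
  counts <- table(labels)
  if (any(counts < k)) {
    warning("class(es) with fewer than k samples leave some folds without them: ",
            paste(names(counts)[counts < k], collapse = ", "))
  }
  set.seed(as.integer(seed))
  fold_of <- setNames(integer(n), names(labels))
  for (cl in levels(labels)) {
    ids <- names(labels)[labels == cl]
    ids <- ids[sample.int(length(ids))]
    n_c <- length(ids)
    r <- n_c %% k
    sizes <- rep(n_c %/% k, k) + c(rep(1L, r), rep(0L, k - r))
    fold_of[ids] <- rep(seq_len(k), times = sizes)
  }
  structure(list(k = k, fold_of = fold_of, seed = as.integer(seed)),
            class = "xmn_folds")
}

#' Fold sizes of a stratified assignment
#' @param folds an `xmn_folds`.
#' @return integer vector of length k: samples per fold.
#' @export
fold_sizes <- function(folds) {
  as.integer(table(factor(folds$fold_of, levels = seq_len(folds$k))))
}

#' Assign test / validation / training roles for one split
#'
#' One fold is the test set; two folds drawn (seeded) without replacement
#' from the remaining folds form the validation set; the rest train. Over
#' the k splits of a cross-validation each fold is the test fold exactly
#' once.
#'
#' @param folds an `xmn_folds`.
#' @param test_fold fold index used as the test set.
#' @param seed seed for the validation-fold draw.
#' @return list with `test`, `validation` (2 fold indices) and `training`
#'   fold indices.
#' @export
assign_roles <- function(folds, test_fold, seed = 1L) {
  k <- folds$k
  if (k < 4L) xmn_abort("k must be >= 4 to reserve 2 validation folds")
  test_fold <- as.integer(test_fold)
  if (test_fold < 1L || test_fold > k) xmn_abort("test_fold out of range")
  rest <- setdiff(seq_len(k), test_fold)
  set.seed(as.integer(seed))
  val <- sort(rest[sample.int(length(rest), 2L)])
  list(test = test_fold, validation = val, training = setdiff(rest, val))
}

#' Classification metrics
#'
#' Per-class precision and recall, macro-averaged F1, balanced accuracy
#' (mean per-class recall) and the Matthews correlation coefficient (the
#' multiclass generalisation, which reduces to the usual binary formula for
#' two classes), plus the confusion matrix. A class absent from `y_true`
#' yields recall 0 with a warning.
#'
#' @param y_true,y_pred factors (or vectors coercible to the `classes`).
#' @param classes character vector of all classes.
#' @return an object of class `xmn_metrics`: list with `confusion`,
#'   `precision`, `recall`, `f1_macro`, `balanced_accuracy`, `mcc`.
#' @export
compute_metrics <- function(y_true, y_pred, classes) {
  y_true <- factor(y_true, levels = classes)
  y_pred <- factor(y_pred, levels = classes)
  if (length(y_true) != length(y_pred)) xmn_abort("y_true and y_pred lengths differ")
  cm <- table(true = y_true, predicted = y_pred)
  tp <- diag(cm)
  row_s <- rowSums(cm) # true counts
  col_s <- colSums(cm) # predicted counts
  if (any(row_s == 0)) {
    warning("class(es) absent from y_true, recall reported as 0: ",
            paste(classes[row_s == 0], collapse = ", "))
  }
  recall <- ifelse(row_s > 0, tp / row_s, 0)
  precision <- ifelse(col_s > 0, tp / col_s, 0)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  n <- sum(cm)
  s <- sum(tp)
  ## multiclass MCC (Gorodkin); binary case equals the textbook formula
  num <- s * n - sum(row_s * col_s)
  den <- sqrt(n^2 - sum(col_s^2)) * sqrt(n^2 - sum(row_s^2))
  mcc <- if (den > 0) num / den else 0
  structure(
    list(
      confusion = cm,
      precision = setNames(as.numeric(precision), classes),
      recall = setNames(as.numeric(recall), classes),
      f1_macro = mean(f1),
      balanced_accuracy = mean(recall),
      mcc = mcc
    ),
    class = "xmn_metrics"
  )
}

#' @export
print.xmn_metrics <- function(x, ...) {
  cat(sprintf(
    "F1(macro)=%.3f  balanced accuracy=%.3f  MCC=%.3f\n",
    x$f1_macro, x$balanced_accuracy, x$mcc
  ))
  print(x$confusion)
  invisible(x)
}

#' Stratified cross-validation of the modular network
#'
#' Runs the full harness: stratified fold assignment, per-split role
#' assignment (1 test fold, 2 validation folds, k-3 training folds),
#' per-gene mean centering (training-split statistics by default), network
#' construction and progressive training per split, per-epoch model
#' selection by validation loss, and evaluation on the held-out test fold.
#' Each sample is predicted exactly once, so the pooled predictions cover
#' the whole dataset.
#'
#' @param x numeric gene-by-sample expression matrix (genes in rows).
#' @param labels factor of class labels named by sample id (all samples in
#'   `colnames(x)`).
#' @param h an `xmn_hierarchy`; it is pruned to the measured genes.
#' @param cfg an [train_config()].
#' @param spec an [module_spec()]; its `n_classes` must match the labels.
#' @param k number of folds.
#' @return an object of class `xmn_cv`: list with `folds`, `roles`,
#'   `models` (per split: `net`, `epoch`, `gene_means`), `predictions`
#'   (data.frame: sample_id, fold, true, predicted, prob_<class>...),
#'   `split_metrics` (per-split `xmn_metrics`), `metrics_table`,
#'   `summary` (median/mean/sd/min/max per metric), `pooled` (metrics on
#'   the pooled predictions) and the pruned `hierarchy`.
#' @export
run_crossval <- function(x, labels, h, cfg = train_config(), spec = NULL, k = 10L) {
  stopifnot(is.matrix(x))
  labels <- as.factor(labels)
  if (is.null(names(labels))) xmn_abort("labels must be named by sample id")
  miss <- setdiff(colnames(x), names(labels))
  if (length(miss)) xmn_abort("sample without label: ", miss[1])
  labels <- droplevels(labels[colnames(x)])
  classes <- levels(labels)
  if (is.null(spec)) spec <- module_spec(n_classes = length(classes))
  if (spec$n_classes != length(classes)) {
    xmn_abort("spec$n_classes (", spec$n_classes, ") != number of classes (",
              length(classes), ")")
  }
  h <- prune_to_genes(h, rownames(x))
  genes <- hierarchy_genes(h)
  x <- x[genes, , drop = FALSE]

  folds <- stratified_folds(labels, k = k, seed = cfg$seed)
  models <- vector("list", k)
  roles_all <- vector("list", k)
  split_metrics <- vector("list", k)
  preds <- list()

  for (split in seq_len(k)) {
    roles <- assign_roles(folds, split, seed = cfg$seed + split)
    roles_all[[split]] <- roles
    id_tr <- names(folds$fold_of)[folds$fold_of %in% roles$training]
    id_va <- names(folds$fold_of)[folds$fold_of %in% roles$validation]
    id_te <- names(folds$fold_of)[folds$fold_of %in% roles$test]

    if (cfg$center == "global") {
      xc <- mean_center(x)
      gene_means <- attr(xc, "gene_means")
    } else {
      gene_means <- rowMeans(x[, id_tr, drop = FALSE])
      xc <- mean_center(x, means = gene_means)
    }
    xt <- t(xc) # samples x genes

    split_seed <- cfg$seed + 1000L * split
    net0 <- build_network(h, spec, seed = split_seed, classes = classes)
    cfg_split <- cfg
    cfg_split$seed <- split_seed
    fit <- train_network(
      net0, xt[id_tr, , drop = FALSE], labels[id_tr],
      xt[id_va, , drop = FALSE], labels[id_va], cfg_split
    )
    best <- select_best(fit$net, fit$history)
    models[[split]] <- list(
      net = best$net, epoch = best$epoch, gene_means = gene_means,
      history = fit$history$log
    )

    pr <- predict_network(best$net, xt[id_te, , drop = FALSE])
    split_metrics[[split]] <- compute_metrics(labels[id_te], pr$class, classes)
    dfp <- data.frame(
      sample_id = id_te, fold = split,
      true = as.character(labels[id_te]), predicted = as.character(pr$class),
      stringsAsFactors = FALSE
    )
    colnames(pr$prob) <- paste0("prob_", classes)
    preds[[split]] <- cbind(dfp, as.data.frame(pr$prob))
  }

  predictions <- do.call(rbind, preds)
  rownames(predictions) <- NULL
  pooled <- compute_metrics(predictions$true, predictions$predicted, classes)

  metric_names <- c("f1_macro", "balanced_accuracy", "mcc")
  tab <- vapply(split_metrics, function(m) {
    unlist(m[metric_names])
  }, numeric(length(metric_names)))
  tab <- t(tab)
  summary_stats <- apply(tab, 2L, function(v) {
    c(median = median(v), mean = mean(v), sd = sd(v), min = min(v), max = max(v))
  })

  structure(
    list(
      folds = folds, roles = roles_all, models = models,
      predictions = predictions, split_metrics = split_metrics,
      metrics_table = as.data.frame(cbind(split = seq_len(k), tab)),
      summary = summary_stats, pooled = pooled,
      hierarchy = h, classes = classes, cfg = cfg, spec = spec
    ),
    class = "xmn_cv"
  )
}

#' @export
print.xmn_cv <- function(x, ...) {
  cat("Cross-validation over", x$folds$k, "splits;",
      nrow(x$predictions), "pooled test predictions\n")
  cat(sprintf(
    "pooled: F1(macro)=%.3f  balanced accuracy=%.3f  MCC=%.3f\n",
    x$pooled$f1_macro, x$pooled$balanced_accuracy, x$pooled$mcc
  ))
  invisible(x)
}

#' Write cross-validation outputs as TSV
#'
#' Writes `folds.tsv` (sample_id, fold), `predictions.tsv` and
#' `metrics.tsv` (per split plus summary rows) into `dir`.
#'
#' @param cv an `xmn_cv`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_crossval <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(
    data.frame(sample_id = names(cv$folds$fold_of), fold = cv$folds$fold_of),
    file.path(dir, "folds.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.table(cv$predictions, file.path(dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- cv$metrics_table
  sum_df <- data.frame(split = rownames(cv$summary), cv$summary)
  colnames(sum_df) <- colnames(mt)
  write.table(rbind(mt, sum_df), file.path(dir, "metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
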