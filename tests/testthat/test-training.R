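test_that("automatic class weights follow the balanced heuristic", {
  w <- class_weights(factor(rep(c("m", "f"), c(50, 50))))
  expect_equal(unname(w[c("m", "f")]), c(1, 1))

  # cohort-style imbalance 434/555
  w2 <- class_weights(factor(rep(c("male", "female"), c(434, 555))))
  expect_equal(w2[["male"]], 989 / (2 * 434), tolerance = 1e-12)
  expect_equal(w2[["female"]], 989 / (2 * 555), tolerance = 1e-12)

  w3 <- class_weights(factor(rep(c("a", "b", "c"), each = 7)))
  expect_equal(unname(w3), rep(1, 3))
  expect_error(class_weights(factor("a", levels = c("a", "b"))), "zero samples")
})

test_that("weighted cross-entropy matches closed forms", {
  expect_equal(weighted_cross_entropy(c(0, 0), 1L), log(2), tolerance = 1e-12)
  # strongly separated scores: loss = log(1 + exp(-20))
  expect_equal(weighted_cross_entropy(c(10, -10), 1L), log1p(exp(-20)),
               tolerance = 1e-6)
  # linear in the class weight
  l1 <- weighted_cross_entropy(c(0.4, -0.2), 1L, w = c(1, 1))
  l2 <- weighted_cross_entropy(c(0.4, -0.2), 1L, w = c(2, 1))
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  # batch loss is the mean over samples
  S <- rbind(c(0, 0), c(10, -10))
  expect_equal(
    weighted_cross_entropy(S, c(1L, 1L)),
    mean(c(log(2), log1p(exp(-20)))),
    tolerance = 1e-12
  )
  # balanced data: automatic weights equal unweighted CE
  y <- factor(rep(c("a", "b"), 5))
  S2 <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(
    weighted_cross_entropy(S2, y, w = class_weights(y)),
    weighted_cross_entropy(S2, y),
    tolerance = 1e-12
  )
})

test_that("the progressive schedule activates layers at their inclusion epochs", {
  cfg <- train_config()
  expect_equal(active_layers(1, cfg), "C")
  expect_equal(active_layers(2, cfg), c("C", "B"))
  expect_equal(active_layers(3, cfg), c("C", "B"))
  expect_equal(active_layers(5, cfg), c("C", "B", "A"))
  expect_equal(active_layers(6, cfg), c("C", "B", "A", "O"))
  expect_equal(active_layers(100, cfg), c("C", "B", "A", "O"))
  expect_error(train_config(inclusion_epochs = c(C = 2, B = 1, A = 4, O = 6)),
               "non-decreasing")
})

test_that("the weighted multi-loss matches hand arithmetic", {
  h <- hierarchy(
    nodes = data.frame(
      id = c("g1", "g2", "c1", "c2", "b1", "a1", "O"),
      level = c("D", "D", "C", "C", "B", "A", "O"), name = 1:7
    ),
    edges = data.frame(
      child_id = c("g1", "g2", "c1", "c2", "b1", "a1"),
      parent_id = c("c1", "c2", "b1", "b1", "a1", "O")
    )
  )
  losses <- c(c1 = 0.6, c2 = 0.4, b1 = 0.5, a1 = 0.3, O = 0.2)
  cfg <- train_config()
  expect_equal(multi_loss(losses, h, cfg, epoch = Inf),
               1.3 * 1.0 + 1.2 * 0.5 + 1.1 * 0.3 + 1.0 * 0.2, tolerance = 1e-12)
  expect_equal(multi_loss(losses, h, cfg, epoch = 3), 1.3 + 0.6, tolerance = 1e-12)
  cfg1 <- train_config(loss_weights = c(C = 1, B = 1, A = 1, O = 1))
  expect_equal(multi_loss(losses, h, cfg1, epoch = Inf), sum(losses), tolerance = 1e-12)
  # mean reduction divides each level by its module count
  cfgm <- train_config(layer_reduce = "mean")
  expect_equal(multi_loss(losses, h, cfgm, epoch = Inf),
               1.3 * 0.5 + 1.2 * 0.5 + 1.1 * 0.3 + 1.0 * 0.2, tolerance = 1e-12)
})

test_that("the L1 penalty weighs input-layer blocks at 0.1 and the rest at 0.01", {
  net <- set_weights(build_network(chain_hierarchy(), module_spec(), seed = 1),
                     function(n) rep(0, n))
  cfg <- train_config()
  expect_equal(l1_penalty(net, cfg), 0)
  net$modules$c1$W[[1]][1, 1] <- 2
  net$modules$c1$Wh[1, 1] <- 3
  expect_equal(l1_penalty(net, cfg), 0.1 * 2 + 0.01 * 3, tolerance = 1e-12)
  # invariant under sign flips
  net$modules$c1$W[[1]][1, 1] <- -2
  net$modules$c1$Wh[1, 1] <- -3
  expect_equal(l1_penalty(net, cfg), 0.23, tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(42)
  h <- twin_hierarchy()
  net <- build_network(h, module_spec(), seed = 5)
  cfg <- train_config(seed = 1)
  x <- matrix(rnorm(4 * 6), 6, 4, dimnames = list(NULL, c("g1", "g2", "g3", "g4")))
  y <- factor(rep(c("class1", "class2"), 3), levels = net$classes)
  w <- setNames(c(1.2, 0.9), net$classes)

  obj_of <- function(n) {
    fwd <- forward(n, x)
    ml <- vapply(n$topo, function(id) {
      weighted_cross_entropy(fwd$head_scores[[id]], y, w, classes = n$classes)
    }, numeric(1))
    multi_loss(ml, n$hierarchy, cfg, epoch = Inf) + l1_penalty(n, cfg)
  }
  fwd <- forward(net, x)
  grads <- xmodnn:::backward(net, fwd, x, y, w, cfg, c("C", "B", "A", "O"))

  eps <- 1e-6
  check <- function(id, get, set) {
    p <- get(net$modules[[id]])
    idx <- sample(length(p), min(4L, length(p)))
    for (j in idx) {
      n2 <- net; n2$modules[[id]] <- set(n2$modules[[id]], j, p[j] + eps)
      n3 <- net; n3$modules[[id]] <- set(n3$modules[[id]], j, p[j] - eps)
      num <- (obj_of(n2) - obj_of(n3)) / (2 * eps)
      expect_equal(get(grads[[id]])[j], num, tolerance = 1e-5)
    }
  }
  for (id in names(net$modules)) {
    for (k in 1:3) {
      check(id, function(m) m$W[[k]],
            function(m, j, v) { m$W[[k]][j] <- v; m })
    }
    check(id, function(m) m$b[[2]],
          function(m, j, v) { m$b[[2]][j] <- v; m })
    check(id, function(m) m$Wh,
          function(m, j, v) { m$Wh[j] <- v; m })
  }
})

test_that("layers are frozen until their inclusion epoch", {
  d <- small_dataset(seed = 2, n_per_class = c(12L, 12L))
  net <- build_network(d$hierarchy, module_spec(), seed = 3,
                       classes = levels(d$labels))
  init <- xmodnn:::snapshot_params(net)
  lvl <- setNames(d$hierarchy$nodes$level, d$hierarchy$nodes$id)
  cfg <- train_config(max_epochs = 1, batch_size = 8, seed = 3)
  fit <- train_network(net, t(d$expression), d$labels, cfg = cfg)
  after <- xmodnn:::snapshot_params(fit$net)
  for (id in names(after)) {
    if (lvl[[id]] == "C") {
      expect_false(identical(after[[id]], init[[id]]))
    } else {
      expect_identical(after[[id]], init[[id]]) # bit-identical
    }
  }
})

test_that("training is bit-reproducible for a fixed seed", {
  d <- small_dataset(seed = 4, n_per_class = c(10L, 10L))
  cfg <- train_config(max_epochs = 3, batch_size = 8, seed = 7)
  run <- function() {
    net <- build_network(d$hierarchy, module_spec(), seed = 7,
                         classes = levels(d$labels))
    train_network(net, t(d$expression), d$labels, cfg = cfg)
  }
  f1 <- run()
  f2 <- run()
  expect_identical(xmodnn:::snapshot_params(f1$net), xmodnn:::snapshot_params(f2$net))
  expect_equal(f1$history$log, f2$history$log)
})

test_that("planted signal is learned within 15 epochs", {
  accs <- sapply(c(9, 10, 11), function(s) {
    d <- small_dataset(seed = s, n_per_class = c(60L, 60L))
    x <- t(mean_center(d$expression))
    idx <- seq_len(nrow(x))
    tr <- idx[idx %% 4 != 0]
    va <- idx[idx %% 4 == 0]
    net <- build_network(d$hierarchy, module_spec(), seed = s,
                         classes = levels(d$labels))
    cfg <- train_config(max_epochs = 15, batch_size = 16, seed = s)
    fit <- train_network(net, x[tr, ], d$labels[tr], x[va, ], d$labels[va], cfg)
    best <- select_best(fit$net, fit$history)
    pred <- predict_network(best$net, x[va, ])$class
    compute_metrics(d$labels[va], pred, levels(d$labels))$balanced_accuracy
  })
  expect_gte(mean(accs), 0.95) # seed-averaged
})

test_that("stronger overall L1 shrinks the weights at convergence", {
  d <- small_dataset(seed = 12, n_per_class = c(20L, 20L))
  x <- t(mean_center(d$expression))
  mean_abs_w <- function(l1) {
    cfg <- train_config(max_epochs = 10, batch_size = 16, l1_all = l1, seed = 5)
    net <- build_network(d$hierarchy, module_spec(), seed = 5,
                         classes = levels(d$labels))
    fit <- train_network(net, x, d$labels, cfg = cfg)
    ws <- unlist(lapply(fit$net$modules, function(m) {
      c(unlist(m$W[-1]), as.vector(m$Wh))
    }))
    mean(abs(ws))
  }
  expect_lt(mean_abs_w(0.02), mean_abs_w(0.01))
})

test_that("checkpoint selection takes the lowest validation loss, earliest on ties", {
  net <- build_network(chain_hierarchy(), module_spec(), seed = 1)
  mk_history <- function(losses) {
    snaps <- lapply(seq_along(losses), function(i) {
      s <- xmodnn:::snapshot_params(net)
      s$c1$Wh[1, 1] <- i # marker
      s
    })
    structure(list(log = data.frame(epoch = seq_along(losses), val_loss = losses),
                   snapshots = snaps), class = "xmn_history")
  }
  expect_equal(select_best(net, mk_history(c(0.9, 0.4, 0.6)))$epoch, 2L)
  expect_equal(select_best(net, mk_history(c(0.5, 0.5)))$epoch, 1L)
  sel <- select_best(net, mk_history(0.7))
  expect_equal(sel$epoch, 1L)
  expect_equal(sel$net$modules$c1$Wh[1, 1], 1)
})
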