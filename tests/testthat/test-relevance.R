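test_that("the epsilon rule matches hand computation on one linear layer", {
  a <- c(1, 2)
  w <- matrix(c(0.5, 0.25), 2, 1)
  # z = 1*0.5 + 2*0.25 = 1: relevance splits 0.5/0.5, conserved
  r0 <- lrp_linear_epsilon(a, w, R = 1, epsilon = 0)
  expect_equal(r0, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(sum(r0), 1, tolerance = 1e-12)
  # epsilon = 1 doubles the denominator and absorbs half the relevance
  r1 <- lrp_linear_epsilon(a, w, R = 1, epsilon = 1)
  expect_equal(r1, c(0.25, 0.25), tolerance = 1e-12)
  expect_lt(sum(r1), 1)
  # zero upper relevance propagates as zero
  expect_equal(lrp_linear_epsilon(a, w, R = 0, epsilon = 0), c(0, 0))
  # matrix (batched) form agrees with per-row vector calls
  A <- matrix(rnorm(6), 3, 2)
  R <- matrix(rnorm(3), 3, 1)
  batch <- lrp_linear_epsilon(A, w, R = R, epsilon = 0.1)
  for (i in 1:3) {
    expect_equal(batch[i, ], lrp_linear_epsilon(A[i, ], w, R = R[i, ], epsilon = 0.1))
  }
})

test_that("relevance is conserved on bias-free networks with epsilon zero", {
  for (s in 1:20) {
    f <- random_biasfree_net(s)
    rmap <- lrp_explain(f$net, f$x, epsilon = 0)
    expect_lt(
      max(abs(rowSums(rmap$gene) - rmap$seed_score) / pmax(abs(rmap$seed_score), 1e-12)),
      1e-6
    )
  }
})

test_that("single-path chain relevance equals the hand-derived value", {
  h <- hierarchy(
    nodes = data.frame(id = c("g1", "c1", "b1", "a1", "O"),
                       level = c("D", "C", "B", "A", "O"), name = 1:5),
    edges = data.frame(child_id = c("g1", "c1", "b1", "a1"),
                       parent_id = c("c1", "b1", "a1", "O"))
  )
  net <- set_weights(
    build_network(h, module_spec(hidden_bias = FALSE), seed = 1),
    function(n) rep(0.5, n)
  )
  x <- c(g1 = 0.8)
  rmap <- lrp_explain(net, x, start_class = "class1", epsilon = 0)
  # single input: all relevance reaching any module flows through g1,
  # so with epsilon = 0 the gene keeps the entire seeded head score
  score <- forward(net, x)$head_scores$O[1, "class1"]
  expect_equal(unname(rmap$gene[1, "g1"]), unname(score), tolerance = 1e-9)
  expect_equal(unname(rmap$seed_score), unname(score))
  # every module on the path carries the full relevance too
  expect_equal(unname(rmap$module[1, ]), rep(unname(score), 4), tolerance = 1e-9)
})

test_that("duplicating a gene with halved outgoing weights splits its relevance", {
  h1 <- hierarchy(
    nodes = data.frame(id = c("g1", "c1", "b1", "a1", "O"),
                       level = c("D", "C", "B", "A", "O"), name = 1:5),
    edges = data.frame(child_id = c("g1", "c1", "b1", "a1"),
                       parent_id = c("c1", "b1", "a1", "O"))
  )
  h2 <- hierarchy(
    nodes = data.frame(id = c("g1", "g1b", "c1", "b1", "a1", "O"),
                       level = c("D", "D", "C", "B", "A", "O"), name = 1:6),
    edges = data.frame(child_id = c("g1", "g1b", "c1", "b1", "a1"),
                       parent_id = c("c1", "c1", "b1", "a1", "O"))
  )
  spec <- module_spec(hidden_bias = FALSE)
  set.seed(99)
  n1 <- build_network(h1, spec, seed = 2)
  n2 <- build_network(h2, spec, seed = 2)
  # same weights everywhere, except the duplicated gene's two input rows
  # each carry half of the original single row
  for (id in names(n1$modules)) {
    n2$modules[[id]]$W <- n1$modules[[id]]$W
    n2$modules[[id]]$Wh <- n1$modules[[id]]$Wh
  }
  n2$modules$c1$W[[1]] <- rbind(n1$modules$c1$W[[1]] / 2,
                                n1$modules$c1$W[[1]] / 2)
  x1 <- c(g1 = 1.3)
  x2 <- c(g1 = 1.3, g1b = 1.3)
  r1 <- lrp_explain(n1, x1, start_class = "class1", epsilon = 0)
  r2 <- lrp_explain(n2, x2, start_class = "class1", epsilon = 0)
  expect_equal(unname(r2$gene[1, "g1"]), unname(r1$gene[1, "g1"]) / 2, tolerance = 1e-9)
  expect_equal(unname(r2$gene[1, "g1b"]), unname(r1$gene[1, "g1"]) / 2, tolerance = 1e-9)
})

test_that("absorbed relevance grows monotonically with epsilon", {
  f <- random_biasfree_net(31)
  absorbed <- sapply(c(0, 1e-4, 1e-2, 0.1, 1), function(eps) {
    rmap <- lrp_explain(f$net, f$x[1, , drop = FALSE], epsilon = eps)
    abs(rmap$seed_score - sum(rmap$gene))
  })
  expect_true(all(diff(absorbed) >= -1e-10))
})

test_that("a gene with zero outgoing weights gets exactly zero relevance", {
  f <- random_biasfree_net(17)
  g <- f$net$gene_ids[1]
  for (id in names(f$net$modules)) {
    m <- f$net$modules[[id]]
    if (g %in% names(m$slices)) {
      f$net$modules[[id]]$W[[1]][m$slices[[g]], ] <- 0
    }
  }
  rmap <- lrp_explain(f$net, f$x, epsilon = 1e-6)
  expect_true(all(rmap$gene[, g] == 0))
})

test_that("module relevance equals the sum over a module's gene descendants in a tree", {
  # in a tree (fanout 1, no multi-membership), conservation holds per subtree
  sp <- synthetic_spec(n_genes = 12, n_C = 3, n_B = 2, n_A = 1,
                       n_per_class = c(4, 4), n_planted = 2, seed = 8)
  hgen <- make_hierarchy(sp)
  net <- build_network(hgen$hierarchy, module_spec(hidden_bias = FALSE), seed = 4)
  x <- matrix(rnorm(2 * 12), 2, dimnames = list(NULL, net$gene_ids))
  rmap <- lrp_explain(net, x, epsilon = 0)
  h <- hgen$hierarchy
  lvl <- setNames(h$nodes$level, h$nodes$id)
  for (id in names(net$modules)) {
    desc <- id
    repeat {
      kids <- unique(unlist(h$children[desc], use.names = FALSE))
      nxt <- union(desc, kids)
      if (setequal(nxt, desc)) break
      desc <- nxt
    }
    genes <- desc[lvl[desc] == "D"]
    expect_equal(unname(rmap$module[, id]),
                 unname(rowSums(rmap$gene[, genes, drop = FALSE])),
                 tolerance = 1e-8)
  }
})

test_that("layer-wise normalization scales each level to unit absolute sum", {
  v <- matrix(c(2, -1, 1, 5), 1, dimnames = list(NULL, c("n1", "n2", "n3", "m1")))
  lv <- c("D", "D", "D", "C")
  out <- normalize_layerwise(v, lv)
  expect_equal(unname(out[1, 1:3]), c(0.5, -0.25, 0.25))
  expect_equal(unname(out[1, 4]), 1) # single-node layer
  # scale invariance and idempotence
  expect_equal(normalize_layerwise(10 * v, lv), out)
  expect_equal(normalize_layerwise(out, lv), out)
  # random maps: absolute sum 1 per level
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rnorm(30), 3)
    colnames(m) <- paste0("n", 1:10)
    lvr <- sample(c("D", "C", "B"), 10, replace = TRUE)
    nm <- normalize_layerwise(m, lvr)
    for (l in unique(lvr)) {
      expect_equal(unname(rowSums(abs(nm[, lvr == l, drop = FALSE]))),
                   rep(1, 3), tolerance = 1e-9)
    }
  }
  expect_warning(normalize_layerwise(matrix(0, 1, 2), c("D", "D")), "all-zero")
})

test_that("global aggregation reduces pooled maps to per-node statistics", {
  vals <- matrix(c(1, 2, 3, -1, 0, 1), 3, 2,
                 dimnames = list(paste0("s", 1:3), c("n1", "n2")))
  agg <- aggregate_global(vals, node_levels = c(n1 = "D", n2 = "D"))
  expect_equal(agg$table$median, c(2, 0))
  expect_equal(agg$table$mean, c(2, 0))
  expect_equal(agg$table$std, c(1, 1))
  expect_equal(agg$table$n, c(3, 3))

  # one prediction: median equals the prediction itself
  one <- aggregate_global(vals[1, , drop = FALSE], node_levels = c(n1 = "D", n2 = "D"))
  expect_equal(one$table$median, unname(vals[1, ]))

  # symmetric pair v / -v has median 0 everywhere
  sym <- aggregate_global(rbind(vals[1, ], -vals[1, ]),
                          node_levels = c(n1 = "D", n2 = "D"))
  expect_equal(sym$table$median, c(0, 0))

  # brute-force sort-based median on random maps
  set.seed(9)
  m <- matrix(rnorm(100 * 5), 100, dimnames = list(NULL, paste0("n", 1:5)))
  agg2 <- aggregate_global(m, node_levels = setNames(rep("D", 5), paste0("n", 1:5)))
  for (j in 1:5) {
    v <- sort(m[, j])
    expect_equal(agg2$table$median[j], (v[50] + v[51]) / 2, tolerance = 1e-12)
  }
})

test_that("per-class aggregates are computed on the matching rows", {
  vals <- matrix(c(1, 5, 2, 6, 3, 7), 3, 2, byrow = TRUE,
                 dimnames = list(paste0("s", 1:3), c("n1", "n2")))
  cl <- factor(c("a", "a", "b"))
  agg <- aggregate_global(vals, node_levels = c(n1 = "D", n2 = "D"), by_class = cl)
  expect_equal(agg$table$median_a, c(1.5, 5.5))
  expect_equal(agg$table$median_b, c(3, 7))
})
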