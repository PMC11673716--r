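# Shared fixtures, all built in code.

## Minimal chain: 2 genes -> c1 -> b1 -> a1 -> O (6 nodes, 5 edges).
chain_hierarchy <- function() {
  hierarchy(
    nodes = data.frame(
      id = c("g1", "g2", "c1", "b1", "a1", "O"),
      level = c("D", "D", "C", "B", "A", "O"),
      name = c("gene 1", "gene 2", "pathway 1", "group 1", "category 1", "output")
    ),
    edges = data.frame(
      child_id = c("g1", "g2", "c1", "b1", "a1"),
      parent_id = c("c1", "c1", "b1", "a1", "O")
    )
  )
}

## Two C pathways under one B: g1,g2 -> c1; g3,g4 -> c2; c1,c2 -> b1 -> a1 -> O.
twin_hierarchy <- function() {
  hierarchy(
    nodes = data.frame(
      id = c("g1", "g2", "g3", "g4", "c1", "c2", "b1", "a1", "O"),
      level = c("D", "D", "D", "D", "C", "C", "B", "A", "O"),
      name = paste("node", 1:9)
    ),
    edges = data.frame(
      child_id = c("g1", "g2", "g3", "g4", "c1", "c2", "b1", "a1"),
      parent_id = c("c1", "c1", "c2", "c2", "b1", "b1", "a1", "O")
    )
  )
}

## Random small hierarchy + bias-free network + random input, for LRP
## property tests.
random_biasfree_net <- function(seed, max_genes = 50L) {
  set.seed(seed)
  n_genes <- sample(4:max_genes, 1)
  n_C <- sample(2:min(6L, n_genes), 1)
  n_B <- sample(1:min(3L, n_C), 1)
  n_A <- sample(1:min(2L, n_B), 1)
  sp <- synthetic_spec(
    n_genes = n_genes, n_C = n_C, n_B = n_B, n_A = n_A,
    membership_fanout = sample(c(1, 1.5), 1), n_per_class = c(5L, 5L),
    n_planted = 1L, seed = seed
  )
  h <- make_hierarchy(sp)$hierarchy
  net <- build_network(
    h, module_spec(hidden_bias = FALSE), seed = seed + 1L
  )
  x <- matrix(rnorm(length(net$gene_ids) * 3), 3,
              dimnames = list(NULL, net$gene_ids))
  list(net = net, x = x)
}

## Set every weight of a network to values drawn from a given function,
## leaving the architecture intact.
set_weights <- function(net, fill) {
  for (id in names(net$modules)) {
    m <- net$modules[[id]]
    for (k in seq_along(m$W)) m$W[[k]][] <- fill(length(m$W[[k]]))
    for (k in seq_along(m$b)) if (!is.null(m$b[[k]])) m$b[[k]][] <- 0
    m$Wh[] <- fill(length(m$Wh))
    if (!is.null(m$bh)) m$bh[] <- 0
    net$modules[[id]] <- m
  }
  net
}

## Small planted two-class dataset for end-to-end tests.
small_dataset <- function(seed = 7, n_genes = 20L, n_per_class = c(30L, 30L)) {
  sp <- synthetic_spec(
    n_genes = n_genes, n_C = 4L, n_B = 2L, n_A = 1L,
    n_per_class = n_per_class, n_planted = 4L, effect_size = 3,
    seed = seed
  )
  make_expression(sp)
}
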