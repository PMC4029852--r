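test_that("identical expression rows give a perfect correlation edge", {
  vals <- rnorm(9, 8)
  em <- one_probe_matrix(vals)
  m <- rbind(em$signals, em$signals)
  rownames(m) <- c("gA", "gB")
  em2 <- expr_matrix(m, em$sample_sheet)
  edges <- correlation_edges(em2, c("gA", "gB"))
  expect_equal(nrow(edges), 1)
  expect_equal(edges$r, 1, tolerance = 1e-12)
})

test_that("correlation significance matches cor.test across random pairs", {
  set.seed(12)
  m <- matrix(2^rnorm(5 * 9, 8), 5, 9,
              dimnames = list(paste0("g", 1:5),
                              sprintf("%s_r%d", rep(c("T0", "T1", "T2"), each = 3), 1:3)))
  sheet <- data.frame(sample_id = colnames(m),
                      condition = rep(c("T0", "T1", "T2"), each = 3),
                      replicate = rep(1:3, 3))
  em <- expr_matrix(m, sheet)
  edges <- correlation_edges(em, paste0("g", 1:5), alpha = 1)
  expect_equal(nrow(edges), choose(5, 2))
  lg <- log2(m)
  for (i in seq_len(nrow(edges))) {
    ct <- cor.test(lg[edges$gene_a[i], ], lg[edges$gene_b[i], ])
    expect_equal(edges$r[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(edges$p[i], ct$p.value, tolerance = 1e-10)
  }
})

test_that("a correlation of 0.7 over 9 points is significant at 0.05", {
  # t = 0.7 sqrt(7) / sqrt(1 - 0.49) = 2.593 on 7 df -> two-sided p = 0.036
  p <- 2 * pt(0.7 * sqrt(7) / sqrt(1 - 0.49), 7, lower.tail = FALSE)
  expect_equal(p, 0.0358, tolerance = 1e-2)
  expect_lt(p, 0.05)
})

test_that("sign handling: negative correlations drop when use_abs is off", {
  vals <- seq(1, 5, length.out = 9)
  m <- rbind(gA = 2^vals, gB = 2^rev(vals))
  colnames(m) <- sprintf("%s_r%d", rep(c("T0", "T1", "T2"), each = 3), 1:3)
  sheet <- data.frame(sample_id = colnames(m),
                      condition = rep(c("T0", "T1", "T2"), each = 3),
                      replicate = rep(1:3, 3))
  em <- expr_matrix(m, sheet)
  with_abs <- correlation_edges(em, c("gA", "gB"), use_abs = TRUE)
  without <- correlation_edges(em, c("gA", "gB"), use_abs = FALSE)
  expect_equal(nrow(with_abs), 1)
  expect_equal(with_abs$r, -1, tolerance = 1e-12)
  expect_equal(nrow(without), 0)
})

test_that("edges are symmetric in gene order and stable to row reversal", {
  sim <- generate_expression(synth_config(n_genes = 30, seed = 44))
  genes <- rownames(sim$matrix$signals)
  e1 <- correlation_edges(sim$matrix, genes, alpha = 0.2)
  e2 <- correlation_edges(sim$matrix, rev(genes), alpha = 0.2)
  expect_equal(e1, e2)
  expect_true(all(e1$gene_a < e1$gene_b))
})

test_that("the network is the catalog restricted to correlated pairs", {
  edges <- tibble::tibble(gene_a = "A", gene_b = "B", r = 0.99, p = 1e-5)
  catalog <- tibble::tibble(source = c("A", "B"),
                            relation = c("activation", "activation"),
                            target = c("B", "C"))
  net <- build_signal_net(edges, catalog)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$source, "A")
  expect_equal(net$edges$target, "B")
  expect_false("C" %in% net$nodes$gene)
  # catalog orientation B -> A also survives an A-B correlation edge
  net2 <- build_signal_net(edges, tibble::tibble(source = "B",
                                                 relation = "inhibition",
                                                 target = "A"))
  expect_equal(nrow(net2$edges), 1)
})

test_that("an empty catalog yields an empty network without error", {
  edges <- tibble::tibble(gene_a = "A", gene_b = "B", r = 0.9, p = 1e-4)
  net <- build_signal_net(edges, tibble::tibble(source = character(),
                                                relation = character(),
                                                target = character()))
  expect_equal(nrow(net$nodes), 0)
  expect_equal(nrow(net$edges), 0)
})

test_that("degree counts distinct neighbors; in/out follow edge direction", {
  # hand-built digraph: a->b, a->c, b->c, c->d, d->e, plus duplicate-typed a->b
  catalog <- tibble::tibble(
    source = c("a", "a", "b", "c", "d", "a"),
    relation = c("activation", "activation", "phosphorylation",
                 "activation", "expression", "inhibition"),
    target = c("b", "c", "c", "d", "e", "b"))
  pairs <- tidyr::expand_grid(gene_a = letters[1:5], gene_b = letters[1:5]) |>
    dplyr::filter(gene_a < gene_b) |>
    dplyr::mutate(r = 0.9, p = 1e-6)
  net <- build_signal_net(pairs, catalog)
  stats <- tibble::deframe(dplyr::select(net$nodes, gene, degree))
  expect_equal(stats[c("a", "b", "c", "d", "e")],
               c(a = 2L, b = 2L, c = 3L, d = 2L, e = 1L))
  expect_equal(net$nodes$indegree[net$nodes$gene == "c"], 2L)
  expect_equal(net$nodes$outdegree[net$nodes$gene == "a"], 2L)
  expect_equal(net$nodes$indegree[net$nodes$gene == "a"], 0L)
})

test_that("betweenness closed forms: path, cycle, star", {
  mk_net <- function(src, tgt) {
    pairs <- tibble::tibble(gene_a = pmin(src, tgt), gene_b = pmax(src, tgt),
                            r = 0.9, p = 1e-6)
    build_signal_net(pairs, tibble::tibble(source = src, relation = "activation",
                                           target = tgt))
  }
  path <- mk_net(c("A", "B"), c("B", "C"))
  expect_equal(path$nodes$bc[path$nodes$gene == "B"], 1.0)
  expect_equal(path$nodes$bc[path$nodes$gene != "B"], c(0, 0))

  cyc <- mk_net(c("A", "B", "C", "D"), c("B", "C", "D", "A"))
  expect_equal(cyc$nodes$bc, rep(1 / 6, 4))

  star <- mk_net(rep("hub", 4), paste0("leaf", 1:4))
  expect_equal(star$nodes$bc[star$nodes$gene == "hub"], 1.0)
  expect_equal(sum(star$nodes$bc), 1.0)
})

test_that("fewer than three nodes gives zero betweenness by convention", {
  net <- build_signal_net(
    tibble::tibble(gene_a = "A", gene_b = "B", r = 0.9, p = 1e-6),
    tibble::tibble(source = "A", relation = "activation", target = "B"))
  expect_equal(net$nodes$bc, c(0, 0))
})

test_that("betweenness equals the brute-force oracle on random small graphs", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(3:8, 1)
    nodes <- letters[1:n]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.45
    if (!any(keep)) next
    src <- pairs[keep, 1]; tgt <- pairs[keep, 2]
    net <- build_signal_net(
      tibble::tibble(gene_a = src, gene_b = tgt, r = 0.9, p = 1e-6),
      tibble::tibble(source = src, relation = "activation", target = tgt))
    oracle <- brute_force_bc(net$nodes$gene, net$edges$source, net$edges$target)
    norm <- (nrow(net$nodes) - 1) * (nrow(net$nodes) - 2) / 2
    if (nrow(net$nodes) < 3) next
    expect_equal(net$nodes$bc, unname(oracle[net$nodes$gene]) / norm,
                 tolerance = 1e-12)
    # conservation: total raw bc equals total pair dependency mass
    expect_equal(sum(net$nodes$bc) * norm, sum(oracle), tolerance = 1e-9)
  }
})

test_that("key-gene ranking breaks ties by degree then id", {
  nodes <- tibble::tibble(gene = c("z", "m", "a", "k"),
                          degree = c(3L, 5L, 5L, 1L),
                          indegree = 0L, outdegree = 0L,
                          bc = c(0.5, 0.5, 0.5, 0.9))
  net <- structure(list(edges = tibble::tibble(), nodes = nodes),
                   class = "gene_network")
  ranked <- rank_key_genes(net, top_k = 4)
  expect_equal(ranked$gene, c("k", "a", "m", "z"))
  expect_equal(rank_key_genes(net, top_k = 1)$gene, "k")
})

test_that("a planted bridge gene ranks first across seeded networks", {
  hits <- vapply(1:20, function(s) {
    cfg <- synth_config(n_genes = 1500, seed = 3000 + s)
    sim <- generate_expression(cfg)
    ann <- generate_annotations(sim$truth, cfg)
    genes <- sim$truth$genes$gene[sim$truth$genes$is_de]
    net <- build_signal_net(correlation_edges(sim$matrix, genes), ann$catalog)
    identical(rank_key_genes(net, 1)$gene, ann$bridge_gene)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
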