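# Shared fixtures and independent oracles used across the suite.

# A small balanced expression matrix with the given per-condition log2 group
# means for each probe (list of numeric vectors) and residual values added
# replicate-wise (exact, no RNG unless noise is supplied).
tiny_matrix <- function(log2_means, reps = 3, conditions = c("T0", "T1", "T2"),
                        noise = NULL) {
  k <- length(conditions)
  probes <- names(log2_means) %||% paste0("p", seq_along(log2_means))
  sheet <- expand.grid(replicate = seq_len(reps), condition = conditions,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  sheet$sample_id <- sprintf("%s_r%d", sheet$condition, sheet$replicate)
  m <- t(vapply(log2_means, function(mu) rep(mu, each = reps), numeric(k * reps)))
  if (!is.null(noise)) m <- m + noise
  rownames(m) <- probes
  colnames(m) <- sheet$sample_id
  expr_matrix(2^m, sheet)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Matrix whose 9 samples carry arbitrary per-sample values for one probe.
one_probe_matrix <- function(values, conditions = c("T0", "T1", "T2"), reps = 3) {
  sheet <- expand.grid(replicate = seq_len(reps), condition = conditions,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  sheet$sample_id <- sprintf("%s_r%d", sheet$condition, sheet$replicate)
  ord <- order(match(sheet$condition, conditions))
  sheet <- sheet[ord, ]
  m <- matrix(values, nrow = 1, dimnames = list("p1", sheet$sample_id))
  expr_matrix(2^m, sheet)
}

# Independent betweenness oracle straight from the definition: BFS shortest
# path distances and counts from every node, then for every unordered pair
# (s, t) the dependency of interior v is sigma(s,v) * sigma(v,t) / sigma(s,t)
# whenever dist(s,v) + dist(v,t) = dist(s,t). Undirected, unweighted;
# returns raw (unnormalized) bc.
brute_force_bc <- function(nodes, edges_a, edges_b) {
  n <- length(nodes)
  adj <- lapply(nodes, function(v) {
    setdiff(unique(c(edges_b[edges_a == v], edges_a[edges_b == v])), v)
  })
  names(adj) <- nodes
  bfs <- function(s) {
    dist <- setNames(rep(Inf, n), nodes)
    sigma <- setNames(numeric(n), nodes)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(nodes, bfs)
  names(sp) <- nodes
  bc <- setNames(numeric(n), nodes)
  for (si in seq_len(n)) for (ti in seq_len(n)) {
    if (si >= ti) next
    s <- nodes[si]; t <- nodes[ti]
    if (is.infinite(sp[[s]]$dist[t])) next
    for (v in setdiff(nodes, c(s, t))) {
      if (sp[[s]]$dist[v] + sp[[v]]$dist[t] == sp[[s]]$dist[t]) {
        bc[v] <- bc[v] + sp[[s]]$sigma[v] * sp[[v]]$sigma[t] / sp[[s]]$sigma[t]
      }
    }
  }
  bc
}

# Per-gene within-condition residual mean square, recomputed from scratch.
gene_s2 <- function(em) {
  lg <- log2(em$signals)
  cond <- em$sample_sheet$condition
  ss <- numeric(nrow(lg))
  df <- 0
  for (cc in unique(cond)) {
    sub <- lg[, cond == cc, drop = FALSE]
    ss <- ss + rowSums((sub - rowMeans(sub))^2)
    df <- df + ncol(sub) - 1
  }
  ss / df
}

# Exhaustive hypergeometric upper tail from binomial coefficients only.
brute_force_hyper_tail <- function(k, K, N, n) {
  ks <- k:min(n, K)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Printed profile table of a three-point CO2 series experiment, used as a
# fixed external input for checks on the significance and conservation logic.
series_profile_table <- function() {
  tibble::tibble(
    profile = 1:16,
    assigned = c(73, 100, 212, 72, 440, 498, 94, 290, 119, 499,
                 136, 864, 171, 322, 311, 531),
    expected = c(127.00, 172.33, 304.83, 127.00, 362.67, 368.33, 207.00,
                 362.67, 172.33, 362.67, 207.00, 483.67, 403.50, 403.50,
                 304.83, 362.67),
    printed_p = c(1.0, 1.0, 1.0, 1.0, 2.24e-05, 1.13e-11, 1.0, 1.0, 1.0,
                  8.22e-13, 1.0, 2.17e-62, 1.0, 1.0, 0.37, 3.00e-18))
}
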