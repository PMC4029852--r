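#' Significantly correlated gene pairs
#'
#' Pearson correlation of log2 signals across all samples for every unordered
#' pair of the selected genes, with the two-sided significance of r from
#' t = r sqrt(d - 2) / sqrt(1 - r^2) on d - 2 degrees of freedom (d = number
#' of expression points). With `use_abs` on (the default) the sign is ignored
#' for inclusion but retained in the record.
#'
#' @param x an [expr_matrix()].
#' @param genes probe ids to correlate (>= 2).
#' @param alpha two-sided significance cutoff for keeping a pair.
#' @param use_abs if `FALSE`, only positively correlated significant pairs
#'   are kept.
#' @return Tibble: `gene_a`, `gene_b` (a < b), `r`, `p`.
#' @export
correlation_edges <- function(x, genes, alpha = 0.05, use_abs = TRUE) {
  stopifnot(inherits(x, "expr_matrix"))
  genes <- unique(genes)
  if (length(genes) < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          r = numeric(), p = numeric()))
  }
  missing_g <- setdiff(genes, rownames(x$signals))
  if (length(missing_g) > 0) {
    abort(paste0("unknown gene(s): ", paste(head(missing_g, 5), collapse = ", ")))
  }
  lg <- log2(x$signals[genes, , drop = FALSE])
  d <- ncol(lg)
  if (d < 3) abort("need >= 3 expression points per gene for correlation edges.")
  zero_var <- apply(lg, 1, stats::sd) == 0
  if (any(zero_var)) {
    warn(paste0("zero-variance gene(s) skipped: ",
                paste(head(genes[zero_var], 5), collapse = ", ")))
    genes <- genes[!zero_var]
    lg <- lg[genes, , drop = FALSE]
    if (length(genes) < 2) {
      return(tibble::tibble(gene_a = character(), gene_b = character(),
                            r = numeric(), p = numeric()))
    }
  }
  cm <- stats::cor(t(lg))
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[ut]
  r_clamped <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_clamped * sqrt(d - 2) / sqrt(1 - r_clamped^2)
  p <- 2 * pt(abs(tstat), d - 2, lower.tail = FALSE)
  edges <- tibble::tibble(gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
                          r = r, p = p) |>
    dplyr::mutate(swap = .data$gene_a > .data$gene_b,
                  tmp = ifelse(.data$swap, .data$gene_a, .data$gene_b),
                  gene_a = ifelse(.data$swap, .data$gene_b, .data$gene_a),
                  gene_b = .data$tmp) |>
    dplyr::select(-"swap", -"tmp") |>
    dplyr::filter(.data$p < alpha)
  if (!use_abs) edges <- dplyr::filter(edges, .data$r > 0)
  dplyr::arrange(edges, .data$gene_a, .data$gene_b)
}

#' Build the signal-transduction network
#'
#' Restricts the directed, typed relations of an interaction catalog to gene
#' pairs that are significantly correlated (either orientation), drops nodes
#' with no surviving edge, and computes per-node degree (distinct neighbors,
#' direction-blind), indegree and outdegree, and normalized betweenness
#' centrality.
#'
#' @param edges tibble from [correlation_edges()].
#' @param catalog interaction tibble (`source`, `relation`, `target`), e.g.
#'   from [read_sif()].
#' @param bc_mode compute betweenness on the `"undirected"` (default) or
#'   `"directed"` view.
#' @return A `gene_network`: list with `edges` (source, relation, target) and
#'   `nodes` (gene, degree, indegree, outdegree, bc).
#' @export
build_signal_net <- function(edges, catalog, bc_mode = c("undirected", "directed")) {
  bc_mode <- match.arg(bc_mode)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  keep <- catalog
  if (nrow(catalog) > 0) {
    allowed <- key(edges$gene_a, edges$gene_b)
    keep <- catalog[key(catalog$source, catalog$target) %in% allowed, , drop = FALSE]
  }
  keep <- tibble::as_tibble(keep)
  nodes <- sort(unique(c(keep$source, keep$target)))
  net <- structure(list(edges = keep,
                        nodes = tibble::tibble(gene = nodes)),
                   class = "gene_network")
  if (length(nodes) == 0) {
    net$nodes <- tibble::tibble(gene = character(), degree = integer(),
                                indegree = integer(), outdegree = integer(),
                                bc = numeric())
    return(net)
  }
  neighbor_pairs <- dplyr::distinct(
    tibble::tibble(a = c(keep$source, keep$target), b = c(keep$target, keep$source)))
  degree <- dplyr::count(neighbor_pairs, .data$a, name = "degree")
  outdeg <- dplyr::count(dplyr::distinct(keep, .data$source, .data$target),
                         .data$source, name = "outdegree")
  indeg <- dplyr::count(dplyr::distinct(keep, .data$source, .data$target),
                        .data$target, name = "indegree")
  net$nodes <- tibble::tibble(gene = nodes) |>
    dplyr::left_join(degree, by = c(gene = "a")) |>
    dplyr::left_join(indeg, by = c(gene = "target")) |>
    dplyr::left_join(outdeg, by = c(gene = "source")) |>
    dplyr::mutate(dplyr::across(c("degree", "indegree", "outdegree"),
                                function(v) dplyr::coalesce(v, 0L)))
  net$nodes$bc <- unname(betweenness_centrality(net, bc_mode)[net$nodes$gene])
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.gene_network <- function(x, ...) x$nodes

#' Normalized betweenness centrality
#'
#' Brandes shortest-path betweenness on the unweighted graph, normalized by
#' (N-1)(N-2)/2 for the undirected view and (N-1)(N-2) for the directed view
#' so values lie in `[0, 1]`. Networks with fewer than 3 nodes have no
#' possible intermediary; all values are 0 by convention.
#'
#' @param network a `gene_network`.
#' @param mode `"undirected"` (default) or `"directed"`.
#' @return Named numeric vector of bc values, one per node.
#' @export
betweenness_centrality <- function(network, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  nodes <- network$nodes$gene
  n <- length(nodes)
  if (n == 0) return(stats::setNames(numeric(0), character(0)))
  if (n < 3 || nrow(network$edges) == 0) {
    return(stats::setNames(numeric(n), nodes))
  }
  g <- igraph::graph_from_data_frame(
    network$edges[, c("source", "target")], directed = (mode == "directed"),
    vertices = nodes)
  if (mode == "undirected") g <- igraph::simplify(g)
  raw <- igraph::betweenness(g, directed = (mode == "directed"), weights = NA)
  denom <- if (mode == "directed") (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  bc <- raw / denom
  stats::setNames(as.numeric(bc[nodes]), nodes)
}

#' Rank key genes by betweenness centrality
#'
#' Orders nodes by descending bc, breaking ties by descending degree then
#' lexicographic gene id, and returns the head of the ranking: the candidate
#' core regulators of the network.
#'
#' @param network a `gene_network`.
#' @param top_k number of genes to return.
#' @return Tibble of the top-ranked nodes with their full stats and `rank`.
#' @export
rank_key_genes <- function(network, top_k = 10) {
  ranked <- network$nodes |>
    dplyr::arrange(dplyr::desc(.data$bc), dplyr::desc(.data$degree), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number())
  head(ranked, top_k)
}
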