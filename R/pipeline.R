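#' Run the full staged analysis
#'
#' Orchestrates the pipeline end-to-end on in-memory inputs: moderated RVM
#' F-test with BH FDR -> DEG selection -> log2-ratio profile assignment with
#' permutation-expected counts and binomial profile significance ->
#' hypergeometric enrichment of the significant-profile genes -> correlation
#' edges intersected with the interaction catalog -> betweenness ranking.
#' Every threshold lands in the run manifest; identical inputs and seed give
#' identical outputs.
#'
#' @param x an [expr_matrix()].
#' @param annotations an `annotation_set`, or NULL to skip enrichment.
#' @param catalog interaction tibble (`source`, `relation`, `target`), or
#'   NULL to skip the network stage.
#' @param p_max,fdr_max DEG selection thresholds.
#' @param alpha_profiles profile-significance level.
#' @param enrich_p_max,enrich_re_min enrichment thresholds.
#' @param net_alpha correlation-edge significance level.
#' @param top_k number of key genes to report.
#' @param min_corr minimum profile-assignment correlation.
#' @param profiles model-profile catalog.
#' @param out_dir if non-NULL, write all stage tables and a JSON manifest
#'   there via [write_results_tables()].
#' @param seed seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return A `co2prof_run` list with elements `prior`, `de`, `degs`,
#'   `profile_stats`, `significant_profiles`, `profile_genes`, `enrichment`,
#'   `enriched`, `network`, `key_genes`, and `params`.
#' @export
run_pipeline <- function(x, annotations = NULL, catalog = NULL,
                         p_max = 0.05, fdr_max = 0.05, alpha_profiles = 0.05,
                         enrich_p_max = 0.05, enrich_re_min = 0,
                         net_alpha = 0.05, top_k = 10, min_corr = 0,
                         profiles = default_profiles(), out_dir = NULL,
                         seed = NA_integer_) {
  stopifnot(inherits(x, "expr_matrix"))
  params <- list(p_max = p_max, fdr_max = fdr_max, alpha_profiles = alpha_profiles,
                 enrich_p_max = enrich_p_max, enrich_re_min = enrich_re_min,
                 net_alpha = net_alpha, top_k = top_k, min_corr = min_corr)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
    message(sprintf("[co2prof] %-10s %6.2fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  prior <- stage("detest", fit_rvm_prior(x))
  de <- rvm_f_test(x, prior)
  degs <- select_degs(de, p_max, fdr_max)

  pstats <- stage("profiles", {
    vectors <- log2_ratio_vectors(x, degs)
    profile_stats(vectors, profiles, min_corr)
  })
  sig_profiles <- significant_profiles(pstats, alpha_profiles)
  assignments <- assign_profiles(log2_ratio_vectors(x, degs), profiles, min_corr)
  profile_genes <- assignments$probe[!is.na(assignments$profile) &
                                       assignments$profile %in% sig_profiles]

  enrichment <- NULL
  enriched <- NULL
  if (!is.null(annotations) && length(profile_genes) > 0) {
    enrichment <- stage("enrich",
      hypergeom_enrichment(profile_genes, rownames(x$signals), annotations))
    enriched <- filter_enriched(enrichment, enrich_p_max, enrich_re_min)
  }

  network <- NULL
  key_genes <- NULL
  if (!is.null(catalog)) {
    network <- stage("signalnet", {
      edges <- if (length(profile_genes) >= 2) {
        correlation_edges(x, profile_genes, net_alpha)
      } else {
        tibble::tibble(gene_a = character(), gene_b = character(),
                       r = numeric(), p = numeric())
      }
      build_signal_net(edges, catalog)
    })
    key_genes <- rank_key_genes(network, top_k)
  }

  run <- structure(
    list(prior = prior, de = de, degs = degs, profile_stats = pstats,
         significant_profiles = sig_profiles, profile_genes = profile_genes,
         enrichment = enrichment, enriched = enriched,
         network = network, key_genes = key_genes, params = params),
    class = "co2prof_run")

  if (!is.null(out_dir)) {
    tables <- list(de_results = de,
                   profile_stats = tibble::as_tibble(pstats))
    if (!is.null(enrichment)) tables$enrichment <- tibble::as_tibble(enrichment)
    if (!is.null(network)) {
      tables$network_nodes <- network$nodes
      tables$network_edges <- network$edges
      tables$key_genes <- key_genes
    }
    write_results_tables(tables, out_dir, params = params, seed = seed)
  }
  run
}

#' @export
print.co2prof_run <- function(x, ...) {
  cat(sprintf(paste0("<co2prof_run> %d DEGs; significant profiles: %s; ",
                     "%s enriched categories; network: %s nodes\n"),
              length(x$degs),
              if (length(x$significant_profiles)) paste(x$significant_profiles, collapse = ", ") else "none",
              if (is.null(x$enriched)) "NA" else nrow(x$enriched),
              if (is.null(x$network)) "NA" else nrow(x$network$nodes)))
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `co2prof_run`.
#' @param ... unused.
#' @export
glance.co2prof_run <- function(x, ...) {
  tibble::tibble(
    n_degs = length(x$degs),
    n_significant_profiles = length(x$significant_profiles),
    n_profile_genes = length(x$profile_genes),
    n_enriched = if (is.null(x$enriched)) NA_integer_ else nrow(x$enriched),
    n_network_nodes = if (is.null(x$network)) NA_integer_ else nrow(x$network$nodes),
    top_gene = if (is.null(x$key_genes) || nrow(x$key_genes) == 0) NA_character_
               else x$key_genes$gene[1])
}
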