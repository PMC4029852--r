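#' Hypergeometric over-representation of annotation categories
#'
#' For a study gene set of size n drawn from a background of size N, a
#' category with K background members and k study hits is scored by the
#' hypergeometric upper tail p = P(X >= k) and the enrichment ratio
#' Re = (k/n) / (K/N). Annotation gene sets are intersected with the
#' background before counting; categories with no study hit are dropped.
#'
#' @param study character vector of study genes (must be within `background`).
#' @param background character vector defining the universe (typically all
#'   probes on the array).
#' @param annotations an `annotation_set`.
#' @param ease use the conservative EASE-score convention: the tail is
#'   computed at k - 1 (the enrichment ratio still uses the unmodified k).
#' @return Tibble: `namespace`, `category`, `description`, `k`, `n`, `K`,
#'   `N`, `p`, `re`.
#' @examples
#' ann <- annotation_set(
#'   tibble::tibble(category = "C1", description = "demo",
#'                  genes = list(paste0("g", 1:5))),
#'   namespace = "demo")
#' hypergeom_enrichment(paste0("g", 1:5), paste0("g", 1:20), ann)
#' @export
hypergeom_enrichment <- function(study, background, annotations, ease = FALSE) {
  stopifnot(inherits(annotations, "annotation_set"))
  study <- unique(study)
  background <- unique(background)
  if (length(study) == 0 || length(background) == 0) {
    abort("study and background sets must be non-empty.")
  }
  offenders <- setdiff(study, background)
  if (length(offenders) > 0) {
    abort(paste0("study genes outside background: ",
                 paste(head(offenders, 5), collapse = ", ")))
  }
  n <- length(study)
  N <- length(background)
  res <- annotations$categories |>
    dplyr::mutate(
      genes_in_bg = purrr::map(.data$genes, intersect, background),
      K = lengths(.data$genes_in_bg),
      k = purrr::map_int(.data$genes_in_bg, function(g) length(intersect(g, study)))) |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::mutate(
      n = n, N = N,
      p = phyper(.data$k - 1 - as.integer(ease), .data$K, N - .data$K, n,
                 lower.tail = FALSE),
      re = (.data$k / n) / (.data$K / N),
      namespace = annotations$namespace) |>
    dplyr::select("namespace", "category", "description",
                  "k", "n", "K", "N", "p", "re")
  class(res) <- c("enrichment_result", class(res))
  res
}

#' Filter and order enrichment results
#'
#' Applies the dual threshold p < `p_max` and Re > `re_min` (use `re_min = 5`
#' for a GO-style enrichment-ratio filter, 0 for a pathway-style p-only
#' filter), sorts by ascending p and adds `neg_log10_p` for plotting.
#'
#' @param results tibble from [hypergeom_enrichment()].
#' @param p_max p-value cutoff (exclusive).
#' @param re_min enrichment-ratio cutoff (exclusive).
#' @param adjust apply Benjamini-Hochberg to the p-values before filtering.
#' @return Filtered, p-sorted tibble with `neg_log10_p` appended.
#' @export
filter_enriched <- function(results, p_max = 0.05, re_min = 0, adjust = FALSE) {
  res <- tibble::as_tibble(results)
  if (adjust && nrow(res) > 0) res$p <- bh_fdr(res$p)
  res |>
    dplyr::filter(.data$p < p_max, .data$re > re_min) |>
    dplyr::arrange(.data$p) |>
    dplyr::mutate(neg_log10_p = -log10(.data$p))
}
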