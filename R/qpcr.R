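#' Relative quantification by the 2^-ddCt method
#'
#' Technical replicates are averaged first. Within each biological replicate
#' block, dCt = mean Ct(target) - mean Ct(reference gene); then
#' ddCt = dCt(condition) - mean dCt(control condition) and the fold change is
#' 2^-ddCt, assuming perfect doubling per cycle. Because the reference gene
#' is differenced within every block, any constant shift of a block's Ct
#' values cancels exactly.
#'
#' @param plate a `qpcr_plate` (see [read_qpcr()] / [qpcr_plate()]).
#' @param control_condition label of the calibrator condition.
#' @return Tibble: `gene`, `condition`, `fold` (mean 2^-ddCt over biological
#'   replicates), `sd` (SD of per-replicate folds), `n_bio`.
#' @examples
#' rows <- expand.grid(gene = c("tgt", "act"), condition = c("T0", "T1"),
#'                     bio_rep = 1, tech_rep = 1:2)
#' rows$ct <- ifelse(rows$gene == "act", 20, ifelse(rows$condition == "T0", 24, 23))
#' ddct_fold_change(qpcr_plate(rows, "act"), "T0")
#' @export
ddct_fold_change <- function(plate, control_condition) {
  stopifnot(inherits(plate, "qpcr_plate"))
  ref <- attr(plate, "reference_gene")
  tab <- tibble::as_tibble(plate)
  if (!control_condition %in% tab$condition) {
    abort(paste0("control condition not present: ", control_condition))
  }
  tech_means <- tab |>
    dplyr::group_by(.data$gene, .data$condition, .data$bio_rep) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  ref_ct <- tech_means |>
    dplyr::filter(.data$gene == ref) |>
    dplyr::select("condition", "bio_rep", ref_ct = "ct")
  dct <- tech_means |>
    dplyr::inner_join(ref_ct, by = c("condition", "bio_rep")) |>
    dplyr::mutate(dct = .data$ct - .data$ref_ct)
  control_dct <- dct |>
    dplyr::filter(.data$condition == control_condition) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(control_dct = mean(.data$dct), .groups = "drop")
  dct |>
    dplyr::inner_join(control_dct, by = "gene") |>
    dplyr::mutate(fold_rep = 2^(-(.data$dct - .data$control_dct))) |>
    dplyr::group_by(.data$gene, .data$condition) |>
    dplyr::summarise(fold = mean(.data$fold_rep),
                     sd = stats::sd(.data$fold_rep),
                     n_bio = dplyr::n(), .groups = "drop")
}

#' Concordance between array and qPCR fold changes
#'
#' Pearson correlation between microarray log2 fold changes and log2 of the
#' qPCR 2^-ddCt folds over matched (gene, condition) pairs, with the
#' two-sided p-value from the t transform of r.
#'
#' @param array_log2fc tibble with columns `gene`, `condition`, `log2fc`.
#' @param qpcr_folds tibble from [ddct_fold_change()].
#' @return One-row tibble: `r`, `p`, `n_pairs`.
#' @export
platform_concordance <- function(array_log2fc, qpcr_folds) {
  matched <- dplyr::inner_join(array_log2fc, qpcr_folds,
                               by = c("gene", "condition"))
  if (nrow(matched) < 3) abort("need >= 3 matched (gene, condition) pairs.")
  r <- stats::cor(matched$log2fc, log2(matched$fold))
  d <- nrow(matched)
  tstat <- r * sqrt(d - 2) / sqrt(1 - r^2)
  tibble::tibble(r = r, p = 2 * pt(abs(tstat), d - 2, lower.tail = FALSE),
                 n_pairs = d)
}
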