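#' Expression matrix container
#'
#' An `expr_matrix` bundles a probes x samples grid of positive, normalized,
#' linear-scale signal intensities with the sample-to-condition design. The
#' pipeline performs its own log2 transforms downstream, so signals must be
#' strictly positive. Conditions are ordered; the first condition is the
#' reference against which all log2 ratios are anchored.
#'
#' @param signals numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids); all entries > 0.
#' @param sample_sheet data frame with columns `sample_id`, `condition`,
#'   `replicate` covering exactly the matrix columns. Condition order is taken
#'   from first appearance in the sheet, not sorted.
#' @return An object of class `expr_matrix` with elements `signals`,
#'   `sample_sheet` (tibble) and `condition_order` (character).
#' @examples
#' m <- matrix(2^rnorm(12, 8), 2, 6,
#'   dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
#' sheet <- data.frame(
#'   sample_id = paste0("s", 1:6),
#'   condition = rep(c("T0", "T1", "T2"), each = 2),
#'   replicate = rep(1:2, 3))
#' em <- expr_matrix(m, sheet)
#' conditions(em)
#' @export
expr_matrix <- function(signals, sample_sheet) {
  if (!is.matrix(signals) || !is.numeric(signals)) {
    abort("`signals` must be a numeric matrix.")
  }
  if (is.null(rownames(signals)) || is.null(colnames(signals))) {
    abort("`signals` must carry probe ids as rownames and sample ids as colnames.")
  }
  sheet <- tibble::as_tibble(sample_sheet)
  required <- c("sample_id", "condition", "replicate")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$condition <- as.character(sheet$condition)
  sheet$replicate <- as.integer(sheet$replicate)

  if (anyDuplicated(rownames(signals))) {
    dup <- unique(rownames(signals)[duplicated(rownames(signals))])
    abort(paste0("duplicate probe id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(signals))) {
    abort("duplicate sample ids in expression matrix.")
  }
  if (anyDuplicated(sheet$sample_id)) {
    abort("duplicate sample ids in sample sheet.")
  }
  not_in_sheet <- setdiff(colnames(signals), sheet$sample_id)
  if (length(not_in_sheet) > 0) {
    abort(paste0("sample(s) missing from sample sheet: ",
                 paste(not_in_sheet, collapse = ", ")))
  }
  extra <- setdiff(sheet$sample_id, colnames(signals))
  if (length(extra) > 0) {
    abort(paste0("sample sheet row(s) with no matrix column: ",
                 paste(extra, collapse = ", ")))
  }
  bad <- which(!is.finite(signals) | signals <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "non-positive or non-finite signal at probe '%s', sample '%s' (log2 undefined)",
      rownames(signals)[bad[1, 1]], colnames(signals)[bad[1, 2]]))
  }
  if (any(!is.finite(sheet$replicate) | sheet$replicate < 1)) {
    abort("replicate indices must be positive integers.")
  }

  cond_order <- unique(sheet$condition)
  if (length(cond_order) < 2) {
    abort("need at least 2 conditions.")
  }
  reps <- table(sheet$condition)
  if (any(reps < 2)) {
    abort(paste0("every condition needs >= 2 replicates; offending: ",
                 paste(names(reps)[reps < 2], collapse = ", ")))
  }

  sheet <- sheet[match(colnames(signals), sheet$sample_id), , drop = FALSE]
  structure(
    list(signals = signals, sample_sheet = sheet, condition_order = cond_order),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d probes x %d samples; conditions: %s\n",
              nrow(x$signals), ncol(x$signals),
              paste(x$condition_order, collapse = " < ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$signals)

#' Condition order of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of condition labels, reference first.
#' @export
conditions <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$condition_order
}

#' Per-condition means of log2 signals
#'
#' @param x an `expr_matrix`.
#' @param probes optional character vector restricting the rows.
#' @return Tibble with a `probe` column and one column of mean log2 signal per
#'   condition, columns in condition order.
#' @export
condition_log2_means <- function(x, probes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  sig <- x$signals
  if (!is.null(probes)) {
    missing_p <- setdiff(probes, rownames(sig))
    if (length(missing_p) > 0) {
      abort(paste0("unknown probe(s): ", paste(head(missing_p, 5), collapse = ", ")))
    }
    sig <- sig[probes, , drop = FALSE]
  }
  lg <- log2(sig)
  cond <- x$sample_sheet$condition[match(colnames(sig), x$sample_sheet$sample_id)]
  means <- vapply(x$condition_order, function(cc) {
    rowMeans(lg[, cond == cc, drop = FALSE])
  }, numeric(nrow(sig)))
  if (nrow(sig) == 1L) means <- matrix(means, nrow = 1, dimnames = list(rownames(sig), x$condition_order))
  tibble::as_tibble(means) |>
    dplyr::mutate(probe = rownames(sig), .before = 1)
}

#' Subset an expression matrix by probes
#' @param x an `expr_matrix`.
#' @param probes probe ids to retain.
#' @return An `expr_matrix` with the selected rows.
#' @export
filter_probes <- function(x, probes) {
  stopifnot(inherits(x, "expr_matrix"))
  missing_p <- setdiff(probes, rownames(x$signals))
  if (length(missing_p) > 0) {
    abort(paste0("unknown probe(s): ", paste(head(missing_p, 5), collapse = ", ")))
  }
  expr_matrix(x$signals[probes, , drop = FALSE], x$sample_sheet)
}
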