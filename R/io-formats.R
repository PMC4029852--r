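#' Read an expression matrix with its sample sheet
#'
#' The expression file is tab-separated: first column probe id, header row of
#' sample ids, positive linear-scale signals. The sample sheet is a CSV with
#' columns `sample_id`, `condition`, `replicate`; condition order is taken
#' from first appearance in the sheet (first condition = reference).
#'
#' @param path path to the expression TSV.
#' @param sample_sheet_path path to the sample-sheet CSV.
#' @return A validated [expr_matrix()].
#' @export
read_expression_matrix <- function(path, sample_sheet_path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2) abort(paste0("expression file has no sample columns: ", path))
  probe_ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(paste0("non-numeric signal values in ", path))
  rownames(m) <- probe_ids
  sheet <- readr::read_csv(sample_sheet_path, show_col_types = FALSE, progress = FALSE)
  expr_matrix(m, sheet)
}

#' Write an expression matrix and its sample sheet
#'
#' @param x an `expr_matrix`.
#' @param path destination TSV for signals.
#' @param sample_sheet_path destination CSV for the design; defaults to
#'   `path` with a `_samples.csv` suffix.
#' @return Invisibly, the two paths written.
#' @export
write_expression_matrix <- function(x, path,
                                    sample_sheet_path = sub("\\.tsv$", "", path) |>
                                      paste0("_samples.csv")) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- tibble::as_tibble(x$signals) |>
    dplyr::mutate(probe_id = rownames(x$signals), .before = 1)
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_csv(x$sample_sheet, sample_sheet_path, progress = FALSE)
  invisible(c(path, sample_sheet_path))
}

#' Read gene sets from a GMT file
#'
#' One category per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path path to the GMT file.
#' @param namespace label for the collection (e.g. "GO-BP", "KEGG").
#' @return An `annotation_set`: list with `namespace` and `categories`, a
#'   tibble of (category, description, genes list-column).
#' @export
read_gmt <- function(path, namespace = "GO-BP") {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parsed <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT parse error at line %d: need >= 3 tab-separated fields", i))
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(sprintf("GMT parse error at line %d: empty gene list", i))
    }
    tibble::tibble(category = fields[1], description = fields[2],
                   genes = list(genes))
  })
  categories <- dplyr::bind_rows(parsed)
  if (anyDuplicated(categories$category)) {
    abort("duplicate category ids in GMT file.")
  }
  annotation_set(categories, namespace)
}

#' Construct an annotation set
#' @param categories tibble with columns `category`, `description` and a
#'   list-column `genes` of character vectors.
#' @param namespace collection label.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(categories, namespace) {
  categories <- tibble::as_tibble(categories)
  stopifnot(all(c("category", "description", "genes") %in% names(categories)))
  if (anyDuplicated(categories$category)) abort("category ids must be unique.")
  if (any(lengths(categories$genes) == 0)) abort("category gene sets must be non-empty.")
  structure(list(namespace = namespace, categories = categories),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d categories, median size %d\n",
              x$namespace, nrow(x$categories),
              as.integer(stats::median(lengths(x$categories$genes)))))
  invisible(x)
}

#' Write an annotation set to GMT
#' @param x an `annotation_set`.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  lines <- purrr::pmap_chr(x$categories, function(category, description, genes) {
    paste(c(category, description, genes), collapse = "\t")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a directed interaction catalog from SIF
#'
#' Each line is `source<TAB>relation<TAB>target[<TAB>target2 ...]`;
#' multi-target lines are expanded to one relation per target and duplicate
#' relations are collapsed.
#'
#' @param path path to the SIF file.
#' @param allow_self keep self-relations (default drops them).
#' @return Tibble with columns `source`, `relation`, `target`.
#' @export
read_sif <- function(path, allow_self = FALSE) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  rel <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("SIF parse error at line %d: need source, relation, target", i))
    }
    tibble::tibble(source = fields[1], relation = fields[2], target = fields[-(1:2)])
  }) |> dplyr::bind_rows()
  if (nrow(rel) > 0 && !allow_self) {
    rel <- dplyr::filter(rel, .data$source != .data$target)
  }
  dplyr::distinct(rel)
}

#' Write an interaction catalog to SIF
#' @param catalog tibble with columns `source`, `relation`, `target`.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(catalog, path) {
  lines <- sprintf("%s\t%s\t%s", catalog$source, catalog$relation, catalog$target)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `gene`, `condition`, `bio_rep`, `tech_rep`, `ct`.
#' Ct values must be finite and within `[0, 45]` cycles.
#'
#' @param path path to the CSV.
#' @param reference_gene id of the housekeeping reference gene; must appear in
#'   every (condition, biological replicate) block.
#' @return A `qpcr_plate`: tibble of Ct rows with the reference gene recorded
#'   as an attribute.
#' @export
read_qpcr <- function(path, reference_gene) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  qpcr_plate(tab, reference_gene)
}

#' Construct a validated qPCR plate
#' @param rows data frame with columns `gene`, `condition`, `bio_rep`,
#'   `tech_rep`, `ct`.
#' @param reference_gene housekeeping gene id.
#' @return A `qpcr_plate` tibble.
#' @export
qpcr_plate <- function(rows, reference_gene) {
  rows <- tibble::as_tibble(rows)
  required <- c("gene", "condition", "bio_rep", "tech_rep", "ct")
  missing_cols <- setdiff(required, names(rows))
  if (length(missing_cols) > 0) {
    abort(paste0("qPCR table missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(rows$ct) | rows$ct < 0 | rows$ct > 45)) {
    abort("Ct values must be finite and within [0, 45] cycles.")
  }
  blocks <- dplyr::distinct(rows, .data$condition, .data$bio_rep)
  ref_blocks <- dplyr::distinct(rows[rows$gene == reference_gene, ],
                                .data$condition, .data$bio_rep)
  missing_blocks <- dplyr::anti_join(blocks, ref_blocks,
                                     by = c("condition", "bio_rep"))
  if (nrow(missing_blocks) > 0) {
    abort(sprintf(
      "reference gene '%s' missing from block (condition %s, bio_rep %s)",
      reference_gene, missing_blocks$condition[1], missing_blocks$bio_rep[1]))
  }
  structure(rows, reference_gene = reference_gene,
            class = c("qpcr_plate", class(rows)))
}

#' Write a qPCR plate to CSV
#' @param plate a `qpcr_plate`.
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_qpcr <- function(plate, path) {
  readr::write_csv(tibble::as_tibble(plate), path, progress = FALSE)
  invisible(path)
}
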