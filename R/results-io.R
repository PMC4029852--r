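#' Write pipeline result tables and a run manifest
#'
#' Every table is written as a TSV with its existing (stable) column order;
#' a JSON manifest records the parameters, the seed, file checksums and the
#' package version so a run is fully reproducible and auditable.
#'
#' @param results named list of data frames (one TSV per element).
#' @param out_dir output directory, created if needed.
#' @param params named list of thresholds/parameters used by the run.
#' @param seed integer seed of the run (NA if none used).
#' @return Invisibly, the manifest path.
#' @export
write_results_tables <- function(results, out_dir, params = list(), seed = NA_integer_) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create output directory: ", out_dir))
  }
  if (file.access(out_dir, mode = 2) != 0) {
    abort(paste0("output directory not writable: ", out_dir))
  }
  stopifnot(is.list(results), !is.null(names(results)), all(nzchar(names(results))))
  files <- purrr::imap_chr(results, function(tab, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    readr::write_tsv(tibble::as_tibble(tab), path, progress = FALSE)
    path
  })
  manifest <- list(
    package = "co2prof",
    version = as.character(utils::packageVersion("co2prof")),
    seed = seed,
    parameters = params,
    tables = purrr::map(files, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}
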