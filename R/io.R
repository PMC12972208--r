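#' Read and write the pipeline's plain-text formats
#'
#' Expression matrices travel as TSV with the feature identifier in the first
#' column and one column per sample; clinical tables, probe-gene maps and QC
#' metric tables as plain TSV; gene signatures as GMT or one-symbol-per-line
#' lists; simulation ground truth and analysis manifests as JSON.
#'
#' @param path File path.
#' @return `read_expression()` returns a wide expression tibble
#'   (`feature_id` + one numeric column per sample); `read_clinical()` and
#'   `read_qc_metrics()` return tibbles; `read_probe_map()` returns a tibble
#'   with columns `probe_id`, `gene_symbol`; `read_shared_probes()` a
#'   character vector.
#' @name senosurv_io
NULL

#' @rdname senosurv_io
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(x)[1] <- "feature_id"
  check_expression(x)
}

#' @rdname senosurv_io
#' @param x Object to write.
#' @export
write_expression <- function(x, path) {
  readr::write_tsv(check_expression(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname senosurv_io
#' @export
read_clinical <- function(path) {
  check_clinical(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname senosurv_io
#' @export
write_clinical <- function(x, path) {
  readr::write_tsv(check_clinical(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname senosurv_io
#' @export
read_qc_metrics <- function(path) {
  qc <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(qc)[1] != "sample_id") names(qc)[1] <- "sample_id"
  as_tibble(qc)
}

#' @rdname senosurv_io
#' @export
write_qc_metrics <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname senosurv_io
#' @export
read_probe_map <- function(path) {
  m <- readr::read_tsv(path, col_names = c("probe_id", "gene_symbol"),
                       col_types = "cc", skip = guess_header(path, c("probe_id", "gene_symbol")),
                       progress = FALSE)
  if (anyDuplicated(m$probe_id)) abort("probe ids must be unique in the probe-gene map")
  m
}

# Skip one line if the file starts with the expected header
guess_header <- function(path, header) {
  first <- readr::read_lines(path, n_max = 1)
  if (length(first) && identical(strsplit(first, "\t")[[1]][seq_along(header)], header)) 1L else 0L
}

#' @rdname senosurv_io
#' @export
read_shared_probes <- function(path) {
  ids <- readr::read_lines(path, progress = FALSE)
  ids <- ids[nzchar(ids)]
  if (!length(ids)) abort("shared-probe list is empty")
  ids
}
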