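#' Serialize a valley test result
#'
#' JSON (default) keeps every field of the result — per-class table, the
#' permutation-null summary and the configuration — and round-trips through
#' [read_results()]. TSV writes the per-class table only.
#'
#' @param result A `valley_test` object.
#' @param path Output path; format from extension (`.json` / `.tsv`)
#'   unless `format` is given.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.tsv$", path)) "tsv" else "json"
  }
  if (format == "tsv") {
    readr::write_tsv(result$by_class, path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(by_class = result$by_class,
           null_summary = result$null_summary,
           config = result$config),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(by_class = as_tibble(x$by_class),
                 null_summary = if (!is.null(x$null_summary)) as_tibble(x$null_summary),
                 controls = NULL,
                 config = x$config),
            class = "valley_test")
}
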