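#' Write stage output tables as TSV
#'
#' Every analysis stage returns tibbles; this writes them with a fixed
#' column order (the tibble's own), floats rounded to 4 decimals, one row
#' per entity. An empty tibble yields a header-only file.
#'
#' @param tbl a data frame
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_table_tsv <- function(tbl, path) {
  stopifnot(is.data.frame(tbl))
  out <- dplyr::mutate(tbl, dplyr::across(
    dplyr::where(is.double), ~ round(.x, 4)))
  # list-columns are not representable in TSV
  out <- out[, !vapply(out, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a set of named tables into a directory
#' @param tables named list of data frames
#' @param dir output directory (created if needed)
#' @return named vector of file paths, invisibly
#' @export
write_tables <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    write_table_tsv(tables[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }, character(1))
  invisible(paths)
}
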