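#' Read and write the package's tabular interchange formats
#'
#' Variant observations travel as VCF-like TSV with columns CHROM, POS,
#' REF, ALT, ALT_COUNT, DEPTH, FILTER (PASS / missed), SAMPLE; copy-number
#' segments as BED-like TSV (chrom, start, end, total_cn, minor_cn,
#' sample); drug plates and expression counts as CSV.
#'
#' @param observations Tibble with `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `called`, `sample`.
#' @param path File path.
#' @return Readers return tibbles in the package's column conventions;
#'   writers return `path` invisibly.
#' @name concord_io
NULL

#' @rdname concord_io
#' @export
write_variant_table <- function(observations, path) {
  observations |>
    mutate(FILTER = ifelse(.data$called, "PASS", "missed")) |>
    select(CHROM = "chrom", POS = "pos", REF = "ref", ALT = "alt",
           ALT_COUNT = "alt_count", DEPTH = "depth", "FILTER",
           SAMPLE = "sample") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname concord_io
#' @export
read_variant_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) |>
    select(chrom = "CHROM", pos = "POS", ref = "REF", alt = "ALT",
           alt_count = "ALT_COUNT", depth = "DEPTH", filter = "FILTER",
           sample = "SAMPLE") |>
    mutate(called = .data$filter == "PASS") |>
    select(-"filter")
}

#' @rdname concord_io
#' @param segments Tibble with `chrom`, `start`, `end`, `total_cn`,
#'   `minor_cn` and optionally `sample`.
#' @export
write_cn_segments <- function(segments, path) {
  readr::write_tsv(segments, path)
  invisible(path)
}

#' @rdname concord_io
#' @export
read_cn_segments <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname concord_io
#' @param plate Long plate tibble (see [simulate_plate()]).
#' @export
write_plate <- function(plate, path) {
  readr::write_csv(plate, path)
  invisible(path)
}

#' @rdname concord_io
#' @export
read_plate <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname concord_io
#' @param fit An `exposure_fit` (or several row-bound together, with a
#'   `sample` column).
#' @export
write_exposures <- function(fit, path) {
  readr::write_csv(fit, path)
  invisible(path)
}
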