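#' Total-area normalization of a cohort table
#'
#' Divides each sample's bucket vector by its sum, so every row sums to one.
#' This corrects for differences in overall sample amount before multivariate
#' analysis. The operation is idempotent and invariant to positive per-sample
#' scale factors.
#'
#' @param data Cohort table (design columns + bucket columns, see
#'   [bucket_cols()]).
#' @return The cohort table with normalized bucket columns, as a tibble.
#' @examples
#' df <- tibble::tibble(sample_id = "s1", dose = "Control", time = "PND21",
#'                      `1.005` = 2, `1.015` = 3, `1.025` = 5)
#' normalize_total_area(df)
#' @export
normalize_total_area <- function(data) {
  bc <- bucket_cols(data)
  m <- bucket_matrix(data)
  rs <- rowSums(m)
  bad <- which(rs <= 0 | !is.finite(rs))
  if (length(bad) > 0) {
    ids <- if ("sample_id" %in% names(data)) data$sample_id[bad] else bad
    abort(paste0("sample(s) with non-positive total area: ",
                 paste(ids, collapse = ", ")))
  }
  out <- tibble::as_tibble(data)
  out[bc] <- tibble::as_tibble(m / rs)
  attr(out, "normalized") <- TRUE
  out
}

#' Read a samples-by-buckets table with design metadata
#'
#' Reads a bucket intensity table in the layout of deposited normalized-bucket
#' NMR tables: one row per sample; the design columns `sample_id`, `dose`,
#' `time` (and optionally `animal_id`); and one column per bucket, headed by
#' its center chemical shift in ppm (conventionally in descending NMR order).
#'
#' @param path File path.
#' @param format `"auto"` (from the extension), `"csv"`, `"tsv"` or `"xlsx"`
#'   (first sheet, single header row; requires the readxl package).
#' @param grid Optional [bucket_grid()] to check the bucket count against.
#' @param override If `TRUE`, a bucket-count mismatch with `grid` is only a
#'   warning (default `FALSE`: warning is still raised; set to silence the
#'   mismatch check entirely is not provided — mismatches should be explicit).
#' @return Cohort tibble with `dose` and `time` as factors.
#' @export
read_bucket_table <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                              grid = NULL, override = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     xlsx = "xlsx", xls = "xlsx",
                     abort(paste0("cannot infer format from extension: ", ext)))
  }
  raw <- switch(format,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading xlsx requires the readxl package")
      }
      readxl::read_excel(path, sheet = 1, col_types = "text")
    })
  raw <- tibble::as_tibble(raw)
  raw <- check_design(raw)
  bc <- bucket_cols(raw)
  if (length(bc) == 0) abort("no bucket (ppm-named) columns found")
  for (col in bc) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in row %d, column '%s'",
                    raw[[col]][bad[1]], bad[1], col))
    }
    raw[[col]] <- v
  }
  ppm <- as.numeric(bc)
  if (is.unsorted(rev(ppm), strictly = FALSE) && is.unsorted(ppm, strictly = FALSE)) {
    warn("bucket columns are not in monotone ppm order")
  }
  if (!is.null(grid) && length(bc) != n_buckets(grid)) {
    msg <- sprintf("table has %d buckets but grid retains %d",
                   length(bc), n_buckets(grid))
    if (override) warn(msg) else abort(paste0(msg, " (pass override = TRUE to accept)"))
  }
  raw
}

#' Write a cohort table to disk
#'
#' @param data Cohort table.
#' @param path Output file path.
#' @param format `"csv"` or `"tsv"`. (No xlsx writer is available; export to
#'   csv and convert externally if a spreadsheet is required.)
#' @return `path`, invisibly.
#' @export
write_bucket_table <- function(data, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  switch(format,
    csv = readr::write_csv(data, path, progress = FALSE),
    tsv = readr::write_tsv(data, path, progress = FALSE))
  invisible(path)
}

#' Read a bucket-to-metabolite annotation map
#'
#' The map is a CSV with columns `metabolite`, `ppm_lo`, `ppm_hi` (one row per
#' resonance interval; a metabolite may have several rows, and intervals of
#' different metabolites may overlap).
#'
#' @param path CSV file path.
#' @return Tibble with columns `metabolite` (character), `ppm_lo`, `ppm_hi`.
#' @export
read_annotation <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(
    metabolite = "c", ppm_lo = "d", ppm_hi = "d"), progress = FALSE)
  if (any(x$ppm_lo > x$ppm_hi)) {
    sw <- x$ppm_lo > x$ppm_hi
    tmp <- x$ppm_lo[sw]; x$ppm_lo[sw] <- x$ppm_hi[sw]; x$ppm_hi[sw] <- tmp
  }
  x
}

#' Map annotation intervals to bucket labels on a grid
#'
#' @param annotation Tibble as returned by [read_annotation()] (columns
#'   `metabolite`, `ppm_lo`, `ppm_hi`).
#' @param grid A [bucket_grid()].
#' @return Tibble with columns `metabolite` and `bucket` (grid label); one row
#'   per (metabolite, bucket) pair. Buckets may map to several metabolites.
#' @export
annotation_buckets <- function(annotation, grid) {
  stopifnot(inherits(grid, "bucket_grid"))
  purrr::pmap_dfr(annotation, function(metabolite, ppm_lo, ppm_hi, ...) {
    hit <- grid$centers >= ppm_lo - 1e-9 & grid$centers <= ppm_hi + 1e-9
    if (!any(hit)) return(tibble::tibble(metabolite = character(),
                                         bucket = character()))
    tibble::tibble(metabolite = metabolite, bucket = grid$labels[hit])
  })
}
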