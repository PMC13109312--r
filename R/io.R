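# Readers and writers for the delimited point/truth tables and the
# structured-text (JSON) detection result document.

#' Read kernel point coordinates from a delimited table
#'
#' Expects a header with at least `id`, `x`, `y` (extra columns are ignored;
#' a `row_label` column, if present, is kept as `true_row`). Parsing is
#' locale-independent: the decimal separator is always the point.
#'
#' @param path Path to the file.
#' @param delim Field delimiter, default comma.
#' @return A tibble with columns `id`, `x`, `y` (and `true_row` when the file
#'   carries ground-truth labels), one row per kernel, in file order.
#' @export
read_points <- function(path, delim = ",") {
  if (!file.exists(path)) {
    stop_kr(paste0("file not found: ", path), "kr_io_error")
  }
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    locale = readr::locale(decimal_mark = "."), progress = FALSE,
    show_col_types = FALSE, trim_ws = TRUE
  )
  need <- c("id", "x", "y")
  if (!all(need %in% names(raw))) {
    stop_kr(paste0("expected header with columns id,x,y in ", path),
            "kr_parse_error")
  }
  if (nrow(raw) == 0L) {
    warn(paste0("no data rows in ", path, "; returning an empty point set."))
    out <- tibble(id = integer(), x = double(), y = double())
    return(out)
  }
  parse_num <- function(col, name) {
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0L) {
      # +1 for the header line
      stop_kr(sprintf("non-numeric or missing `%s` at line %d of %s",
                      name, bad[1L] + 1L, path), "kr_parse_error")
    }
    val
  }
  out <- tibble(
    id = parse_num(raw$id, "id"),
    x = parse_num(raw$x, "x"),
    y = parse_num(raw$y, "y")
  )
  if ("row_label" %in% names(raw)) {
    lab <- suppressWarnings(as.integer(raw$row_label))
    out$true_row <- lab
  }
  out
}

#' Write kernel point coordinates to a delimited table
#'
#' @param points Tibble with columns `id`, `x`, `y`; an optional `true_row`
#'   column is written as `row_label`.
#' @param path Output path.
#' @param delim Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, delim = ",") {
  pts <- as_points(points)
  out <- dplyr::select(pts, "id", "x", "y")
  if ("true_row" %in% names(pts)) out$row_label <- pts$true_row
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Write a row-detection result to a structured-text document
#'
#' Serializes a [detect_rows()] result (rows with member ids and partial
#' flags, outliers, the phenotype and the parameters) as JSON. The document
#' round-trips losslessly through [read_detection()].
#'
#' @param result A `row_detection` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detection <- function(result, path) {
  stopifnot(inherits(result, "row_detection"))
  ph <- ear_phenotype(result)
  doc <- list(
    kernels_per_ear = ph$kernels_per_ear,
    rows_per_ear = ph$rows_per_ear,
    kernels_per_row = result$rows$n_kernels,
    rows = purrr::pmap(
      list(result$rows$row, result$rows$partial),
      function(k, part) {
        list(id = k, partial = part,
             member_ids = result$points$id[which(!is.na(result$points$row) &
                                                   result$points$row == k)])
      }
    ),
    outliers = result$points$id[result$points$outlier],
    c_star = result$c_star,
    c_half = result$c_half,
    params = unclass(result$params)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a row-detection result document
#'
#' @param path Path to a JSON document written by [write_detection()].
#' @return A list with elements `kernels_per_ear`, `rows_per_ear`,
#'   `kernels_per_row`, `rows` (tibble of `row`, `partial` and list-column
#'   `member_ids`), `outliers`, `c_star`, `c_half` and `params`.
#' @export
read_detection <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(doc$rows, function(r) {
    tibble(row = as.integer(r$id), partial = isTRUE(r$partial),
           member_ids = list(as.numeric(unlist(r$member_ids))))
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(row = integer(), partial = logical(), member_ids = list())
  }
  list(
    kernels_per_ear = as.integer(doc$kernels_per_ear),
    rows_per_ear = as.integer(doc$rows_per_ear),
    kernels_per_row = as.integer(unlist(doc$kernels_per_row)),
    rows = rows,
    outliers = as.numeric(unlist(doc$outliers)),
    c_star = as.integer(doc$c_star),
    c_half = as.integer(doc$c_half),
    params = do.call(unicorn_params, doc$params)
  )
}
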