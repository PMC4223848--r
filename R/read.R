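#' Read a ratings table from delimited text
#'
#' Expects a header row and columns `id,x,y,<item1>,<item2>,...`:
#' one row per rater, planar coordinates in meters (or lon/lat when the
#' downstream distance metric is great-circle), and one integer category
#' code per rating item.  Missing answers must be encoded as their
#' dedicated category code (e.g. 6 in [green_score_scheme()]); an empty
#' cell is treated as a data error, not as a missing rating.
#'
#' @param path Path to a CSV file.
#' @param items Optional character vector restricting which rating
#'   columns to keep; defaults to every column after `id`, `x`, `y`.
#'
#' @return A tibble with columns `id`, `x`, `y` and one integer column
#'   per rating item.
#' @export
read_ratings <- function(path, items = NULL) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("id", "x", "y")
  missing_cols <- setdiff(required, names(dat))
  if (length(missing_cols) > 0) {
    abort(paste0("Input is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  item_cols <- setdiff(names(dat), required)
  if (!is.null(items)) {
    unknown <- setdiff(items, item_cols)
    if (length(unknown) > 0) {
      abort(paste0("Unknown rating item(s): ", paste(unknown, collapse = ", "),
                   ". Available: ", paste(item_cols, collapse = ", ")))
    }
    item_cols <- items
  }
  if (length(item_cols) == 0) {
    abort("Input has no rating item columns after `id`, `x`, `y`.")
  }
  dat <- dplyr::select(dat, dplyr::all_of(c(required, item_cols)))
  dat <- dplyr::mutate(dat, dplyr::across(dplyr::all_of(item_cols), as.integer))
  validate_ratings(dat, item_cols)
  tibble::as_tibble(dat)
}

#' Write a ratings table as CSV
#'
#' @param data Ratings tibble as returned by [read_ratings()] or
#'   [simulate_ratings()].
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_ratings <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}

validate_ratings <- function(data, item_cols = NULL) {
  if (anyDuplicated(data$id) > 0L) {
    abort("Rater ids must be unique.")
  }
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    abort("All coordinates must be finite numbers.")
  }
  item_cols <- item_cols %||% setdiff(names(data), c("id", "x", "y"))
  for (col in item_cols) {
    if (anyNA(data[[col]])) {
      abort(paste0(
        "Empty or non-integer cells in rating column `", col, "`. ",
        "Encode missing answers as their dedicated category code."
      ))
    }
  }
  invisible(data)
}
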