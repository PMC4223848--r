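#' Weighted index-by-neighbor contingency table
#'
#' Converts matched sets plus the ratings of one item into the weighted
#' cross-tabulation that all association statistics are computed from.
#' Cell (j, k) holds the weighted proportion of matched sets whose index
#' rater answered j while a nearest neighbor answered k,
#' \deqn{o_{jk} = \frac{1}{n} \sum_i \frac{1}{m_i} x_i(j,k),}
#' where `x_i(j,k)` counts neighbors rated k in set i with index rating
#' j, `m_i` is the tied-neighbor count and `n` the number of matched
#' sets.  Chance expectations downstream use the index margins `p_j`
#' (relative counts of index ratings over the analyzed sets), under the
#' assumption that nearest neighbors share the index raters' overall
#' rating distribution; the weighted neighbor margins are kept so that
#' assumption can be checked.
#'
#' @param sets Matched sets from [nearest_neighbor_sets()].
#' @param data The ratings tibble the sets were built from.
#' @param item Name of the rating column to tabulate.
#' @param scheme A [rating_scheme]; inferred from the data when `NULL`.
#'
#' @return An object of class `wct`: a list with `cells` (c x c matrix
#'   of proportions summing to 1), `p_index`, `p_neighbor`, `n_sets`,
#'   `codes`, `labels`, `item`.
#' @examples
#' pts <- tibble::tibble(id = 1:4, x = c(0, 1, 50, 51), y = 0,
#'                       q = c(1L, 1L, 2L, 2L))
#' sets <- nearest_neighbor_sets(pts, max_radius = 10)
#' weighted_crosstab(sets, pts, "q")
#' @export
weighted_crosstab <- function(sets, data, item, scheme = NULL) {
  if (nrow(sets) == 0) {
    abort("No matched sets: nothing to tabulate.")
  }
  if (!item %in% names(data)) {
    abort(paste0("Rating item `", item, "` not found in the data."))
  }
  ratings <- setNames(as.integer(data[[item]]), as.character(data$id))
  scheme <- if (is.null(scheme)) infer_scheme(ratings) else check_scheme(scheme)
  j <- ratings[as.character(sets$index_id)]
  k <- ratings[as.character(sets$neighbor_id)]
  if (anyNA(j) || anyNA(k)) {
    abort("Matched sets reference raters without a rating for this item.")
  }
  bad <- setdiff(unique(c(j, k)), scheme$codes)
  if (length(bad) > 0) {
    abort(paste0("Rating code(s) outside the scheme: ",
                 paste(bad, collapse = ", ")))
  }
  c_ <- length(scheme$codes)
  n_sets <- attr(sets, "n_sets") %||% dplyr::n_distinct(sets$index_id)

  jf <- match(j, scheme$codes)
  kf <- match(k, scheme$codes)
  cells <- matrix(0, c_, c_, dimnames = list(scheme$codes, scheme$codes))
  acc <- rowsum(sets$weight, group = (jf - 1L) * c_ + kf)
  idx <- as.integer(rownames(acc))
  cells[cbind((idx - 1L) %/% c_ + 1L, (idx - 1L) %% c_ + 1L)] <- acc[, 1]
  cells <- cells / n_sets

  # index margins: each set's index rating counted once
  first <- !duplicated(sets$index_id)
  p_index <- tabulate(jf[first], nbins = c_) / n_sets
  names(p_index) <- scheme$codes

  new_wct(cells, p_index = p_index, n_sets = n_sets,
          codes = scheme$codes, labels = scheme$labels, item = item,
          design = attr(sets, "design"))
}

#' Construct a weighted contingency table from a matrix
#'
#' For precomputed tables (e.g. published agreement tables, or tables
#' built outside this package).  Cells must be nonnegative proportions
#' summing to 1; index margins default to the row sums.
#'
#' @param cells Square numeric matrix of weighted proportions.
#' @param n_sets Effective number of matched sets behind the table.
#' @param p_index Index-rater margins; defaults to `rowSums(cells)`.
#' @param codes Category codes; default taken from dimnames or `1:c`.
#' @param labels Display labels.
#' @param item Item name carried into outputs.
#' @return A `wct` object.
#' @export
as_wct <- function(cells, n_sets, p_index = NULL, codes = NULL,
                   labels = NULL, item = "item") {
  cells <- as.matrix(cells)
  if (nrow(cells) != ncol(cells)) abort("`cells` must be square.")
  codes <- codes %||%
    (if (!is.null(rownames(cells))) as.integer(rownames(cells))
     else seq_len(nrow(cells)))
  p_index <- p_index %||% rowSums(cells)
  new_wct(cells, p_index = p_index, n_sets = n_sets, codes = codes,
          labels = labels %||% as.character(codes), item = item)
}

new_wct <- function(cells, p_index, n_sets, codes, labels, item,
                    design = NULL) {
  dimnames(cells) <- list(codes, codes)
  names(p_index) <- codes
  x <- structure(
    list(cells = cells, p_index = p_index, p_neighbor = colSums(cells),
         n_sets = n_sets, codes = codes, labels = labels, item = item,
         design = design),
    class = "wct"
  )
  validate_wct(x)
}

validate_wct <- function(x, tol = 1e-12) {
  if (any(x$cells < -tol)) abort("Contingency cells must be nonnegative.")
  if (abs(sum(x$cells) - 1) > 1e-8) {
    abort("Contingency cells must sum to 1.")
  }
  if (max(abs(rowSums(x$cells) - x$p_index)) > 1e-8) {
    abort("Row sums must equal the index margins.")
  }
  x
}

#' Dichotomize a contingency table for one category pair
#'
#' Collapses the full c x c table into the 2 x 2 table over
#' \{a, not-a\} (index) by \{b, not-b\} (neighbor) whose overall kappa
#' equals the category-specific kappa of the pair.  `a = b` gives the
#' a / not-a same-category table.
#'
#' @param table A `wct`.
#' @param a Index category code.
#' @param b Neighbor category code (default `a`).
#' @return A 2 x 2 `wct` with codes `1` (= the named category) and
#'   `2` (= its complement).
#' @export
dichotomize <- function(table, a, b = a) {
  ia <- match_code(table, a)
  ib <- match_code(table, b)
  cells <- table$cells
  m2 <- matrix(c(
    cells[ia, ib],            sum(cells[ia, -ib]),
    sum(cells[-ia, ib]),      sum(cells[-ia, -ib])
  ), 2, 2, byrow = TRUE)
  p2 <- c(table$p_index[ia], 1 - table$p_index[ia])
  new_wct(m2, p_index = p2, n_sets = table$n_sets, codes = 1:2,
          labels = c(paste0(a), paste0("not ", a)), item = table$item,
          design = table$design)
}

match_code <- function(table, code) {
  i <- match(code, table$codes)
  if (is.na(i)) {
    abort(paste0("Unknown category code `", code, "` for item `",
                 table$item, "`."))
  }
  i
}

#' @export
print.wct <- function(x, digits = 4, ...) {
  cat("<wct> weighted index-by-neighbor table, item `", x$item, "`, ",
      x$n_sets, " matched sets\n", sep = "")
  print(round(x$cells, digits))
  cat("index margins:   ", paste(round(x$p_index, digits), collapse = " "), "\n")
  cat("neighbor margins:", paste(round(x$p_neighbor, digits), collapse = " "), "\n")
  invisible(x)
}

#' Tidy a weighted contingency table into long format
#'
#' @param x A `wct`.
#' @param ... Unused.
#' @return Tibble with one row per (index, neighbor) cell:
#'   `item`, `index_cat`, `neighbor_cat`, `obs` (cell proportion) and
#'   `expected` (product of margins, the chance-expected colocation).
#' @export
tidy.wct <- function(x, ...) {
  grid <- tidyr::expand_grid(index_cat = x$codes, neighbor_cat = x$codes)
  dplyr::mutate(
    grid,
    item = x$item,
    obs = as.vector(t(x$cells)),  # neighbor category varies fastest
    expected = unname(x$p_index[match(.data$index_cat, x$codes)] *
                        x$p_index[match(.data$neighbor_cat, x$codes)]),
    .before = 1
  )
}

#' @export
glance.wct <- function(x, ...) {
  tibble::tibble(
    item = x$item, n_categories = length(x$codes), n_sets = x$n_sets,
    total_mass = sum(x$cells),
    margin_discrepancy = max(abs(x$p_index - x$p_neighbor))
  )
}
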