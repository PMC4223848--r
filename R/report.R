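#' Run the full reliability analysis
#'
#' Drives the whole pipeline for one ratings table: per item and per
#' maximum radius, builds matched sets, the weighted contingency table,
#' the complete association matrix, and (optionally) the collapsed
#' table with a [evaluate_collapse()] report for every within-group
#' pair of the collapse specification.
#'
#' @param data Ratings tibble (see [read_ratings()]).
#' @param items Character vector of rating columns to analyze;
#'   default: every column after `id`, `x`, `y`.
#' @param radii Numeric vector of maximum radii in meters (e.g.
#'   `c(50, 100, 500, 1000)` for a sensitivity analysis).
#' @param metric Distance metric, see [nearest_neighbor_sets()].
#' @param scheme Optional [rating_scheme] shared by the items.
#' @param collapse Optional collapse specification string such as
#'   `"1+2,3+4,5+6"`.
#' @param tau Tolerance for collapse criterion ii.
#' @return A tibble of class `clq_report`: one row per item x radius
#'   with summary columns (`n_sets`, `n_excluded`, `median_distance`,
#'   `q025_distance`, `q975_distance`, `symmetry_diagnostic`) and
#'   list-columns `assoc` (the [association_matrix()]), and, when a
#'   collapse spec is given, `assoc_collapsed` and `collapse_reports`.
#' @export
analyze_ratings <- function(data, items = NULL, radii = 500,
                            metric = c("euclidean", "greatcircle"),
                            scheme = NULL, collapse = NULL, tau = 0.15) {
  metric <- match.arg(metric)
  items <- items %||% setdiff(names(data), c("id", "x", "y"))
  if (length(items) == 0) abort("No rating items to analyze.")
  unknown <- setdiff(items, names(data))
  if (length(unknown) > 0) {
    abort(paste0("Unknown rating item(s): ", paste(unknown, collapse = ", ")))
  }
  if (length(radii) == 0 || any(radii <= 0)) {
    abort("`radii` must be a nonempty vector of positive distances.")
  }
  validate_ratings(data, items)

  rows <- purrr::map_dfr(sort(radii), function(r) {
    sets <- nearest_neighbor_sets(data, max_radius = r, metric = metric)
    gs <- glance(sets)
    purrr::map_dfr(items, function(it) {
      tab <- weighted_crosstab(sets, data, it, scheme = scheme)
      assoc <- association_matrix(tab)
      row <- tibble::tibble(
        item = it, max_radius = r,
        n_sets = gs$n_sets, n_excluded = gs$n_excluded,
        median_distance = gs$median_distance,
        q025_distance = gs$q025_distance,
        q975_distance = gs$q975_distance,
        symmetry_diagnostic = attr(assoc, "symmetry_diagnostic"),
        assoc = list(assoc)
      )
      if (!is.null(collapse)) {
        groups <- parse_collapse_spec(collapse)
        ctab <- collapse_table(tab, groups)
        row$assoc_collapsed <- list(association_matrix(ctab))
        pairs <- purrr::list_rbind(purrr::imap(groups, function(cc, nm) {
          if (length(cc) < 2) return(NULL)
          combs <- utils::combn(cc, 2)
          purrr::map_dfr(seq_len(ncol(combs)), function(i) {
            evaluate_collapse(tab, combs[1, i], combs[2, i],
                              spec = groups, tau = tau)
          })
        }))
        row$collapse_reports <- list(pairs)
      }
      row
    })
  })
  structure(rows, class = c("clq_report", class(tibble::tibble())),
            metric = metric, collapse = collapse)
}

#' @export
print.clq_report <- function(x, ...) {
  cat("<clq_report> ", dplyr::n_distinct(x$item), " item(s) x ",
      dplyr::n_distinct(x$max_radius), " radius/radii\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "\n== item `%s`, radius %g m: %d sets (%d excluded), NN distance median %.0f m (2.5-97.5%%: %.0f-%.0f m) ==\n",
      x$item[i], x$max_radius[i], x$n_sets[i], x$n_excluded[i],
      x$median_distance[i], x$q025_distance[i], x$q975_distance[i]))
    cat(render_agreement_table(x$assoc[[i]]), sep = "\n")
    if (!is.null(x$collapse_reports)) {
      rep_i <- x$collapse_reports[[i]]
      if (nrow(rep_i) > 0) {
        cat("\ncollapse evaluation:\n")
        for (j in seq_len(nrow(rep_i))) print(rep_i[j, ])
      }
    }
  }
  invisible(x)
}

#' Render an association matrix as a published-style agreement table
#'
#' One row per index category with its relative frequency, and per
#' neighbor category the cell `Obs/Exp CLQ (kappa %)stars`, with
#' observed and expected colocation as percentages.  By default only
#' the upper triangle (top-left to bottom-right) is shown, mirroring
#' the presentation convention for near-symmetric tables.
#'
#' @param assoc A `clq_assoc` tibble.
#' @param upper_only Show only pairs with `a <= b`?
#' @return Character vector of table lines.
#' @export
render_agreement_table <- function(assoc, upper_only = TRUE) {
  dat <- tibble::as_tibble(assoc)
  codes <- sort(unique(dat$a))
  cell_txt <- function(r) {
    if (!r$defined) return("n/a")
    sprintf("%s/%s %s (%s)%s",
            fmt_pct(100 * r$obs), fmt_pct(100 * r$expected),
            format_clq(r$clq), format_kappa_pct(r$kappa), r$stars)
  }
  header <- c("index", "freq%", paste0("nb:", codes))
  lines <- purrr::map_chr(codes, function(a) {
    row <- purrr::map_chr(codes, function(b) {
      if (upper_only && b < a) return("")
      r <- dat[dat$a == a & dat$b == b, ]
      if (nrow(r) != 1) return("")
      cell_txt(r)
    })
    pa <- dat$p_a[dat$a == a][1]
    paste(c(a, fmt_pct(100 * pa), row), collapse = "\t")
  })
  c(paste(header, collapse = "\t"), lines,
    "cells: Obs/Exp %  CLQ (kappa %)  *0.01<=p<0.05 **p<0.01 ***p<0.001")
}

# percentages shown with one decimal below 10, whole numbers above
fmt_pct <- function(x) {
  ifelse(abs(x) < 10, sprintf("%.2g", x), sprintf("%.0f", x))
}

#' Write and re-read association results in long format
#'
#' The machine-readable companion of [render_agreement_table()]: one
#' row per ordered category pair with full-precision statistics,
#' `item,index_cat,neighbor_cat,obs_pct,exp_pct,clq,clq_max,
#' kappa_exact,kappa_from_clq,se,p,stars`.
#'
#' @param assoc A `clq_assoc` tibble.
#' @param path Output CSV path.
#' @return `write_association_long()`: the long tibble, invisibly.
#' @export
write_association_long <- function(assoc, path) {
  long <- tibble::tibble(
    item = assoc$item, index_cat = assoc$a, neighbor_cat = assoc$b,
    obs_pct = 100 * assoc$obs, exp_pct = 100 * assoc$expected,
    clq = assoc$clq, clq_max = assoc$clq_max,
    kappa_exact = assoc$kappa, kappa_from_clq = assoc$kappa_clq,
    se = assoc$se, p = assoc$p_value, stars = assoc$stars,
    p_a = assoc$p_a, p_b = assoc$p_b, n_sets = assoc$n_sets
  )
  readr::write_csv(long, path, progress = FALSE)
  invisible(long)
}

#' @rdname write_association_long
#' @return `read_association_long()`: the association tibble
#'   reconstructed from disk, renderable again with
#'   [render_agreement_table()].
#' @export
read_association_long <- function(path) {
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(stars = readr::col_character()))
  res <- tibble::tibble(
    item = long$item, a = long$index_cat, b = long$neighbor_cat,
    p_a = long$p_a, p_b = long$p_b,
    obs = long$obs_pct / 100, expected = long$exp_pct / 100,
    clq = long$clq, clq_max = long$clq_max,
    kappa = long$kappa_exact, kappa_clq = long$kappa_from_clq,
    se = long$se, p_value = long$p,
    stars = dplyr::coalesce(long$stars, ""),
    n_sets = long$n_sets, defined = !is.na(long$clq)
  )
  structure(res, class = c("clq_assoc", class(tibble::tibble())),
            item = res$item[1], n_sets = res$n_sets[1],
            symmetry_diagnostic = NA_real_)
}

#' Write a full analysis report to a directory
#'
#' Emits, per item and radius, the long-format association CSV
#' (`assoc_<item>_<radius>m.csv`, plus `_collapsed` when a collapse
#' spec was analyzed), a collapse-report CSV, a matched-set summary
#' CSV, and a plain-text rendering of the agreement tables.
#'
#' @param report A `clq_report` from [analyze_ratings()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  summary_path <- file.path(dir, "matched_set_summary.csv")
  readr::write_csv(
    dplyr::select(tibble::as_tibble(report), -dplyr::any_of(
      c("assoc", "assoc_collapsed", "collapse_reports"))),
    summary_path, progress = FALSE)
  paths <- c(paths, summary_path)
  txt <- character(0)
  for (i in seq_len(nrow(report))) {
    stem <- sprintf("%s_%gm", report$item[i], report$max_radius[i])
    p <- file.path(dir, paste0("assoc_", stem, ".csv"))
    write_association_long(report$assoc[[i]], p)
    paths <- c(paths, p)
    txt <- c(txt, sprintf("== %s, radius %g m ==", report$item[i],
                          report$max_radius[i]),
             render_agreement_table(report$assoc[[i]]), "")
    if (!is.null(report$assoc_collapsed)) {
      p2 <- file.path(dir, paste0("assoc_", stem, "_collapsed.csv"))
      write_association_long(report$assoc_collapsed[[i]], p2)
      paths <- c(paths, p2)
      txt <- c(txt, sprintf("== %s, radius %g m, collapsed ==",
                            report$item[i], report$max_radius[i]),
               render_agreement_table(report$assoc_collapsed[[i]]), "")
      p3 <- file.path(dir, paste0("collapse_", stem, ".csv"))
      readr::write_csv(report$collapse_reports[[i]], p3, progress = FALSE)
      paths <- c(paths, p3)
    }
  }
  txt_path <- file.path(dir, "agreement_tables.txt")
  writeLines(txt, txt_path)
  paths <- c(paths, txt_path)
  invisible(paths)
}
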