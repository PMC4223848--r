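#' Parse a category-collapse specification
#'
#' Turns the compact syntax `"1+2,3+4,5+6"` into a named list of
#' integer vectors, one per super-category; group labels default to the
#' `+`-joined codes.
#'
#' @param spec A string like `"1+2,3+4,5+6"`, or an already-formed
#'   (optionally named) list of integer vectors.
#' @return Named list of integer vectors.
#' @export
parse_collapse_spec <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
    groups <- lapply(parts, function(p) {
      as.integer(strsplit(trimws(p), "+", fixed = TRUE)[[1]])
    })
    names(groups) <- vapply(groups, paste, "", collapse = "+")
  } else if (is.list(spec)) {
    groups <- lapply(spec, as.integer)
    if (is.null(names(groups)) || any(names(groups) == "")) {
      names(groups) <- vapply(groups, paste, "", collapse = "+")
    }
  } else {
    abort("`spec` must be a string like \"1+2,3+4\" or a list of code vectors.")
  }
  if (any(vapply(groups, anyNA, TRUE))) abort("Non-integer code in collapse spec.")
  all_codes <- unlist(groups)
  if (anyDuplicated(all_codes) > 0L) {
    abort("Collapse groups must be disjoint.")
  }
  groups
}

#' Collapse rating categories of a contingency table
#'
#' Sums cells and margins over groups of category codes, e.g. merging
#' an ordinal Disagree/Disagree-completely pair into one super-category.
#' Codes not mentioned in the spec are kept as singleton groups, so the
#' groups always partition the table's categories.  Mass and index
#' margins are conserved exactly.
#'
#' @param table A `wct`.
#' @param spec Collapse specification (see [parse_collapse_spec()]).
#' @return A `wct` over the super-categories, whose codes are
#'   renumbered `1..g` in spec order with the group labels attached.
#' @examples
#' tab <- as_wct(matrix(1 / 16, 4, 4), n_sets = 100)
#' collapse_table(tab, "1+2,3+4")
#' @export
collapse_table <- function(table, spec) {
  groups <- parse_collapse_spec(spec)
  unknown <- setdiff(unlist(groups), table$codes)
  if (length(unknown) > 0) {
    abort(paste0("Collapse spec mentions unknown code(s): ",
                 paste(unknown, collapse = ", ")))
  }
  leftover <- setdiff(table$codes, unlist(groups))
  if (length(leftover) > 0) {
    singles <- setNames(as.list(leftover), as.character(leftover))
    groups <- c(groups, singles)
  }
  g <- length(groups)
  # membership matrix: rows original categories, cols groups
  memb <- vapply(groups, function(cc) table$codes %in% cc, logical(length(table$codes)))
  memb <- matrix(as.numeric(memb), ncol = g)
  cells <- t(memb) %*% table$cells %*% memb
  p_index <- as.vector(t(memb) %*% table$p_index)
  new_wct(cells, p_index = p_index, n_sets = table$n_sets,
          codes = seq_len(g), labels = names(groups), item = table$item,
          design = table$design)
}

#' Evaluate whether two rating categories can be combined
#'
#' Applies three criteria for combining a pair of categorical ratings
#' without loss of reliability:
#' \describe{
#'   \item{i}{the two ratings cluster spatially: cross-category
#'     CLQ > 1 and kappa > 0;}
#'   \item{ii}{the cross-category CLQ is of the same magnitude as the
#'     lower of the two same-category CLQs, operationalized as
#'     `clq(a,b) >= (1 - tau) * min(clq(a,a), clq(b,b))`;}
#'   \item{iii}{the same-category kappa of the merged category exceeds
#'     both original same-category kappas.}
#' }
#' The verdict is the conjunction of the three.  `tau` is a free
#' tolerance for "same magnitude" (the criterion is qualitative);
#' the default 0.15 reproduces the customary judgement calls on
#' near-boundary pairs.
#'
#' @param table Original `wct`.
#' @param a,b The candidate pair of original category codes.
#' @param spec Collapse specification; must place `a` and `b` in one
#'   group.  Default merges just `a` and `b`.
#' @param tau Relative tolerance for criterion ii (default 0.15).
#' @return One-row tibble of class `collapse_report` with the
#'   underlying statistics, the three criterion booleans and `verdict`.
#' @export
evaluate_collapse <- function(table, a, b,
                              spec = paste0(a, "+", b), tau = 0.15) {
  groups <- parse_collapse_spec(spec)
  gi <- which(vapply(groups, function(cc) a %in% cc && b %in% cc, TRUE))
  if (length(gi) != 1) {
    abort("`spec` must place `a` and `b` together in exactly one group.")
  }
  collapsed <- collapse_table(table, groups)
  # group index within the collapsed table (leftover singletons come after)
  g_code <- collapsed$codes[gi]

  cross_clq <- clq(table, a, b)
  cross_kappa <- kappa_exact(table, a, b)
  clq_aa <- clq(table, a, a); clq_bb <- clq(table, b, b)
  kap_aa <- kappa_exact(table, a, a); kap_bb <- kappa_exact(table, b, b)
  clq_gg <- clq(collapsed, g_code, g_code)
  kap_gg <- kappa_exact(collapsed, g_code, g_code)

  crit <- collapse_criteria(cross_clq, cross_kappa, clq_aa, clq_bb,
                            kap_aa, kap_bb, kap_gg, tau = tau)
  structure(
    tibble::tibble(
      item = table$item, a = a, b = b, group = names(groups)[gi], tau = tau,
      clq_ab = cross_clq, kappa_ab = cross_kappa,
      clq_aa = clq_aa, clq_bb = clq_bb,
      kappa_aa = kap_aa, kappa_bb = kap_bb,
      clq_collapsed = clq_gg, kappa_collapsed = kap_gg,
      criterion_i = crit$i, criterion_ii = crit$ii, criterion_iii = crit$iii,
      verdict = crit$verdict
    ),
    class = c("collapse_report", class(tibble::tibble()))
  )
}

#' Collapse criteria from precomputed statistics
#'
#' Scalar form of the three-criterion decision in [evaluate_collapse()],
#' usable when only the association statistics are available (for
#' instance when re-assessing a published agreement table).
#'
#' @param clq_ab,kappa_ab Cross-category CLQ and kappa for the pair.
#' @param clq_aa,clq_bb Same-category CLQs of the two candidates.
#' @param kappa_aa,kappa_bb Same-category kappas of the two candidates.
#' @param kappa_collapsed Same-category kappa of the merged category.
#' @param tau Relative tolerance for criterion ii.
#' @return List with logicals `i`, `ii`, `iii` and `verdict`.
#' @export
collapse_criteria <- function(clq_ab, kappa_ab, clq_aa, clq_bb,
                              kappa_aa, kappa_bb, kappa_collapsed,
                              tau = 0.15) {
  if (anyNA(c(clq_ab, kappa_ab, clq_aa, clq_bb, kappa_aa, kappa_bb,
              kappa_collapsed))) {
    abort("All statistics must be available to evaluate the criteria.")
  }
  i <- clq_ab > 1 && kappa_ab > 0
  ii <- clq_ab >= (1 - tau) * min(clq_aa, clq_bb)
  iii <- kappa_collapsed > max(kappa_aa, kappa_bb)
  list(i = i, ii = ii, iii = iii, verdict = i && ii && iii)
}

#' @export
print.collapse_report <- function(x, ...) {
  cat(sprintf(
    "<collapse_report> item `%s`: combine %s and %s into `%s`?\n",
    x$item, x$a, x$b, x$group))
  cat(sprintf("  i   clustering:        CLQ(a,b) = %s, kappa = %s  -> %s\n",
              format_clq(x$clq_ab), format_kappa_pct(x$kappa_ab),
              x$criterion_i))
  cat(sprintf("  ii  same magnitude:    %s vs min(%s, %s) (tau = %.2f)  -> %s\n",
              format_clq(x$clq_ab), format_clq(x$clq_aa),
              format_clq(x$clq_bb), x$tau, x$criterion_ii))
  cat(sprintf("  iii kappa increases:   %s vs max(%s, %s)  -> %s\n",
              format_kappa_pct(x$kappa_collapsed),
              format_kappa_pct(x$kappa_aa), format_kappa_pct(x$kappa_bb),
              x$criterion_iii))
  cat(sprintf("  verdict: collapse %ssupported\n",
              if (x$verdict) "" else "NOT "))
  invisible(x)
}
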