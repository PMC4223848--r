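#' Colocation quotient for a category pair
#'
#' The CLQ compares the observed index-neighbor colocation of two
#' ratings with its chance expectation,
#' \deqn{CLQ(a,b) = \frac{o_{ab}}{p_a \, p_b},}
#' under a sampling-with-replacement convention: the index rating is
#' included in the chance-expected agreement, so no finite-population
#' correction is applied.  CLQ = 1 means chance-level colocation,
#' CLQ > 1 spatial clustering of the pair, CLQ < 1 separation; CLQ = 0
#' occurs only when no nearest neighbor of an a-rating rated b.
#'
#' @param table A `wct` from [weighted_crosstab()].
#' @param a Index category code.
#' @param b Neighbor category code (default `a`: same-category CLQ).
#' @return The CLQ, or `NA` (with a warning of class
#'   `clqkappa_undefined`) when a margin is zero.
#' @seealso [clq_max()], [kappa_from_clq()], [kappa_exact()]
#' @export
clq <- function(table, a, b = a) {
  ia <- match_code(table, a); ib <- match_code(table, b)
  pa <- table$p_index[ia]; pb <- table$p_index[ib]
  if (pa <= 0 || pb <= 0) {
    return(undefined_stat("CLQ undefined: zero margin for category ",
                          if (pa <= 0) a else b))
  }
  unname(table$cells[ia, ib] / (pa * pb))
}

#' Theoretical maximum of the colocation quotient
#'
#' Conditions on the total proportion `p_a + p_b` of the two ratings
#' and assumes equal occurrence of a and b, giving
#' \deqn{CLQ_{max} = \frac{p_a + p_b}{2\,p_a p_b},}
#' which reduces to `1/p_a` for a same-category quotient.  The maximum
#' grows as the rarer rating gets rarer and as the two relative
#' frequencies become more similar.
#'
#' @param p_a,p_b Relative frequencies of the two categories (both must
#'   be positive).  Omit `p_b` for the same-category maximum.
#' @param same Logical; `TRUE` treats the pair as one category twice
#'   (default when `p_b` is omitted), in which case the constraint
#'   `p_a + p_b <= 1` does not apply.
#' @return The maximum CLQ attainable for these margins.
#' @export
clq_max <- function(p_a, p_b = p_a, same = missing(p_b)) {
  if (!is.finite(p_a) || !is.finite(p_b) || p_a <= 0 || p_b <= 0) {
    return(undefined_stat("CLQ maximum undefined for zero margin"))
  }
  if (!same && p_a + p_b > 1 + 1e-9) {
    abort("`p_a + p_b` must not exceed 1 for distinct categories.")
  }
  unname((p_a + p_b) / (2 * p_a * p_b))
}

#' Exact kappa for one category or a category pair
#'
#' Chance-corrected agreement computed on the 2 x 2 dichotomization of
#' the rating scale,
#' \deqn{\kappa(a,b) = \frac{P_O(a,b) - P_E(a,b)}{1 - P_E(a,b)},}
#' where `P_O` is the sum of the two agreement cells of the
#' \{a, not-a\} x \{b, not-b\} table and
#' `P_E = p_a p_b + (1 - p_a)(1 - p_b)` is the chance-expected
#' agreement under the assumption that neighbors share the index
#' raters' rating distribution.  With `a == b` this is the
#' category-specific kappa (reliability of rating a); with `a != b` it
#' measures association between different index-neighbor ratings.
#'
#' @inheritParams clq
#' @return Kappa in `[-1, 1]`, or `NA` when `P_E = 1` (degenerate
#'   margin).
#' @export
kappa_exact <- function(table, a, b = a) {
  d <- dichotomize(table, a, b)
  pa <- table$p_index[match_code(table, a)]
  pb <- table$p_index[match_code(table, b)]
  p_o <- d$cells[1, 1] + d$cells[2, 2]
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e >= 1) {
    return(undefined_stat("kappa undefined: degenerate margins (P_E = 1)"))
  }
  unname((p_o - p_e) / (1 - p_e))
}

#' Approximate kappa from a colocation quotient
#'
#' Normalizes CLQ onto the kappa scale by subtracting one and dividing
#' by the theoretical maximum minus one:
#' \deqn{\kappa \approx \frac{CLQ - 1}{CLQ_{max} - 1}
#'   = \frac{2 p_a p_b (CLQ - 1)}{p_a + p_b - 2 p_a p_b}.}
#' The identity with [kappa_exact()] is exact when index and neighbor
#' margins coincide for the pair; otherwise the discrepancy is of the
#' order of the margin discrepancy.
#'
#' @param clq Colocation quotient (>= 0).
#' @inheritParams clq_max
#' @return Approximate kappa; 0 at `clq = 1`, 1 at `clq = clq_max`.
#' @export
kappa_from_clq <- function(clq, p_a, p_b = p_a, same = missing(p_b)) {
  cmax <- clq_max(p_a, p_b, same = same)
  if (is.na(cmax)) return(NA_real_)
  unname((clq - 1) / (cmax - 1))
}

#' Approximate null standard error of kappa
#'
#' Large-sample standard error of kappa under the null hypothesis of no
#' agreement.  The baseline is the two-rater null variance of Fleiss,
#' Cohen and Everitt applied to the dichotomized 2 x 2 table with the
#' number of matched sets as the effective sample size (each weighted
#' set contributes as though it contained two raters):
#' \deqn{SE_0 = \sqrt{\frac{P_E + P_E^2 - \sum_i r_i s_i (r_i + s_i)}
#'   {n\,(1 - P_E)^2}},}
#' with `r`, `s` the row (index) and column (neighbor) margins of the
#' 2 x 2 table and `P_E = sum(r * s)`.
#'
#' That baseline treats the matched sets as independent rater pairs,
#' which a nearest-neighbor design violates: when two raters are each
#' other's nearest neighbor the same two ratings enter twice (for the
#' same-category statistic the two agreement indicators coincide), and
#' one rater can serve as the neighbor of several index raters.  When
#' the table was built from matched sets, so the pairing geometry is
#' known, the null variance is instead computed from the Hoeffding
#' decomposition of the agreement indicator under random relabeling:
#' the index- and neighbor-linear components get the exact permutation
#' variance of a weighted linear statistic in each rater's index- and
#' neighbor-service weights (the index component vanishes when every
#' pooled rater serves as index exactly once), and the interaction
#' component contributes through the squared tie weights plus a
#' covariance term for mutual (reversed) pairs.  For tables supplied as
#' bare matrices ([as_wct()]) the uncorrected baseline is returned.
#' The permutation null ([permutation_null()]) is the reference this
#' computation is validated against.
#'
#' @inheritParams clq
#' @return The null standard error, or `NA` for degenerate margins.
#' @export
null_se <- function(table, a, b = a) {
  if (table$n_sets < 2) abort("Need at least 2 matched sets for a SE.")
  d <- dichotomize(table, a, b)
  r <- d$p_index
  s <- d$p_neighbor
  p_e_m <- sum(r * s)
  if (p_e_m >= 1) {
    return(undefined_stat("SE undefined: degenerate margins (P_E = 1)"))
  }
  n <- table$n_sets
  n_fc <- p_e_m + p_e_m^2 - sum(r * s * (r + s))
  if (is.null(table$design)) {
    return(sqrt(n_fc / (n * (1 - p_e_m)^2)))
  }
  pa <- unname(table$p_index[match_code(table, a)])
  pb <- unname(table$p_index[match_code(table, b)])
  ia <- match_code(table, a); ib <- match_code(table, b)
  cv <- agreement_indicator_moments(pa, pb, same = (ia == ib))
  des <- table$design
  # The statistic is P_O minus the chance expectation estimated from
  # the index raters' margins; its index-linear component cancels
  # against the margin estimate, leaving the neighbor-linear function
  # weighted by each rater's neighbor-service minus index-service
  # weight.  Permutation variance of that linear statistic plus the
  # interaction terms (squared tie weights, reversed-pair covariance).
  s_gf <- (des$SW2nb - 2 * des$SWnb_idx) / n^2 + 1 / n
  var_po <- s_gf * cv$v_g +
    (des$S2 * cv$e_h2 + des$R * cv$e_hrev) / n^2
  var_po <- max(var_po, 0)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  sqrt(var_po) / (1 - p_e)
}

# Hoeffding components of the dichotomized agreement indicator
# A = [index in a][neighbor in b] + [index not in a][neighbor not in b]
# under random labeling with P(a) = pa, P(b) = pb (same = TRUE treats
# a and b as one category): variances and covariance of the index- and
# neighbor-linear parts, the interaction second moment, and the
# interaction covariance between a pair and its reverse.
agreement_indicator_moments <- function(pa, pb, same) {
  if (same) {
    p_t <- c(pa, 1 - pa)              # types: a, other
    alpha <- c(1, 0); beta <- c(1, 0)
  } else {
    p_t <- c(pa, pb, 1 - pa - pb)     # types: a, b, other
    alpha <- c(1, 0, 0); beta <- c(0, 1, 0)
  }
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  f <- alpha * pb + (1 - alpha) * (1 - pb) - p_e   # index-linear part
  g <- beta * pa + (1 - beta) * (1 - pa) - p_e     # neighbor-linear part
  a_fun <- outer(alpha, beta) + outer(1 - alpha, 1 - beta)
  h <- a_fun - outer(f, rep(1, length(p_t))) -
    outer(rep(1, length(p_t)), g) - p_e            # interaction part
  pp <- outer(p_t, p_t)
  list(
    v_f = sum(p_t * f^2),
    v_g = sum(p_t * g^2),
    c_fg = sum(p_t * f * g),
    e_h2 = sum(pp * h^2),
    e_hrev = sum(pp * h * t(h))
  )
}

#' Two-sided p-value and significance stars for kappa
#'
#' Normal-approximation p-value for `kappa / se` under the
#' no-agreement null, with the conventional star bands:
#' `"*"` for 0.01 <= p < 0.05, `"**"` for 0.001 <= p < 0.01,
#' `"***"` for p < 0.001.
#'
#' @param kappa Kappa estimate.
#' @param se Positive null standard error.
#' @return `kappa_p_value()`: the two-sided p-value.
#' @export
kappa_p_value <- function(kappa, se) {
  if (any(!is.na(se) & se <= 0)) abort("`se` must be positive.")
  2 * pnorm(-abs(kappa / se))
}

#' @rdname kappa_p_value
#' @param p A p-value (vectorized).
#' @return `significance_stars()`: `""`, `"*"`, `"**"` or `"***"`.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Association statistics for one ordered category pair
#'
#' Bundles the observed and chance-expected colocation, CLQ and its
#' maximum, exact and CLQ-normalized kappa, the approximate null SE,
#' p-value and stars for index rating `a` against neighbor rating `b`.
#'
#' @inheritParams clq
#' @return One-row tibble.
#' @export
pair_association <- function(table, a, b = a) {
  ia <- match_code(table, a); ib <- match_code(table, b)
  pa <- unname(table$p_index[ia]); pb <- unname(table$p_index[ib])
  obs <- unname(table$cells[ia, ib])
  defined <- pa > 0 && pb > 0
  if (defined) {
    q <- obs / (pa * pb)
    qmax <- clq_max(pa, pb, same = (ia == ib))
    ke <- kappa_exact(table, a, b)
    kc <- (q - 1) / (qmax - 1)
    se <- null_se(table, a, b)
    p <- if (is.na(se)) NA_real_ else kappa_p_value(ke, se)
  } else {
    q <- qmax <- ke <- kc <- se <- p <- NA_real_
  }
  tibble::tibble(
    item = table$item, a = a, b = b,
    p_a = pa, p_b = pb, obs = obs, expected = pa * pb,
    clq = q, clq_max = qmax,
    kappa = ke, kappa_clq = kc,
    se = se, p_value = p, stars = significance_stars(p),
    n_sets = table$n_sets, defined = defined
  )
}

#' Full association matrix over all ordered category pairs
#'
#' Computes [pair_association()] for every ordered pair (a, b) of the
#' table's categories; both (a, b) and (b, a) are reported (kappa and
#' CLQ are asymmetric measures, even though empirical tables are often
#' near-symmetric).  A symmetry diagnostic, the largest
#' `|CLQ(a,b) - CLQ(b,a)|` over defined pairs, is attached and shown by
#' [glance()].
#'
#' @param table A `wct`.
#' @return Tibble of class `clq_assoc`, one row per ordered pair.
#' @examples
#' tab <- as_wct(matrix(c(.3, .1, .1, .5), 2, 2), n_sets = 100)
#' association_matrix(tab)
#' @export
association_matrix <- function(table) {
  pairs <- tidyr::expand_grid(a = table$codes, b = table$codes)
  res <- purrr::pmap_dfr(pairs, function(a, b) {
    withCallingHandlers(
      pair_association(table, a, b),
      clqkappa_undefined = function(w) invokeRestart("muffleWarning")
    )
  })
  sym <- dplyr::inner_join(
    dplyr::filter(res, .data$a < .data$b),
    dplyr::select(res, a2 = "a", b2 = "b", clq2 = "clq"),
    by = c(a = "b2", b = "a2")
  )
  asym <- suppressWarnings(max(abs(sym$clq - sym$clq2), na.rm = TRUE))
  structure(
    res,
    class = c("clq_assoc", class(tibble::tibble())),
    item = table$item, n_sets = table$n_sets,
    symmetry_diagnostic = if (is.finite(asym)) asym else NA_real_
  )
}

#' @export
tidy.clq_assoc <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.clq_assoc <- function(x, ...) {
  tibble::tibble(
    item = attr(x, "item"),
    n_sets = attr(x, "n_sets"),
    n_pairs = nrow(x),
    n_undefined = sum(!x$defined),
    symmetry_diagnostic = attr(x, "symmetry_diagnostic")
  )
}

#' Heatmap of an association matrix
#'
#' Tiles filled by CLQ on a log scale (white at the chance level 1,
#' blue for separation, red for clustering), annotated with
#' `CLQ (kappa %)` and stars in the style of published agreement
#' tables.
#'
#' @param object A `clq_assoc` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.clq_assoc <- function(object, ...) {
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    label = ifelse(.data$defined,
                   paste0(format_clq(.data$clq), "\n(",
                          format_kappa_pct(.data$kappa), ")", .data$stars),
                   "n/a")
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$b),
                                    y = factor(.data$a, levels = rev(sort(unique(.data$a)))),
                                    fill = log2(pmax(.data$clq, 1 / 16)))) +
    ggplot2::geom_tile(color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#3b6fb6", mid = "white",
                                  high = "#c23b22", midpoint = 0,
                                  name = "log2 CLQ") +
    ggplot2::labs(x = "Nearest-neighbor rating", y = "Index rating",
                  title = paste0("Index-neighbor association: ",
                                 attr(object, "item")),
                  subtitle = "cell text: CLQ (kappa %) with significance stars") +
    ggplot2::theme_minimal()
}

#' Display rounding used in agreement tables
#'
#' CLQ is shown to two significant figures; kappa as a percentage,
#' with one decimal below 10 percent (in absolute value) and whole
#' percent above.  Internal computation is always full precision.
#'
#' @param x Numeric vector.
#' @return Character vector.
#' @export
format_clq <- function(x) {
  ifelse(is.na(x), "n/a",
         formatC(signif(x, 2), digits = 2, format = "g", flag = "#"))
}

#' @rdname format_clq
#' @export
format_kappa_pct <- function(x) {
  pct <- 100 * x
  ifelse(is.na(pct), "n/a",
         ifelse(abs(pct) < 10, sprintf("%.1f", pct),
                sprintf("%.0f", pct)))
}

undefined_stat <- function(...) {
  warn(paste0(...), class = "clqkappa_undefined")
  NA_real_
}
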