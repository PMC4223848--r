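#' Permutation null distribution of CLQ and kappa
#'
#' Validation oracle for the analytic null standard error: ratings are
#' randomly reassigned across the rater locations (the overall rating
#' margins are preserved exactly, the spatial arrangement destroyed),
#' and the pair's CLQ and exact kappa are recomputed for each
#' permutation on the fixed matched-set geometry.
#'
#' @inheritParams weighted_crosstab
#' @param a,b Category codes of the pair under study.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble of class `clq_perm` with columns `perm`, `clq`,
#'   `kappa`; attribute `observed` holds the unpermuted pair
#'   association.  [glance()] summarizes the empirical null mean and SD
#'   next to the analytic SE.
#' @export
permutation_null <- function(data, sets, item, a, b = a, n_perm = 999,
                             seed = NULL, scheme = NULL) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (!is.null(seed)) set.seed(seed)
  ratings <- as.integer(data[[item]])
  ids <- as.character(data$id)
  ipos <- match(as.character(sets$index_id), ids)
  npos <- match(as.character(sets$neighbor_id), ids)
  w <- sets$weight
  first <- !duplicated(sets$index_id)
  ifirst <- ipos[first]
  n_sets <- length(ifirst)

  one <- function(r) {
    j <- r[ipos]; k <- r[npos]
    pa <- sum(r[ifirst] == a) / n_sets
    pb <- sum(r[ifirst] == b) / n_sets
    if (pa <= 0 || pb <= 0) return(c(NA_real_, NA_real_))
    o_ab <- sum(w[j == a & k == b]) / n_sets
    o_nn <- sum(w[j != a & k != b]) / n_sets
    p_e <- pa * pb + (1 - pa) * (1 - pb)
    c(o_ab / (pa * pb), (o_ab + o_nn - p_e) / (1 - p_e))
  }

  draws <- vapply(seq_len(n_perm),
                  function(i) one(sample(ratings)),
                  numeric(2))
  tab <- weighted_crosstab(sets, data, item, scheme = scheme)
  structure(
    tibble::tibble(perm = seq_len(n_perm),
                   clq = draws[1, ], kappa = draws[2, ]),
    class = c("clq_perm", class(tibble::tibble())),
    observed = pair_association(tab, a, b),
    a = a, b = b, item = item, n_sets = n_sets
  )
}

#' @export
glance.clq_perm <- function(x, ...) {
  obs <- attr(x, "observed")
  tibble::tibble(
    item = attr(x, "item"), a = attr(x, "a"), b = attr(x, "b"),
    n_perm = nrow(x),
    mean_clq = mean(x$clq, na.rm = TRUE),
    mean_kappa = mean(x$kappa, na.rm = TRUE),
    sd_kappa = stats::sd(x$kappa, na.rm = TRUE),
    se_analytic = obs$se,
    observed_kappa = obs$kappa,
    p_perm = (1 + sum(abs(x$kappa) >= abs(obs$kappa), na.rm = TRUE)) /
      (1 + sum(!is.na(x$kappa)))
  )
}

#' Histogram of a permutation null with the analytic approximation
#'
#' @param object A `clq_perm` object.
#' @param ... Unused.
#' @return A ggplot object: the empirical kappa null with the normal
#'   density implied by the analytic null SE and the observed kappa.
#' @export
autoplot.clq_perm <- function(object, ...) {
  obs <- attr(object, "observed")
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(x = .data$kappa)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, fill = "grey80", color = "grey50") +
    ggplot2::stat_function(
      fun = stats::dnorm,
      args = list(mean = 0, sd = obs$se), color = "#3b6fb6"
    ) +
    ggplot2::geom_vline(xintercept = obs$kappa, color = "#c23b22") +
    ggplot2::labs(
      x = "kappa under random relabeling", y = "density",
      title = sprintf("Permutation null, %s (%s, %s)",
                      attr(object, "item"), attr(object, "a"),
                      attr(object, "b")),
      subtitle = "blue: analytic null SE; red: observed kappa"
    ) +
    ggplot2::theme_minimal()
}
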