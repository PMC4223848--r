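# Independent oracles used across the suite.  These stay deliberately
# naive (full distance matrices, explicit loops) so they do not share
# code paths with the package implementation.

# Brute-force first-order nearest neighbors with ties, O(n^2) in R.
brute_force_nn <- function(data, max_radius, tol = 1e-9) {
  n <- nrow(data)
  dm <- as.matrix(stats::dist(cbind(data$x, data$y)))
  diag(dm) <- Inf
  out <- list()
  for (i in seq_len(n)) {
    dmin <- min(dm[i, ])
    if (dmin <= max_radius) {
      js <- which(dm[i, ] <= dmin + tol)
      out[[length(out) + 1]] <- tibble::tibble(
        index_id = data$id[i],
        neighbor_id = data$id[js],
        distance = dm[i, js],
        m = length(js),
        weight = 1 / length(js)
      )
    }
  }
  empty <- tibble::tibble(index_id = integer(), neighbor_id = integer(),
                          distance = numeric(), m = integer(),
                          weight = numeric())
  dplyr::bind_rows(c(list(empty), out))
}

# canonical ordering (and attribute stripping) for comparing pair tables
sort_pairs <- function(x) {
  out <- tibble::tibble(
    index_id = as.integer(x$index_id),
    neighbor_id = as.integer(x$neighbor_id),
    distance = unname(as.numeric(x$distance)),
    m = as.integer(x$m),
    weight = unname(as.numeric(x$weight))
  )
  dplyr::arrange(out, index_id, neighbor_id)
}

# Random weighted contingency table; symmetric = TRUE forces equal
# index and neighbor margins (the condition for the CLQ-kappa identity).
random_wct <- function(c_ = 4, n_sets = 1000, symmetric = FALSE) {
  m <- matrix(stats::runif(c_ * c_, 0.01, 1), c_, c_)
  if (symmetric) m <- (m + t(m)) / 2
  m <- m / sum(m)
  as_wct(m, n_sets = n_sets)
}

# Overall kappa of a square table: diagonal observed agreement vs the
# chance expectation from the index margins (used as the oracle for the
# dichotomize-then-kappa path).
overall_kappa <- function(tab) {
  p_o <- sum(diag(tab$cells))
  p_e <- sum(tab$p_index^2)
  (p_o - p_e) / (1 - p_e)
}

# Fixture: two matched sets, both with index rating a; set 1 has one
# neighbor rated b, set 2 two tied neighbors rated b and c.
microdata_two_sets <- function() {
  data <- tibble::tibble(
    id = c("i1", "n1", "i2", "n2a", "n2b"),
    x = c(0, 1, 100, 101, 99),
    y = c(0, 0, 0, 0, 0),
    q = c(1L, 2L, 1L, 2L, 3L)  # a = 1, b = 2, c = 3
  )
  sets <- tibble::tibble(
    index_id = c("i1", "i2", "i2"),
    neighbor_id = c("n1", "n2a", "n2b"),
    distance = c(1, 1, 1),
    m = c(1L, 2L, 2L),
    weight = c(1, 0.5, 0.5)
  )
  list(data = data, sets = sets)
}
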