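#' Build first-order nearest-neighbor matched sets
#'
#' For every rater (the *index*), finds the closest other rater(s)
#' within `max_radius`.  When several raters sit at exactly the minimum
#' distance (within `tie_tol`), all of them enter the matched set with
#' weight `1/m`, where `m` is the number of tied neighbors, so that
#' after weighting each set contributes as though it contained two
#' raters.  Raters with no neighbor inside the radius are excluded; the
#' excluded ids are attached to the result.  Co-located raters
#' (distance 0, e.g. the same multistory building) are legal neighbors;
#' a rater is never its own neighbor.
#'
#' @param data Ratings tibble with columns `id`, `x`, `y` (see
#'   [read_ratings()]).  Coordinates must be in meters in a common
#'   planar projection for the Euclidean metric, or lon/lat degrees for
#'   the great-circle metric.
#' @param max_radius Maximum nearest-neighbor distance in meters (> 0).
#' @param metric `"euclidean"` (planar, default) or `"greatcircle"`
#'   (Haversine on lon/lat via the geosphere package).
#' @param tie_tol Absolute distance tolerance in meters for declaring
#'   ties; survey geocoding is far coarser than the default `1e-9`.
#'
#' @return A tibble of class `matched_sets` with one row per
#'   (index, neighbor) pair: `index_id`, `neighbor_id`, `distance`,
#'   `m` (tied-neighbor count of the set) and `weight` (`1/m`).
#'   Attributes: `n_sets`, `excluded_ids`, `max_radius`, `metric`.
#'   Use [glance()] for a one-row summary.
#' @examples
#' pts <- tibble::tibble(id = 1:3, x = c(0, 0, 0), y = c(0, 30, 600))
#' sets <- nearest_neighbor_sets(pts, max_radius = 500)
#' attr(sets, "excluded_ids")  # the rater 570 m from anyone
#' @export
nearest_neighbor_sets <- function(data, max_radius = 500,
                                  metric = c("euclidean", "greatcircle"),
                                  tie_tol = 1e-9) {
  metric <- match.arg(metric)
  if (!is.numeric(max_radius) || length(max_radius) != 1 || max_radius <= 0) {
    abort("`max_radius` must be a single positive number of meters.")
  }
  if (nrow(data) < 2) {
    abort("Nearest-neighbor analysis needs at least 2 raters.")
  }
  validate_ratings(data, item_cols = character())

  if (metric == "euclidean") {
    res <- nn_pairs_euclidean(as.numeric(data$x), as.numeric(data$y),
                              max_radius, tie_tol)
  } else {
    res <- nn_pairs_greatcircle(data$x, data$y, max_radius, tie_tol)
  }

  pairs <- tibble::tibble(
    index_pos = res$index_pos,
    neighbor_pos = res$neighbor_pos,
    distance = res$distance
  )
  pairs <- dplyr::mutate(
    dplyr::group_by(pairs, .data$index_pos),
    m = dplyr::n(), weight = 1 / .data$m
  )
  pairs <- dplyr::ungroup(pairs)

  out <- tibble::tibble(
    index_id = data$id[pairs$index_pos],
    neighbor_id = data$id[pairs$neighbor_pos],
    distance = pairs$distance,
    m = pairs$m,
    weight = pairs$weight
  )
  included <- unique(pairs$index_pos)
  structure(
    out,
    class = c("matched_sets", class(tibble::tibble()))
    ,
    n_sets = length(included),
    excluded_ids = data$id[setdiff(seq_len(nrow(data)), included)],
    max_radius = max_radius,
    metric = metric,
    tie_tol = tie_tol,
    design = pair_design_counts(pairs$index_pos, pairs$neighbor_pos,
                                pairs$weight, n_pool = nrow(data))
  )
}

# Geometry summaries of the directed (index -> neighbor) pair graph
# that determine the permutation-null variance of agreement statistics:
# how often each rater serves as index (weight 1 or 0) and as neighbor
# (sum of tie weights), and the weight carried by mutual (reversed)
# pairs, whose agreement indicators stay correlated even after the
# rater-level margins are fixed.
pair_design_counts <- function(ipos, npos, w, n_pool) {
  key <- (ipos - 1) * n_pool + npos
  rev_key <- (npos - 1) * n_pool + ipos
  rev_match <- match(rev_key, key)
  w_nb <- rowsum(w, npos)                      # neighbor-service weight
  idx_raters <- unique(ipos)
  w_nb_at_idx <- w_nb[match(idx_raters, as.integer(rownames(w_nb))), 1]
  list(
    n = length(idx_raters),
    n_pool = n_pool,
    S2 = sum(w^2),
    R = sum(w * w[rev_match], na.rm = TRUE),
    SW2nb = sum(w_nb^2),
    SWnb_idx = sum(w_nb_at_idx, na.rm = TRUE)
  )
}

# Great-circle fallback: full Haversine distance matrix (small-n path;
# geodesic surveys at national scale fit comfortably in memory in blocks).
nn_pairs_greatcircle <- function(lon, lat, max_radius, tol) {
  n <- length(lon)
  pts <- cbind(lon, lat)
  dm <- geosphere::distm(pts, fun = geosphere::distHaversine)
  diag(dm) <- Inf
  index_pos <- integer(0); neighbor_pos <- integer(0); distance <- numeric(0)
  for (i in seq_len(n)) {
    dmin <- min(dm[i, ])
    if (dmin <= max_radius) {
      js <- which(dm[i, ] <= dmin + tol)
      index_pos <- c(index_pos, rep.int(i, length(js)))
      neighbor_pos <- c(neighbor_pos, js)
      distance <- c(distance, dm[i, js])
    }
  }
  list(index_pos = index_pos, neighbor_pos = neighbor_pos, distance = distance)
}

#' @export
print.matched_sets <- function(x, ...) {
  cat("<matched_sets> ", attr(x, "n_sets"), " sets, ",
      length(attr(x, "excluded_ids")), " rater(s) excluded (radius ",
      attr(x, "max_radius"), " m, ", attr(x, "metric"), ")\n", sep = "")
  NextMethod()
}

#' Summarize matched sets
#'
#' @param x A `matched_sets` object.
#' @param ... Unused.
#' @return One-row tibble: number of sets, number excluded, median and
#'   2.5-97.5 percentile nearest-neighbor distance, radius and metric.
#' @export
glance.matched_sets <- function(x, ...) {
  # one distance per set (the tied distance), not per pair
  d <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(x), .data$index_id),
                        distance = .data$distance[1])$distance
  tibble::tibble(
    n_sets = attr(x, "n_sets"),
    n_excluded = length(attr(x, "excluded_ids")),
    median_distance = median(d),
    q025_distance = unname(quantile(d, 0.025)),
    q975_distance = unname(quantile(d, 0.975)),
    max_radius = attr(x, "max_radius"),
    metric = attr(x, "metric")
  )
}
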