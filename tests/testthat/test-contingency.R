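test_that("tie weights enter the table as in the hand enumeration", {
  md <- microdata_two_sets()
  tab <- weighted_crosstab(md$sets, md$data, "q", scheme = rating_scheme(1:3))
  # o_ab = (1 * 1 + 0.5 * 1) / 2, o_ac = (0.5 * 1) / 2
  expect_equal(tab$cells["1", "2"], 0.75)
  expect_equal(tab$cells["1", "3"], 0.25)
  expect_equal(sum(tab$cells), 1)
  expect_equal(unname(tab$p_index), c(1, 0, 0))
  expect_equal(tab$n_sets, 2)
})

test_that("unanimous ratings give a degenerate one-cell table", {
  pts <- tibble::tibble(id = 1:4, x = c(0, 1, 50, 51), y = 0,
                        q = c(2L, 2L, 2L, 2L))
  sets <- nearest_neighbor_sets(pts, max_radius = 10)
  tab <- weighted_crosstab(sets, pts, "q", scheme = rating_scheme(1:3))
  expect_equal(tab$cells["2", "2"], 1)
  expect_equal(sum(tab$cells), 1)
})

test_that("mass conservation and margin consistency hold on random data", {
  set.seed(11)
  d <- simulate_ratings(n_raters = 300, domain = 1500, patch = 200, seed = 11)
  sets <- nearest_neighbor_sets(d, max_radius = 500)
  tab <- weighted_crosstab(sets, d, "rating")
  expect_equal(sum(tab$cells), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(tab$cells)), unname(tab$p_index),
               tolerance = 1e-12)
  expect_equal(sum(tab$p_index), 1, tolerance = 1e-12)
  expect_equal(unname(colSums(tab$cells)), unname(tab$p_neighbor))
  expect_true(all(tab$cells >= 0))
})

test_that("with no ties the table is the plain cross-tabulation over n", {
  pts <- tibble::tibble(id = 1:6, x = c(0, 1, 50, 51, 100, 101.5), y = 0,
                        q = c(1L, 2L, 2L, 2L, 1L, 1L))
  sets <- nearest_neighbor_sets(pts, max_radius = 10)
  expect_true(all(sets$m == 1))
  tab <- weighted_crosstab(sets, pts, "q")
  plain <- table(factor(pts$q[match(sets$index_id, pts$id)], levels = 1:2),
                 factor(pts$q[match(sets$neighbor_id, pts$id)], levels = 1:2))
  expect_equal(unclass(tab$cells), unclass(plain / 6),
               ignore_attr = TRUE)
})

test_that("relabeling rater order does not change the table", {
  set.seed(3)
  d <- simulate_ratings(n_raters = 120, domain = 800, patch = 150, seed = 3)
  sets <- nearest_neighbor_sets(d, max_radius = 400)
  tab1 <- weighted_crosstab(sets, d, "rating")
  shuffle <- sample(nrow(d))
  d2 <- d[shuffle, ]
  sets2 <- nearest_neighbor_sets(d2, max_radius = 400)
  tab2 <- weighted_crosstab(sets2, d2, "rating")
  expect_equal(tab1$cells, tab2$cells, tolerance = 1e-12)
  expect_equal(tab1$p_index, tab2$p_index)
})

test_that("dichotomize sums the parent cells and recomputes margins", {
  tab <- as_wct(matrix(1 / 16, 4, 4), n_sets = 100)
  d <- dichotomize(tab, 1, 2)
  expect_equal(as.vector(t(d$cells)), c(1 / 16, 3 / 16, 3 / 16, 9 / 16))
  expect_equal(unname(d$p_index), c(0.25, 0.75))
  expect_equal(sum(d$cells), 1)

  # a = b on an identity table keeps the diagonal structure
  ident <- as_wct(diag(c(0.2, 0.3, 0.5)), n_sets = 100)
  d2 <- dichotomize(ident, 2, 2)
  expect_equal(unname(diag(d2$cells)), c(0.3, 0.7))
  expect_equal(sum(d2$cells) - sum(diag(d2$cells)), 0)
})

test_that("invalid tables and inputs are rejected", {
  md <- microdata_two_sets()
  expect_error(weighted_crosstab(md$sets, md$data, "q",
                                 scheme = rating_scheme(1:2)),
               "outside the scheme")
  expect_error(weighted_crosstab(md$sets[0, ], md$data, "q"), "No matched")
  expect_error(weighted_crosstab(md$sets, md$data, "nope"), "not found")
  expect_error(dichotomize(as_wct(matrix(0.25, 2, 2), 10), 7), "Unknown")
  expect_error(as_wct(matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2), 10), "sum to 1")
})

test_that("tidy gives the long cell-by-cell view with chance expectations", {
  tab <- as_wct(matrix(c(.3, .1, .2, .4), 2, 2, byrow = TRUE), n_sets = 50)
  td <- tidy(tab)
  expect_equal(nrow(td), 4)
  expect_equal(td$obs, c(.3, .1, .2, .4))
  expect_equal(td$expected, c(.4 * .4, .4 * .6, .6 * .4, .6 * .6))
})

test_that("empty rating cells in input files are a hard error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y,green", "1,0,0,1", "2,5,5,", "3,9,9,2"), f)
  expect_error(read_ratings(f), "Empty")
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y,green", "1,0,0,1", "2,5,5,3"), f2)
  d <- read_ratings(f2)
  expect_equal(d$green, c(1L, 3L))
})
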