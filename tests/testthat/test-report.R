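test_that("analyze_ratings reproduces hand-computed cells on micro data", {
  md <- microdata_two_sets()
  # make every rater's nearest neighbor land as in the fixture:
  # i1<->n1 at 1 m; i2 has n2a and n2b tied at 1 m
  rep <- analyze_ratings(md$data, items = "q", radii = 10,
                         scheme = rating_scheme(1:3))
  expect_equal(nrow(rep), 1)
  am <- rep$assoc[[1]]
  tab <- weighted_crosstab(nearest_neighbor_sets(md$data, 10), md$data, "q",
                           scheme = rating_scheme(1:3))
  expect_equal(am$obs[am$a == 1 & am$b == 2], tab$cells["1", "2"])
  expect_equal(rep$n_sets, tab$n_sets)
})

test_that("a sensitivity analysis over radii nests the matched sets", {
  set.seed(61)
  d <- simulate_ratings(n_raters = 400, domain = 4000, patch = 400, seed = 61)
  rep <- analyze_ratings(d, radii = c(50, 500))
  expect_equal(rep$max_radius, c(50, 500))
  expect_lt(rep$n_sets[1], rep$n_sets[2])
  expect_gt(rep$n_excluded[1], rep$n_excluded[2])
})

test_that("long-format output round-trips and re-renders identically", {
  set.seed(71)
  d <- simulate_ratings(n_raters = 300, domain = 1500, patch = 250, seed = 71)
  sets <- nearest_neighbor_sets(d, max_radius = 500)
  tab <- weighted_crosstab(sets, d, "rating")
  am <- association_matrix(tab)
  f <- withr::local_tempfile(fileext = ".csv")
  write_association_long(am, f)
  am2 <- read_association_long(f)
  expect_equal(render_agreement_table(am2), render_agreement_table(am))
  expect_equal(am2$clq, am$clq, tolerance = 1e-12)
  expect_equal(am2$stars, am$stars)
})

test_that("write_report emits the full file set", {
  set.seed(81)
  d <- simulate_ratings(n_raters = 250, domain = 1500, patch = 250, seed = 81)
  rep <- analyze_ratings(d, radii = 400, collapse = "1+2,3+4,5+6")
  dir <- withr::local_tempdir()
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "matched_set_summary.csv")))
  expect_true(file.exists(file.path(dir, "assoc_rating_400m.csv")))
  expect_true(file.exists(file.path(dir, "assoc_rating_400m_collapsed.csv")))
  expect_true(file.exists(file.path(dir, "collapse_rating_400m.csv")))
  expect_true(file.exists(file.path(dir, "agreement_tables.txt")))
  reports <- rep$collapse_reports[[1]]
  expect_equal(nrow(reports), 3)  # one per within-group pair
  expect_true(all(c("criterion_i", "criterion_ii", "criterion_iii",
                    "verdict") %in% names(reports)))
})

test_that("location-independent ratings report near-chance associations", {
  mis <- matrix(rep(c(0.25, 0.35, 0.3, 0.1), each = 4), 4, 4)
  d <- simulate_ratings(n_raters = 2000, domain = 2500, patch = 250,
                        latent_probs = rep(0.25, 4),
                        misclassification = mis,
                        p_indefinite = 0, p_missing = 0, seed = 91)
  rep <- analyze_ratings(d, radii = 1000)
  am <- rep$assoc[[1]]
  expect_lt(mean(abs(am$kappa)), 0.02)
  expect_equal(mean(am$clq[am$defined]), 1, tolerance = 0.1)
  expect_lt(mean(am$stars != ""), 0.25)
})

test_that("unknown items and bad radii fail loudly", {
  d <- simulate_ratings(n_raters = 50, seed = 2)
  expect_error(analyze_ratings(d, items = "nope"), "Unknown rating item")
  expect_error(analyze_ratings(d, radii = numeric(0)), "nonempty")
  expect_error(analyze_ratings(d, radii = -1), "positive")
})

test_that("the command-line entry point runs end to end", {
  exe <- system.file("exec", "clqkappa", package = "clqkappa")
  expect_true(nzchar(exe))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "sim.csv")
  libs <- paste(.libPaths(), collapse = .Platform$path.sep)
  env <- paste0("R_LIBS=", shQuote(libs))
  out1 <- system2("Rscript", c(exe, "simulate", "--n-raters", "200",
                               "--seed", "5", "--out", csv),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(csv))
  outdir <- file.path(dir, "report")
  out2 <- system2("Rscript", c(exe, "analyze", "--input", csv,
                               "--radius", "500,1000",
                               "--collapse", "1+2,3+4,5+6",
                               "--out-dir", outdir),
                  env = env, stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(outdir, "agreement_tables.txt")))
  expect_true(file.exists(file.path(outdir, "assoc_rating_500m.csv")))
})
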