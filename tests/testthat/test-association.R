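test_that("clq is the observed over chance-expected colocation", {
  # margins and observed cell chosen to mirror a published worked
  # example (index shares 34% / 12%, cross-cell 5.1%)
  cells <- matrix(c(0.20, 0.051, 0.089,
                    0.030, 0.060, 0.030,
                    0.170, 0.170, 0.200), 3, 3, byrow = TRUE)
  tab <- as_wct(cells, n_sets = 26210)
  expect_equal(clq(tab, 1, 2), 0.051 / (0.34 * 0.12))
  # the published display (obs 5.1%, exp 4.0%) rounds its CLQ from full
  # precision: 1.275 prints as 1.3
  expect_equal(format_clq(1.275), "1.3")

  # chance-level and zero-colocation endpoints
  ind <- as_wct(outer(c(.3, .7), c(.3, .7)), n_sets = 100)
  expect_equal(clq(ind, 1, 2), 1)
  z <- as_wct(matrix(c(.3, 0, .2, .5), 2, 2, byrow = TRUE), n_sets = 100)
  expect_equal(clq(z, 1, 2), 0)
})

test_that("zero margins yield an explicit not-available marker", {
  tab <- as_wct(matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE), n_sets = 10)
  expect_warning(v <- clq(tab, 1, 2), class = "clqkappa_undefined")
  expect_true(is.na(v))
  expect_warning(clq_max(0, 0.5), class = "clqkappa_undefined")
})

test_that("clq_max matches the closed form and its back-calculations", {
  expect_equal(clq_max(0.5, 0.5), 2)
  expect_equal(clq_max(0.34, 0.12), (0.34 + 0.12) / (2 * 0.34 * 0.12))
  expect_equal(clq_max(0.34, 0.12), 5.637, tolerance = 1e-3)
  # same-category reduction to 1/p, unconstrained by p_a + p_b <= 1
  expect_equal(clq_max(0.12), 1 / 0.12)
  expect_equal(clq_max(0.6), 1 / 0.6)
  expect_error(clq_max(0.6, 0.6), "exceed 1")
})

test_that("normalized CLQ reproduces published kappa values", {
  # cross-category: CLQ 1.3 at margins 34% / 12% -> approx 6.5%,
  # matching the printed exact kappa 6.6% within input rounding
  expect_equal(100 * kappa_from_clq(1.3, 0.34, 0.12), 6.6, tolerance = 0.025)
  # same-category: CLQ 2.5 at 12% -> printed 20%
  expect_equal(round(100 * kappa_from_clq(2.5, 0.12)), 20)
  # same-category: CLQ 1.6 at 28% -> printed 23%
  expect_equal(round(100 * kappa_from_clq(1.6, 0.28)), 23)
  # endpoints of the normalization
  expect_equal(kappa_from_clq(1, 0.3, 0.2), 0)
  expect_equal(kappa_from_clq(clq_max(0.3, 0.2), 0.3, 0.2), 1)
})

test_that("kappa_exact follows the 2x2 arithmetic", {
  # P_O = 0.62 with 0.46/0.54 margins on both sides -> 0.23510...
  cells <- matrix(c(0.27, 0.19, 0.19, 0.35), 2, 2, byrow = TRUE)
  tab <- as_wct(cells, n_sets = 1000)
  p_e <- 0.46^2 + 0.54^2
  expect_equal(kappa_exact(tab, 1, 1), (0.62 - p_e) / (1 - p_e))
  expect_equal(kappa_exact(tab, 1, 1), 0.2351, tolerance = 1e-3)

  ident <- as_wct(diag(c(0.2, 0.3, 0.5)), n_sets = 100)
  for (a in 1:3) expect_equal(kappa_exact(ident, a, a), 1)

  ind <- as_wct(outer(c(.2, .3, .5), c(.2, .3, .5)), n_sets = 100)
  for (a in 1:3) for (b in 1:3) expect_equal(kappa_exact(ind, a, b), 0)
})

test_that("category-specific kappa equals overall kappa after dichotomization", {
  set.seed(101)
  for (i in 1:200) {
    tab <- random_wct(c_ = sample(3:6, 1))
    a <- sample(tab$codes, 1)
    expect_equal(kappa_exact(tab, a, a),
                 overall_kappa(dichotomize(tab, a, a)),
                 tolerance = 1e-12)
  }
})

test_that("CLQ-normalized kappa equals exact kappa under equal margins", {
  set.seed(202)
  for (i in 1:200) {
    tab <- random_wct(c_ = sample(3:5, 1), symmetric = TRUE)
    a <- sample(tab$codes, 1); b <- sample(tab$codes, 1)
    expect_equal(kappa_from_clq(clq(tab, a, b), tab$p_index[a],
                                tab$p_index[b], same = (a == b)),
                 kappa_exact(tab, a, b), tolerance = 1e-9)
  }
})

test_that("clq and normalized kappa agree in sign around the chance level", {
  set.seed(303)
  for (i in 1:100) {
    tab <- random_wct(c_ = 4)
    a <- sample(1:4, 1); b <- sample(1:4, 1)
    q <- clq(tab, a, b)
    k <- kappa_from_clq(q, tab$p_index[a], tab$p_index[b], same = (a == b))
    expect_equal(sign(k), sign(q - 1))
  }
})

test_that("null SE has the closed-form symmetric value and 1/sqrt(n) scaling", {
  cells <- matrix(0.25, 2, 2)
  expect_equal(null_se(as_wct(cells, n_sets = 100), 1, 1), 0.1)
  expect_equal(null_se(as_wct(cells, n_sets = 200), 1, 1), 0.1 / sqrt(2))
  set.seed(5)
  tab1 <- random_wct(c_ = 4, n_sets = 500)
  tab2 <- as_wct(tab1$cells, n_sets = 1000)
  expect_equal(null_se(tab1, 1, 2) / null_se(tab2, 1, 2), sqrt(2))
})

test_that("p-values and stars follow the two-sided normal bands", {
  expect_equal(kappa_p_value(0, 0.1), 1)
  expect_equal(kappa_p_value(0.196, 0.1), 0.05, tolerance = 1e-2)
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0005, NA)),
               c("", "*", "**", "***", ""))
  expect_error(kappa_p_value(0.1, 0), "positive")
})

test_that("association matrix matches independent scalar recomputation", {
  set.seed(17)
  tab <- random_wct(c_ = 3, n_sets = 400)
  am <- association_matrix(tab)
  expect_equal(nrow(am), 9)
  for (i in seq_len(nrow(am))) {
    a <- am$a[i]; b <- am$b[i]
    expect_equal(am$clq[i], clq(tab, a, b))
    expect_equal(am$kappa[i], kappa_exact(tab, a, b))
    expect_equal(am$se[i], null_se(tab, a, b))
    expect_equal(am$kappa_clq[i],
                 kappa_from_clq(clq(tab, a, b), tab$p_index[a],
                                tab$p_index[b], same = (a == b)))
  }
})

test_that("symmetric tables give symmetric CLQ; identity tables separate off-diagonal", {
  set.seed(23)
  tab <- random_wct(c_ = 4, symmetric = TRUE)
  am <- association_matrix(tab)
  expect_equal(attr(am, "symmetry_diagnostic"), 0, tolerance = 1e-12)
  ident <- as_wct(diag(c(0.2, 0.3, 0.5)), n_sets = 100)
  am2 <- suppressWarnings(association_matrix(ident))
  expect_true(all(am2$kappa[am2$a == am2$b] == 1))
  expect_true(all(am2$kappa[am2$a != am2$b] < 0))
})

test_that("zero-margin categories are flagged per cell, not dropped", {
  cells <- matrix(c(0.5, 0, 0.5, 0, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  cells[3, ] <- c(0.25, 0, 0.25)
  tab <- as_wct(cells / sum(cells), n_sets = 50)
  am <- association_matrix(tab)
  expect_equal(nrow(am), 9)
  expect_true(all(!am$defined[am$a == 2 | am$b == 2]))
  expect_true(all(is.na(am$clq[!am$defined])))
})

test_that("display rounding mirrors the agreement-table conventions", {
  expect_equal(format_clq(c(1.275, 0.572, 2.5, 1.02, 8.33)),
               c("1.3", "0.57", "2.5", "1.0", "8.3"))
  expect_equal(format_kappa_pct(c(0.0656, 0.21, -0.231, 0.049, -0.012)),
               c("6.6", "21", "-23", "4.9", "-1.2"))
})
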