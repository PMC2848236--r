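test_that("sequential correction reproduces the four-carbon worked example", {
  tbl <- build_binomial_table(4, four_carbon_na)
  corrected <- correct_sequential(four_carbon_observed, tbl)
  expect_equal(round(corrected, 2), c(1, 1, 0, 0, 0))
})

test_that("contamination of a pure monoisotopic peak lays out the B(0, k) row", {
  tbl <- build_binomial_table(4, four_carbon_na)
  cont <- contaminate_sequential(c(1, 0, 0, 0, 0), tbl)
  expect_equal(signif(cont, 3),
               c(0.956, 4.29e-2, 7.22e-4, 5.40e-6, 1.51e-8),
               tolerance = 1e-3)
})

test_that("a delta at the top label count is untouched by contamination", {
  tbl <- build_binomial_table(6, 0.01109)
  delta_top <- c(numeric(6), 1)
  expect_equal(contaminate_sequential(delta_top, tbl), delta_top)
})

test_that("contamination conserves total intensity", {
  set.seed(11)
  for (m in c(1, 5, 20, 60)) {
    tbl <- build_binomial_table(m, 0.01109)
    v <- rand_spectrum(m)
    expect_lt(abs(sum(contaminate_sequential(v, tbl)) - sum(v)) / sum(v),
              1e-12)
  }
})

test_that("correct and contaminate are exact inverses across sizes and abundances", {
  set.seed(7)
  for (na in c(0.001, 0.01109, 0.1)) {
    for (m in c(1, 2, 5, 13, 27, 41, 60)) {
      tbl <- build_binomial_table(m, na)
      v <- rand_spectrum(m)
      round_trip <- correct_sequential(contaminate_sequential(v, tbl), tbl)
      # error relative to the spectrum scale; the solve's conditioning
      # grows like (1-na)^-element_max, so per-entry ratios at the
      # largest sizes are additionally checked only at the physical
      # 13C abundance
      expect_lt(scale_relative_error(round_trip, v), 1e-12)
      if (na == 0.01109) expect_lt(max(abs(round_trip - v) / v), 1e-12)
      back <- contaminate_sequential(
        pmax(correct_sequential(contaminate_sequential(v, tbl), tbl), 0), tbl)
      expect_lt(scale_relative_error(back, contaminate_sequential(v, tbl)),
                1e-12)
    }
  }
})

test_that("transforms reject malformed spectra", {
  tbl <- build_binomial_table(4, 0.01109)
  expect_error(correct_sequential(c(1, 2, 3), tbl), "element_max")
  expect_error(correct_sequential(c(1, NA, 0, 0, 0), tbl), "missing")
  expect_error(contaminate_sequential(c(1, -0.1, 0, 0, 0), tbl),
               "non-negative")
  expect_error(correct_sequential(four_carbon_observed, "not a table"),
               "binomial_table")
})

test_that("dual-label transforms invert each other and conserve intensity", {
  set.seed(23)
  ct <- build_binomial_table(3, 0.01109)
  nt <- build_binomial_table(2, default_na_15n())
  x <- rand_matrix_spectrum(3, 2)
  cont <- contaminate_dual(x, ct, nt)
  expect_lt(abs(sum(cont) - sum(x)) / sum(x), 1e-12)
  expect_lt(max(abs(correct_dual(cont, ct, nt) - x) / x), 1e-12)
})

test_that("dual-label contamination of a single light molecule factorizes", {
  naC <- 0.01109
  naN <- default_na_15n()
  ct <- build_binomial_table(1, naC)
  nt <- build_binomial_table(1, naN)
  x <- matrix(c(1, 0, 0, 0), 2, 2)
  expected <- matrix(c((1 - naC) * (1 - naN), naC * (1 - naN),
                       (1 - naC) * naN, naC * naN), 2, 2)
  expect_equal(contaminate_dual(x, ct, nt), expected, tolerance = 1e-14)
})

test_that("dual label with a single-cell nitrogen axis reduces to the single-label transform", {
  set.seed(5)
  ct <- build_binomial_table(8, 0.01109)
  nt <- build_binomial_table(0, default_na_15n())
  v <- rand_spectrum(8)
  x <- matrix(v, ncol = 1)
  expect_equal(as.vector(contaminate_dual(x, ct, nt)),
               contaminate_sequential(v, ct), tolerance = 1e-14)
  obs <- contaminate_sequential(v, ct)
  expect_equal(as.vector(correct_dual(matrix(obs, ncol = 1), ct, nt)),
               correct_sequential(obs, ct), tolerance = 1e-14)
})

test_that("dual-label contamination separates into independent row and column thinning", {
  set.seed(31)
  ct <- build_binomial_table(5, 0.01109)
  nt <- build_binomial_table(4, default_na_15n())
  x <- rand_matrix_spectrum(5, 4)
  # contaminate carbon along columns, then nitrogen along rows
  by_axes <- apply(x, 2, contaminate_sequential, table = ct)
  by_axes <- t(apply(by_axes, 1, contaminate_sequential, table = nt))
  expect_equal(contaminate_dual(x, ct, nt), by_axes, tolerance = 1e-13)
})

test_that("delta at the fully labeled dual corner is unchanged", {
  ct <- build_binomial_table(2, 0.01109)
  nt <- build_binomial_table(1, default_na_15n())
  x <- matrix(0, 3, 2)
  x[3, 2] <- 1
  expect_equal(contaminate_dual(x, ct, nt), x)
})

test_that("dual-label dimension mismatches are rejected", {
  ct <- build_binomial_table(3, 0.01109)
  nt <- build_binomial_table(2, default_na_15n())
  expect_error(correct_dual(matrix(1, 3, 3), ct, nt), "3x3")
  expect_error(contaminate_dual(matrix(1, 4, 2), ct, nt), "4x2")
})
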