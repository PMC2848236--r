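test_that("built-in scenarios lay out the expected clean spectra", {
  unlabeled <- generate_clean_spectrum(builtin_scenario("unlabeled"))
  expect_equal(unlabeled, c(1, numeric(20)))

  mixed <- generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
  expect_equal(mixed[c(9, 11, 13)], rep(1 / 3, 3))
  expect_equal(sum(mixed), 1)

  full <- generate_clean_spectrum(builtin_scenario("fully_labeled"))
  expect_equal(full, c(numeric(20), 1))

  for (name in c("unlabeled", "mixed_8_10_12", "fully_labeled")) {
    spectrum <- generate_clean_spectrum(builtin_scenario(name))
    expect_lt(abs(sum(spectrum) - 1), 1e-12)
  }
})

test_that("scenario validation rejects inconsistent fractions", {
  expect_error(labeling_scenario(c(`0` = 0.5, `1` = 0.6), 4), "sum to 1")
  expect_error(labeling_scenario(c(`9` = 1), 4), "exceed")
  expect_error(labeling_scenario(c(`0` = 0.5, `0` = 0.5), 4), "duplicate")
  expect_error(labeling_scenario(c(`-1` = 1), 4), "non-negative")
})

test_that("every built-in scenario survives contaminate then iterative correction", {
  tbl <- build_binomial_table(20, 0.01109)
  for (name in c("unlabeled", "mixed_8_10_12", "fully_labeled")) {
    clean <- generate_clean_spectrum(builtin_scenario(name))
    res <- iterative_correct(contaminate_sequential(clean, tbl))
    expect_lt(max(abs(res$corrected - clean)), 1e-9, label = name)
  }
})

test_that("the brute-force convolution oracle handles its closed-form cases", {
  cc <- correction_constants(na_c = 0.3)
  expect_equal(brute_force_contaminate(c(1, 0), cc), c(0.7, 0.3))
  expect_equal(brute_force_contaminate(c(0, 1), cc), c(0, 1))
  expect_equal(brute_force_contaminate(c(0, 0, 1), cc), c(0, 0, 1))
})

test_that("analytic contamination agrees with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:40) {
    m <- sample(1:40, 1)
    na <- sample(c(0.001, 0.01109, 0.1), 1)
    v <- rand_spectrum(m)
    tbl <- build_binomial_table(m, na)
    analytic <- contaminate_sequential(v, tbl)
    oracle <- brute_force_contaminate(v, correction_constants(na_c = na))
    expect_lt(max(abs(analytic - oracle) / oracle), 1e-12)
  }
})

test_that("the dual-label oracle matches the analytic dual transform", {
  set.seed(55)
  cc <- nitrogen_constants()
  for (rep in 1:10) {
    c_max <- sample(1:12, 1)
    n_max <- sample(1:8, 1)
    x <- rand_matrix_spectrum(c_max, n_max)
    analytic <- contaminate_dual(x,
                                 build_binomial_table(c_max, cc$na_c),
                                 build_binomial_table(n_max, cc$na_n))
    oracle <- brute_force_contaminate(x, cc)
    expect_lt(max(abs(analytic - oracle) / oracle), 1e-12)
  }
})

test_that("perturbation is reproducible, bounded and optional", {
  v <- c(1, 0.5, 0.1, 0)
  expect_identical(perturb_spectrum(v, 0, seed = 1), v)
  a <- perturb_spectrum(v, 0.05, seed = 42)
  b <- perturb_spectrum(v, 0.05, seed = 42)
  expect_identical(a, b)
  expect_false(identical(a, perturb_spectrum(v, 0.05, seed = 43)))
  expect_true(all(abs(a - v) <= 0.05 * v + 1e-15))
  # caller's random stream is untouched
  set.seed(9); before <- runif(3)
  set.seed(9); invisible(perturb_spectrum(v, 0.05, seed = 1)); after <- runif(3)
  expect_identical(before, after)
})

test_that("five-percent noise raises the quality residual in nearly every seed", {
  tbl <- build_binomial_table(20, 0.01109)
  clean <- generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
  observed <- contaminate_sequential(clean, tbl)
  base <- quality_residual(observed, iterative_correct(observed))
  worse <- sum(vapply(1:100, function(seed) {
    noisy <- perturb_spectrum(observed, 0.05, seed = seed)
    quality_residual(noisy, iterative_correct(noisy)) > base
  }, logical(1)))
  expect_gte(worse, 95)
})
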