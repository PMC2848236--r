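test_that("supplementation fills absent peaks without touching observations", {
  complete <- c(1, 0.5, 0.2)
  out <- supplement_missing(complete)
  expect_identical(out$spectrum, complete)
  expect_length(out$supplemented, 0)

  partial <- c(1, 0.5, NA, 0.1)
  first <- supplement_missing(partial, estimate = NULL)
  expect_identical(first$spectrum, c(1, 0.5, 0, 0.1))
  expect_identical(first$supplemented, 2L)

  est <- c(9, 9, 0.33, 9)
  later <- supplement_missing(partial, estimate = est)
  expect_identical(later$spectrum, c(1, 0.5, 0.33, 0.1))

  expect_error(supplement_missing(c(NA_real_, NA_real_)), "no observed")
  expect_error(supplement_missing(c(0, 0)), "positive")
})

test_that("negative intensities are flattened to zero and recorded", {
  out <- flatten_negatives(c(1.0, -0.02, 0.5))
  expect_equal(out$spectrum, c(1.0, 0, 0.5))
  expect_identical(out$flattened, 1L)

  clean <- flatten_negatives(c(0.2, 0, 0.8))
  expect_identical(clean$spectrum, c(0.2, 0, 0.8))
  expect_length(clean$flattened, 0)

  all_neg <- flatten_negatives(c(-1, -2))
  expect_equal(all_neg$spectrum, c(0, 0))
  expect_error(renormalize(all_neg$spectrum, 1), "degenerate")
})

test_that("renormalization rescales to the requested basis", {
  expect_equal(renormalize(c(2, 2), 1), c(0.5, 0.5))
  v <- c(0.3, 0.7)
  expect_equal(renormalize(v, 1), v, tolerance = 1e-15)
  expect_error(renormalize(c(1, 1), 0), "positive")
})

test_that("a complete consistent input converges immediately to the single-pass solution", {
  tbl <- build_binomial_table(20, 0.01109)
  clean <- generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
  observed <- contaminate_sequential(clean, tbl)
  res <- iterative_correct(observed)
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  expect_lt(max(abs(res$corrected - clean)), 1e-12)
  expect_lt(res$residual, 1e-12)
  expect_equal(res$corrected, correct_sequential(observed, tbl),
               tolerance = 1e-12)
})

test_that("the worked four-carbon set converges with a small nonzero residual", {
  res <- iterative_correct(four_carbon_observed)
  expect_equal(round(res$corrected, 2), c(1, 1, 0, 0, 0))
  expect_true(res$converged)
  expect_lte(res$iterations, 100L)
  # printed values carry 3-significant-figure rounding, so the set is
  # close to, but not exactly, self-consistent
  expect_gt(res$residual, 0)
  expect_lt(res$residual, 1e-3)
})

test_that("accepted residuals decrease strictly and missing peaks are compensated", {
  tbl <- build_binomial_table(20, 0.01109)
  clean <- generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
  observed <- contaminate_sequential(clean, tbl)
  observed[10] <- NA  # drop the M+9 peak
  res <- iterative_correct(observed)
  expect_true(res$converged)
  expect_gt(res$iterations, 1L)
  expect_true(all(diff(res$residual_trace) < 0))
  expect_identical(res$supplemented, 9L)
  frac <- res$corrected / sum(res$corrected)
  labeled <- clean > 0
  expect_lt(max(abs(frac[labeled] - clean[labeled]) / clean[labeled]), 0.01)
  expect_lt(max(abs(frac[!labeled])), 0.01 * max(clean))
})

test_that("correction is scale invariant", {
  tbl <- build_binomial_table(12, 0.01109)
  clean <- c(0.2, numeric(5), 0.5, numeric(5), 0.3)
  observed <- contaminate_sequential(clean, tbl)
  observed[4] <- NA
  a <- iterative_correct(observed)
  b <- iterative_correct(observed * 1000)
  expect_equal(b$corrected, a$corrected * 1000, tolerance = 1e-12)
})

test_that("dual-label spectra run through the same iterative loop", {
  set.seed(91)
  ct <- build_binomial_table(6, 0.01109)
  nt <- build_binomial_table(3, default_na_15n())
  clean <- matrix(0, 7, 4)
  clean[1, 1] <- 0.5
  clean[5, 3] <- 0.5
  observed <- contaminate_dual(clean, ct, nt)
  res <- iterative_correct(observed, constants = nitrogen_constants())
  expect_true(res$converged)
  expect_lt(max(abs(res$corrected - clean)), 1e-12)

  observed[2, 1] <- NA
  res2 <- iterative_correct(observed, constants = nitrogen_constants())
  expect_true(res2$converged)
  expect_equal(unname(res2$supplemented), cbind(1L, 0L), ignore_attr = TRUE)
  expect_lt(max(abs(res2$corrected - clean)), 0.01 * max(clean))
})

test_that("the quality residual flags perturbed data", {
  tbl <- build_binomial_table(20, 0.01109)
  clean <- generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
  observed <- contaminate_sequential(clean, tbl)
  base <- quality_residual(observed, iterative_correct(observed))
  expect_lt(base, 1e-12)

  worse <- 0L
  n_seeds <- 100L
  for (seed in seq_len(n_seeds)) {
    noisy <- observed
    idx <- 9 + (seed %% 5)  # perturb one of the labeled-region peaks
    noisy[idx] <- noisy[idx] * 1.05
    r <- quality_residual(noisy, iterative_correct(noisy))
    if (r > base) worse <- worse + 1L
  }
  expect_gte(worse, 95L)
})

test_that("iteration cap returns the last state with a warning", {
  tbl <- build_binomial_table(20, 0.01109)
  clean <- generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
  observed <- contaminate_sequential(clean, tbl)
  observed[10] <- NA
  expect_warning(res <- iterative_correct(observed, max_iter = 2),
                 "still improving")
  expect_false(res$converged)
  expect_equal(res$iterations, 2L)
})
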