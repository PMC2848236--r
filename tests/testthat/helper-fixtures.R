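# Shared fixtures: the printed four-carbon worked example (observed
# intensities, its published B(n, k) cells and loss fractions), and
# small random-spectrum generators used by the property tests.

four_carbon_na <- 0.01109

four_carbon_observed <- c(0.956, 1.01, 3.33e-2, 3.70e-4, 1.38e-6)

# published B(n, k) cells, 3 significant figures, keyed "n,k"
four_carbon_terms <- c(
  "0,1" = 4.29e-2, "0,2" = 7.22e-4, "0,3" = 5.40e-6, "0,4" = 1.51e-8,
  "1,2" = 3.25e-2, "1,3" = 3.65e-4, "1,4" = 1.36e-6,
  "2,3" = 2.19e-2, "2,4" = 1.23e-4,
  "3,4" = 1.11e-2
)

# published loss fractions B_sum(n), 3 significant figures
four_carbon_loss <- c("0" = 4.36e-2, "1" = 3.29e-2, "2" = 2.21e-2,
                      "3" = 1.11e-2, "4" = 0)

rand_spectrum <- function(element_max) {
  runif(element_max + 1)
}

rand_matrix_spectrum <- function(c_max, n_max) {
  matrix(runif((c_max + 1) * (n_max + 1)), c_max + 1, n_max + 1)
}

# Round-trip error relative to the spectrum scale (the measure used for
# the conditioning sweeps; entries near zero make per-entry ratios
# meaningless for random test vectors).
scale_relative_error <- function(result, truth) {
  max(abs(result - truth)) / max(abs(truth))
}

nitrogen_constants <- function(precision = "double") {
  correction_constants(na_n = default_na_15n(), precision = precision)
}
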