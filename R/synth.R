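# Synthetic labeling scenarios and an independent brute-force forward
# model, used both as a data generator for users and as the oracle the
# analytic transforms are validated against.

#' Describe a tracer labeling pattern
#'
#' A labeling scenario places fractions of the metabolite pool at given
#' tracer-derived heavy-atom counts; the clean (uncontaminated) spectrum
#' is a mixture of deltas at those counts.
#'
#' @param fractions Named numeric: names are heavy-atom counts, values
#'   the pool fractions (non-negative, summing to 1).
#' @param element_max Number of atoms of the labeled element.
#' @param name Optional scenario label.
#' @return An object of class `"labeling_scenario"`.
#' @seealso [builtin_scenario()] for ready-made scenarios,
#'   [generate_clean_spectrum()].
#' @export
#' @examples
#' labeling_scenario(c(`8` = 1/3, `10` = 1/3, `12` = 1/3), element_max = 20)
labeling_scenario <- function(fractions, element_max, name = NULL) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1L,
            !is.null(names(fractions)),
            length(element_max) == 1L, element_max >= 0)
  counts <- suppressWarnings(as.integer(names(fractions)))
  if (anyNA(counts) || any(counts < 0)) {
    stop("names of `fractions` must be non-negative heavy-atom counts",
         call. = FALSE)
  }
  if (any(counts > element_max)) {
    stop("label counts exceed element_max", call. = FALSE)
  }
  if (anyDuplicated(counts)) {
    stop("duplicate label counts in `fractions`", call. = FALSE)
  }
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-12) {
    stop("`fractions` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(
    list(label_counts = counts, fractions = unname(fractions),
         element_max = as.integer(element_max),
         name = name %||% "custom"),
    class = "labeling_scenario"
  )
}

#' Ready-made labeling scenarios
#'
#' Three canonical single-element test patterns for a 20-atom
#' metabolite (size adjustable):
#'
#' * `"unlabeled"` — no tracer incorporation; the whole pool at count 0,
#'   so the contaminated spectrum is pure natural abundance and the
#'   correction must collapse it back to the monoisotopic peak.
#' * `"mixed_8_10_12"` — equal thirds of the pool carrying 8, 10 and 12
#'   tracer atoms; exhibits the tapering of natural-abundance spill as
#'   the number of remaining light atoms shrinks.
#' * `"fully_labeled"` — the whole pool at `element_max`; natural
#'   abundance has no atoms left to act on, so contamination is the
#'   identity.
#'
#' @param name Scenario name (see above).
#' @param element_max Number of atoms of the labeled element
#'   (default 20; `"mixed_8_10_12"` requires at least 12).
#' @return A [labeling_scenario()].
#' @export
#' @examples
#' generate_clean_spectrum(builtin_scenario("mixed_8_10_12"))
builtin_scenario <- function(name = c("unlabeled", "mixed_8_10_12",
                                      "fully_labeled"),
                             element_max = 20L) {
  name <- match.arg(name)
  fractions <- switch(
    name,
    unlabeled = c(`0` = 1),
    mixed_8_10_12 = c(`8` = 1 / 3, `10` = 1 / 3, `12` = 1 / 3),
    fully_labeled = stats::setNames(1, element_max)
  )
  labeling_scenario(fractions, element_max, name = name)
}

#' Clean (uncontaminated) spectrum of a labeling scenario
#'
#' @param scenario A [labeling_scenario()].
#' @return Numeric vector of length `element_max + 1` summing to 1, with
#'   each pool fraction at its heavy-atom count.
#' @export
generate_clean_spectrum <- function(scenario) {
  stopifnot(inherits(scenario, "labeling_scenario"))
  spectrum <- numeric(scenario$element_max + 1L)
  spectrum[scenario$label_counts + 1L] <- scenario$fractions
  spectrum
}

#' Brute-force natural-abundance forward model (validation oracle)
#'
#' Contaminates a clean spectrum by explicit binomial convolution: the
#' intensity at label count `n` is spread over `n + j` with the
#' probability mass of `Binomial(element_max - n, na)` evaluated by a
#' direct product recurrence — deliberately sharing no code with the
#' analytic transforms so it can serve as an independent oracle.  For
#' dual-label matrices the carbon and nitrogen convolutions are applied
#' as an outer product per cell.
#'
#' @param clean Complete non-negative numeric vector or matrix.
#' @param constants A [correction_constants()] object; matrices require
#'   `na_n` to be set.
#' @param element For vector input, which element carries the label.
#' @return Contaminated spectrum of the same shape.
#' @export
#' @examples
#' brute_force_contaminate(c(1, 0), correction_constants())
brute_force_contaminate <- function(clean,
                                    constants = correction_constants(),
                                    element = c("C", "N")) {
  stopifnot(inherits(constants, "correction_constants"))
  clean <- spectrum_values(clean)
  if (anyNA(clean) || any(clean < 0)) {
    stop("`clean` must be complete and non-negative", call. = FALSE)
  }
  if (is.matrix(clean)) {
    na_c <- constants$na_c
    na_n <- abundance_for(constants, "N")
    c_max <- nrow(clean) - 1L
    n_max <- ncol(clean) - 1L
    out <- matrix(0, c_max + 1L, n_max + 1L)
    for (x in 0:c_max) {
      pmf_c <- binom_pmf_direct(c_max - x, na_c)
      for (y in 0:n_max) {
        if (clean[x + 1L, y + 1L] == 0) next
        pmf_n <- binom_pmf_direct(n_max - y, na_n)
        block <- clean[x + 1L, y + 1L] * outer(pmf_c, pmf_n)
        rows <- (x + 1L):(c_max + 1L)
        cols <- (y + 1L):(n_max + 1L)
        out[rows, cols] <- out[rows, cols] + block
      }
    }
    return(out)
  }
  element <- match.arg(element)
  na <- abundance_for(constants, element)
  m <- length(clean) - 1L
  out <- numeric(m + 1L)
  for (n in 0:m) {
    if (clean[n + 1L] == 0) next
    pmf <- binom_pmf_direct(m - n, na)
    out[(n + 1L):(m + 1L)] <- out[(n + 1L):(m + 1L)] + clean[n + 1L] * pmf
  }
  out
}

# Binomial(size, p) mass by the multiplicative recurrence
# p(j) = p(j-1) * (size-j+1)/j * p/(1-p), anchored at p(0) = (1-p)^size.
binom_pmf_direct <- function(size, p) {
  if (size == 0L) return(1)
  pmf <- numeric(size + 1L)
  pmf[1L] <- (1 - p)^size
  if (p > 0) {
    ratio <- p / (1 - p)
    for (j in seq_len(size)) {
      pmf[j + 1L] <- pmf[j] * ((size - j + 1) / j) * ratio
    }
  }
  pmf
}

#' Multiplicative noise perturbation of a spectrum
#'
#' Scales each intensity by `1 + uniform(-relative_noise,
#' +relative_noise)` (clipped at zero), reproducibly for a fixed seed.
#' Used to probe the sensitivity of the quality-control residual to
#' measurement error.
#'
#' @param spectrum Numeric vector or matrix; `NA` entries pass through.
#' @param relative_noise Non-negative noise half-width (e.g. `0.05` for
#'   plus or minus five percent).
#' @param seed Integer seed; the caller's random state is left
#'   untouched.
#' @return Perturbed spectrum of the same shape.
#' @export
#' @examples
#' perturb_spectrum(c(1, 0.5, 0.1), relative_noise = 0.05, seed = 7)
perturb_spectrum <- function(spectrum, relative_noise, seed) {
  stopifnot(is.numeric(relative_noise), length(relative_noise) == 1L,
            relative_noise >= 0)
  values <- spectrum_values(spectrum)
  if (relative_noise == 0) return(values)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  noise <- runif(length(values), -relative_noise, relative_noise)
  out <- pmax(values * (1 + noise), 0)
  if (is.matrix(values)) dim(out) <- dim(values)
  out
}
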