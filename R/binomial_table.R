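# Largest element count handled per precision mode.  In double precision
# the implementation is validated up to 269 atoms of the labeled element;
# beyond that the table is evaluated in extended (80-bit) precision.
DOUBLE_MAX_ATOMS <- 269L
EXTENDED_MAX_ATOMS <- 2000L

#' Binomial natural-abundance redistribution term B(n, k)
#'
#' Fraction of the intensity of a molecule carrying `n` tracer-derived
#' heavy atoms that is observed at total heavy-atom count `k`, because
#' natural abundance converts `k - n` of the remaining
#' `element_max - n` light atoms:
#' \deqn{B(n,k) = \binom{C_{max}-n}{k-n}\; na^{k-n}\,(1-na)^{C_{max}-k}.}
#' The binomial coefficient counts the mass-equivalent isotopomers, i.e.
#' the ways the `k - n` naturally occurring heavy atoms can be placed.
#'
#' @param n Number of heavy atoms incorporated from the labeling source.
#' @param k Total number of heavy atoms observed (`n <= k <= element_max`).
#' @param element_max Number of atoms of the labeled element in the
#'   molecule.
#' @param na Fractional natural abundance of the heavy isotope, in
#'   `[0, 1)`.
#' @return A fraction in `[0, 1]`.  `n` and `k` may be vectors of equal
#'   length, in which case the result is vectorized.
#' @seealso [loss_fraction_sum()], [build_binomial_table()]
#' @export
#' @examples
#' binomial_term(0, 1, element_max = 4, na = 0.01109)
#' # for fixed n the terms over k form a probability distribution:
#' sum(binomial_term(2, 2:10, element_max = 10, na = 0.01109))
binomial_term <- function(n, k, element_max, na) {
  stopifnot(is.numeric(n), is.numeric(k),
            length(element_max) == 1L, length(na) == 1L)
  if (is.na(na) || na < 0 || na >= 1) {
    stop("`na` must be a fraction in [0, 1)", call. = FALSE)
  }
  if (any(n < 0) || any(k < n) || any(k > element_max)) {
    stop("require 0 <= n <= k <= element_max", call. = FALSE)
  }
  bterm_double(n, k, element_max, na)
}

# log-space evaluation: never forms the raw binomial coefficient, so it
# cannot overflow for any element_max a double can index
bterm_double <- function(n, k, m, na) {
  if (na == 0) return(as.numeric(k == n))
  exp(lchoose(m - n, k - n) + (k - n) * log(na) + (m - k) * log1p(-na))
}

#' Loss fraction B_sum(n): intensity leaked to heavier isotopologues
#'
#' Fraction of the intensity of a species with `n` tracer-derived heavy
#' atoms that natural abundance moves to heavier isotopologues,
#' \eqn{B_{sum}(n) = \sum_{k=n+1}^{C_{max}} B(n,k)}.  The sum has the
#' closed form \eqn{1-(1-na)^{C_{max}-n}}; this function evaluates the
#' series directly (the agreement with the closed form is one of the
#' package's self-checks).
#'
#' @inheritParams binomial_term
#' @return A fraction in `[0, 1)`; `0` when `n == element_max` (a fully
#'   labeled molecule has no light atoms left to convert).
#' @export
#' @examples
#' loss_fraction_sum(0, element_max = 4, na = 0.01109)
loss_fraction_sum <- function(n, element_max, na) {
  stopifnot(length(n) == 1L)
  if (n < 0 || n > element_max) {
    stop("require 0 <= n <= element_max", call. = FALSE)
  }
  if (n == element_max) return(0)
  sum(binomial_term(n, (n + 1):element_max, element_max, na))
}

#' Precompute the binomial redistribution table for one element
#'
#' Builds all terms `B(n, k)` for `0 <= n <= k <= element_max` together
#' with the loss fractions `B_sum(n)`, the quantities needed by the
#' sequential correction and its forward model.  The table is the unit of
#' work the iterative algorithm precalculates once per metabolite.
#'
#' In `"double"` mode the table is evaluated in IEEE double precision
#' and `element_max` must be below 270; larger molecules are handled by
#' `"extended"` mode, which evaluates every term in 80-bit extended
#' precision in compiled code.
#'
#' @inheritParams binomial_term
#' @param precision `"double"` or `"extended"`.
#' @return An object of class `"binomial_table"`: a list with
#'   `element_max`, `na`, `precision`, `terms` (an upper-triangular
#'   `(element_max+1) x (element_max+1)` matrix, rows indexed by `n`,
#'   columns by `k`) and `loss_sums` (`B_sum(0..element_max)`).
#' @export
#' @examples
#' tbl <- build_binomial_table(4, na = 0.01109)
#' tbl$terms["0", "1"]       # B(0, 1)
#' tbl$loss_sums[["0"]]      # B_sum(0)
build_binomial_table <- function(element_max, na,
                                 precision = c("double", "extended")) {
  precision <- match.arg(precision)
  stopifnot(length(element_max) == 1L, element_max >= 0,
            element_max == as.integer(element_max))
  element_max <- as.integer(element_max)
  if (is.na(na) || na < 0 || na >= 1) {
    stop("`na` must be a fraction in [0, 1)", call. = FALSE)
  }
  if (precision == "double" && element_max > DOUBLE_MAX_ATOMS) {
    stop(sprintf(paste0("element_max must be less than %d in double ",
                        "precision mode (got %d); use precision = ",
                        "\"extended\""),
                 DOUBLE_MAX_ATOMS + 1L, element_max), call. = FALSE)
  }
  if (precision == "extended" && element_max > EXTENDED_MAX_ATOMS) {
    stop(sprintf("element_max must be at most %d in extended precision mode",
                 EXTENDED_MAX_ATOMS), call. = FALSE)
  }

  m1 <- element_max + 1L
  if (precision == "extended") {
    built <- ext_binomial_table(element_max, na)
    terms <- built$terms
    loss_sums <- built$loss_sums
  } else {
    if (na == 0) {
      terms <- diag(m1)
    } else {
      nrow_idx <- matrix(0:element_max, m1, m1)        # n down rows
      kcol_idx <- t(nrow_idx)                          # k across columns
      terms <- exp(lchoose(element_max - nrow_idx, kcol_idx - nrow_idx) +
                     (kcol_idx - nrow_idx) * log(na) +
                     (element_max - kcol_idx) * log1p(-na))
      terms[kcol_idx < nrow_idx] <- 0
    }
    loss_sums <- -expm1((element_max - 0:element_max) * log1p(-na))
  }
  dimnames(terms) <- list(n = 0:element_max, k = 0:element_max)
  names(loss_sums) <- 0:element_max

  structure(
    list(element_max = element_max, na = na, precision = precision,
         terms = terms, loss_sums = loss_sums),
    class = "binomial_table"
  )
}

#' @export
print.binomial_table <- function(x, ...) {
  cat(sprintf("Binomial redistribution table (%s precision)\n", x$precision))
  cat(sprintf("  element_max: %d   natural abundance: %g\n",
              x$element_max, x$na))
  cat(sprintf("  B_sum(0) = %.4g (loss fraction of the monoisotopic peak)\n",
              x$loss_sums[[1L]]))
  invisible(x)
}

check_table <- function(table, what = "table") {
  if (!inherits(table, "binomial_table")) {
    stop(sprintf("`%s` must be a binomial_table (see build_binomial_table)",
                 what), call. = FALSE)
  }
  invisible(table)
}
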