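# Single-pass analytic transforms: the sequential correction (the exact
# triangular solve) and its forward model ("contamination"), for one or
# two labeled elements.  These are the algebraic core; missing peaks,
# negative flattening and renormalization live in iterative_correct().

#' Remove natural-abundance contributions from a complete isotopologue set
#'
#' Applies the sequential correction in ascending label-count order:
#' \deqn{I_{M+i} = \frac{I_{M+i;NA} - \sum_{x<i} I_{M+x}\,B(x,i)}
#'                      {1 - B_{sum}(i)},}
#' i.e. each observed intensity has the spill-over from all lighter,
#' already-corrected isotopologues subtracted and is then rescaled for
#' its own loss to heavier peaks.  The order matters: corrected
#' intensities at lower label counts are inputs to higher ones.
#'
#' The input must be complete (no `NA`s); supplementation of missing
#' peaks is the job of [iterative_correct()].  The output may contain
#' small negative values when the observed set is noisy — deliberately
#' not clipped here, so that the transform remains the exact algebraic
#' inverse of [contaminate_sequential()].
#'
#' @param observed Numeric vector of observed intensities
#'   `I(M+0) .. I(M+element_max)`, length `element_max + 1`.
#' @param table A [build_binomial_table()] result for the same element
#'   count and abundance.
#' @return Numeric vector of corrected intensities, same length.
#' @seealso [contaminate_sequential()], [iterative_correct()]
#' @export
#' @examples
#' tbl <- build_binomial_table(4, na = 0.01109)
#' correct_sequential(c(0.956, 1.01, 3.33e-2, 3.70e-4, 1.38e-6), tbl)
correct_sequential <- function(observed, table) {
  check_table(table)
  observed <- spectrum_values(observed)
  check_vector_input(observed, table, allow_negative = TRUE)
  if (table$precision == "extended") {
    res <- ext_correct(as.numeric(observed), extended_lo(observed), table$na)
    return(with_extended_lo(res))
  }
  m1 <- table$element_max + 1L
  corrected <- numeric(m1)
  for (i in seq_len(m1)) {
    spill <- if (i > 1L) {
      sum(corrected[seq_len(i - 1L)] * table$terms[seq_len(i - 1L), i])
    } else 0
    corrected[i] <- (observed[i] - spill) / (1 - table$loss_sums[[i]])
  }
  corrected
}

#' Forward-model natural abundance onto a corrected isotopologue set
#'
#' The inverse of [correct_sequential()]: redistributes each corrected
#' intensity over heavier isotopologues with the binomial weights
#' `B(n, k)`,
#' \deqn{I_{M+k;NA} = \sum_{n \le k} I_{M+n}\,B(n,k).}
#' Because the weights for fixed `n` sum to one over `k`, total
#' intensity is conserved exactly.
#'
#' @param corrected Numeric vector of non-negative intensities, length
#'   `element_max + 1`.
#' @inheritParams correct_sequential
#' @return Numeric vector of natural-abundance-contaminated intensities.
#' @export
#' @examples
#' tbl <- build_binomial_table(4, na = 0.01109)
#' contaminate_sequential(c(1, 0, 0, 0, 0), tbl)
contaminate_sequential <- function(corrected, table) {
  check_table(table)
  corrected <- spectrum_values(corrected)
  check_vector_input(corrected, table, allow_negative = FALSE)
  if (table$precision == "extended") {
    res <- ext_contaminate(as.numeric(corrected), extended_lo(corrected),
                           table$na)
    return(with_extended_lo(res))
  }
  as.vector(crossprod(table$terms, as.numeric(corrected)))
}

#' Dual-label correction over a (13C count, 15N count) intensity matrix
#'
#' For simultaneous carbon and nitrogen labeling every observed cell is
#' a product-binomial mixture of lighter cells,
#' `B_C(x, i) * B_N(y, j)`, and the correction is the two-dimensional
#' sequential solve
#' \deqn{I_{i,j} = \frac{I_{i,j;NA} - \sum_{(x,y)\le(i,j),\,(x,y)\ne(i,j)}
#'       I_{x,y}\,B_C(x,i)\,B_N(y,j)}{B_C(i,i)\,B_N(j,j)},}
#' evaluated row-major ascending so that every lighter cell precedes the
#' one being corrected.  With `n_max = 0` this reduces exactly to
#' [correct_sequential()] over carbon.
#'
#' @param observed Numeric matrix of observed intensities,
#'   `(c_max + 1) x (n_max + 1)`, rows indexed by 13C count, columns by
#'   15N count.
#' @param carbon_table,nitrogen_table [build_binomial_table()] results
#'   for the two elements (double precision).
#' @return Matrix of corrected intensities, same dimensions.
#' @export
#' @examples
#' ct <- build_binomial_table(3, na = 0.01109)
#' nt <- build_binomial_table(2, na = 0.00364)
#' x <- matrix(0, 4, 3); x[1, 1] <- 1
#' correct_dual(contaminate_dual(x, ct, nt), ct, nt)
correct_dual <- function(observed, carbon_table, nitrogen_table) {
  observed <- spectrum_values(observed)
  check_matrix_input(observed, carbon_table, nitrogen_table)
  Bc <- carbon_table$terms
  Bn <- nitrogen_table$terms
  cm1 <- nrow(observed)
  nm1 <- ncol(observed)
  corrected <- matrix(0, cm1, nm1)
  for (i in seq_len(cm1)) {
    for (j in seq_len(nm1)) {
      w <- outer(Bc[seq_len(i), i], Bn[seq_len(j), j])
      # corrected[i, j] is still 0, so the full block sum excludes it
      spill <- sum(corrected[seq_len(i), seq_len(j), drop = FALSE] * w)
      corrected[i, j] <- (observed[i, j] - spill) / (Bc[i, i] * Bn[j, j])
    }
  }
  dimnames(corrected) <- NULL
  corrected
}

#' Dual-label forward model
#'
#' Inverse of [correct_dual()]: applies carbon and nitrogen
#' natural-abundance redistribution independently along the two axes,
#' \deqn{I_{i,j;NA} = \sum_{x\le i}\sum_{y\le j}
#'       I_{x,y}\,B_C(x,i)\,B_N(y,j),}
#' which is the matrix product `t(B_C) I B_N`.  Total intensity is
#' conserved.
#'
#' @param corrected Non-negative numeric matrix,
#'   `(c_max + 1) x (n_max + 1)`.
#' @inheritParams correct_dual
#' @return Matrix of contaminated intensities, same dimensions.
#' @export
contaminate_dual <- function(corrected, carbon_table, nitrogen_table) {
  corrected <- spectrum_values(corrected)
  check_matrix_input(corrected, carbon_table, nitrogen_table,
                     allow_negative = FALSE)
  out <- crossprod(carbon_table$terms, corrected) %*% nitrogen_table$terms
  dimnames(out) <- NULL
  out
}

# Extended-precision spectra carry the sub-double remainder of each
# intensity in an attribute, so chained extended-mode transforms keep
# the full 64-bit-mantissa value across the R boundary.  Plain doubles
# (attribute absent) are accepted everywhere.
extended_lo <- function(x) {
  lo <- attr(x, "extended_lo")
  if (is.null(lo)) NULL else as.numeric(lo)
}

with_extended_lo <- function(res) {
  out <- res$hi
  attr(out, "extended_lo") <- res$lo
  out
}

check_vector_input <- function(x, table, allow_negative = FALSE) {
  if (!is.numeric(x) || !is.null(dim(x))) {
    stop("expected a numeric intensity vector", call. = FALSE)
  }
  if (length(x) != table$element_max + 1L) {
    stop(sprintf("spectrum has %d entries but the table was built for element_max = %d (expect %d)",
                 length(x), table$element_max, table$element_max + 1L),
         call. = FALSE)
  }
  if (anyNA(x)) {
    stop("spectrum contains missing values; supplement them first (see iterative_correct)",
         call. = FALSE)
  }
  if (!allow_negative && any(x < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  invisible(x)
}

check_matrix_input <- function(x, carbon_table, nitrogen_table,
                               allow_negative = TRUE) {
  check_table(carbon_table, "carbon_table")
  check_table(nitrogen_table, "nitrogen_table")
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expected a numeric intensity matrix (rows = 13C count, columns = 15N count)",
         call. = FALSE)
  }
  if (nrow(x) != carbon_table$element_max + 1L ||
      ncol(x) != nitrogen_table$element_max + 1L) {
    stop(sprintf("matrix is %dx%d but tables expect %dx%d",
                 nrow(x), ncol(x),
                 carbon_table$element_max + 1L,
                 nitrogen_table$element_max + 1L), call. = FALSE)
  }
  if (anyNA(x)) {
    stop("spectrum contains missing values; supplement them first (see iterative_correct)",
         call. = FALSE)
  }
  if (carbon_table$precision == "extended" ||
      nitrogen_table$precision == "extended") {
    stop("dual-label transforms are implemented in double precision only",
         call. = FALSE)
  }
  if (!allow_negative && any(x < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  invisible(x)
}
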