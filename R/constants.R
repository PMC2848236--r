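#' Fractional natural abundance of carbon-13
#'
#' Fraction of naturally occurring carbon that is the heavy isotope
#' \eqn{^{13}}C.  This is the default used by every carbon-mode
#' correction in the package; it can be overridden per analysis via
#' [correction_constants()].
#'
#' @return A length-one numeric fraction.
#' @seealso [default_na_15n()]
#' @export
#' @examples
#' default_na_13c()
default_na_13c <- function() 0.01109

#' Fractional natural abundance of nitrogen-15
#'
#' The IUPAC representative isotopic composition of \eqn{^{15}}N
#' (0.00364).  Nitrogen-mode corrections never assume this silently: the
#' abundance must be passed explicitly (for example as
#' `correction_constants(na_n = default_na_15n())`), so that the choice
#' of constant is always visible in the analysis.
#'
#' @return A length-one numeric fraction.
#' @export
#' @examples
#' correction_constants(na_n = default_na_15n())
default_na_15n <- function() 0.00364

#' Natural-abundance constants and numeric precision for a correction
#'
#' Bundles the fractional natural abundances used by the correction
#' together with the floating-point mode the binomial tables are
#' evaluated in.
#'
#' @param na_c Fractional natural abundance of \eqn{^{13}}C, in
#'   `[0, 0.5)`.  Defaults to [default_na_13c()].
#' @param na_n Fractional natural abundance of \eqn{^{15}}N, in
#'   `[0, 0.5)`, or `NULL` (the default).  Nitrogen and dual-label modes
#'   refuse to run until a value is given explicitly; see
#'   [default_na_15n()].
#' @param precision `"double"` (IEEE 64-bit; molecules up to 269 atoms of
#'   the labeled element) or `"extended"` (80-bit extended precision,
#'   for larger molecules).  See [build_binomial_table()] for the limits.
#'
#' @return An object of class `"correction_constants"`: a list with
#'   elements `na_c`, `na_n` and `precision`.
#' @export
#' @examples
#' correction_constants()
#' correction_constants(na_n = default_na_15n(), precision = "extended")
correction_constants <- function(na_c = default_na_13c(),
                                 na_n = NULL,
                                 precision = c("double", "extended")) {
  precision <- match.arg(precision)
  check_abundance(na_c, "na_c")
  if (!is.null(na_n)) check_abundance(na_n, "na_n")
  structure(
    list(na_c = na_c, na_n = na_n, precision = precision),
    class = "correction_constants"
  )
}

#' @export
print.correction_constants <- function(x, ...) {
  cat("Natural-abundance correction constants\n")
  cat(sprintf("  13C abundance: %g\n", x$na_c))
  cat(sprintf("  15N abundance: %s\n",
              if (is.null(x$na_n)) "<unset - required for nitrogen modes>"
              else format(x$na_n)))
  cat(sprintf("  precision:     %s\n", x$precision))
  invisible(x)
}

check_abundance <- function(na, what) {
  if (!is.numeric(na) || length(na) != 1L || is.na(na) ||
      na < 0 || na >= 0.5) {
    stop(sprintf("`%s` must be a single fraction in [0, 0.5), got %s",
                 what, deparse(na)), call. = FALSE)
  }
  invisible(na)
}

# Abundance for one element, failing loudly when 15N was never set.
abundance_for <- function(constants, element) {
  if (element == "C") return(constants$na_c)
  if (is.null(constants$na_n)) {
    stop("the 15N natural abundance has no implicit default; ",
         "set it explicitly, e.g. correction_constants(na_n = default_na_15n())",
         call. = FALSE)
  }
  constants$na_n
}
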