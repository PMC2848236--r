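#' Isotopologue intensity spectrum
#'
#' A light container for one metabolite's relative isotopologue
#' intensities: a vector `I(M+0) .. I(M+max)` for a single labeled
#' element, or a `(c_max + 1) x (n_max + 1)` matrix for dual 13C/15N
#' labeling.  `NA` entries mark isotopologues that were not observed
#' (missing peaks) — distinct from an explicit zero, which is data.
#'
#' Most functions in the package also accept plain numeric vectors and
#' matrices; the class mainly carries the element maxima and the
#' normalization basis through the I/O and reporting layers.
#'
#' @param intensities Numeric vector or matrix of non-negative
#'   intensities; `NA` = missing peak.
#' @param element For vector input, which element carries the label
#'   (`"C"` or `"N"`).  Matrix input is always dual `"CN"`.
#' @param normalization_basis Positive scale used when reporting
#'   fractional intensities; defaults to the sum of the observed
#'   (non-`NA`) entries.
#' @return An object of class `"isotopologue_spectrum"`.
#' @export
#' @examples
#' isotopologue_spectrum(c(0.956, 1.01, 3.33e-2, 3.70e-4, 1.38e-6))
isotopologue_spectrum <- function(intensities, element = c("C", "N", "CN"),
                                  normalization_basis = NULL) {
  element <- match.arg(element)
  if (!is.numeric(intensities)) {
    stop("`intensities` must be numeric", call. = FALSE)
  }
  dual <- is.matrix(intensities)
  if (dual) element <- "CN"
  if (!dual && element == "CN") {
    stop("dual-label spectra must be matrices (rows = 13C, cols = 15N)",
         call. = FALSE)
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative (use NA for missing peaks)",
         call. = FALSE)
  }
  if (all(is.na(intensities))) {
    stop("spectrum has no observed entries", call. = FALSE)
  }
  basis <- normalization_basis %||% sum(intensities, na.rm = TRUE)
  if (!is.numeric(basis) || length(basis) != 1L || basis <= 0) {
    stop("`normalization_basis` must be a positive scalar", call. = FALSE)
  }
  maxima <- if (dual) {
    c(C = nrow(intensities) - 1L, N = ncol(intensities) - 1L)
  } else {
    stats::setNames(length(intensities) - 1L, element)
  }
  structure(
    list(intensities = intensities, element = element,
         element_maxima = maxima, normalization_basis = basis),
    class = "isotopologue_spectrum"
  )
}

#' @export
print.isotopologue_spectrum <- function(x, ...) {
  lab <- paste(sprintf("%s_max = %d", names(x$element_maxima),
                       x$element_maxima), collapse = ", ")
  cat(sprintf("Isotopologue spectrum (%s label; %s)\n", x$element, lab))
  n_missing <- sum(is.na(x$intensities))
  if (n_missing > 0) cat(sprintf("  %d missing peak(s)\n", n_missing))
  print(x$intensities, ...)
  invisible(x)
}

# Plain values out of either a spectrum object or raw numeric input.
spectrum_values <- function(x) {
  if (inherits(x, "isotopologue_spectrum")) x$intensities else x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
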