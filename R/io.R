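# Delimited-table readers and writers for isotopologue intensity sets.
# Dialect: one header line; '#' lines are comments; decimal points only.
# Single-label files carry (isotopologue, intensity) columns, dual-label
# files (c13, n15, intensity); an optional metabolite column separates
# several metabolites in one file.  Absent indices are missing peaks,
# not zeros.

#' Read isotopologue intensity tables
#'
#' @param path Path to a TSV or CSV file.  Required columns:
#'   `isotopologue` + `intensity` (single label) or `c13` + `n15` +
#'   `intensity` (dual label); a `corrected` column is accepted in place
#'   of `intensity`, so result files written by
#'   [write_correction_result()] can be re-read.  An optional
#'   `metabolite` column splits the file into several tables.
#' @param format `"auto"` (by file extension, default), `"tsv"` or
#'   `"csv"`.
#' @param value_col Column to take intensities from; by default
#'   `intensity`, falling back to `corrected`.  Rows whose value is the
#'   literal `NA` are treated as absent (missing peaks), so result files
#'   with supplemented peaks re-read cleanly.
#' @return A list of objects of class `"isotopologue_table"`, each with
#'   `metabolite_id`, `indices` (integer vector, or two-column matrix
#'   for dual label), `intensities` and `provenance`.  An empty file
#'   yields an empty list with a warning.
#' @seealso [table_spectrum()] to expand a table into a correction-ready
#'   spectrum.
#' @export
read_isotopologue_table <- function(path, format = c("auto", "tsv", "csv"),
                                    value_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    read.table(path, header = TRUE, sep = sep, comment.char = "#",
               stringsAsFactors = FALSE, strip.white = TRUE,
               blank.lines.skip = TRUE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) {
        return(data.frame())
      }
      stop(sprintf("failed to parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  if (nrow(df) == 0L) {
    warning(sprintf("no data rows in %s", path), call. = FALSE)
    return(list())
  }
  names(df) <- tolower(names(df))
  intensity_col <- value_col %||%
    intersect(c("intensity", "corrected"), names(df))[1]
  if (is.na(intensity_col) || !intensity_col %in% names(df)) {
    stop(sprintf("%s: need an `intensity` (or `corrected`) column", path),
         call. = FALSE)
  }
  dual <- all(c("c13", "n15") %in% names(df))
  if (!dual && !"isotopologue" %in% names(df)) {
    stop(sprintf("%s: need an `isotopologue` column (or `c13` + `n15`)",
                 path), call. = FALSE)
  }

  ids <- if ("metabolite" %in% names(df)) as.character(df$metabolite)
         else rep("metabolite_1", nrow(df))
  col <- df[[intensity_col]]
  if (is.numeric(col)) {
    # read.table already parsed it at full precision
    absent <- is.na(col)
    intens <- col
  } else {
    raw <- trimws(as.character(col))
    absent <- raw == "NA"
    intens <- suppressWarnings(as.numeric(raw))
  }
  bad <- which(!absent & (!is.finite(intens) | intens < 0))
  if (length(bad)) {
    stop(sprintf("%s: non-finite or negative intensity on data row %d",
                 path, bad[1L]), call. = FALSE)
  }
  keep <- which(!absent)
  if (!length(keep)) {
    warning(sprintf("no observed intensities in %s", path), call. = FALSE)
    return(list())
  }
  df <- df[keep, , drop = FALSE]
  ids <- ids[keep]
  intens <- intens[keep]

  lapply(split(seq_len(nrow(df)), factor(ids, unique(ids))), function(rows) {
    if (dual) {
      idx <- cbind(c = parse_counts(df$c13[rows], path),
                   n = parse_counts(df$n15[rows], path))
      key <- paste(idx[, 1L], idx[, 2L])
    } else {
      idx <- parse_counts(df$isotopologue[rows], path)
      key <- idx
    }
    if (anyDuplicated(key)) {
      stop(sprintf("%s: duplicate isotopologue index for metabolite %s",
                   path, ids[rows[1L]]), call. = FALSE)
    }
    structure(
      list(metabolite_id = ids[rows[1L]], indices = idx,
           intensities = intens[rows], provenance = path),
      class = "isotopologue_table")
  })
}

parse_counts <- function(x, path) {
  counts <- suppressWarnings(as.integer(x))
  if (anyNA(counts) || any(counts < 0)) {
    stop(sprintf("%s: isotopologue indices must be non-negative integers",
                 path), call. = FALSE)
  }
  counts
}

#' Expand an isotopologue table into a correction-ready spectrum
#'
#' Lays the table's rows out as a dense vector (or matrix) indexed by
#' heavy-atom count, with `NA` at every absent index so the iterative
#' algorithm can supplement it.  When no element maximum is given the
#' largest observed index is used, with a warning — trailing unobserved
#' isotopologues change the correction, so an explicit maximum from the
#' molecular formula is preferred.
#'
#' @param table One `"isotopologue_table"` from
#'   [read_isotopologue_table()].
#' @param c_max,n_max Element maxima; `NULL` to infer from the data.
#' @return Numeric vector (single label) or matrix (dual label) with
#'   `NA` for missing peaks.
#' @export
table_spectrum <- function(table, c_max = NULL, n_max = NULL) {
  stopifnot(inherits(table, "isotopologue_table"))
  dual <- is.matrix(table$indices)
  if (dual) {
    c_max <- infer_max(c_max, table$indices[, 1L], "c_max",
                       table$metabolite_id)
    n_max <- infer_max(n_max, table$indices[, 2L], "n_max",
                       table$metabolite_id)
    spectrum <- matrix(NA_real_, c_max + 1L, n_max + 1L)
    spectrum[cbind(table$indices[, 1L] + 1L, table$indices[, 2L] + 1L)] <-
      table$intensities
  } else {
    c_max <- infer_max(c_max, table$indices, "element max",
                       table$metabolite_id)
    spectrum <- rep(NA_real_, c_max + 1L)
    spectrum[table$indices + 1L] <- table$intensities
  }
  spectrum
}

infer_max <- function(given, indices, what, id) {
  if (!is.null(given)) {
    if (given < max(indices)) {
      stop(sprintf("%s = %d is below the largest observed index %d (%s)",
                   what, given, max(indices), id), call. = FALSE)
    }
    return(as.integer(given))
  }
  warning(sprintf("%s not given for %s; using largest observed index %d",
                  what, id, max(indices)), call. = FALSE)
  as.integer(max(indices))
}

#' Write a correction result as a delimited table
#'
#' Emits the observed, corrected and recalculated (forward-modelled)
#' intensities side by side, preceded by `#` comment lines recording the
#' iteration count, residual, convergence flag and the flattened /
#' supplemented peak indices.  Intensities are printed with 17
#' significant digits, so a write/read round trip preserves them
#' exactly.
#'
#' @param result A `"correction_result"` from [iterative_correct()].
#' @param path Output file path, or an open connection (e.g. `stdout()`).
#' @param format `"tsv"` (default) or `"csv"`.
#' @param metabolite_id Identifier written in the `metabolite` column.
#' @param col_names Write the column-header line (set to `FALSE` when
#'   appending further metabolites to an already-written file).
#' @return `path`, invisibly.
#' @export
write_correction_result <- function(result, path, format = c("tsv", "csv"),
                                    metabolite_id = "metabolite_1",
                                    col_names = TRUE) {
  stopifnot(inherits(result, "correction_result"))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  dual <- is.matrix(result$corrected)

  header <- c(
    "# natural-abundance correction result",
    sprintf("# element: %s", result$element),
    sprintf("# iterations: %d", result$iterations),
    sprintf("# residual (%s): %.17g", result$residual_norm, result$residual),
    sprintf("# converged: %s", result$converged),
    sprintf("# normalization basis: %.17g", result$basis),
    sprintf("# flattened: %s",
            if (NROW(result$flattened)) format_counts(result$flattened)
            else "none"),
    sprintf("# supplemented: %s",
            if (NROW(result$supplemented)) format_counts(result$supplemented)
            else "none")
  )

  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  if (dual) {
    idx <- expand.grid(c13 = 0:(nrow(result$corrected) - 1L),
                       n15 = 0:(ncol(result$corrected) - 1L))
    df <- data.frame(metabolite = metabolite_id,
                     c13 = idx$c13, n15 = idx$n15,
                     intensity = num(as.vector(result$observed)),
                     corrected = num(as.vector(result$corrected)),
                     recalculated = num(as.vector(result$recalculated)))
  } else {
    df <- data.frame(metabolite = metabolite_id,
                     isotopologue = seq_along(result$corrected) - 1L,
                     intensity = num(result$observed),
                     corrected = num(result$corrected),
                     recalculated = num(result$recalculated))
  }
  con <- open_dest(path)
  if (con$owned) on.exit(close(con$con))
  writeLines(header, con$con)
  write.table(df, con$con, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = col_names)
  invisible(path)
}

open_dest <- function(path) {
  if (inherits(path, "connection")) {
    list(con = path, owned = FALSE)
  } else {
    list(con = file(path, "w"), owned = TRUE)
  }
}

#' Write a plain spectrum as a delimited table
#'
#' Serializes a spectrum in the format [read_isotopologue_table()]
#' accepts; `NA` (missing) entries are omitted, i.e. written as absent
#' rows.
#'
#' @param spectrum Numeric vector or matrix (`NA` = missing peak).
#' @param path Output file path or an open connection.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param metabolite_id Identifier for the `metabolite` column.
#' @param col_names Write the column-header line (set to `FALSE` when
#'   appending).
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectrum, path, format = c("tsv", "csv"),
                                 metabolite_id = "metabolite_1",
                                 col_names = TRUE) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  spectrum <- spectrum_values(spectrum)
  if (is.matrix(spectrum)) {
    idx <- which(!is.na(spectrum), arr.ind = TRUE)
    df <- data.frame(metabolite = metabolite_id,
                     c13 = idx[, 1L] - 1L, n15 = idx[, 2L] - 1L,
                     intensity = sprintf("%.17g", spectrum[idx]))
  } else {
    keep <- which(!is.na(spectrum))
    df <- data.frame(metabolite = metabolite_id,
                     isotopologue = keep - 1L,
                     intensity = sprintf("%.17g", spectrum[keep]))
  }
  con <- open_dest(path)
  if (con$owned) on.exit(close(con$con))
  write.table(df, con$con, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = col_names)
  invisible(path)
}
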