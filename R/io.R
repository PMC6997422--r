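#' Read a flat table of laboratory results
#'
#' Parses a CSV/TSV file with one test result per row and an optional
#' patient-ID column.  A header line is detected automatically: if the value
#' field of the first line does not parse as a number, the line is treated
#' as a header.  Only the decimal-point dialect is supported; comma-decimal
#' files must be converted explicitly.  Rows whose value field does not
#' parse are collected (with their row numbers), reported, and skipped; the
#' run only fails if no row parses at all.
#'
#' @param path path to the input file.
#' @param value_column column holding the result value: an index or, when a
#'   header is present, a name.
#' @param patient_column optional column holding the patient identifier.
#' @param delimiter field delimiter, default `","`.
#' @return An object of class `lab_table`: a data frame with columns `value`
#'   and (when requested) `patient_id`, with attributes `bad_rows` (input
#'   row numbers that failed to parse) and `n_input_rows`.
#' @export
read_lab_table <- function(path, value_column = 1L, patient_column = NULL,
                           delimiter = ",") {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("input file is empty: ", path)

  fields <- strsplit(lines, delimiter, fixed = TRUE)
  fields <- lapply(fields, trimws)

  resolve <- function(column, header) {
    if (is.numeric(column)) return(as.integer(column))
    i <- match(column, header)
    if (is.na(i)) stop("column '", column, "' not found in header")
    i
  }

  first <- fields[[1L]]
  vi <- if (is.numeric(value_column)) as.integer(value_column) else NA_integer_
  has_header <- if (!is.na(vi) && vi <= length(first)) {
    is.na(suppressWarnings(as.numeric(first[vi])))
  } else TRUE
  header <- if (has_header) first else NULL
  vi <- resolve(value_column, header)
  pi <- if (is.null(patient_column)) NULL else resolve(patient_column, header)
  body_idx <- if (has_header) seq_along(lines)[-1L] else seq_along(lines)
  if (length(body_idx) == 0L) stop("no data rows in ", path)

  get_field <- function(i, col) {
    f <- fields[[i]]
    if (col <= length(f)) f[col] else NA_character_
  }
  raw <- vapply(body_idx, get_field, character(1), col = vi)
  vals <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(vals))
  if (length(bad) == length(vals))
    stop("no parsable value rows in ", path)
  if (length(bad) > 0L)
    message("read_lab_table: ", length(bad), " unparsable value row(s) ",
            "skipped (first at input row ", body_idx[bad[1L]], ")")
  keep <- which(!is.na(vals))

  out <- data.frame(value = vals[keep])
  if (!is.null(pi))
    out$patient_id <- vapply(body_idx[keep], get_field, character(1), col = pi)
  attr(out, "bad_rows") <- body_idx[bad]
  attr(out, "n_input_rows") <- length(body_idx)
  class(out) <- c("lab_table", "data.frame")
  out
}

#' Keep one randomly selected row per patient
#'
#' Deduplicates repeat measurements by retaining exactly one uniformly
#' chosen row per distinct patient ID (deterministic given `seed`); rows
#' without an ID (`NA` or empty) are kept as singletons.  Output rows keep
#' the input order of their first occurrence per patient group.
#'
#' @param table a `lab_table` (or data frame) with columns `value` and
#'   `patient_id`.
#' @param seed integer seed for the per-patient selection.
#' @return A `lab_table` with one row per patient plus all un-identified
#'   rows.
#' @export
one_sample_per_patient <- function(table, seed = 1L) {
  if (is.null(table$patient_id))
    stop("one_sample_per_patient requires a patient_id column")
  id <- as.character(table$patient_id)
  no_id <- is.na(id) | !nzchar(id)
  keep_idx <- which(no_id)
  groups <- split(which(!no_id), id[!no_id])
  groups <- groups[order(names(groups))]  # ID order, not row order
  picked <- with_rng_stream(rng_streams(seed, 1L)[[1L]], {
    vapply(groups, function(rows) {
      if (length(rows) == 1L) rows else rows[sample.int(length(rows), 1L)]
    }, integer(1))
  })
  out <- table[sort(c(keep_idx, unname(picked))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_patients") <- length(groups)
  class(out) <- c("lab_table", "data.frame")
  out
}
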