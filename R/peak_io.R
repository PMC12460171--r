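# Peak-table input, validation, and MID assembly.

PEAK_TABLE_COLUMNS <- c("sample_id", "metabolite", "formula",
                        "tracer_element", "isotopologue_index", "intensity")

#' Parse an elemental formula into atom counts
#'
#' Tokenizes a Hill-notation molecular formula (e.g. `"C16H31O2"`) into a
#' named integer vector of element counts. Charge annotations are not
#' supported: the formula is entered as the measured elemental composition
#' of the detected ion (for saponified palmitate, the carboxylate anion's
#' composition), since isotope correction depends only on atom counts.
#'
#' @param formula Character scalar such as `"C16H31O2"`.
#' @return Named integer vector of strictly positive element counts.
#' @examples
#' parse_formula("C16H31O2")
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula) ||
      !nzchar(formula)) {
    stop("'formula' must be a single non-empty string", call. = FALSE)
  }
  tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1L]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop(sprintf("cannot parse formula '%s'", formula), call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", tokens)
  digits <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(digits), suppressWarnings(as.integer(digits)), 1L)
  if (anyNA(counts) || any(counts <= 0L)) {
    stop(sprintf("formula '%s' has a non-positive element count", formula),
         call. = FALSE)
  }
  out <- vapply(unique(elements), function(e) sum(counts[elements == e]),
                integer(1))
  out
}

#' Count atoms of one element in a formula
#'
#' @param formula Character scalar formula.
#' @param element Element symbol, e.g. `"C"` or `"H"`.
#' @return Integer count (0 when the element is absent).
#' @export
count_element <- function(formula, element) {
  counts <- parse_formula(formula)
  if (element %in% names(counts)) counts[[element]] else 0L
}

#' Read a long-format isotopologue peak table
#'
#' Reads the one-row-per-isotopologue CSV export convention of LC-MS peak
#' pickers: columns `sample_id, metabolite, formula, tracer_element,
#' isotopologue_index, intensity`. Every row is validated: the formula must
#' parse, the tracer element must occur in the formula, the isotopologue
#' index must not exceed the tracer atom count, and intensities must be
#' non-negative.
#'
#' @param path Path to a UTF-8 CSV file with the header above.
#' @param dialect Input dialect; only `"long_csv"` is supported.
#' @return A `data.frame` of validated peak records, row order preserved.
#' @seealso [assemble_mids()] to build per-sample MIDs,
#'   [write_peak_table()] for the inverse operation.
#' @export
read_peak_table <- function(path, dialect = "long_csv") {
  dialect <- match.arg(dialect, "long_csv")
  if (!file.exists(path)) {
    stop(sprintf("peak table not found: '%s'", path), call. = FALSE)
  }
  records <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(PEAK_TABLE_COLUMNS, names(records))
  if (length(missing)) {
    stop(sprintf("peak table '%s' is missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  records <- records[PEAK_TABLE_COLUMNS]
  validate_peak_records(records)
  records
}

#' Write a peak table to long CSV
#'
#' @param records Peak-record `data.frame` (see [read_peak_table()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(records, path) {
  write.csv(records[PEAK_TABLE_COLUMNS], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Validate peak records
#'
#' Checks the invariants of a peak-record table; called by
#' [read_peak_table()] and [assemble_mids()]. Errors name the offending
#' data row (header = line 1 of the file).
#'
#' @param records Peak-record `data.frame`.
#' @return `records`, invisibly.
#' @export
validate_peak_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("no records", call. = FALSE)
  }
  missing <- setdiff(PEAK_TABLE_COLUMNS, names(records))
  if (length(missing)) {
    stop(sprintf("peak records missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(is.na(records$intensity) | records$intensity < 0)
  if (length(bad)) {
    stop(sprintf("negative or missing intensity at row %d (line %d)",
                 bad[1L], bad[1L] + 1L), call. = FALSE)
  }
  idx <- records$isotopologue_index
  bad <- which(is.na(idx) | idx < 0 | idx != floor(idx))
  if (length(bad)) {
    stop(sprintf("invalid isotopologue_index at row %d (line %d)",
                 bad[1L], bad[1L] + 1L), call. = FALSE)
  }
  # parse each distinct formula once
  for (f in unique(records$formula)) {
    counts <- tryCatch(parse_formula(f), error = function(e) {
      row <- which(records$formula == f)[1L]
      stop(sprintf("row %d (line %d): %s", row, row + 1L, conditionMessage(e)),
           call. = FALSE)
    })
    rows <- which(records$formula == f)
    tracer <- records$tracer_element[rows]
    bad <- rows[!tracer %in% names(counts)]
    if (length(bad)) {
      stop(sprintf(
        "row %d (line %d): tracer element '%s' absent from formula '%s'",
        bad[1L], bad[1L] + 1L, records$tracer_element[bad[1L]], f),
        call. = FALSE)
    }
    n_tracer <- counts[records$tracer_element[rows]]
    over <- rows[records$isotopologue_index[rows] > n_tracer]
    if (length(over)) {
      r <- over[1L]
      stop(sprintf(
        paste0("row %d (line %d): isotopologue_index %d exceeds the %d ",
               "%s atoms of formula '%s'"),
        r, r + 1L, records$isotopologue_index[r],
        count_element(f, records$tracer_element[r]),
        records$tracer_element[r], f), call. = FALSE)
    }
  }
  invisible(records)
}

#' Read sample metadata
#'
#' Reads per-sample metadata: `sample_id`, `group`, and the optional columns
#' `tissue_mass_mg`, `extraction_volume_ul`, `dose_time`, `collection_time`
#' (ISO-8601 timestamps) and `body_water_acetone_fraction`.
#'
#' @param path CSV path.
#' @return `data.frame` with timestamp columns parsed to `POSIXct` (UTC).
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("sample metadata not found: '%s'", path), call. = FALSE)
  }
  meta <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(meta)) {
      stop(sprintf("sample metadata missing column: %s", col), call. = FALSE)
    }
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  for (col in c("dose_time", "collection_time")) {
    if (col %in% names(meta)) {
      # accept the ISO-8601 'T' separator
      meta[[col]] <- as.POSIXct(sub("T", " ", meta[[col]], fixed = TRUE),
                                tz = "UTC")
    }
  }
  if (all(c("dose_time", "collection_time") %in% names(meta))) {
    both <- !is.na(meta$dose_time) & !is.na(meta$collection_time)
    if (any(both & meta$collection_time <= meta$dose_time)) {
      stop("collection_time must be after dose_time", call. = FALSE)
    }
  }
  if ("tissue_mass_mg" %in% names(meta) &&
      any(!is.na(meta$tissue_mass_mg) & meta$tissue_mass_mg <= 0)) {
    stop("tissue_mass_mg must be > 0 when present", call. = FALSE)
  }
  meta
}

#' Assemble raw MIDs from peak records
#'
#' Groups validated records by (sample, metabolite) and builds one raw
#' intensity vector per key, of length tracer-atom-count + 1 (entries
#' M0..Mn). Isotopologues absent from the table are zero-filled with a
#' warning; duplicate (sample, metabolite, index) rows are an error. The
#' vectors are raw ion counts, not yet normalized or corrected.
#'
#' @param records Peak-record `data.frame` (validated or not; validation is
#'   re-run).
#' @return Named list (names `"sample|metabolite"`); each element a list
#'   with `sample_id`, `metabolite`, `formula`, `tracer_element`, `n_atoms`
#'   and the numeric `intensities` vector.
#' @export
assemble_mids <- function(records) {
  validate_peak_records(records)
  key <- paste(records$sample_id, records$metabolite, sep = "|")
  out <- lapply(split(seq_len(nrow(records)), key), function(rows) {
    rec <- records[rows, ]
    if (length(unique(rec$formula)) != 1L ||
        length(unique(rec$tracer_element)) != 1L) {
      stop(sprintf("inconsistent formula/tracer for sample '%s', '%s'",
                   rec$sample_id[1L], rec$metabolite[1L]), call. = FALSE)
    }
    n <- count_element(rec$formula[1L], rec$tracer_element[1L])
    dup <- rec$isotopologue_index[duplicated(rec$isotopologue_index)]
    if (length(dup)) {
      stop(sprintf(
        "duplicate isotopologue(s) %s for sample '%s', metabolite '%s'",
        paste(unique(dup), collapse = ", "),
        rec$sample_id[1L], rec$metabolite[1L]), call. = FALSE)
    }
    intens <- numeric(n + 1L)
    intens[rec$isotopologue_index + 1L] <- rec$intensity
    n_missing <- n + 1L - nrow(rec)
    if (n_missing > 0L) {
      warning(sprintf(
        "sample '%s', metabolite '%s': %d missing isotopologue(s) zero-filled",
        rec$sample_id[1L], rec$metabolite[1L], n_missing), call. = FALSE)
    }
    list(sample_id = rec$sample_id[1L], metabolite = rec$metabolite[1L],
         formula = rec$formula[1L], tracer_element = rec$tracer_element[1L],
         n_atoms = n, intensities = intens)
  })
  out[unique(key)]
}
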