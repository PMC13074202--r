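#' Construct a cohort table
#'
#' A `cohort_table` couples a schema, a data frame with one column per schema
#' variable, and an explicit logical missingness mask aligned to rows x
#' variables. `NA`/empty cells in the data correspond exactly to `TRUE` mask
#' entries; the identifier column is never maskable. Multi-select (multihot)
#' cells are stored as semicolon-joined option labels, with the empty string
#' denoting an explicit empty selection (distinct from missing).
#'
#' @param schema A `cohort_schema`.
#' @param data A data frame whose columns match the schema names (any order;
#'   they are reordered to schema order).
#' @param mask Optional logical matrix (rows x variables). If omitted it is
#'   derived from `NA` entries in `data`.
#' @return A `cohort_table`.
#' @export
cohort_table <- function(schema, data, mask = NULL) {
  stopifnot(inherits(schema, "cohort_schema"), is.data.frame(data))
  nm <- schema_names(schema)
  missing_cols <- setdiff(nm, names(data))
  extra_cols <- setdiff(names(data), nm)
  if (length(missing_cols) || length(extra_cols))
    stop("schema mismatch; missing columns: [",
         paste(missing_cols, collapse = ", "), "], unexpected columns: [",
         paste(extra_cols, collapse = ", "), "]")
  data <- data[nm]
  rownames(data) <- NULL
  if (is.null(mask)) {
    mask <- vapply(data, is.na, logical(nrow(data)))
    mask <- matrix(mask, nrow = nrow(data), dimnames = list(NULL, nm))
  }
  stopifnot(is.logical(mask), nrow(mask) == nrow(data), ncol(mask) == length(nm))
  colnames(mask) <- nm
  id <- identifier_variable(schema)
  if (any(mask[, id])) stop("identifier column may not contain missing values")
  ids <- data[[id]]
  if (anyDuplicated(ids)) stop("identifiers are not unique: ",
                               paste(utils::head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  for (v in nm) {
    na_here <- is.na(data[[v]])
    if (!identical(unname(na_here), unname(mask[, v])))
      data[[v]][mask[, v]] <- NA
  }
  structure(list(schema = schema, data = data, mask = mask),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$data), " patients x ", length(x$schema) - 1L,
      " variables; ", sum(x$mask), " missing cells\n", sep = "")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$data)

data_variables <- function(schema) setdiff(schema_names(schema), identifier_variable(schema))

split_multihot <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) character() else strsplit(cell, ";", fixed = TRUE)[[1]]
}

#' Read a cohort CSV against a schema
#'
#' The CSV must carry a header whose names equal the schema names (any
#' column order; values are bound by name). Cells equal to `missing_token`
#' become masked entries. Numeric cells are parsed per the declared kind; an
#' unparseable numeric raises an error addressed by row and column.
#' Categorical values outside the declared category list are collected into
#' the `validation` attribute, never silently coerced. Multihot cells are
#' semicolon-joined option lists; the token `"0"` denotes an explicit empty
#' selection.
#'
#' @param path CSV file path.
#' @param schema A `cohort_schema`.
#' @param missing_token String representing a missing cell (default `""`).
#' @return A `cohort_table`; attribute `validation` holds a data frame of
#'   out-of-category anomalies (row, variable, value).
#' @export
read_cohort <- function(path, schema, missing_token = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  nm <- schema_names(schema)
  missing_cols <- setdiff(nm, names(raw))
  extra_cols <- setdiff(names(raw), nm)
  if (length(missing_cols) || length(extra_cols))
    stop("header does not match schema; missing: [",
         paste(missing_cols, collapse = ", "), "], unexpected: [",
         paste(extra_cols, collapse = ", "), "]")
  raw <- raw[nm]
  n <- nrow(raw)
  mask <- matrix(FALSE, n, length(nm), dimnames = list(NULL, nm))
  anomalies <- list()
  out <- vector("list", length(nm)); names(out) <- nm
  for (v in nm) {
    spec <- schema[[v]]
    cells <- raw[[v]]
    is_miss <- cells == missing_token
    if ("identifier" %in% spec$roles && any(is_miss))
      stop("identifier column ", v, " contains missing cells")
    mask[, v] <- is_miss
    if (spec$kind == "numeric") {
      parsed <- suppressWarnings(as.numeric(cells))
      bad <- which(!is_miss & is.na(parsed))
      if (length(bad))
        stop("unparseable numeric value ", dQuote(cells[bad[1]]), " at row ",
             bad[1], ", column ", dQuote(v))
      parsed[is_miss] <- NA_real_
      out[[v]] <- parsed
    } else if (spec$kind == "categorical") {
      vals <- cells
      vals[is_miss] <- NA_character_
      if (!identical(spec$categories, "any")) {
        bad <- which(!is_miss & !(vals %in% spec$categories))
        if (length(bad))
          anomalies[[v]] <- data.frame(row = bad, variable = v,
                                       value = cells[bad])
      }
      out[[v]] <- vals
    } else { # multihot
      vals <- cells
      vals[is_miss] <- NA_character_
      vals[!is_miss & vals == "0"] <- ""
      sel <- lapply(vals[!is_miss], split_multihot)
      bad_opt <- !vapply(sel, function(s) all(s %in% spec$categories), logical(1))
      if (any(bad_opt)) {
        rows <- which(!is_miss)[bad_opt]
        anomalies[[v]] <- data.frame(row = rows, variable = v,
                                     value = cells[rows])
      }
      out[[v]] <- vals
    }
  }
  tab <- cohort_table(schema, as.data.frame(out, check.names = FALSE), mask)
  attr(tab, "validation") <-
    if (length(anomalies)) do.call(rbind, unname(anomalies))
    else data.frame(row = integer(), variable = character(), value = character())
  tab
}

#' Write a cohort table to CSV
#'
#' Round-trip exact: `read_cohort(write_cohort(x))` reproduces values and
#' mask cell for cell. Masked cells are serialized as `missing_token`;
#' numeric values are printed with 17 significant digits; an explicit empty
#' multihot selection is serialized as `"0"`.
#'
#' @param cohort A `cohort_table`.
#' @param path Output CSV path.
#' @param missing_token Missing-cell token (default `""`).
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, missing_token = "") {
  stopifnot(inherits(cohort, "cohort_table"))
  nm <- schema_names(cohort$schema)
  cols <- lapply(nm, function(v) {
    spec <- cohort$schema[[v]]
    x <- cohort$data[[v]]
    chr <- if (spec$kind == "numeric") {
      ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
    } else if (spec$kind == "multihot") {
      ifelse(is.na(x), NA_character_, ifelse(nzchar(x), x, "0"))
    } else as.character(x)
    chr[cohort$mask[, v]] <- missing_token
    chr
  })
  names(cols) <- nm
  df <- as.data.frame(cols, check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = missing_token)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write cohort to ", path, ": ", conditionMessage(ok))
  invisible(path)
}

#' Summarize missingness of a cohort
#'
#' Fractions are computed over data variables (the identifier is excluded
#' from all denominators). Per-row fractions drive the record filter.
#'
#' @param cohort A `cohort_table`.
#' @return A list with `total_cells`, `missing_cells`, `fraction`,
#'   `per_variable` (named fraction vector), `per_row` (data frame with
#'   identifier, missing count and fraction).
#' @export
missingness_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  vars <- data_variables(cohort$schema)
  m <- cohort$mask[, vars, drop = FALSE]
  id <- cohort$data[[identifier_variable(cohort$schema)]]
  per_row <- rowSums(m)
  list(
    total_cells = length(m),
    missing_cells = sum(m),
    fraction = if (length(m)) sum(m) / length(m) else 0,
    per_variable = colMeans(m),
    per_row = data.frame(id = id, missing = per_row,
                         fraction = per_row / length(vars))
  )
}
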