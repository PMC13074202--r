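#' Preprocessing configuration
#'
#' @param max_missing_fraction Per-record missingness threshold; rows whose
#'   missing fraction is strictly greater are removed (default 0.5, so a row
#'   missing exactly half its cells is kept).
#' @param knn_k Neighbor count for numeric KNN imputation, or the sentinel
#'   `"sqrt"` for `round(sqrt(n_rows))`.
#' @param meters_cutoff Heights strictly below this value are taken to be in
#'   meters and multiplied by 100 (default 3; no adult height is ambiguous
#'   across 3 under either unit).
#' @param numeric_method `"knn"` (default) or `"median"`; the median variant
#'   exists for sensitivity comparisons of downstream cluster structure.
#' @return A `preprocess_config`.
#' @export
preprocess_config <- function(max_missing_fraction = 0.5, knn_k = "sqrt",
                              meters_cutoff = 3.0,
                              numeric_method = c("knn", "median")) {
  stopifnot(max_missing_fraction > 0, max_missing_fraction < 1)
  if (!identical(knn_k, "sqrt")) stopifnot(is.numeric(knn_k), knn_k >= 1)
  structure(list(max_missing_fraction = max_missing_fraction,
                 knn_k = knn_k, meters_cutoff = meters_cutoff,
                 numeric_method = match.arg(numeric_method)),
            class = "preprocess_config")
}

#' Median imputation of numeric variables
#'
#' Baseline alternative to [impute_numeric_knn()] for sensitivity checks:
#' each missing numeric cell takes the variable's observed median.
#'
#' @param cohort A `cohort_table`.
#' @return List: `cohort` and `report` with `numeric_cells_imputed`.
#' @export
impute_numeric_median <- function(cohort) {
  n_imputed <- 0L
  for (v in data_variables(cohort$schema)) {
    if (cohort$schema[[v]]$kind != "numeric") next
    x <- cohort$data[[v]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    if (all(is.na(x)))
      stop("cannot impute variable observed in no row: ", v)
    cohort$data[[v]][miss] <- stats::median(x, na.rm = TRUE)
    cohort$mask[miss, v] <- FALSE
    n_imputed <- n_imputed + length(miss)
  }
  list(cohort = cohort, report = list(numeric_cells_imputed = n_imputed))
}

empty_flags <- function() data.frame(id = character(), variable = character(),
                                     value = numeric(), low = numeric(),
                                     high = numeric())

#' Remove records with excessive missingness
#'
#' Rows whose missing fraction (over data variables) strictly exceeds
#' `config$max_missing_fraction` are dropped; all other rows pass untouched.
#'
#' @param cohort A `cohort_table`.
#' @param config A `preprocess_config`.
#' @return List: `cohort` (filtered) and `report` with `rows_dropped` count
#'   and the dropped identifiers.
#' @export
filter_incomplete_records <- function(cohort, config = preprocess_config()) {
  ms <- missingness_summary(cohort)
  drop <- ms$per_row$fraction > config$max_missing_fraction
  kept <- cohort_table(cohort$schema,
                       cohort$data[!drop, , drop = FALSE],
                       cohort$mask[!drop, , drop = FALSE])
  list(cohort = kept,
       report = list(rows_dropped = sum(drop),
                     dropped_ids = ms$per_row$id[drop]))
}

#' Repair heights recorded in meters
#'
#' Non-missing height values strictly below `config$meters_cutoff` are
#' multiplied by 100; every correction is counted and addressed.
#'
#' @param cohort A `cohort_table` whose schema declares a cm-unit `height`.
#' @param config A `preprocess_config`.
#' @return List: `cohort` (corrected) and `report` with `unit_corrections`
#'   count and corrected identifiers.
#' @export
correct_height_units <- function(cohort, config = preprocess_config()) {
  if (!"height" %in% schema_names(cohort$schema))
    stop("schema declares no height variable")
  h <- cohort$data[["height"]]
  fix <- !is.na(h) & h < config$meters_cutoff
  cohort$data[["height"]][fix] <- h[fix] * 100
  id <- cohort$data[[identifier_variable(cohort$schema)]]
  list(cohort = cohort,
       report = list(unit_corrections = sum(fix), corrected_ids = id[fix]))
}

#' Flag clinically implausible values
#'
#' Non-missing numeric values outside their schema plausible range are
#' flagged with full addresses. Correction-over-deletion: nothing is
#' removed or altered here.
#'
#' @param cohort A `cohort_table`.
#' @return Data frame of flags (id, variable, value, low, high).
#' @export
flag_implausible <- function(cohort) {
  id <- cohort$data[[identifier_variable(cohort$schema)]]
  out <- list()
  for (v in data_variables(cohort$schema)) {
    spec <- cohort$schema[[v]]
    if (spec$kind != "numeric" || is.null(spec$plausible_range)) next
    x <- cohort$data[[v]]
    bad <- !is.na(x) & (x < spec$plausible_range[1] | x > spec$plausible_range[2])
    if (any(bad))
      out[[v]] <- data.frame(id = id[bad], variable = v, value = x[bad],
                             low = spec$plausible_range[1],
                             high = spec$plausible_range[2])
  }
  if (length(out)) do.call(rbind, unname(out)) else empty_flags()
}

# Pairwise partial distances on z-scaled numeric coordinates. Missing
# coordinates are skipped and the squared distance is rescaled by
# total dims / observed dims (standard partial-distance convention).
partial_distances <- function(X) {
  W <- !is.na(X)
  Z <- scale(X)
  sds <- attr(Z, "scaled:scale")
  Z[, sds == 0 | is.na(sds)] <- 0
  A <- Z; A[!W] <- 0
  A2 <- A^2
  Wn <- W * 1
  ss <- A2 %*% t(Wn) + Wn %*% t(A2) - 2 * A %*% t(A)
  obs <- Wn %*% t(Wn)
  d2 <- ifelse(obs > 0, ncol(X) / obs * ss, Inf)
  d2[d2 < 0] <- 0 # numerical noise
  sqrt(d2)
}

#' KNN imputation of numeric variables
#'
#' Each missing numeric cell is replaced by the mean of that variable over
#' the k nearest rows, with Euclidean distance computed on z-scaled,
#' mutually observed numeric coordinates (rescaled by total/observed
#' dimension count). Rows missing the target variable are excluded as
#' neighbors; observed cells are never altered. With the `"sqrt"` sentinel,
#' `k = round(sqrt(n_rows))`.
#'
#' @param cohort A `cohort_table`.
#' @param config A `preprocess_config`.
#' @return List: `cohort` (imputed) and `report` with
#'   `numeric_cells_imputed` and the `k` used.
#' @export
impute_numeric_knn <- function(cohort, config = preprocess_config()) {
  num_vars <- Filter(function(v) cohort$schema[[v]]$kind == "numeric",
                     data_variables(cohort$schema))
  X <- as.matrix(cohort$data[num_vars])
  n <- nrow(X)
  k <- if (identical(config$knn_k, "sqrt")) round(sqrt(n)) else as.integer(config$knn_k)
  k <- max(1L, k)
  all_missing <- num_vars[colSums(!is.na(X)) == 0]
  if (length(all_missing))
    stop("cannot impute variable(s) observed in no row: ",
         paste(all_missing, collapse = ", "))
  n_imputed <- 0L
  if (anyNA(X)) {
    D <- partial_distances(X)
    diag(D) <- Inf
    for (v in num_vars) {
      miss <- which(is.na(X[, v]))
      if (!length(miss)) next
      donors <- which(!is.na(X[, v]))
      for (i in miss) {
        d <- D[i, donors]
        nb <- donors[order(d)][seq_len(min(k, length(donors)))]
        val <- mean(X[nb, v])
        cohort$data[[v]][i] <- val
        cohort$mask[i, v] <- FALSE
        n_imputed <- n_imputed + 1L
      }
    }
  }
  list(cohort = cohort,
       report = list(numeric_cells_imputed = n_imputed, k = k))
}

#' Mode imputation of categorical variables
#'
#' Each missing categorical cell is set to the variable's most frequent
#' observed category. Ties break by schema category order and are logged.
#'
#' @param cohort A `cohort_table`.
#' @return List: `cohort` and `report` with per-variable imputed counts,
#'   imputed value, and tie flags.
#' @export
impute_categorical_mode <- function(cohort) {
  rows <- list()
  for (v in data_variables(cohort$schema)) {
    spec <- cohort$schema[[v]]
    if (spec$kind != "categorical") next
    x <- cohort$data[[v]]
    miss <- which(is.na(x))
    if (!length(miss)) next
    obs <- x[!is.na(x)]
    if (!length(obs))
      stop("cannot impute categorical variable observed in no row: ", v)
    counts <- table(factor(obs, levels = spec$categories))
    top <- max(counts)
    winners <- names(counts)[counts == top]
    mode_val <- winners[1] # schema category order breaks ties
    cohort$data[[v]][miss] <- mode_val
    cohort$mask[miss, v] <- FALSE
    rows[[v]] <- data.frame(variable = v, n_imputed = length(miss),
                            imputed_value = mode_val,
                            tie = length(winners) > 1)
  }
  report <- if (length(rows)) do.call(rbind, unname(rows))
            else data.frame(variable = character(), n_imputed = integer(),
                            imputed_value = character(), tie = logical())
  list(cohort = cohort, report = list(categorical_cells_imputed = report))
}

#' Map blank multi-select entries to explicit zeros
#'
#' A missing multihot cell means no option was recorded; it becomes an
#' explicit empty selection (all-zero indicator vector) and its mask bit is
#' cleared. Recorded selections are untouched.
#'
#' @param cohort A `cohort_table`.
#' @return The updated `cohort_table`.
#' @export
multihot_fill_zero <- function(cohort) {
  for (v in data_variables(cohort$schema)) {
    if (cohort$schema[[v]]$kind != "multihot") next
    miss <- cohort$mask[, v]
    cohort$data[[v]][miss] <- ""
    cohort$mask[miss, v] <- FALSE
  }
  cohort
}

#' Z-score standardization of numeric variables
#'
#' Column-wise `(x - mean) / sd` with the population (denominator n)
#' standard deviation. Constant columns are emitted as zeros with a
#' warning. Column means and sds are retained for inverse transforms.
#'
#' @param cohort A `cohort_table`.
#' @param variables Names of numeric, fully imputed variables.
#' @return A `standardized_matrix`: list with `values` (rows x variables
#'   numeric matrix), `means`, `sds`, `variables`.
#' @export
zscore_standardize <- function(cohort, variables) {
  kinds <- schema_kinds(cohort$schema)[variables]
  if (any(kinds != "numeric"))
    stop("non-numeric variable(s) requested: ",
         paste(variables[kinds != "numeric"], collapse = ", "))
  X <- as.matrix(cohort$data[variables])
  if (anyNA(X))
    stop("variables must be fully imputed before standardization")
  n <- nrow(X)
  mu <- colMeans(X)
  sds <- sqrt(colMeans(sweep(X, 2, mu)^2)) # population sd
  const <- sds == 0
  if (any(const)) {
    warning("constant column(s) emitted as zeros: ",
            paste(variables[const], collapse = ", "))
    sds[const] <- 1
  }
  Z <- sweep(sweep(X, 2, mu), 2, sds, `/`)
  sds[const] <- 0
  structure(list(values = Z, means = mu, sds = sds, variables = variables),
            class = "standardized_matrix")
}

#' One-hot encode a cohort
#'
#' Emits one indicator column per (variable, category) declared in the
#' schema; multihot variables emit one indicator per option; numeric
#' variables pass through unchanged. Categorical cells must already be
#' imputed. The column registry is ordered and reproducible.
#'
#' @param cohort A `cohort_table`.
#' @return List: `matrix` (numeric) and `registry` (data frame of column,
#'   variable, category).
#' @export
one_hot_encode <- function(cohort) {
  cols <- list(); reg <- list()
  for (v in data_variables(cohort$schema)) {
    spec <- cohort$schema[[v]]
    x <- cohort$data[[v]]
    if (spec$kind == "numeric") {
      cols[[v]] <- x
      reg[[length(reg) + 1L]] <- data.frame(column = v, variable = v,
                                            category = NA_character_)
    } else if (spec$kind == "categorical") {
      if (anyNA(x)) stop("categorical variable ", v, " has unimputed cells")
      for (cat in spec$categories) {
        cn <- paste0(v, "=", cat)
        cols[[cn]] <- as.numeric(x == cat)
        reg[[length(reg) + 1L]] <- data.frame(column = cn, variable = v,
                                              category = cat)
      }
    } else {
      sel <- lapply(ifelse(is.na(x), "", x), split_multihot)
      for (cat in spec$categories) {
        cn <- paste0(v, "=", cat)
        cols[[cn]] <- vapply(sel, function(s) as.numeric(cat %in% s), numeric(1))
        reg[[length(reg) + 1L]] <- data.frame(column = cn, variable = v,
                                              category = cat)
      }
    }
  }
  list(matrix = do.call(cbind, cols), registry = do.call(rbind, reg))
}

#' Pearson correlation matrix of standardized variables
#'
#' @param matrix A `standardized_matrix`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_correlations <- function(matrix) {
  stopifnot(inherits(matrix, "standardized_matrix"), nrow(matrix$values) >= 2)
  r <- suppressWarnings(stats::cor(matrix$values))
  diag(r) <- 1
  r
}

#' Run the fixed preprocessing pipeline
#'
#' Stage order is fixed: record filter, height unit repair, plausibility
#' flags, numeric KNN imputation, categorical mode imputation, multihot
#' zero-fill. BMI (when present alongside weight and height) is recomputed
#' from the repaired, imputed weight and height so the derived variable
#' stays consistent. The returned table has zero masked cells.
#'
#' @param cohort A `cohort_table`.
#' @param config A `preprocess_config`.
#' @return List: `cohort` (clean), `report` (aggregated `preprocess_report`),
#'   `flags` (implausible-value data frame).
#' @export
preprocess_cohort <- function(cohort, config = preprocess_config()) {
  f <- filter_incomplete_records(cohort, config)
  u <- correct_height_units(f$cohort, config)
  flags <- flag_implausible(u$cohort)
  k <- if (identical(config$numeric_method, "median"))
    impute_numeric_median(u$cohort)
  else impute_numeric_knn(u$cohort, config)
  m <- impute_categorical_mode(k$cohort)
  clean <- multihot_fill_zero(m$cohort)
  nm <- schema_names(clean$schema)
  if (all(c("bmi", "weight", "height") %in% nm)) {
    clean$data[["bmi"]] <- clean$data[["weight"]] / (clean$data[["height"]] / 100)^2
    clean$mask[, "bmi"] <- FALSE
  }
  report <- structure(c(f$report, u$report, k$report, m$report,
                        list(out_of_range_flags = flags)),
                      class = "preprocess_report")
  list(cohort = clean, report = report, flags = flags)
}
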