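#' Construct a binary cohort
#'
#' A cohort is a patient-by-variable table of 0/1 indicators with a
#' designated outcome column. Continuous columns (e.g. raw age in years) may
#' be carried alongside the binary ones; they are excluded from transaction
#' encoding until dichotomized with [dichotomize()].
#'
#' @param data a data.frame; binary columns must contain only 0 and 1,
#'   any other numeric column is treated as continuous.
#' @param outcome name of the binary outcome column.
#' @param age_raw optional named list of retained raw numeric vectors
#'   (populated by [dichotomize()]).
#' @return an object of class `cohort`.
#' @export
cohort <- function(data, outcome, age_raw = list()) {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  if (!outcome %in% names(data)) {
    stop("outcome column '", outcome, "' not found in cohort", call. = FALSE)
  }
  continuous <- character(0)
  for (col in names(data)) {
    v <- data[[col]]
    if (anyNA(v)) {
      stop("missing cell in column '", col, "': cohorts must be complete",
           call. = FALSE)
    }
    if (!is.numeric(v)) {
      stop("column '", col, "' is not numeric; encode tokens via read_cohort()",
           call. = FALSE)
    }
    if (all(v %in% c(0, 1))) {
      data[[col]] <- as.integer(v)
    } else {
      continuous <- c(continuous, col)
    }
  }
  if (outcome %in% continuous) {
    stop("outcome column '", outcome, "' must be binary 0/1", call. = FALSE)
  }
  structure(
    list(data = data, outcome = outcome, continuous = continuous,
         age_raw = age_raw),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$data), " patients x ", ncol(x$data), " variables; ",
      "outcome = ", x$outcome,
      " (", sum(x$data[[x$outcome]]), " positive)\n", sep = "")
  if (length(x$continuous)) {
    cat("  continuous (not yet dichotomized): ",
        paste(x$continuous, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Number of patients in a cohort
#' @param x a `cohort`.
#' @return integer row count.
#' @export
n_patients <- function(x) nrow(x$data)

#' Built-in token dialect for string-coded cohorts
#'
#' Mapping used by UCI-style symptom tables: Yes/Positive/Female code 1,
#' No/Negative/Male code 0 (female sex is the outcome-enriched stratum in
#' the diabetes cohort, hence the positive code).
#'
#' @param ... named overrides or additions, e.g. `Present = 1`.
#' @return named integer vector mapping tokens to 0/1.
#' @export
uci_dialect <- function(...) {
  base <- c(Yes = 1L, No = 0L, Positive = 1L, Negative = 0L,
            Female = 1L, Male = 0L)
  extra <- c(...)
  if (length(extra)) {
    extra <- stats::setNames(as.integer(extra), names(extra))
    base <- c(extra, base[!names(base) %in% names(extra)])
  }
  base
}

#' Read a cohort CSV
#'
#' Reads a comma-separated file with a header row, one row per patient and
#' one column per variable. String tokens are translated through `dialect`;
#' unmapped tokens and missing cells are hard errors, never imputed.
#' Numeric columns whose values are not all 0/1 are kept as continuous
#' (see [dichotomize()]).
#'
#' @param path path to the CSV file.
#' @param outcome name of the outcome column.
#' @param dialect named vector mapping string tokens to 0/1; defaults to
#'   [uci_dialect()].
#' @return a validated [cohort()].
#' @export
read_cohort <- function(path, outcome, dialect = uci_dialect()) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = NA, na.strings = character(0))
  if (nrow(raw) == 0) stop("empty cohort file: ", path, call. = FALSE)
  for (col in names(raw)) {
    v <- raw[[col]]
    if (is.character(v)) {
      blank <- which(!nzchar(trimws(v)))
      if (length(blank)) {
        stop("missing cell at row ", blank[1], ", column '", col, "'",
             call. = FALSE)
      }
      v <- trimws(v)
      # a fully numeric string column is read as numbers, not tokens
      num <- suppressWarnings(as.numeric(v))
      if (!anyNA(num)) {
        raw[[col]] <- num
        next
      }
      unknown <- setdiff(unique(v), names(dialect))
      if (length(unknown)) {
        at <- which(v == unknown[1])[1]
        stop("unknown token '", unknown[1], "' at row ", at, ", column '",
             col, "' (add it to the dialect)", call. = FALSE)
      }
      raw[[col]] <- as.integer(dialect[v])
    } else if (anyNA(v)) {
      at <- which(is.na(v))[1]
      stop("missing cell at row ", at, ", column '", col, "'", call. = FALSE)
    }
  }
  cohort(raw, outcome = outcome)
}

#' Write a cohort as canonical 0/1 CSV
#'
#' @param x a `cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dichotomize a continuous column
#'
#' Appends a binary column coding 1 where the value lies strictly above
#' `cutoff` (the midpoint-threshold convention, matching [roc_cutoff()]'s
#' positive-is-above rule: for integer ages a cutoff of 46.5 codes 47 and
#' older as 1). The raw numeric column is removed from the binary table and
#' retained in `$age_raw`.
#'
#' @param x a `cohort`.
#' @param column name of the continuous column.
#' @param cutoff finite numeric threshold; values > cutoff code 1.
#' @param new_name name for the appended binary column (default: `column`).
#' @return the updated `cohort`.
#' @export
dichotomize <- function(x, column, cutoff, new_name = column) {
  stopifnot(inherits(x, "cohort"), is.finite(cutoff))
  if (!column %in% names(x$data) && !column %in% names(x$age_raw)) {
    stop("column '", column, "' not found", call. = FALSE)
  }
  # prefer retained raw values so re-applying after dichotomization works
  v <- if (column %in% names(x$age_raw)) x$age_raw[[column]] else x$data[[column]]
  if (!is.numeric(v)) stop("column '", column, "' is not numeric", call. = FALSE)
  d <- x$data
  d[[column]] <- NULL
  d[[new_name]] <- as.integer(v > cutoff)
  raw <- x$age_raw
  raw[[column]] <- v
  cohort(d, outcome = x$outcome, age_raw = raw)
}

#' Convert a cohort to transactions
#'
#' Each patient becomes the set of `"<Variable>=1"` tokens for their
#' 1-valued binary columns. Only presence items are emitted by default
#' because outcome-targeted rules are built from positive indicators;
#' absence tokens (`"<Variable>=0"`) can be added explicitly.
#'
#' @param x a `cohort`; continuous columns are skipped.
#' @param include_absence also emit `"<Variable>=0"` tokens.
#' @return an object of class `transaction_set` with elements
#'   `items` (list of per-patient token vectors), `n` (patient count) and
#'   `item_universe` (all tokens observed, canonically sorted).
#' @export
to_transactions <- function(x, include_absence = FALSE) {
  stopifnot(inherits(x, "cohort"))
  cols <- setdiff(names(x$data), x$continuous)
  m <- as.matrix(x$data[cols])
  token <- function(names, suffix) {
    # paste0(character(0), ...) would yield a bare suffix token
    if (length(names) == 0L) character(0) else paste0(names, suffix)
  }
  trans <- lapply(seq_len(nrow(m)), function(i) {
    present <- token(cols[m[i, ] == 1L], "=1")
    if (include_absence) {
      present <- c(present, token(cols[m[i, ] == 0L], "=0"))
    }
    sort_items(present)
  })
  transaction_set(trans)
}

#' Construct a transaction set
#'
#' @param items list of character vectors, one per transaction; empty
#'   vectors are allowed and still counted.
#' @return a `transaction_set`.
#' @export
transaction_set <- function(items) {
  stopifnot(is.list(items))
  items <- lapply(items, function(t) sort_items(unique(as.character(t))))
  structure(
    list(items = items, n = length(items),
         item_universe = sort_items(unique(unlist(items)))),
    class = "transaction_set"
  )
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("<transaction_set> ", x$n, " transactions over ",
      length(x$item_universe), " items\n", sep = "")
  invisible(x)
}

# n x p logical incidence matrix of a transaction set (items as columns)
incidence_matrix <- function(tset) {
  u <- tset$item_universe
  m <- matrix(FALSE, nrow = tset$n, ncol = length(u),
              dimnames = list(NULL, u))
  for (i in seq_len(tset$n)) {
    m[i, tset$items[[i]]] <- TRUE
  }
  m
}
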