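#' Build a categorical dataset from a data frame
#'
#' Converts a table of categorical observations (rows = samples, columns =
#' variables) into the integer-coded form used by all information and
#' complexity computations. Values are treated as opaque categorical labels
#' and coded `1..r_v` in lexicographic order of their string representation,
#' so the coding (and every downstream tie-break) is deterministic across
#' runs and independent of row order. The number of levels `r_v` of a
#' variable is the number of *observed* distinct categories; theoretical
#' levels that never occur in the data are ignored, which matches the
#' plug-in (maximum-likelihood) estimators used throughout.
#'
#' Missing values are rejected: the method assumes complete cases.
#'
#' @param x A data frame (or matrix) of categorical observations. Factors,
#'   characters, integers and logicals are all accepted and coerced to
#'   character labels.
#' @return An object of class `categorical_dataset`: a list with elements
#'   `codes` (integer matrix, entries in `1..r_v`), `levels` (integer vector
#'   of per-variable level counts), `labels` (list of sorted level labels),
#'   `variable_names`, and `n` (sample count).
#' @examples
#' d <- as_categorical_dataset(data.frame(a = c("x", "y", "x"), b = c(0, 1, 1)))
#' d$levels
#' @export
as_categorical_dataset <- function(x) {
  if (inherits(x, "categorical_dataset")) return(x)
  if (is.matrix(x)) x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame or matrix of categorical observations.")
  }
  if (nrow(x) < 1L) abort("dataset must contain at least one sample (N >= 1).")
  if (ncol(x) < 1L) abort("dataset must contain at least one variable.")
  vn <- names(x) %||% paste0("V", seq_len(ncol(x)))
  cols <- lapply(x, function(col) {
    if (is.factor(col)) col <- as.character(col)
    col <- as.character(col)
    if (anyNA(col) || any(!nzchar(col))) {
      abort("missing or empty cells found; complete-case categorical data required.")
    }
    labs <- sort(unique(col), method = "radix")
    list(code = match(col, labs), labels = labs)
  })
  codes <- vapply(cols, `[[`, integer(nrow(x)), "code")
  if (!is.matrix(codes)) codes <- matrix(codes, nrow = nrow(x))
  colnames(codes) <- vn
  levels <- vapply(cols, function(c) length(c$labels), integer(1))
  if (nrow(x) < 10L) {
    warn(sprintf("only N = %d samples; information estimates will be very noisy.", nrow(x)))
  }
  if (any(levels == 1L)) {
    warn(sprintf(
      "variable(s) %s are constant (a single observed level).",
      paste(vn[levels == 1L], collapse = ", ")
    ))
  }
  structure(
    list(
      codes = codes,
      levels = unname(levels),
      labels = lapply(cols, `[[`, "labels"),
      variable_names = vn,
      n = nrow(x)
    ),
    class = "categorical_dataset"
  )
}

#' Read a delimited table of categorical observations
#'
#' Thin reader over [readr::read_delim()] producing a [as_categorical_dataset()]
#' object. All columns are read as character; ragged rows raise a format
#' error and blank cells a missing-data error.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; by default `"\t"` for `.tsv` files and `","`
#'   otherwise.
#' @param col_names Whether the first row holds variable names.
#' @return A `categorical_dataset`.
#' @export
read_categorical <- function(path, delim = NULL, col_names = TRUE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  delim <- delim %||% if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  # readr warns on parsing problems; they are escalated to errors below
  tb <- suppressWarnings(readr::read_delim(
    path,
    delim = delim, col_names = col_names,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  pb <- readr::problems(tb)
  if (nrow(pb) > 0L) {
    abort(sprintf("malformed table (%d parsing problem(s), first at row %d): ragged or corrupt rows.",
                  nrow(pb), pb$row[1]))
  }
  if (nrow(tb) < 1L) abort("table has no data rows; N >= 1 samples required.")
  as_categorical_dataset(as.data.frame(tb))
}

#' @export
print.categorical_dataset <- function(x, ...) {
  cat(sprintf(
    "<categorical_dataset> %d samples x %d variables\n", x$n,
    length(x$variable_names)
  ))
  cat("  levels:", paste0(x$variable_names, "(", x$levels, ")", collapse = " "), "\n")
  invisible(x)
}

# resolve variable names or indices to integer column indices
var_index <- function(ds, vars) {
  if (length(vars) == 0L) return(integer(0))
  if (is.character(vars)) {
    idx <- match(vars, ds$variable_names)
    if (anyNA(idx)) abort(sprintf("unknown variable(s): %s", paste(vars[is.na(idx)], collapse = ", ")))
  } else {
    idx <- as.integer(vars)
    if (any(idx < 1L | idx > length(ds$variable_names))) abort("variable index out of range.")
  }
  if (anyDuplicated(idx)) abort("variable indices must be distinct.")
  idx
}

# mixed-radix joint state per sample (double to avoid integer overflow);
# empty subset = the single empty state
joint_code <- function(ds, vars) {
  if (length(vars) == 0L) return(rep.int(1, ds$n))
  m <- ds$codes[, vars, drop = FALSE]
  r <- ds$levels[vars]
  mult <- cumprod(c(1, r[-length(r)]))
  as.vector((m - 1) %*% mult) + 1
}

# counts over observed joint states only (order: first appearance)
joint_counts <- function(ds, vars) {
  code <- joint_code(ds, vars)
  u <- unique(code)
  tabulate(match(code, u), nbins = length(u))
}

#' Joint contingency counts over a variable subset
#'
#' Counts the observed joint states of an ordered subset of variables.
#' Unobserved state combinations are implicitly zero (the table is sparse
#' over observed states), and counts always sum to `N`. An empty subset
#' yields the single empty state with count `N`.
#'
#' @param data A `categorical_dataset` (or coercible data frame).
#' @param variables Variable names or indices (possibly empty).
#' @return A tibble with one column per requested variable (original labels)
#'   plus a count column `n`; total count available as `attr(, "total")`.
#' @examples
#' d <- as_categorical_dataset(data.frame(a = rep(0:1, each = 5), b = rep(0:1, each = 5)))
#' count_joint(d, c("a", "b"))
#' @export
count_joint <- function(data, variables) {
  ds <- as_categorical_dataset(data)
  vars <- var_index(ds, variables)
  if (length(vars) == 0L) {
    out <- tibble::tibble(n = ds$n)
  } else {
    code <- joint_code(ds, vars)
    u <- unique(code)
    cnt <- tabulate(match(code, u), nbins = length(u))
    first_row <- match(u, code)
    cols <- lapply(vars, function(v) ds$labels[[v]][ds$codes[first_row, v]])
    names(cols) <- ds$variable_names[vars]
    out <- tibble::as_tibble(cols)
    out$n <- cnt
    out <- dplyr::arrange(out, dplyr::across(dplyr::all_of(ds$variable_names[vars])))
  }
  attr(out, "total") <- ds$n
  attr(out, "variables") <- ds$variable_names[vars]
  out
}
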