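# Plug-in (maximum-likelihood) information estimators on sparse joint-count
# tables. All quantities are in nats. An optional per-fit cache environment
# memoizes entropies by variable subset so the iterative skeleton search
# never recomputes a table.

entropy_from_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) abort("empty table: entropy undefined.")
  log(n) - sum(counts * log(counts)) / n
}

# memoized entropy over a variable subset (unordered)
ds_entropy <- function(ds, vars, cache = NULL) {
  if (length(vars) == 0L) return(0)
  vars <- sort(vars)
  if (!is.null(cache)) {
    key <- paste(vars, collapse = ",")
    h <- cache[[key]]
    if (!is.null(h)) return(h)
  }
  h <- entropy_from_counts(joint_counts(ds, vars))
  if (!is.null(cache)) cache[[key]] <- h
  h
}

#' Plug-in Shannon entropy of a contingency table
#'
#' Maximum-likelihood ("plug-in") estimate `H = -sum (n_s/N) log(n_s/N)` in
#' nats, with the convention `0 log 0 = 0`. Zero cells contribute nothing, so
#' only observed states need to be supplied.
#'
#' @param counts A numeric vector of nonnegative counts, or a tibble from
#'   [count_joint()] (its `n` column is used).
#' @return Entropy in nats, in `[0, log(#observed states)]`.
#' @examples
#' shannon_entropy(c(5, 5)) # log 2
#' @export
shannon_entropy <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$n
  if (!is.numeric(counts) || length(counts) == 0L) abort("`counts` must be a nonempty numeric vector.")
  if (any(counts < 0)) abort("counts must be nonnegative.")
  entropy_from_counts(counts)
}

check_distinct_roles <- function(...) {
  idx <- c(...)
  if (anyDuplicated(idx)) abort("variables x, y, z and the conditioning set must be distinct.")
}

# I(x;y|u) = H(x,u) + H(y,u) - H(x,y,u) - H(u); tiny negative values from
# floating-point cancellation are clamped to zero
cmi_idx <- function(ds, x, y, u = integer(0), cache = NULL) {
  v <- ds_entropy(ds, c(x, u), cache) + ds_entropy(ds, c(y, u), cache) -
    ds_entropy(ds, c(x, y, u), cache) - ds_entropy(ds, u, cache)
  if (v < 0) v <- 0
  v
}

i3_idx <- function(ds, x, y, z, u = integer(0), cache = NULL) {
  cmi_idx(ds, x, y, u, cache) - cmi_idx(ds, x, y, c(u, z), cache)
}

#' (Conditional) mutual information
#'
#' Plug-in conditional mutual information `I(x;y|{u_i})` in nats, computed
#' from the four-entropy combination
#' `H(x,{u}) + H(y,{u}) - H(x,y,{u}) - H({u})`. With an empty conditioning
#' set this reduces to the mutual information `I(x;y)`. The estimate is
#' nonnegative; negligible negative values due to floating-point
#' cancellation are clamped to 0.
#'
#' @param data A `categorical_dataset` or data frame.
#' @param x,y Variable names or indices.
#' @param cond Conditioning variables (names or indices; default none).
#' @return Mutual information in nats.
#' @examples
#' d <- data.frame(a = rep(0:1, 8), b = rep(0:1, 8))
#' mutual_information(d, "a", "b") # log 2
#' @export
mutual_information <- function(data, x, y, cond = character(0)) {
  ds <- as_categorical_dataset(data)
  xi <- var_index(ds, x); yi <- var_index(ds, y); ui <- var_index(ds, cond)
  check_distinct_roles(xi, yi, ui)
  cmi_idx(ds, xi, yi, ui)
}

#' (Conditional) 3-point information
#'
#' `I(x;y;z|{u_i}) = I(x;y|{u_i}) - I(x;y|z,{u_i})`, the difference between a
#' conditional mutual information and the same quantity further conditioned
#' on `z`. Unlike 2-point mutual information it can take either sign: a
#' significantly negative value indicates that a v-structure (collider on
#' `z`) is more likely than the Markov-equivalent chain/fork alternatives,
#' a significantly positive value the converse. The quantity is invariant
#' under all six permutations of `x`, `y`, `z`.
#'
#' @inheritParams mutual_information
#' @param z Third variable (name or index).
#' @return 3-point information in nats (sign unconstrained).
#' @export
three_point_information <- function(data, x, y, z, cond = character(0)) {
  ds <- as_categorical_dataset(data)
  xi <- var_index(ds, x); yi <- var_index(ds, y); zi <- var_index(ds, z)
  ui <- var_index(ds, cond)
  check_distinct_roles(xi, yi, zi, ui)
  i3_idx(ds, xi, yi, zi, ui)
}

#' Decompose a mutual information into successive 3-point contributions
#'
#' Expands `I(x;y)` along an ordered list of contributors `u_1, ..., u_n`:
#' `I(x;y) = I(x;y;u_1) + I(x;y;u_2|u_1) + ... + I(x;y;u_n|{u_i}_{n-1})
#'  + I(x;y|{u_i}_n)`.
#' The terms telescope, so they sum to `I(x;y)` exactly (up to floating
#' point), and the final residual `I(x;y|{u_i}_n)` does not depend on the
#' insertion order of a fixed contributor set.
#'
#' @inheritParams mutual_information
#' @param contributors Ordered contributor variables (names or indices).
#' @return A tibble with one row per term: `term` (label), `type`
#'   (`"three_point"` or `"residual"`), `value` (nats).
#' @export
info_decompose <- function(data, x, y, contributors = character(0)) {
  ds <- as_categorical_dataset(data)
  xi <- var_index(ds, x); yi <- var_index(ds, y)
  ui <- var_index(ds, contributors)
  check_distinct_roles(xi, yi, ui)
  cache <- new.env(parent = emptyenv())
  nm <- ds$variable_names
  k <- length(ui)
  # successive conditional MIs; each 3-point term is a difference of
  # neighbours, so the telescoping sum is exact
  cmis <- vapply(0:k, function(i) cmi_idx(ds, xi, yi, ui[seq_len(i)], cache), numeric(1))
  terms <- character(0); values <- numeric(0); types <- character(0)
  if (k > 0) {
    for (i in seq_len(k)) {
      given <- if (i > 1) paste0("|", paste(nm[ui[seq_len(i - 1)]], collapse = ",")) else ""
      terms <- c(terms, sprintf("I(%s;%s;%s%s)", nm[xi], nm[yi], nm[ui[i]], given))
      values <- c(values, cmis[i] - cmis[i + 1])
      types <- c(types, "three_point")
    }
  }
  terms <- c(terms, sprintf(
    "I(%s;%s%s)", nm[xi], nm[yi],
    if (k > 0) paste0("|", paste(nm[ui], collapse = ",")) else ""
  ))
  values <- c(values, cmis[k + 1])
  types <- c(types, "residual")
  tibble::tibble(term = terms, type = types, value = values)
}
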