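# NML and MDL/BIC complexity terms. The universal multinomial normalization
# constant C^r_n is computed in log-space: the exact binomial sum for r = 2
# (log-sum-exp; overflow-safe for n in the thousands), the Szpankowski
# expansion above a configurable switch-over, and the linear-time recursion
# C^r_n = C^{r-1}_n + n/(r-2) C^{r-2}_n for r >= 3. Values are memoized
# package-wide: counts recur constantly across NML evaluations.

.lmc_cache <- new.env(parent = emptyenv())

log_c2_exact <- function(n) {
  h <- 0:n
  lt <- lchoose(n, h)
  pos <- h > 0L
  lt[pos] <- lt[pos] + h[pos] * log(h[pos] / n)
  pos <- h < n
  lt[pos] <- lt[pos] + (n - h[pos]) * log((n - h[pos]) / n)
  logsumexp(lt)
}

log_c2_szpankowski <- function(n) {
  0.5 * log(n * pi / 2) + sqrt(8 / (9 * n * pi)) + (3 * pi - 16) / (36 * n * pi)
}

log_multinomial_one <- function(n, r, exact_limit) {
  if (n == 0L || r == 1L) return(0)
  key <- paste0(r, ":", n, ":", exact_limit)
  v <- .lmc_cache[[key]]
  if (!is.null(v)) return(v)
  if (r == 2L) {
    v <- if (n <= exact_limit) log_c2_exact(n) else log_c2_szpankowski(n)
  } else {
    # recursion upward in r (denominator r-2 >= 1, so r = 2 is never recursed)
    v2 <- log_multinomial_one(n, 2L, exact_limit)
    prev2 <- 0          # log C^1_n
    prev1 <- v2         # log C^2_n
    for (rr in 3:r) {
      cur <- logaddexp(prev1, log(n) - log(rr - 2) + prev2)
      kk <- paste0(rr, ":", n, ":", exact_limit)
      if (is.null(.lmc_cache[[kk]])) .lmc_cache[[kk]] <- cur
      prev2 <- prev1
      prev1 <- cur
    }
    v <- prev1
  }
  .lmc_cache[[key]] <- v
  v
}

#' Log of the universal multinomial normalization constant
#'
#' Computes `log C^r_n`, the normalization constant of the normalized
#' maximum likelihood (NML) code for a multinomial variable with `r`
#' categories observed `n` times: the sum over all partitions
#' `l_1 + ... + l_r = n` of the multinomial coefficient times
#' `prod (l_k/n)^{l_k}`. Base cases are `C^r_0 = 1` and `C^1_n = 1`. For
#' `r = 2` the exact binomial sum is evaluated in log-space up to
#' `exact_limit`, above which the Szpankowski asymptotic expansion (relative
#' error well below 0.1% beyond n = 1000) is used; higher `r` follow the
#' linear-time recursion `C^r_n = C^{r-1}_n + n/(r-2) C^{r-2}_n`.
#'
#' @param n Sample count(s); nonnegative integer (vectorized).
#' @param r Number of categories; positive integer scalar.
#' @param exact_limit Largest `n` for which the exact `r = 2` sum is used
#'   (default 1000).
#' @return `log C^r_n` (vector along `n`), in nats.
#' @examples
#' log_multinomial_constant(0, 5) # 0
#' exp(log_multinomial_constant(2, 3)) # 4.5
#' @export
log_multinomial_constant <- function(n, r, exact_limit = 1000L) {
  if (any(n < 0) || any(n != floor(n))) abort("`n` must be nonnegative integer(s).")
  if (length(r) != 1L || r < 1 || r != floor(r)) abort("`r` must be a positive integer scalar.")
  vapply(as.integer(n), log_multinomial_one, numeric(1), r = as.integer(r),
         exact_limit = as.integer(exact_limit))
}

#' MDL/BIC pairwise complexity
#'
#' The MDL (equivalently BIC) complexity of an edge between `x` and `y`
#' conditioned on `{u_i}`:
#' `k = (1/2) (r_x - 1)(r_y - 1) prod_i r_{u_i} log N` (natural log).
#' This is the large-`N` Laplace limit of the NML complexity.
#'
#' @param r_x,r_y Level counts of the endpoint variables.
#' @param r_u Integer vector of level counts of the conditioning variables
#'   (default none).
#' @param n Sample count (`N >= 2`).
#' @return Complexity in nats (`>= 0`; 0 when either endpoint is constant).
#' @examples
#' mdl_pair_complexity(2, 2, n = 100) # log(100)/2
#' @export
mdl_pair_complexity <- function(r_x, r_y, r_u = integer(0), n) {
  if (n < 2) abort("MDL complexity requires N >= 2.")
  0.5 * (r_x - 1) * (r_y - 1) * prod(r_u) * log(n)
}

# NML pairwise complexity on integer-indexed variables, memoizable per fit
nml_pair_idx <- function(ds, x, y, u = integer(0), cache = NULL,
                         exact_limit = 1000L) {
  if (!is.null(cache)) {
    key <- paste0("k:", paste(sort(c(x, y)), collapse = ","), "|",
                  paste(sort(u), collapse = ","))
    v <- cache[[key]]
    if (!is.null(v)) return(v)
  }
  rx <- ds$levels[x]
  ry <- ds$levels[y]
  g <- joint_code(ds, u)
  gu <- unique(g)
  gi <- match(g, gu)
  ng <- length(gu)
  nj <- tabulate(gi, nbins = ng)
  # cross counts N_{k_x j'} and N_{k_y j'}; unobserved cells contribute
  # log C^r_0 = 0 and are dropped
  nxj <- tabulate((gi - 1L) * rx + ds$codes[, x], nbins = ng * rx)
  nyj <- tabulate((gi - 1L) * ry + ds$codes[, y], nbins = ng * ry)
  nxj <- nxj[nxj > 0L]
  nyj <- nyj[nyj > 0L]
  v <- 0.5 * (
    sum(log_multinomial_constant(nxj, ry, exact_limit)) -
      sum(log_multinomial_constant(nj, ry, exact_limit)) +
      sum(log_multinomial_constant(nyj, rx, exact_limit)) -
      sum(log_multinomial_constant(nj, rx, exact_limit))
  )
  if (!is.null(cache)) cache[[key]] <- v
  v
}

#' NML pairwise complexity
#'
#' The factorized, xy-symmetrized normalized-maximum-likelihood complexity
#' of an edge between `x` and `y` conditioned on `{u_i}`:
#' half the sum, over observed joint states `j'` of `{u_i}`, of
#' `sum_{k_x} log C^{r_y}_{N_{k_x j'}} - log C^{r_y}_{N_{j'}} +
#'  sum_{k_y} log C^{r_x}_{N_{k_y j'}} - log C^{r_x}_{N_{j'}}`.
#' Unobserved parent states contribute `log C^r_0 = 0`, so the sparse
#' iteration over observed states is exact. The value is symmetric under
#' swapping `x` and `y` by construction.
#'
#' @inheritParams mutual_information
#' @param u Conditioning variables (names or indices; default none).
#' @param exact_limit Passed to [log_multinomial_constant()].
#' @return Complexity in nats.
#' @export
nml_pair_complexity <- function(data, x, y, u = character(0), exact_limit = 1000L) {
  ds <- as_categorical_dataset(data)
  xi <- var_index(ds, x); yi <- var_index(ds, y); ui <- var_index(ds, u)
  check_distinct_roles(xi, yi, ui)
  nml_pair_idx(ds, xi, yi, ui, exact_limit = exact_limit)
}

pair_complexity_idx <- function(ds, x, y, u = integer(0),
                                score = c("nml", "mdl"), cache = NULL) {
  score <- match.arg(score)
  if (score == "mdl") {
    mdl_pair_complexity(ds$levels[x], ds$levels[y], ds$levels[u], ds$n)
  } else {
    nml_pair_idx(ds, x, y, u, cache = cache)
  }
}

three_point_complexity_idx <- function(ds, x, y, z, u = integer(0),
                                       score = c("nml", "mdl"), cache = NULL) {
  pair_complexity_idx(ds, x, y, c(u, z), score, cache) -
    pair_complexity_idx(ds, x, y, u, score, cache)
}

#' 3-point complexity term
#'
#' `k_{x;y;z|{u_i}} = k_{x;y|{u_i},z} - k_{x;y|{u_i}}`, the increment of the
#' pairwise complexity when `z` joins the conditioning set; same score kind
#' on both sides. Positive whenever all implicated variables have at least
#' two levels.
#'
#' @inheritParams mutual_information
#' @param z Third variable.
#' @param u Conditioning variables (default none).
#' @param score `"nml"` (default) or `"mdl"`.
#' @return Complexity increment in nats.
#' @export
three_point_complexity <- function(data, x, y, z, u = character(0),
                                   score = c("nml", "mdl")) {
  ds <- as_categorical_dataset(data)
  xi <- var_index(ds, x); yi <- var_index(ds, y); zi <- var_index(ds, z)
  ui <- var_index(ds, u)
  check_distinct_roles(xi, yi, zi, ui)
  three_point_complexity_idx(ds, xi, yi, zi, ui, match.arg(score))
}
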