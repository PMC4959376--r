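test_that("multinomial constant: base cases and small closed forms", {
  expect_equal(log_multinomial_constant(0, 5), 0)  # C^r_0 = 1
  expect_equal(log_multinomial_constant(7, 1), 0)  # C^1_n = 1
  expect_equal(log_multinomial_constant(1, 2), log(2), tolerance = 1e-12)
  # C^3_2 = C^2_2 + 2 C^1_2 = 2.5 + 2 = 4.5
  expect_equal(exp(log_multinomial_constant(2, 3)), 4.5, tolerance = 1e-9)
  expect_error(log_multinomial_constant(-1, 2), "nonnegative")
})

test_that("multinomial constant matches the brute-force partition sum", {
  for (r in 1:5) for (n in 0:12) {
    expect_equal(
      log_multinomial_constant(n, r),
      log(oracle_multinomial_constant(n, r)),
      tolerance = 1e-9,
      label = sprintf("log C^%d_%d", r, n)
    )
  }
})

test_that("the r-recursion is consistent up to n = 1000", {
  ns <- c(1:20, 50, 100, 250, 500, 1000)
  for (r in 3:6) {
    lhs <- log_multinomial_constant(ns, r)
    rhs <- mapply(function(n) {
      logaddexp_ <- function(a, b) { m <- max(a, b); m + log1p(exp(min(a, b) - m)) }
      logaddexp_(log_multinomial_constant(n, r - 1),
                 log(n) - log(r - 2) + log_multinomial_constant(n, r - 2))
    }, ns)
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("Szpankowski approximation is within 0.1% of the exact binary constant", {
  exact_log_c2 <- function(n) {
    h <- 0:n
    lt <- lchoose(n, h) +
      ifelse(h == 0, 0, h * log(h / n)) +
      ifelse(h == n, 0, (n - h) * log((n - h) / n))
    m <- max(lt)
    m + log(sum(exp(lt - m)))
  }
  for (n in c(1000, 1500, 2000, 3000, 5000)) {
    exact <- exp(exact_log_c2(n))
    approx <- exp(log_multinomial_constant(n, 2))  # approximation regime n > 1000
    if (n == 1000) approx <- exp(log_multinomial_constant(n, 2, exact_limit = 999L))
    expect_lt(abs(exact - approx) / exact, 1e-3)
  }
})

test_that("cached values are monotone in n and r", {
  ns <- c(0, 1, 2, 5, 10, 50, 200, 1000, 2000)
  for (r in 2:5) {
    v <- log_multinomial_constant(ns, r)
    expect_true(all(diff(v) >= 0))
  }
  for (n in c(1, 10, 100)) {
    v <- vapply(1:6, function(r) log_multinomial_constant(n, r), numeric(1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("MDL pairwise complexity follows the closed form", {
  expect_equal(mdl_pair_complexity(2, 2, n = 100), 0.5 * log(100), tolerance = 1e-12)
  expect_equal(mdl_pair_complexity(2, 2, r_u = 3, n = 100), 1.5 * log(100), tolerance = 1e-12)
  expect_equal(mdl_pair_complexity(1, 4, n = 50), 0) # constant endpoint
  expect_error(mdl_pair_complexity(2, 2, n = 1), "N >= 2")
})

test_that("NML pairwise complexity: hand-computed value, symmetry, asymptotics", {
  # 10-sample binary table: x = (0x6, 1x4), y = (0x5, 1x5), no conditioning.
  # Eq: k = 1/2 (sum_kx log C^2_{N_kx} - log C^2_N + sum_ky log C^2_{N_ky} - log C^2_N)
  df <- data.frame(
    x = c(rep("0", 6), rep("1", 4)),
    y = c(rep("0", 5), rep("1", 5))
  )
  lc <- function(n) log(oracle_multinomial_constant(n, 2))
  by_hand <- 0.5 * ((lc(6) + lc(4) - lc(10)) + (lc(5) + lc(5) - lc(10)))
  expect_equal(nml_pair_complexity(df, "x", "y"), by_hand, tolerance = 1e-9)
  # xy-symmetry on random data with a conditioning set
  withr::local_seed(5)
  rdf <- random_cat_df(50, 4)
  expect_equal(
    nml_pair_complexity(rdf, "v1", "v2", u = c("v3", "v4")),
    nml_pair_complexity(rdf, "v2", "v1", u = c("v4", "v3")),
    tolerance = 1e-12
  )
  # duplicating the dataset: complexity grows sublinearly; NML/MDL -> O(1)
  base <- data.frame(x = rep(c("0", "1"), 5), y = c(rep("0", 4), rep("1", 6)))
  big <- base[rep(seq_len(10), 100), ]
  k_small <- nml_pair_complexity(base, "x", "y")
  k_big <- nml_pair_complexity(big, "x", "y")
  expect_lt(k_big / k_small, 10) # far below the 100x data growth
  ratio <- k_big / mdl_pair_complexity(2, 2, n = 1000)
  expect_lt(abs(ratio - 1), 0.5) # approaching the Laplace (MDL) limit
})

test_that("3-point complexity is a same-score difference and positive for r >= 2", {
  # MDL closed form: k_{x;y|z} - k_{x;y} = 1/2 (2 - 1) log N = 1/2 log 100
  df <- random_cat_df(100, 3, levels = 2)
  expect_equal(
    three_point_complexity(df, "v1", "v2", "v3", score = "mdl"),
    0.5 * log(100),
    tolerance = 1e-12
  )
  withr::local_seed(21)
  for (rep in 1:10) {
    rdf <- random_cat_df(50, 3, levels = 2)
    expect_gt(three_point_complexity(rdf, "v1", "v2", "v3", score = "nml"), 0)
    expect_gt(three_point_complexity(rdf, "v1", "v2", "v3", score = "mdl"), 0)
  }
  # conditioning on a constant adds nothing under MDL
  cdf <- data.frame(a = rep(c("0", "1"), 10), b = rep(c("0", "1"), each = 10),
                    k = rep("c", 20))
  expect_warning(ds <- as_categorical_dataset(cdf), "constant")
  expect_equal(three_point_complexity(ds, "a", "b", "k", score = "mdl"), 0)
})
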