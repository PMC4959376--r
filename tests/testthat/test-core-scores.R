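test_that("shifted information subtracts (adds) the complexity over N", {
  withr::local_seed(4)
  df <- random_cat_df(200, 3, levels = 2)
  for (score in c("nml", "mdl")) {
    si <- shifted_information(df, "v1", "v2", z = "v3", score = score)
    expect_equal(si$I2_shifted, si$I2 - si$k2 / 200, tolerance = 1e-12)
    expect_equal(si$I3_shifted, si$I3 + si$k3 / 200, tolerance = 1e-12)
  }
  # independent pair: complexity dominates, shifted information negative
  ind <- expand.grid(a = c("0", "1"), b = c("0", "1"), stringsAsFactors = FALSE)
  ind <- ind[rep(1:4, each = 25), ]
  expect_lt(shifted_information(ind, "a", "b")$I2_shifted, 0)
  # identical pair at N = 1000 under MDL: I' = log 2 - log(1000)/2000 > 0
  idn <- data.frame(a = rep(c("0", "1"), 500), b = rep(c("0", "1"), 500))
  expect_equal(shifted_information(idn, "a", "b", score = "mdl")$I2_shifted,
               log(2) - log(1000) / 2000, tolerance = 1e-12)
})

test_that("non-v probability is the logistic of N times the shifted 3-point term", {
  expect_equal(threeoff2:::prob_non_v_value(100, 0), 0.5)
  expect_equal(threeoff2:::prob_non_v_value(1, log(3)), 0.75, tolerance = 1e-12)
  expect_equal(threeoff2:::prob_non_v_value(1e6, -1), 0, tolerance = 1e-12)
  expect_equal(threeoff2:::prob_non_v_value(1e6, 1), 1, tolerance = 1e-12)
  # strict monotonicity in the information term
  v <- vapply(seq(-0.02, 0.02, by = 0.005),
              function(i) threeoff2:::prob_non_v_value(500, i), numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("base probabilities normalize to one and favor the weakest pair", {
  withr::local_seed(8)
  for (rep in 1:25) {
    df <- random_cat_df(60, 3)
    v <- names(df)
    p1 <- prob_base(df, v[1], v[2], v[3])
    p2 <- prob_base(df, v[1], v[3], v[2])
    p3 <- prob_base(df, v[2], v[3], v[1])
    expect_equal(p1 + p2 + p3, 1, tolerance = 1e-12)
  }
  # symmetric triple: all three bases equally likely
  expect_equal(threeoff2:::prob_base_value(100, 0.1, 0.1, 0.1), 1 / 3, tolerance = 1e-12)
  # xy much weaker than the other pairs: base probability -> 1
  expect_gt(threeoff2:::prob_base_value(1000, 0.001, 0.5, 0.5), 0.999)
  # extreme magnitudes must not overflow
  expect_equal(threeoff2:::prob_base_value(1e6, 0, 5, 5), 1, tolerance = 1e-12)
  expect_equal(threeoff2:::prob_base_value(1e6, 5, 0, 0), 0, tolerance = 1e-12)
})

test_that("raw-mode probabilities reproduce the likelihood-ratio identity", {
  # with u = {} and raw information, P_nv = L_nv / (L_nv + L_v),
  # the likelihood ratio being exp(-N * I(x;y;z))
  withr::local_seed(12)
  df <- random_cat_df(40, 3)
  v <- names(df)
  i3 <- three_point_information(df, v[1], v[2], v[3])
  expected <- 1 / (1 + exp(-40 * i3))
  expect_equal(prob_non_v(df, v[1], v[2], v[3], score = "mdl", rank = "raw"),
               expected, tolerance = 1e-12)
})

test_that("contribution score is the minimum of the two probabilities", {
  withr::local_seed(31)
  for (rep in 1:10) {
    df <- random_cat_df(80, 4)
    v <- sample(names(df))
    cs <- contribution_score(df, v[1], v[2], v[3], u = v[4])
    expect_equal(cs$s_lb, min(cs$p_nv, cs$p_base))
    expect_true(cs$p_nv >= 0 && cs$p_nv <= 1)
    expect_true(cs$p_base >= 0 && cs$p_base <= 1)
  }
})

test_that("v-structure data yields a sub-half contribution score for the collider", {
  net <- bn_fixture("v_structure")
  df <- sample_bn(net, 5000, seed = 2)
  cs <- contribution_score(df, "x", "y", "z")
  expect_lt(cs$p_nv, 0.5) # collider: z is not a non-v contributor
  expect_lt(cs$s_lb, 0.5)
  expect_false(cs$eligible)
})

test_that("best contributor picks the chain middle node and ignores noise", {
  net <- bn_fixture("chain")
  df <- sample_bn(net, 5000, seed = 2)
  b <- best_contributor(df, "x", "y", candidates = "z")
  expect_equal(b$z, "z")
  expect_gt(b$rank, 0.5)
  # add an independent noise node: the middle node still wins
  withr::local_seed(17)
  df$noise <- as.character(sample(0:1, nrow(df), replace = TRUE))
  b2 <- best_contributor(df, "x", "y", candidates = c("noise", "z"))
  expect_equal(b2$z, "z")
  # empty candidate set: no contributor
  b3 <- best_contributor(df, "x", "y", candidates = character(0))
  expect_true(is.na(b3$z))
  expect_equal(b3$rank, 0)
  expect_error(best_contributor(df, "x", "y", candidates = "x"), "exclude")
})
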