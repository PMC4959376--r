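# 3off2 core scores: complexity-shifted information, v/non-v probabilities,
# the lower-bound contribution score and the edge rank. All exponentials of
# +/- N * I are taken in the log domain (plogis / log-sum-exp), so extreme
# magnitudes are handled stably.

resolve_rank_mode <- function(rank, score) {
  rank <- match.arg(rank, c("auto", "shifted", "raw"))
  # recommended pairings: NML works best with shifted terms, MDL with raw
  if (rank == "auto") if (score == "nml") "shifted" else "raw" else rank
}

# raw and shifted 2-point information for an edge given a conditioning set
edge_information_idx <- function(ds, x, y, u = integer(0), score = "nml",
                                 cache = NULL) {
  i2 <- cmi_idx(ds, x, y, u, cache)
  k2 <- pair_complexity_idx(ds, x, y, u, score, cache)
  list(I2 = i2, k2 = k2, I2_shifted = i2 - k2 / ds$n)
}

# full raw + shifted triple information for (x,y,z | u)
triple_information_idx <- function(ds, x, y, z, u = integer(0), score = "nml",
                                   cache = NULL) {
  i2 <- cmi_idx(ds, x, y, u, cache)
  i2z <- cmi_idx(ds, x, y, c(u, z), cache)
  k2 <- pair_complexity_idx(ds, x, y, u, score, cache)
  k2z <- pair_complexity_idx(ds, x, y, c(u, z), score, cache)
  i3 <- i2 - i2z
  k3 <- k2z - k2
  list(
    I2 = i2, I2_shifted = i2 - k2 / ds$n,
    I3 = i3, I3_shifted = i3 + k3 / ds$n,
    k2 = k2, k3 = k3
  )
}

#' Complexity-shifted 2- and 3-point information
#'
#' Shifted information trades raw dependence against model complexity:
#' `I'(x;y|{u}) = I(x;y|{u}) - k_{x;y|{u}}/N` and
#' `I'(x;y;z|{u}) = I(x;y;z|{u}) + k_{x;y;z|{u}}/N`.
#' A negative shifted 2-point information means the conditional independence
#' model is more likely than keeping the edge; a negative shifted 3-point
#' information means a v-structure on `z` is more likely than the
#' chain/fork alternatives.
#'
#' @inheritParams mutual_information
#' @param z Optional third variable; when `NULL` only the 2-point terms are
#'   returned.
#' @param u Conditioning variables (default none).
#' @param score `"nml"` (default) or `"mdl"` complexity.
#' @return A one-row tibble with raw and shifted information (and the
#'   complexity terms used), in nats.
#' @export
shifted_information <- function(data, x, y, z = NULL, u = character(0),
                                score = c("nml", "mdl")) {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  xi <- var_index(ds, x); yi <- var_index(ds, y); ui <- var_index(ds, u)
  if (is.null(z)) {
    check_distinct_roles(xi, yi, ui)
    e <- edge_information_idx(ds, xi, yi, ui, score)
    tibble::tibble(I2 = e$I2, I2_shifted = e$I2_shifted, k2 = e$k2)
  } else {
    zi <- var_index(ds, z)
    check_distinct_roles(xi, yi, zi, ui)
    t <- triple_information_idx(ds, xi, yi, zi, ui, score)
    tibble::tibble(
      I2 = t$I2, I2_shifted = t$I2_shifted,
      I3 = t$I3, I3_shifted = t$I3_shifted,
      k2 = t$k2, k3 = t$k3
    )
  }
}

# P_nv = 1 / (1 + exp(-N * I3term)): logistic in N * I3
prob_non_v_value <- function(n, i3term) {
  plogis(n * i3term)
}

# P_b(xy) = softmax of -N * I2term over the three bases; returns the xy one
prob_base_value <- function(n, i_xy, i_xz, i_yz) {
  a <- -n * c(i_xy, i_xz, i_yz)
  exp(a[1] - logsumexp(a))
}

#' Probability that a triple is a (generalized) non-v-structure
#'
#' `P_nv = 1 / (1 + exp(-N I'(x;y;z|{u_i})))`: above 1/2 exactly when the
#' (shifted) conditional 3-point information is positive, i.e. when the
#' chain/fork alternatives are more likely than the collider on `z`.
#'
#' @inheritParams three_point_information
#' @param u Conditioning variables (default none).
#' @param score `"nml"` or `"mdl"`.
#' @param rank `"shifted"` (use complexity-shifted information; default for
#'   NML via `"auto"`), `"raw"` (default for MDL), or `"auto"`.
#' @return Probability in (0, 1).
#' @export
prob_non_v <- function(data, x, y, z, u = character(0),
                       score = c("nml", "mdl"), rank = "auto") {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  mode <- resolve_rank_mode(rank, score)
  xi <- var_index(ds, x); yi <- var_index(ds, y); zi <- var_index(ds, z)
  ui <- var_index(ds, u)
  check_distinct_roles(xi, yi, zi, ui)
  t <- triple_information_idx(ds, xi, yi, zi, ui, score)
  prob_non_v_value(ds$n, if (mode == "shifted") t$I3_shifted else t$I3)
}

#' Probability that `xy` is the base of a triple
#'
#' Among the three possible bases `xy`, `xz`, `yz` of the triple, the base
#' probability is the softmax of `-N I'(pair|{u_i})`: the pair with the
#' lowest (shifted) conditional mutual information is the most likely base,
#' consistent with the Data Processing Inequality. The three base
#' probabilities sum to 1.
#'
#' @inheritParams prob_non_v
#' @return Probability in (0, 1).
#' @export
prob_base <- function(data, x, y, z, u = character(0),
                      score = c("nml", "mdl"), rank = "auto") {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  mode <- resolve_rank_mode(rank, score)
  xi <- var_index(ds, x); yi <- var_index(ds, y); zi <- var_index(ds, z)
  ui <- var_index(ds, u)
  check_distinct_roles(xi, yi, zi, ui)
  use <- function(x1, y1) {
    e <- edge_information_idx(ds, x1, y1, ui, score)
    if (mode == "shifted") e$I2_shifted else e$I2
  }
  prob_base_value(ds$n, use(xi, yi), use(xi, zi), use(yi, zi))
}

# internal: full triple score for candidate z on edge (x,y | u)
triple_score_idx <- function(ds, x, y, z, u = integer(0), score = "nml",
                             mode = "shifted", cache = NULL) {
  t <- triple_information_idx(ds, x, y, z, u, score, cache)
  pick <- function(raw, shifted) if (mode == "shifted") shifted else raw
  exz <- edge_information_idx(ds, x, z, u, score, cache)
  eyz <- edge_information_idx(ds, y, z, u, score, cache)
  p_nv <- prob_non_v_value(ds$n, pick(t$I3, t$I3_shifted))
  p_b <- prob_base_value(
    ds$n,
    pick(t$I2, t$I2_shifted),
    pick(exz$I2, exz$I2_shifted),
    pick(eyz$I2, eyz$I2_shifted)
  )
  list(
    I2 = t$I2, I2_shifted = t$I2_shifted,
    I3 = t$I3, I3_shifted = t$I3_shifted,
    p_nv = p_nv, p_base = p_b, s_lb = min(p_nv, p_b),
    eligible = pick(t$I3, t$I3_shifted) > 0
  )
}

#' Lower-bound contribution score of a candidate node
#'
#' The probability that `z` genuinely contributes (indirectly) to the
#' dependence between `x` and `y` given `{u_i}` is bounded below by
#' `S_lb = min(P_nv, P_b)`: both the non-v-structure condition and the base
#' condition must hold for `z` to be an indirect contributor.
#'
#' @inheritParams prob_non_v
#' @return A one-row tibble with the raw and shifted 2-/3-point information,
#'   `p_nv`, `p_base`, `s_lb` and the eligibility flag (positive 3-point
#'   contribution in the active mode).
#' @export
contribution_score <- function(data, x, y, z, u = character(0),
                               score = c("nml", "mdl"), rank = "auto") {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  mode <- resolve_rank_mode(rank, score)
  xi <- var_index(ds, x); yi <- var_index(ds, y); zi <- var_index(ds, z)
  ui <- var_index(ds, u)
  check_distinct_roles(xi, yi, zi, ui)
  s <- triple_score_idx(ds, xi, yi, zi, ui, score, mode)
  tibble::tibble(
    x = ds$variable_names[xi], y = ds$variable_names[yi],
    z = ds$variable_names[zi],
    cond = paste(ds$variable_names[ui], collapse = ","),
    I2 = s$I2, I2_shifted = s$I2_shifted,
    I3 = s$I3, I3_shifted = s$I3_shifted,
    p_nv = s$p_nv, p_base = s$p_base, s_lb = s$s_lb,
    eligible = s$eligible
  )
}

# best eligible contributor among candidates. Primary key: the lower-bound
# score S_lb. At large N the probabilities of all plausible contributors
# saturate at 1, so exact ties are the rule, not the exception; they are
# resolved by the magnitude of the positive 3-point contribution itself
# (taking off the maximum contribution minimizes the remaining 2-point
# information), then lexicographically by name. Without the information
# tie-break, a collider's child can be conditioned on before the true
# mediator, permanently re-opening the very path it sits on.
best_contributor_idx <- function(ds, x, y, u, candidates, score = "nml",
                                 mode = "shifted", cache = NULL) {
  if (length(candidates) == 0L) return(list(z = NA_integer_, rank = 0))
  # deterministic order: lexicographic on names
  candidates <- candidates[order(ds$variable_names[candidates], method = "radix")]
  best_z <- NA_integer_
  best_rank <- 0
  best_i3 <- -Inf
  for (z in candidates) {
    s <- triple_score_idx(ds, x, y, z, u, score, mode, cache)
    if (!s$eligible) next
    i3 <- if (mode == "shifted") s$I3_shifted else s$I3
    if (is.na(best_z) || s$s_lb > best_rank ||
        (s$s_lb == best_rank && i3 > best_i3)) {
      best_z <- z
      best_rank <- s$s_lb
      best_i3 <- i3
    }
  }
  list(z = best_z, rank = if (is.na(best_z)) 0 else best_rank)
}

#' Most likely contributor to an edge
#'
#' Evaluates [contribution_score()] for every candidate and returns the one
#' maximizing the lower-bound score `S_lb` (the edge rank
#' `R(xy;z|{u_i}) = max_z S_lb`). Candidates whose 3-point contribution is
#' not positive (in the active mode) are ineligible: a negative contribution
#' signals a v-structure, not an indirect path. Ties break lexicographically
#' on the candidate name.
#'
#' @inheritParams prob_non_v
#' @param candidates Candidate contributor variables (names or indices).
#' @return A one-row tibble with `z` (name, or `NA` when no candidate is
#'   eligible) and `rank`.
#' @export
best_contributor <- function(data, x, y, u = character(0), candidates,
                             score = c("nml", "mdl"), rank = "auto") {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  mode <- resolve_rank_mode(rank, score)
  xi <- var_index(ds, x); yi <- var_index(ds, y); ui <- var_index(ds, u)
  ci <- var_index(ds, candidates)
  if (length(intersect(ci, c(xi, yi, ui))) > 0L) {
    abort("candidates must exclude x, y and the conditioning set.")
  }
  b <- best_contributor_idx(ds, xi, yi, ui, ci, score, mode)
  tibble::tibble(
    z = if (is.na(b$z)) NA_character_ else ds$variable_names[b$z],
    rank = b$rank
  )
}
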