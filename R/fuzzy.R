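# Fuzzification, rule matching, normalization and defuzzification.
#
# Each model input is partitioned by a composite family of membership
# functions on the standardized/projected scale: one Z-shaped function on the
# left, Gaussians in the middle, one S-shaped function on the right.  The Z/S
# plateaus absorb inputs of any magnitude, so no clamping is needed.

#' Z-shaped membership function
#'
#' Piecewise quadratic, 1 for `x <= a` (the shoulder), 0 for `x >= b`
#' (the foot), with value 1/2 at the midpoint:
#' \deqn{\mu(x) = 1 - 2((x-a)/(b-a))^2} on the upper half and
#' \deqn{\mu(x) = 2((x-b)/(b-a))^2} on the lower half.
#'
#' @param x Numeric vector.
#' @param a Shoulder (left edge of the descent), `a < b`.
#' @param b Foot (right edge of the descent).
#' @return Memberships in `[0, 1]`.
#' @export
mu_z <- function(x, a, b) {
  if (!(a < b)) stop("mu_z requires a < b", call. = FALSE)
  mid <- (a + b) / 2
  w <- (b - a)
  ifelse(x <= a, 1,
  ifelse(x <= mid, 1 - 2 * ((x - a) / w)^2,
  ifelse(x <= b, 2 * ((x - b) / w)^2, 0)))
}

#' Gaussian membership function
#'
#' `exp(-(x - c)^2 / (2 sigma^2))`; strictly positive everywhere, so any
#' finite input retains some membership in a Gaussian partition.
#'
#' @param x Numeric vector.
#' @param c Center.
#' @param sigma Width, `sigma > 0`.
#' @return Memberships in `(0, 1]`.
#' @export
mu_gauss <- function(x, c, sigma) {
  if (!(sigma > 0)) stop("mu_gauss requires sigma > 0", call. = FALSE)
  exp(-(x - c)^2 / (2 * sigma^2))
}

#' S-shaped membership function
#'
#' Mirror image of [mu_z()]: 0 for `x <= a` (the foot), 1 for `x >= b`
#' (the shoulder). Satisfies `mu_s(x, a, b) == mu_z(-x, -b, -a)`.
#'
#' @param x Numeric vector.
#' @param a Foot, `a < b`.
#' @param b Shoulder.
#' @return Memberships in `[0, 1]`.
#' @export
mu_s <- function(x, a, b) {
  if (!(a < b)) stop("mu_s requires a < b", call. = FALSE)
  mid <- (a + b) / 2
  w <- (b - a)
  ifelse(x <= a, 0,
  ifelse(x <= mid, 2 * ((x - a) / w)^2,
  ifelse(x <= b, 1 - 2 * ((x - b) / w)^2, 1)))
}

partition_presets <- list(
  # 4 partitions per input: Z(-1.5, -0.5), Gaussians at +-0.5 (sigma 0.2690),
  # S(0.5, 1.5).  The working preset for the reduced 4-5 component models.
  partitions4 = list(z = c(a = -1.5, b = -0.5),
                     centers = c(-0.5, 0.5), sigma = 0.2690,
                     s = c(a = 0.5, b = 1.5)),
  # 8 partitions (NB, NM, NS, NZ, PZ, PS, PM, PB): Z(-1.75, -1), six
  # Gaussians at +-1.25, +-0.75, +-0.25 (sigma 0.1213), S(1, 1.75).
  partitions8 = list(z = c(a = -1.75, b = -1),
                     centers = c(-1.25, -0.75, -0.25, 0.25, 0.75, 1.25),
                     sigma = 0.1213,
                     s = c(a = 1, b = 1.75))
)

validate_partition <- function(p) {
  stopifnot(p$z["a"] < p$z["b"], p$s["a"] < p$s["b"], p$sigma > 0,
            length(p$centers) >= 1, !is.unsorted(p$centers, strictly = TRUE),
            all(p$centers > p$z["a"]), all(p$centers < p$s["b"]))
  m <- length(p$centers) + 2
  if (m < 3) stop("need at least 3 partitions per input", call. = FALSE)
  invisible(p)
}

#' Build fuzzy partitions for the model inputs
#'
#' Each of the `n` inputs gets an ordered family of membership functions: one
#' Z-shaped, several Gaussians with a shared width, one S-shaped. Two presets
#' ship with the package: `"partitions4"` (the default working set: Z(-1.5,
#' -0.5), Gaussians at ±0.5 with σ = 0.2690, S(0.5, 1.5)) and
#' `"partitions8"` (the fine NB…PB set: Z(-1.75, -1), Gaussians at ±0.25,
#' ±0.75, ±1.25 with σ = 0.1213, S(1, 1.75)).
#'
#' @param n Number of model inputs (retained principal components).
#' @param preset `"partitions4"` or `"partitions8"`, or a list with elements
#'   `z = c(a, b)`, `centers`, `sigma`, `s = c(a, b)` used for every input.
#' @return Object of class `wl_partitions`: a list of n per-input partition
#'   specs plus attribute `counts` (partitions per input).
#' @export
fuzzy_partitions <- function(n, preset = "partitions4") {
  spec <- if (is.character(preset)) {
    if (!preset %in% names(partition_presets))
      stop("unknown preset '", preset, "'", call. = FALSE)
    partition_presets[[preset]]
  } else preset
  validate_partition(spec)
  per_input <- rep(list(spec), n)
  structure(per_input,
            counts = rep(length(spec$centers) + 2L, n),
            preset = if (is.character(preset)) preset else "custom",
            class = "wl_partitions")
}

#' Memberships of one input value in its partitions
#'
#' Entry q is the membership of `x` in the q-th partition of input `p`,
#' ordered Z, Gaussians (ascending centers), S.
#'
#' @param x Scalar input value (standardized/projected scale).
#' @param partitions A `wl_partitions` object.
#' @param p Input index.
#' @return Numeric vector of length `m_p`, values in `[0, 1]`.
#' @export
memberships <- function(x, partitions, p = 1L) {
  spec <- partitions[[p]]
  c(mu_z(x, spec$z[["a"]], spec$z[["b"]]),
    vapply(spec$centers, function(cc) mu_gauss(x, cc, spec$sigma), numeric(1)),
    mu_s(x, spec$s[["a"]], spec$s[["b"]]))
}

#' Total number of fuzzy rules
#'
#' One rule per combination of partitions across inputs: `m = prod(m_p)`.
#'
#' @param counts Integer vector of partitions per input.
#' @return Rule count.
#' @export
rule_count <- function(counts) {
  stopifnot(all(counts >= 1))
  prod(counts)
}

# Rule index <-> antecedent tuple, lexicographic with q_1 the SLOWEST-varying
# digit.  Frozen: weight serialization depends on this order.
rule_index_to_tuple <- function(j, counts) {
  counts <- as.integer(counts)
  n <- length(counts)
  q <- integer(n)
  j0 <- as.integer(j) - 1L
  for (p in n:1) {
    q[p] <- j0 %% counts[p] + 1L
    j0 <- j0 %/% counts[p]
  }
  q
}

rule_tuple_to_index <- function(q, counts) {
  j0 <- 0L
  for (p in seq_along(counts)) j0 <- j0 * counts[p] + (q[p] - 1L)
  j0 + 1L
}

#' Applicability of every fuzzy rule (min t-norm)
#'
#' Rule j's firing strength is the minimum of its antecedent memberships:
#' `R_j = min_p mu_p[q_p(j)]` where `(q_1..q_n)` is rule j's partition tuple.
#' Rules are ordered lexicographically with `q_1` slowest-varying.
#'
#' @param mu_list List of n membership vectors, one per input (see
#'   [memberships()]).
#' @return Numeric vector of length `prod(m_p)`.
#' @export
rule_applicability <- function(mu_list) {
  counts <- lengths(mu_list)
  # outer min over the partition grid, q_1 slowest: build by successive
  # pairwise minimum with the later input varying fastest
  R <- mu_list[[1]]
  for (p in seq_along(mu_list)[-1]) {
    R <- pmin(rep(R, each = counts[p]),
              rep_len(mu_list[[p]], length(R) * counts[p]))
  }
  R
}

#' Normalize rule applicabilities
#'
#' Divides by the total so the result sums to one and defuzzification becomes
#' a convex combination of weights. If every rule fires with strength zero
#' (possible only for degenerate hand-built partitions, since Gaussian tails
#' never vanish), the default is an error; with `fallback = TRUE` a uniform
#' vector is returned with a warning.
#'
#' @param R Nonnegative applicability vector.
#' @param fallback Return uniform 1/m instead of erroring when `sum(R) == 0`.
#' @return Probability vector of the same length.
#' @export
normalize_applicability <- function(R, fallback = FALSE) {
  if (any(R < 0)) stop("applicabilities must be nonnegative", call. = FALSE)
  s <- sum(R)
  if (s == 0) {
    if (!fallback) stop("all rule applicabilities are zero", call. = FALSE)
    warning("all rule applicabilities zero; using uniform fallback")
    return(rep(1 / length(R), length(R)))
  }
  R / s
}

#' Defuzzify normalized applicabilities to crisp outputs
#'
#' Weighted sum `y_i = sum_j w_ij Rbar_j`, the matrix-vector product of the
#' r x m weight matrix with the normalized applicability vector. With r = 1
#' this is the classic single-output weighted defuzzification.
#'
#' @param Rbar Normalized applicability vector (sums to 1).
#' @param weights r x m numeric matrix (or a length-m vector for r = 1).
#' @return Numeric vector of length r.
#' @export
defuzzify <- function(Rbar, weights) {
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  if (ncol(weights) != length(Rbar))
    stop("weight columns (", ncol(weights), ") must match rule count (",
         length(Rbar), ")", call. = FALSE)
  drop(weights %*% Rbar)
}

# Normalized applicability vectors for a matrix of projected inputs,
# one column per observation (m x t).  The forward pass and the weight
# learner both consume this.
applicability_matrix <- function(scores, partitions, fallback = FALSE) {
  scores <- as.matrix(scores)
  n <- length(partitions)
  if (ncol(scores) != n)
    stop("projected score columns must match partition count", call. = FALSE)
  apply(scores, 1, function(row) {
    mu <- lapply(seq_len(n), function(p) memberships(row[p], partitions, p))
    normalize_applicability(rule_applicability(mu), fallback = fallback)
  })
}
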