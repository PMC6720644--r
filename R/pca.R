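# Correlation-matrix PCA with contribution-rate component selection.

#' Correlation coefficient matrix of standardized data
#'
#' After z-scoring, the covariance of any two columns equals their Pearson
#' correlation, so the matrix is computed as the cross-product of z-scores
#' divided by t - 1.
#'
#' @param std A `wl_standardizer` (uses its `values`) or an already
#'   standardized numeric matrix.
#' @return Symmetric k x k matrix with unit diagonal.
#' @export
correlation_matrix <- function(std) {
  z <- if (inherits(std, "wl_standardizer")) std$values else as.matrix(std)
  if (nrow(z) < 2) stop("need at least 2 rows", call. = FALSE)
  r <- crossprod(z) / (nrow(z) - 1)
  # symmetrize against roundoff and pin the diagonal
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Eigendecompose a correlation matrix
#'
#' Eigenvalues are returned in descending order with orthonormal loading
#' vectors. The sign of each vector is fixed so its largest-magnitude entry
#' is positive, making decompositions comparable across platforms; serialized
#' models store the loadings explicitly so results never depend on the
#' convention. Ties in eigenvalue are kept in the order the decomposition
#' returns them (stable).
#'
#' @param R Symmetric k x k correlation matrix.
#' @return List with `eigenvalues` (length k, descending) and `loadings`
#'   (k x k matrix, one component per column).
#' @export
eigendecompose <- function(R) {
  R <- as.matrix(R)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8)
    stop("correlation matrix must be symmetric", call. = FALSE)
  e <- eigen(R, symmetric = TRUE)  # already sorted descending
  vec <- e$vectors
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(eigenvalues = e$values, loadings = vec)
}

#' Contribution rates of principal components
#'
#' Each eigenvalue's share of the total variance, in percent:
#' C_i = 100 * lambda_i / sum(lambda). Tiny negative eigenvalues from
#' roundoff are clamped to zero.
#'
#' @param eigenvalues Numeric vector of eigenvalues.
#' @return Numeric vector of percentages summing to 100.
#' @export
contribution_rates <- function(eigenvalues) {
  ev <- as.numeric(eigenvalues)
  if (any(ev < -1e-10)) stop("negative eigenvalue beyond roundoff", call. = FALSE)
  ev[ev < 0] <- 0
  if (sum(ev) == 0) stop("all eigenvalues are zero", call. = FALSE)
  100 * ev / sum(ev)
}

#' Select the number of components by cumulative contribution
#'
#' Smallest n whose cumulative contribution rate reaches the threshold.
#' The conventional band for "covers most of the information" is a cumulative
#' rate of 70-90%; the package default threshold is 0.75.
#'
#' @param rates Contribution rates in percent (descending components).
#' @param threshold Fraction in (0, 1].
#' @return Integer number of components.
#' @export
select_components <- function(rates, threshold = 0.75) {
  stopifnot(threshold > 0, threshold <= 1)
  cum <- cumsum(rates)
  which(cum >= 100 * threshold - 1e-9)[1]
}

#' Fit the full PCA transform
#'
#' Correlation matrix, eigendecomposition, contribution rates and component
#' selection in one step.
#'
#' @param std A `wl_standardizer` or standardized matrix.
#' @param threshold Cumulative-contribution threshold, see
#'   [select_components()].
#' @return Object of class `wl_pca`: `eigenvalues`, `loadings` (k x k),
#'   `contribution_rates`, `cumulative_rates` (percent), `n_selected`,
#'   `threshold`.
#' @export
fit_pca <- function(std, threshold = 0.75) {
  R <- correlation_matrix(std)
  e <- eigendecompose(R)
  rates <- contribution_rates(e$eigenvalues)
  structure(
    list(eigenvalues = e$eigenvalues,
         loadings = e$loadings,
         contribution_rates = rates,
         cumulative_rates = cumsum(rates),
         n_selected = select_components(rates, threshold),
         threshold = threshold),
    class = "wl_pca"
  )
}

#' Project standardized data onto the selected components
#'
#' Component scores X_p = sum_i a_pi x_i for p = 1..n, i.e. the standardized
#' data times the first n loading vectors.
#'
#' @param std_values Standardized t x k matrix (or `wl_standardizer`).
#' @param transform A `wl_pca` object.
#' @param n Number of components; defaults to `transform$n_selected`.
#' @return t x n matrix of component scores.
#' @export
project <- function(std_values, transform, n = transform$n_selected) {
  z <- if (inherits(std_values, "wl_standardizer")) std_values$values
       else as.matrix(std_values)
  if (ncol(z) != nrow(transform$loadings))
    stop("column count mismatch with PCA loadings", call. = FALSE)
  z %*% transform$loadings[, seq_len(n), drop = FALSE]
}
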