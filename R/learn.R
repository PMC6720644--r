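# Error-feedforward gradient-descent learning of the defuzzification weights.
#
# With memberships and PCA frozen, the model is linear in the weights, so the
# per-sample cost is a convex quadratic and batch gradient descent with a
# small enough learning rate decreases it monotonically.

#' Training configuration
#'
#' @param beta Learning rate, default 0.75.
#' @param tau Error-tolerance threshold on the aggregate dataset error
#'   (RMSE, NASA-TLX units), default 5 — the instrument's minimum division.
#' @param max_epochs Epoch cap, default 10000.
#' @param init Weight initialization: `"zeros"` (default, deterministic),
#'   `"constant"` (value `v`), or `"uniform"` (seeded draw over `[lo, hi]`).
#' @param v Constant init value.
#' @param lo,hi Uniform init range (default the output scale `[0, 100]`).
#' @param seed Seed for the uniform init.
#' @return A `wl_train_config` list.
#' @export
train_config <- function(beta = 0.75, tau = 5, max_epochs = 10000L,
                         init = c("zeros", "constant", "uniform"),
                         v = 0, lo = 0, hi = 100, seed = 1L) {
  stopifnot(beta > 0, tau > 0, max_epochs >= 1)
  structure(list(beta = beta, tau = tau, max_epochs = as.integer(max_epochs),
                 init = match.arg(init), v = v, lo = lo, hi = hi,
                 seed = as.integer(seed)),
            class = "wl_train_config")
}

#' Per-sample error cost
#'
#' Half squared error summed over outputs: `sum_i (y_e - y_a)^2 / 2`.
#'
#' @param expected,actual Numeric vectors of equal length r.
#' @return Nonnegative scalar, zero iff the vectors are equal.
#' @export
error_cost <- function(expected, actual) {
  if (length(expected) != length(actual))
    stop("expected/actual length mismatch", call. = FALSE)
  sum((expected - actual)^2) / 2
}

#' Aggregate dataset error (RMSE)
#'
#' Root-mean-square of residuals across all samples and outputs. For a
#' single output this equals `sqrt(2 * mean per-sample error cost)`. The
#' training loop stops when this drops below `tau`.
#'
#' @param residuals Numeric vector or matrix of expected - actual residuals.
#' @return Nonnegative scalar.
#' @export
aggregate_error <- function(residuals) {
  r <- as.numeric(residuals)
  if (!length(r)) stop("no residuals", call. = FALSE)
  sqrt(mean(r^2))
}

#' Gradient of the error cost in the weights
#'
#' For weight `w_ij` (output i, rule j): `dEc/dw_ij = -(y_ei - y_ai) * Rbar_j`.
#'
#' @param expected,actual Output vectors of length r.
#' @param Rbar Normalized applicability vector of length m.
#' @return r x m gradient matrix.
#' @export
weight_gradient <- function(expected, actual, Rbar) {
  if (length(expected) != length(actual))
    stop("expected/actual length mismatch", call. = FALSE)
  -outer(expected - actual, Rbar)
}

#' One batch gradient-descent epoch
#'
#' Accumulates the per-sample steps `beta * (y_e - y_a) * Rbar_j` over the
#' whole batch at the current weights, then applies the summed delta:
#' `w <- w + beta * (Ye - Ya) %*% t(Rbar)`.
#'
#' @param weights r x m weight matrix.
#' @param Rbar m x t matrix of normalized applicabilities (one column per
#'   sample, see the forward pass).
#' @param expected r x t matrix of expected outputs.
#' @param beta Learning rate.
#' @return List: updated `weights`, `rmse` (aggregate error at the epoch's
#'   START, i.e. of the outputs the update was computed from), `mean_cost`
#'   (mean per-sample half-squared-error).
#' @export
epoch_update <- function(weights, Rbar, expected, beta) {
  actual <- weights %*% Rbar
  resid <- expected - actual            # r x t
  weights <- weights + beta * resid %*% t(Rbar)
  if (!all(is.finite(weights)))
    stop("non-finite weights after update; learning rate too large",
         call. = FALSE)
  list(weights = weights,
       rmse = aggregate_error(resid),
       mean_cost = mean(colSums(resid^2) / 2))
}

#' Train the defuzzification weights
#'
#' Iterates [epoch_update()] (one full pass per epoch) until the aggregate
#' RMSE falls below `config$tau` or `max_epochs` is reached. Only the
#' Layer-5-to-6 weights are learned; standardizer, PCA and membership
#' parameters stay frozen. Deterministic given the config (including the
#' seed when the init is randomized). Non-convergence is reported via the
#' trace, not an error; divergence to non-finite weights aborts.
#'
#' @param model An untrained (or warm-started) `wl_fusion_model`.
#' @param x Raw feature matrix or feature table of training samples.
#' @param y Expected outputs: vector (r = 1) or t x r matrix.
#' @param config A [train_config()].
#' @return List with `model` (weights updated) and `trace`, a
#'   `wl_training_trace`: data.frame of per-epoch `epoch`, `rmse`,
#'   `mean_cost`, plus attributes `converged`, `epochs`, `final_rmse`.
#' @export
train_weights <- function(model, x, y, config = train_config()) {
  if (is.data.frame(x)) x <- feature_matrix(x)
  y <- if (is.null(dim(y))) matrix(y, nrow = 1) else t(as.matrix(y))  # r x t
  if (ncol(y) != nrow(x)) stop("sample count mismatch", call. = FALSE)
  if (nrow(y) != model$r) stop("output count mismatch", call. = FALSE)
  if (ncol(y) == 0) stop("empty training set", call. = FALSE)

  scores <- project_features(model, x)
  Rbar <- applicability_matrix(scores, model$partitions)   # m x t

  w <- init_weights(model$r, ncol(model$weights), config,
                    current = model$weights)
  rmse <- aggregate_error(y - w %*% Rbar)
  trace <- data.frame(epoch = integer(0), rmse = numeric(0),
                      mean_cost = numeric(0))
  epoch <- 0L
  while (rmse >= config$tau && epoch < config$max_epochs) {
    epoch <- epoch + 1L
    st <- epoch_update(w, Rbar, y, config$beta)
    w <- st$weights
    rmse <- aggregate_error(y - w %*% Rbar)
    trace <- rbind(trace, data.frame(epoch = epoch, rmse = rmse,
                                     mean_cost = st$mean_cost))
  }
  model$weights <- w
  attr(trace, "converged") <- rmse < config$tau
  attr(trace, "epochs") <- epoch
  attr(trace, "final_rmse") <- rmse
  class(trace) <- c("wl_training_trace", "data.frame")
  list(model = model, trace = trace)
}

init_weights <- function(r, m, config, current = NULL) {
  switch(config$init,
    zeros = matrix(0, r, m),
    constant = matrix(config$v, r, m),
    uniform = {
      set.seed(config$seed)
      matrix(stats::runif(r * m, config$lo, config$hi), r, m)
    })
}

#' @export
print.wl_training_trace <- function(x, ...) {
  cat(sprintf("training trace: %d epoch(s), final RMSE %.4f, converged: %s\n",
              attr(x, "epochs"), attr(x, "final_rmse"),
              attr(x, "converged")))
  invisible(x)
}
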