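# Fusion model: standardizer + PCA + partitions + defuzzification weights.

#' Construct a fusion model
#'
#' Bundles the fitted pipeline stages. The weight matrix is r x m where
#' m = prod(partitions per input); rules are ordered lexicographically with
#' the first input's partition index slowest-varying ("lex-q1-slowest"),
#' and serialized weights depend on that order.
#'
#' @param standardizer A `wl_standardizer`.
#' @param pca A `wl_pca`.
#' @param partitions A `wl_partitions` with `pca$n_selected` inputs.
#' @param weights r x m matrix (NASA-TLX output units); defaults to a single
#'   output of zeros.
#' @return Object of class `wl_fusion_model`.
#' @export
fusion_model <- function(standardizer, pca, partitions, weights = NULL) {
  m <- rule_count(attr(partitions, "counts"))
  if (is.null(weights)) weights <- matrix(0, nrow = 1, ncol = m)
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1)
  if (ncol(weights) != m)
    stop("weight matrix must have ", m, " columns (rule count)", call. = FALSE)
  if (!all(is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (length(partitions) != pca$n_selected)
    stop("partitions must cover the ", pca$n_selected, " selected components",
         call. = FALSE)
  structure(
    list(standardizer = standardizer, pca = pca, partitions = partitions,
         weights = weights, r = nrow(weights),
         rule_order = "lex-q1-slowest"),
    class = "wl_fusion_model"
  )
}

#' Fit the untrained pipeline stages on a feature matrix
#'
#' Standardizes, fits PCA, selects components, and attaches the partition
#' preset; weights start at zero and are learned with [train_weights()].
#'
#' @param x Raw t x k feature matrix (see [feature_matrix()]).
#' @param threshold Cumulative-contribution threshold for component
#'   selection.
#' @param preset Partition preset, see [fuzzy_partitions()].
#' @param r Number of outputs (1 for the averaged TLX score, 6 for the raw
#'   dimensions).
#' @return An untrained `wl_fusion_model`.
#' @export
fit_pipeline <- function(x, threshold = 0.75, preset = "partitions4", r = 1L) {
  std <- zscore_standardize(x)
  pca <- fit_pca(std, threshold = threshold)
  parts <- fuzzy_partitions(pca$n_selected, preset = preset)
  m <- rule_count(attr(parts, "counts"))
  fusion_model(std, pca, parts, matrix(0, nrow = r, ncol = m))
}

# Projected component scores for raw features (t x n).
project_features <- function(model, x) {
  z <- apply_standardization(x, model$standardizer)
  project(z, model$pca)
}

#' Predict workload from raw features
#'
#' Full forward pass: standardize with the training parameters, project onto
#' the retained principal components, fuzzify, take rule applicability
#' minima, normalize, and defuzzify against the learned weights. The output
#' is a convex combination of the weights, so it always lies within their
#' range.
#'
#' @param object A trained `wl_fusion_model`.
#' @param newdata Feature table (data.frame with x1..x11) or raw feature
#'   matrix.
#' @param unify Also report scores snapped to the NASA-TLX grid
#'   ([unify_to_scale()]).
#' @param ... Unused.
#' @return If `r = 1`, a data.frame with column `raw` (plus `unified` when
#'   requested); otherwise a t x r matrix of raw outputs.
#' @export
predict.wl_fusion_model <- function(object, newdata, unify = FALSE, ...) {
  x <- if (is.data.frame(newdata)) feature_matrix(newdata) else as.matrix(newdata)
  scores <- project_features(object, x)
  Rbar <- applicability_matrix(scores, object$partitions)
  y <- object$weights %*% Rbar  # r x t
  if (object$r > 1L && !unify) return(t(y))
  out <- data.frame(raw = drop(y[1, ]))
  if (unify) out$unified <- unify_to_scale(out$raw)
  out
}

#' Serialize / deserialize a fusion model as JSON
#'
#' The JSON stores the standardizer parameters, PCA eigenvalues and loadings
#' (row-major), partition parameters per input, the weight matrix row-major,
#' and the frozen rule order, so a model trained elsewhere reproduces
#' identical predictions.
#'
#' @param model A `wl_fusion_model`.
#' @param path Output / input JSON file path.
#' @return `model_to_json` invisibly returns `path`; `model_from_json`
#'   returns the reconstructed `wl_fusion_model`.
#' @export
model_to_json <- function(model, path) {
  k <- length(model$standardizer$center)
  payload <- list(
    format = "wlfuse-model",
    version = 1L,
    rule_order = model$rule_order,
    r = model$r,
    standardizer = list(
      columns = as.list(model$standardizer$columns),
      center = as.numeric(model$standardizer$center),
      scale = as.numeric(model$standardizer$scale)
    ),
    pca = list(
      eigenvalues = as.numeric(model$pca$eigenvalues),
      loadings_row_major = as.numeric(t(model$pca$loadings)),
      k = k,
      n_selected = model$pca$n_selected,
      threshold = model$pca$threshold
    ),
    partitions = lapply(model$partitions, function(p) list(
      z = as.numeric(p$z), centers = as.numeric(p$centers),
      sigma = as.numeric(p$sigma), s = as.numeric(p$s)
    )),
    weights_row_major = as.numeric(t(model$weights))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "wlfuse-model"))
    stop("not a wlfuse model JSON", call. = FALSE)
  k <- p$pca$k
  std <- structure(
    list(values = NULL,
         center = stats::setNames(p$standardizer$center, p$standardizer$columns),
         scale = stats::setNames(p$standardizer$scale, p$standardizer$columns),
         columns = p$standardizer$columns),
    class = "wl_standardizer")
  loadings <- matrix(p$pca$loadings_row_major, nrow = k, byrow = TRUE)
  rates <- contribution_rates(p$pca$eigenvalues)
  pca <- structure(
    list(eigenvalues = p$pca$eigenvalues, loadings = loadings,
         contribution_rates = rates, cumulative_rates = cumsum(rates),
         n_selected = p$pca$n_selected, threshold = p$pca$threshold),
    class = "wl_pca")
  specs <- if (is.data.frame(p$partitions)) {
    lapply(seq_len(nrow(p$partitions)), function(i)
      list(z = c(a = p$partitions$z[[i]][1], b = p$partitions$z[[i]][2]),
           centers = p$partitions$centers[[i]],
           sigma = p$partitions$sigma[[i]],
           s = c(a = p$partitions$s[[i]][1], b = p$partitions$s[[i]][2])))
  } else {
    lapply(p$partitions, function(q)
      list(z = c(a = q$z[1], b = q$z[2]), centers = q$centers,
           sigma = q$sigma, s = c(a = q$s[1], b = q$s[2])))
  }
  parts <- structure(specs,
                     counts = vapply(specs, function(q) length(q$centers) + 2L,
                                     integer(1)),
                     preset = "serialized", class = "wl_partitions")
  for (spec in specs) validate_partition(spec)
  m <- rule_count(attr(parts, "counts"))
  if (length(p$weights_row_major) != p$r * m)
    stop("weight count (", length(p$weights_row_major),
         ") does not match r x rule count (", p$r * m, ")", call. = FALSE)
  weights <- matrix(p$weights_row_major, nrow = p$r, byrow = TRUE)
  fusion_model(std, pca, parts, weights)
}

#' @export
print.wl_fusion_model <- function(x, ...) {
  cat("wlfuse fusion model\n")
  cat("  features:   ", length(x$standardizer$center), "\n")
  cat("  components: ", x$pca$n_selected,
      sprintf(" (cumulative %.2f%%)",
              x$pca$cumulative_rates[x$pca$n_selected]), "\n")
  cat("  partitions: ", paste(attr(x$partitions, "counts"), collapse = "x"),
      " -> ", ncol(x$weights), "rules\n")
  cat("  outputs:    ", x$r, "\n")
  invisible(x)
}
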