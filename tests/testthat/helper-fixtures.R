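# Shared fixtures, built in code.

# The ten fully printed rows of the published raw-vs-unified prediction
# tables (taxiing, normal climbing, fault, flaring out per run).
printed_predictions <- function() {
  raw <- rbind(
    c(40.68,  3.49, 44.12,   0.00),
    c(18.30, 18.87, 64.73,   6.06),
    c(60.69,  0.00, 68.65,  37.92),
    c(14.63,  2.69, 56.69,   7.21),
    c(13.55, 12.66, 72.74,   0.50),
    c(44.23, 57.39, 75.95, 102.26),
    c(21.15,  4.00, 52.51,  -3.13),
    c(51.69, 22.26, 38.31,  20.45),
    c( 0.00,  0.95, 55.00,  15.22),
    c(61.68,  7.73, 73.33,  10.99))
  unified <- rbind(
    c(40,  5, 45,   0),
    c(20, 20, 65,   5),
    c(60,  0, 70,  40),
    c(15,  5, 55,   5),
    c(15, 15, 75,   0),
    c(45, 55, 75, 100),
    c(20,  5, 55,  -5),
    c(50, 20, 40,  20),
    c( 0,  0, 55,  15),
    c(60, 10, 75,  10))
  list(raw = raw, unified = unified)
}

# Published per-component contribution rates (%) of the 11-feature PCA.
printed_rates <- function() {
  c(29.48, 19.93, 17.75, 10.00, 8.28, 5.10, 4.32, 2.98, 1.66, 0.36, 0.14)
}

# A tiny valid feature table.
tiny_feature_table <- function() {
  data.frame(
    run_id = c("run01", "run01"), subject_id = c("s01", "s01"),
    difficulty = c("LL", "LL"), phase = c("taxiing", "fault"),
    x1 = c(1.0, 2.0), x2 = c(5, 40), x3 = c(10, 25),
    x4 = c(70, 95), x5 = c(0.9, 0.7), x6 = c(30, 50),
    x7 = c(0.06, 0.03), x8 = c(4.2, 5.0),
    x9 = c(70, 80), x10 = c(15, 12), x11 = c(10, 6))
}

# Hand-built identity-pipeline model: k inputs pass through untouched
# (center 0, scale 1, identity loadings), n = k components retained.
identity_model <- function(k = 2, preset = "partitions4", weights = NULL) {
  std <- structure(
    list(values = NULL, center = stats::setNames(rep(0, k), paste0("x", 1:k)),
         scale = stats::setNames(rep(1, k), paste0("x", 1:k)),
         columns = paste0("x", 1:k)),
    class = "wl_standardizer")
  rates <- contribution_rates(rep(1, k))
  pca <- structure(
    list(eigenvalues = rep(1, k), loadings = diag(k),
         contribution_rates = rates, cumulative_rates = cumsum(rates),
         n_selected = k, threshold = 1),
    class = "wl_pca")
  parts <- fuzzy_partitions(k, preset = preset)
  fusion_model(std, pca, parts, weights)
}

# 3-partition custom spec for small hand-checked models.
three_partitions <- function() {
  list(z = c(a = -1.5, b = -0.5), centers = 0, sigma = 0.5,
       s = c(a = 0.5, b = 1.5))
}

# From-scratch single-expression forward pass for an identity-pipeline
# model (independent of the package's layered implementation).
naive_forward <- function(x, specs, weights) {
  mu <- lapply(seq_along(specs), function(p) {
    sp <- specs[[p]]
    zc <- function(v, a, b) { # Z-shape
      m <- (a + b) / 2
      if (v <= a) 1 else if (v <= m) 1 - 2 * ((v - a) / (b - a))^2
      else if (v <= b) 2 * ((v - b) / (b - a))^2 else 0
    }
    sc <- function(v, a, b) { # S-shape
      m <- (a + b) / 2
      if (v <= a) 0 else if (v <= m) 2 * ((v - a) / (b - a))^2
      else if (v <= b) 1 - 2 * ((v - b) / (b - a))^2 else 1
    }
    c(zc(x[p], sp$z[["a"]], sp$z[["b"]]),
      sapply(sp$centers, function(cc) exp(-(x[p] - cc)^2 / (2 * sp$sigma^2))),
      sc(x[p], sp$s[["a"]], sp$s[["b"]]))
  })
  counts <- lengths(mu)
  grid <- expand.grid(rev(lapply(counts, seq_len)))[, length(counts):1, drop = FALSE]
  R <- apply(grid, 1, function(q)
    min(mapply(function(p, qq) mu[[p]][qq], seq_along(mu), q)))
  Rbar <- R / sum(R)
  as.numeric(weights %*% Rbar)
}
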