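test_that("Z, Gaussian and S membership functions match their closed forms", {
  expect_equal(mu_z(c(-3, -1.5), -1.5, -0.5), c(1, 1))   # plateau
  expect_equal(mu_z(-1, -1.5, -0.5), 0.5)                # midpoint
  expect_equal(mu_z(-1.25, -1.5, -0.5), 0.875)           # upper branch
  expect_equal(mu_z(c(-0.5, 2), -1.5, -0.5), c(0, 0))
  expect_error(mu_z(0, 1, 1), "a < b")

  expect_equal(mu_gauss(0.3, 0.3, 0.1), 1)
  expect_equal(mu_gauss(c(0.2, 0.4), 0.3, 0.1), rep(exp(-0.5), 2))
  d <- runif(5, 0, 2)
  expect_equal(mu_gauss(0.3 + d, 0.3, 0.25), mu_gauss(0.3 - d, 0.3, 0.25))
  expect_error(mu_gauss(0, 0, -1), "sigma > 0")

  expect_equal(mu_s(c(1.5, 9), 0.5, 1.5), c(1, 1))
  expect_equal(mu_s(1, 0.5, 1.5), 0.5)
  expect_equal(mu_s(0.75, 0.5, 1.5), 0.125)              # lower branch
  expect_error(mu_s(0, 2, 1), "a < b")

  # mirror identity mu_s(x; a, b) == mu_z(-x; -b, -a), on a dense grid
  x <- seq(-3, 3, by = 0.01)
  expect_equal(mu_s(x, 0.5, 1.5), mu_z(-x, -1.5, -0.5), tolerance = 1e-12)
  expect_true(all(mu_z(x, -1.2, 0.3) >= 0 & mu_z(x, -1.2, 0.3) <= 1))
  expect_true(all(mu_s(x, -0.2, 1.3) >= 0 & mu_s(x, -0.2, 1.3) <= 1))
})

test_that("composite memberships evaluate the preset partitions", {
  p4 <- fuzzy_partitions(1, "partitions4")
  expect_lt(max(abs(memberships(0, p4) - c(0, 0.1778, 0.1778, 0))), 1e-4)
  expect_equal(memberships(-10, p4)[1], 1)
  expect_lt(max(memberships(-10, p4)[-1]), 1e-10)

  p8 <- fuzzy_partitions(1, "partitions8")
  expect_equal(attr(p8, "counts"), 8L)
  expect_equal(memberships(-1.75, p8)[1], 1)  # Z shoulder
  mu <- memberships(0.4, p8)
  expect_true(all(mu >= 0 & mu <= 1))
  expect_error(fuzzy_partitions(2, "nope"), "unknown preset")
})

test_that("rule count and index<->tuple mapping form a bijection", {
  expect_equal(rule_count(rep(4, 4)), 256)
  expect_equal(rule_count(rep(4, 5)), 4^5)
  expect_equal(rule_count(c(5, 5, 5, 5)), 625)
  expect_equal(rule_count(8), 8)

  counts <- c(3, 4, 2)
  m <- rule_count(counts)
  tuples <- t(vapply(1:m, wlfuse:::rule_index_to_tuple, integer(3),
                     counts = counts))
  expect_equal(nrow(unique(tuples)), m)  # bijection
  for (j in 1:m)
    expect_equal(wlfuse:::rule_tuple_to_index(tuples[j, ], counts), j)
  # lex order, q_1 slowest: first tuple all 1s, second bumps the LAST input
  expect_equal(tuples[1, ], c(1L, 1L, 1L))
  expect_equal(tuples[2, ], c(1L, 1L, 2L))
  expect_equal(tuples[m, ], counts)
})

test_that("rule applicability is the antecedent minimum in frozen order", {
  mu <- list(c(0.2, 0.8), c(0.5, 0.1))
  R <- rule_applicability(mu)
  # brute force over all 4 tuples, q_1 slowest
  oracle <- c(min(0.2, 0.5), min(0.2, 0.1), min(0.8, 0.5), min(0.8, 0.1))
  expect_equal(R, oracle)

  expect_equal(rule_applicability(list(rep(0.3, 3), rep(0.3, 2))),
               rep(0.3, 6))
  R0 <- rule_applicability(list(c(0, 1), c(1, 1)))
  expect_equal(R0[1:2], c(0, 0))  # zero antecedent kills its rules

  # random cross-check against exhaustive enumeration
  set.seed(12)
  mu <- list(runif(4), runif(3), runif(4))
  R <- rule_applicability(mu)
  counts <- lengths(mu)
  for (j in seq_along(R)) {
    q <- wlfuse:::rule_index_to_tuple(j, counts)
    expect_equal(R[j], min(mu[[1]][q[1]], mu[[2]][q[2]], mu[[3]][q[3]]))
  }
})

test_that("normalization yields a probability vector with guarded zero case", {
  expect_equal(normalize_applicability(rep(1, 4)), rep(0.25, 4))
  expect_equal(normalize_applicability(c(2, 0, 0, 0)), c(1, 0, 0, 0))
  expect_error(normalize_applicability(rep(0, 4)), "all rule applicabilities")
  expect_warning(u <- normalize_applicability(rep(0, 4), fallback = TRUE),
                 "uniform fallback")
  expect_equal(u, rep(0.25, 4))
  expect_error(normalize_applicability(c(-1, 2)), "nonnegative")
  set.seed(13)
  for (i in 1:5) {
    R <- runif(20)
    expect_equal(sum(normalize_applicability(R)), 1, tolerance = 1e-12)
  }
})

test_that("defuzzification is the weight-applicability product", {
  Rbar <- c(0.5, 0.25, 0.25)
  expect_equal(defuzzify(Rbar, rep(7, 3)), 7)          # constant weights
  expect_equal(defuzzify(c(0, 1, 0), matrix(1:6, 2)), c(3, 4))  # one-hot
  W <- matrix(runif(6), 2, 3)
  oracle <- c(sum(W[1, ] * Rbar), sum(W[2, ] * Rbar))  # double loop
  expect_equal(defuzzify(Rbar, W), oracle)
  expect_error(defuzzify(c(0.5, 0.5), W), "must match rule count")
})

test_that("predict composes the layers and stays within the weight range", {
  set.seed(14)
  w <- matrix(runif(16, 0, 100), 1)
  model <- identity_model(k = 2, weights = w)
  x <- matrix(runif(20, -2, 2), 10, 2)
  out <- predict(model, x)
  expect_true(all(out$raw >= min(w) & out$raw <= max(w)))

  const <- identity_model(k = 2, weights = matrix(42, 1, 16))
  expect_equal(predict(const, x)$raw, rep(42, 10))

  outu <- predict(model, x, unify = TRUE)
  expect_true(all(outu$unified %% 5 == 0))
  expect_true(all(abs(outu$unified - outu$raw) <= 2.5))
})

test_that("predict matches a from-scratch forward-pass recomputation", {
  spec <- three_partitions()
  set.seed(15)
  w <- matrix(runif(9, 0, 100), 1)
  model <- identity_model(k = 2, preset = spec, weights = w)
  for (x in list(c(0.3, -0.7), c(-2, 2), c(0, 0), c(1.1, 0.2))) {
    got <- predict(model, matrix(x, 1))$raw
    expect_equal(got, naive_forward(x, list(spec, spec), w),
                 tolerance = 1e-12)
  }
})

test_that("models survive a JSON round trip and reject tampered weights", {
  set.seed(16)
  camp <- generate_campaign(campaign_config(seed = 16, n_subjects = 4))
  train <- camp$features[camp$features$phase == "fault", ]
  y <- aggregate_tlx(camp$tlx)
  model <- fit_pipeline(feature_matrix(train))
  fit <- train_weights(model, train, y,
                       train_config(beta = 0.5, max_epochs = 200))
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(fit$model, path)
  back <- model_from_json(path)
  expect_equal(predict(back, train)$raw, predict(fit$model, train)$raw,
               tolerance = 1e-12)
  expect_equal(back$pca$n_selected, fit$model$pca$n_selected)

  # weight count inconsistent with the partition grid -> schema error
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$weights_row_major <- p$weights_row_major[-1]
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA)
  expect_error(model_from_json(path), "does not match")
})
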