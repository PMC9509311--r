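test_that("noiseless two-regime data is recovered exactly", {
  d <- two_regime_data(200, seed = 3)
  fit <- model_tree(d, max_rules = 2, min_leaf_n = 20)
  expect_length(fit$rules, 2)
  sp <- fit$rules[[1]]$path[[1]]
  expect_equal(sp$feature, "nir")
  expect_lt(abs(sp$threshold - 0.4), 0.02)
  leaves <- lapply(fit$rules, function(r) {
    c(r$leaf$intercept, r$leaf$coefficients["nir"])
  })
  low <- leaves[[which(sapply(fit$rules,
                              function(r) r$path[[1]]$side == "<="))]]
  high <- leaves[[which(sapply(fit$rules,
                               function(r) r$path[[1]]$side == ">"))]]
  expect_equal(unname(low), c(0, 2), tolerance = 1e-6)
  expect_equal(unname(high), c(-1.2, 5), tolerance = 1e-6)
})

test_that("a single-rule tree is exactly weighted least squares", {
  d <- weighted_linear_data()
  fit <- model_tree(d, max_rules = 1)
  oracle <- stats::lm(lai ~ b_a + b_b + b_c, data = d, weights = d$weight)
  got <- c(fit$rules[[1]]$leaf$intercept, fit$rules[[1]]$leaf$coefficients)
  expect_equal(unname(got), unname(stats::coef(oracle)), tolerance = 1e-8)
  # predictions pass through the weighted centroid
  centroid <- d |>
    dplyr::summarise(dplyr::across(c("b_a", "b_b", "b_c"),
                                   ~ sum(.x * d$weight) / sum(d$weight)))
  expect_equal(as.numeric(predict(fit, centroid)),
               sum(d$lai * d$weight) / sum(d$weight), tolerance = 1e-10)
})

test_that("integer weights are equivalent to sample duplication", {
  set.seed(5)
  d1 <- tibble::tibble(nir = runif(60), red = runif(60))
  d1$lai <- 1 + 2 * d1$nir - d1$red + rnorm(60, 0, 0.1)
  d1$weight <- sample(1:3, 60, replace = TRUE)
  d2 <- d1[rep(seq_len(60), d1$weight), ]
  d2$weight <- 1
  fA <- model_tree(d1, max_rules = 3, min_leaf_n = 10)
  fB <- model_tree(d2, max_rules = 3, min_leaf_n = 10)
  grid <- tibble::tibble(nir = runif(50), red = runif(50))
  expect_equal(as.numeric(predict(fA, grid)),
               as.numeric(predict(fB, grid)), tolerance = 1e-10)
})

test_that("deepening the rule budget never increases training RMSE", {
  set.seed(6)
  d <- tibble::tibble(nir = runif(300))
  d$lai <- sin(4 * d$nir) + 2 + rnorm(300, 0, 0.05)
  rmse <- vapply(1:6, function(k) {
    model_tree(d, max_rules = k, min_leaf_n = 15)$train_rmse
  }, numeric(1))
  expect_true(all(diff(rmse) <= 1e-9))
})

test_that("prediction clamps negatives, flags them, and validates features", {
  set.seed(7)
  d <- tibble::tibble(nir = runif(50))
  d$lai <- 2 * d$nir - 0.5  # linear, negative below nir = 0.25
  fit <- model_tree(d, max_rules = 1)
  p <- predict(fit, tibble::tibble(nir = c(0, 0.5)))
  expect_equal(as.numeric(p), c(0, 0.5), tolerance = 1e-8)
  expect_identical(attr(p, "clamped"), c(TRUE, FALSE))
  p2 <- predict(fit, tibble::tibble(nir = 0), clamp = FALSE)
  expect_equal(as.numeric(p2), -0.5, tolerance = 1e-8)
  expect_error(predict(fit, tibble::tibble(red = 1)), "nir")
  # exactly one rule matches any point (partition property)
  fit2 <- model_tree(two_regime_data(), max_rules = 4, min_leaf_n = 20)
  xs <- tibble::tibble(nir = seq(0, 0.8, length.out = 101))
  expect_false(any(is.na(predict(fit2, xs))))
})

test_that("degenerate inputs are handled per contract", {
  d <- tibble::tibble(nir = runif(30), lai = 1.7)
  fit <- model_tree(d, max_rules = 5, min_leaf_n = 5)
  expect_length(fit$rules, 1)                   # constant outcome: no split
  expect_length(fit$rules[[1]]$leaf$retained, 0)  # intercept-only leaf
  expect_equal(fit$rules[[1]]$leaf$intercept, 1.7)
  expect_error(model_tree(d, max_rules = 0), "max_rules")
  expect_error(model_tree(dplyr::select(d, "lai")), "feature")
})

test_that("tidy and glance summarize the fitted rules", {
  fit <- model_tree(two_regime_data(), max_rules = 2, min_leaf_n = 20)
  td <- tidy(fit)
  expect_true(all(c("rule", "condition", "term", "estimate") %in% names(td)))
  expect_setequal(unique(td$rule), 1:2)
  gl <- glance(fit)
  expect_equal(gl$n_rules, 2)
  expect_equal(gl$n, 200)
  expect_lt(gl$train_rmse, 1e-8)
  expect_match(format(fit), "Rule 2")
})

test_that("hybrid area-fraction weights follow the closed form", {
  w <- hybrid_weights(260, 50000, 0.03)
  # w_ground = 0.03 * 50260 / 260, w_background = 0.97 * 50260 / 50000
  expect_equal(w$weight[w$group == "ground"], 0.03 * 50260 / 260,
               tolerance = 1e-12)
  expect_equal(w$weight[w$group == "background"], 0.97 * 50260 / 50000,
               tolerance = 1e-12)
  expect_equal(w$weight_share[w$group == "ground"], 0.03, tolerance = 1e-12)
  # symmetric case: both weights are 1
  w2 <- hybrid_weights(100, 100, 0.5)
  expect_equal(w2$weight, c(1, 1))
  expect_error(hybrid_weights(10, 10, 1.2), "area_fraction")
  expect_error(hybrid_weights(0, 10, 0.3), "counts")
})
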