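# Inner optimization, evidence re-estimation and the full fit loop.

test_that("inner optimization decreases F monotonely and respects budget", {
  ds <- blob_dataset(n_per_class = 40, seed = 1)
  m <- mlp_init(4, 4, seed = 1, features = colnames(ds$features))
  g <- weight_groups(4, 4, colnames(ds$features))
  alphas <- rep(0.01, length(g))
  f0 <- ard_objective(m, g, alphas, ds)
  res <- train_inner(m, g, alphas, ds, train_config(hidden_count = 4,
                                                    inner_iterations = 60,
                                                    seed = 1))
  expect_lte(res$objective, f0)
  expect_true(all(diff(res$trace) <= 0))
  expect_lte(res$iterations, 60)
  # run to convergence; restarting from that minimum barely moves F
  conv <- train_inner(res$model, g, alphas, ds,
                      train_config(hidden_count = 4,
                                   inner_iterations = 2000, seed = 1))
  res2 <- train_inner(conv$model, g, alphas, ds,
                      train_config(hidden_count = 4,
                                   inner_iterations = 2000, seed = 1))
  expect_lte(res2$objective, conv$objective)
  expect_lt(abs(res2$objective - conv$objective),
            1e-4 * (1 + abs(conv$objective)))
})

test_that("a linearly separable toy set is fit to 100% training accuracy", {
  ds <- blob_dataset(n_per_class = 25, n_features = 2, n_informative = 2,
                     separation = 4, seed = 2)
  m <- mlp_init(2, 3, seed = 2, features = colnames(ds$features))
  g <- weight_groups(2, 3, colnames(ds$features))
  res <- train_inner(m, g, rep(1e-4, length(g)), ds,
                     train_config(hidden_count = 3,
                                  inner_iterations = 200, seed = 2))
  pred <- predict_labels(res$model, ds$features)
  expect_equal(mean(pred == ds$labels), 1)
})

test_that("evidence update recovers the closed form for a diagonal Hessian", {
  # strongly curved diagonal A: inverse diagonal ~ 0, so gamma_k ~ |W(k)|
  # and alpha_k ~ |W(k)| / (2 Ew_k)
  m <- random_small_model(n = 3, hidden = 2, seed = 3)
  g <- weight_groups(3, 2)
  omega <- mlpard:::pack_weights(m)
  alphas <- rep(0.5, length(g))
  inv_diag <- rep(1e-12, length(omega)) # eigenvalues >> alpha
  up <- mlpard:::evidence_update(omega, g, alphas, inv_diag, 1e6)
  for (k in seq_along(g)) {
    wk <- length(g[[k]])
    ew <- 0.5 * sum(omega[g[[k]]]^2)
    expect_equal(up$gammas[[k]], wk, tolerance = 1e-9)
    expect_equal(up$alphas[[k]], min(wk / (2 * ew), 1e6), tolerance = 1e-6)
  }
})

test_that("an all-zero weight group gets alpha clamped to alpha_max", {
  ds <- blob_dataset(n_per_class = 20, seed = 4)
  m <- random_small_model(n = 4, hidden = 2, seed = 4)
  m$W1[, 2] <- 0 # zero out feature f2's group
  g <- weight_groups(4, 2, colnames(ds$features))
  res <- suppressMessages(
    reestimate_alphas(m, g, rep(0.1, length(g)), ds, alpha_max = 1e6))
  expect_identical(res$alphas[["f2"]], 1e6)
  expect_true(all(res$alphas > 0 & res$alphas <= 1e6))
  expect_true(all(res$gammas >= 0 & res$gammas <= lengths(g)))
})

test_that("re-estimation matches a dense explicit-inverse oracle (4-3-1)", {
  ds <- blob_dataset(n_per_class = 30, seed = 5)
  m <- mlp_init(4, 3, seed = 5, features = colnames(ds$features))
  g <- weight_groups(4, 3, colnames(ds$features))
  alphas <- rep(0.05, length(g))
  # settle near a minimum first so the exact Hessian is positive definite
  m <- train_inner(m, g, alphas, ds,
                   train_config(hidden_count = 3, inner_iterations = 150,
                                seed = 5))$model
  prod <- reestimate_alphas(m, g, alphas, ds, alpha_max = 1e6)
  # oracle: explicit dense inverse, hand-written update
  A <- ard_hessian(m, g, alphas, ds, method = "exact")
  Ainv <- solve(A)
  omega <- mlpard:::pack_weights(m)
  for (k in seq_along(g)) {
    idx <- g[[k]]
    gamma_k <- min(max(length(idx) - alphas[k] * sum(diag(Ainv)[idx]), 0),
                   length(idx))
    ew <- 0.5 * sum(omega[idx]^2)
    a_k <- min(max(if (ew <= 0) 1e6 else gamma_k / (2 * ew), 1e-8), 1e6)
    expect_equal(prod$gammas[[k]], gamma_k, tolerance = 1e-8)
    expect_equal(prod$alphas[[k]], a_k,
                 tolerance = 1e-8 * max(1, abs(a_k)))
  }
})

test_that("fit is deterministic, traces its cycles and rejects one class", {
  ds <- blob_dataset(n_per_class = 30, seed = 6)
  cfg <- train_config(hidden_count = 3, inner_iterations = 50,
                      outer_cycles = 3, seed = 6)
  f1 <- suppressMessages(mlp_ard_fit(ds, cfg))
  f2 <- suppressMessages(mlp_ard_fit(ds, cfg))
  expect_identical(mlpard:::pack_weights(f1$model),
                   mlpard:::pack_weights(f2$model))
  expect_identical(f1$alphas, f2$alphas)
  expect_true(all(c("cycle", "G", "F") %in% names(f1$trace)))
  expect_lte(nrow(f1$trace), 3)
  only1 <- mlpard:::subset_pixels(ds, which(ds$labels == 1L))
  expect_error(mlp_ard_fit(only1, cfg), "both classes")
})

test_that("alpha and group norm are inversely related after fitting", {
  # features f1, f2 informative; f3, f4 pure noise
  ds <- blob_dataset(n_per_class = 60, n_features = 4, n_informative = 2,
                     separation = 3, seed = 7)
  std <- fit_standardization(ds)
  fit <- suppressMessages(
    mlp_ard_fit(apply_standardization(std, ds),
                train_config(hidden_count = 4, inner_iterations = 80,
                             outer_cycles = 6, seed = 7)))
  feat_alphas <- fit$alphas[colnames(ds$features)]
  g <- fit$groups
  norms <- vapply(colnames(ds$features), function(f) {
    sqrt(2 * group_penalty(fit$model, g, f))
  }, numeric(1))
  expect_lt(stats::cor(feat_alphas, norms, method = "spearman"), 0)
})

test_that("model serialization round-trips bit-identically", {
  ds <- blob_dataset(n_per_class = 20, seed = 8)
  fit <- suppressMessages(
    mlp_ard_fit(ds, train_config(hidden_count = 3, inner_iterations = 30,
                                 outer_cycles = 2, seed = 8)))
  std <- fit_standardization(ds)
  path <- withr::local_tempfile(fileext = ".txt")
  save_mlp_ard(fit, path, standardization = std)
  loaded <- load_mlp_ard(path)
  expect_identical(mlpard:::pack_weights(loaded$model),
                   mlpard:::pack_weights(fit$model))
  expect_identical(loaded$alphas, fit$alphas)
  expect_identical(loaded$standardization$center, std$center)
  set.seed(9)
  X <- matrix(rnorm(20), 5, 4)
  expect_identical(mlp_forward(loaded$model, X), mlp_forward(fit$model, X))
  expect_identical(loaded$seed, fit$config$seed)
})
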