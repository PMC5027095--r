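test_that("resample plans are balanced, disjoint from positives and reproducible", {
  universe <- sprintf("g%03d", 1:100)
  pos <- universe[1:5]
  plan <- make_resample_plan(pos, universe, n_resamples = 3, master_seed = 7)
  expect_length(plan$negative_sets, 3)
  for (neg in plan$negative_sets) {
    expect_length(neg, 5)
    expect_length(intersect(neg, pos), 0)
    expect_equal(anyDuplicated(neg), 0L)
  }
  plan2 <- make_resample_plan(pos, universe, n_resamples = 3, master_seed = 7)
  expect_identical(plan$negative_sets, plan2$negative_sets)
  expect_false(identical(
    plan$negative_sets,
    make_resample_plan(pos, universe, n_resamples = 3, master_seed = 8)$negative_sets
  ))
  expect_error(
    make_resample_plan(universe[1:5], universe[1:6], n_resamples = 1),
    "cannot draw"
  )
})

test_that("the penalty path shrinks everything to zero at its largest lambda", {
  rf <- random_features(100, 8, planted = 1, seed = 2)
  labels <- rf$labels
  fit <- fit_lasso_logistic(rf$features, labels, inner_folds = 5)
  lam_max <- max(fit$cv_deviance_path$lambda)
  beta_at_max <- coef_at_lambda(fit, lam_max)[-1]
  expect_true(all(beta_at_max == 0))
  expect_setequal(fit$selected, names(fit$coefficients)[fit$coefficients != 0])
})

test_that("a noiseless label-aligned column is selected at the CV-chosen lambda", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 200
    y <- rep(c(1, 0), each = n / 2)
    cols <- list("sig.count" = (2 * y - 1)) # noiseless monotone transform of the label
    info <- list(tibble::tibble(
      column = "sig.count", dataset_id = "sig",
      feature_type = "count", assay_class = "epigenetic"
    ))
    for (j in 1:9) {
      id <- sprintf("n%02d.count", j)
      cols[[id]] <- rnorm(n)
      info[[j + 1]] <- tibble::tibble(
        column = id, dataset_id = sprintf("n%02d", j),
        feature_type = "count", assay_class = "epigenetic"
      )
    }
    f <- zscore_normalize(manual_features(
      sprintf("g%04d", 1:n), cols, dplyr::bind_rows(info)
    ))
    fit <- fit_lasso_logistic(
      f, stats::setNames(y, sprintf("g%04d", 1:n)),
      inner_folds = 10, fold_seed = s
    )
    hits <- hits + ("sig.count" %in% fit$selected)
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("the penalized fit matches a brute-force objective search at fixed lambda", {
  for (s in 1:3) {
    set.seed(s)
    n <- 20
    y <- rep(c(1, 0), each = n / 2)
    x1 <- rnorm(n) + 0.8 * y
    x2 <- rnorm(n)
    f <- zscore_normalize(manual_features(
      sprintf("g%02d", 1:n),
      list("a.count" = x1, "b.count" = x2),
      tibble::tibble(
        column = c("a.count", "b.count"), dataset_id = c("a", "b"),
        feature_type = "count", assay_class = "epigenetic"
      )
    ))
    lambda <- 0.08
    grid <- sort(c(lambda, exp(seq(log(0.6), log(0.005), length.out = 40))), decreasing = TRUE)
    fit <- fit_lasso_logistic(
      f, stats::setNames(y, sprintf("g%02d", 1:n)),
      lambda_grid = grid, inner_folds = 4, thresh = 1e-12
    )
    got <- coef_at_lambda(fit, lambda)
    x <- as.matrix(f[, c("a.count", "b.count")])
    oracle <- brute_force_lasso(x, y, lambda)
    expect_equal(unname(got), oracle$par, tolerance = 1e-3)
    expect_lt(
      abs(lasso_objective(unname(got), x, y, lambda) - oracle$value), 1e-4
    )
  }
})

test_that("at vanishing penalty the fit approaches the unpenalized logistic solution", {
  set.seed(6)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  x1 <- rnorm(n) + 0.6 * y
  x2 <- rnorm(n)
  f <- zscore_normalize(manual_features(
    sprintf("g%02d", 1:n),
    list("a.count" = x1, "b.count" = x2),
    tibble::tibble(
      column = c("a.count", "b.count"), dataset_id = c("a", "b"),
      feature_type = "count", assay_class = "epigenetic"
    )
  ))
  grid <- exp(seq(log(0.5), log(1e-5), length.out = 60))
  fit <- fit_lasso_logistic(
    f, stats::setNames(y, sprintf("g%02d", 1:n)),
    lambda_grid = grid, inner_folds = 4, thresh = 1e-12
  )
  beta <- coef_at_lambda(fit, 1e-5)
  x <- as.matrix(f[, c("a.count", "b.count")])
  glm_fit <- stats::glm(y ~ x, family = stats::binomial())
  obj_glmnet <- lasso_objective(unname(beta), x, y, lambda = 0)
  obj_glm <- lasso_objective(unname(stats::coef(glm_fit)), x, y, lambda = 0)
  expect_lt(abs(obj_glmnet - obj_glm), 1e-4)
})

test_that("signature aggregation reports exact k/n frequencies and honors the threshold", {
  rf <- random_features(120, 4, planted = 2, effect = 1.5, seed = 3)
  plan <- make_resample_plan(
    names(rf$labels)[rf$labels == 1], names(rf$labels),
    n_resamples = 8, master_seed = 2
  )
  sig <- select_signature(rf$features, plan, "combined", inner_folds = 4)
  freq <- tidy(sig, all = TRUE)$selection_frequency
  expect_true(all(abs(freq * 8 - round(freq * 8)) < 1e-12))
  expect_true(all(tidy(sig)$selection_frequency >= 0.5))
  # planted columns dominate the selection
  expect_true(all(
    rf$planted_columns %in% tidy(sig, all = TRUE)$column[
      tidy(sig, all = TRUE)$selection_frequency >= 0.5
    ]
  ))
  expect_true(all(tidy(sig)$sign[
    paste0(tidy(sig)$dataset_id, ".", tidy(sig)$feature_type) %in% rf$planted_columns
  ] == "+"))

  # identical inputs give identical signatures
  sig2 <- select_signature(rf$features, plan, "combined", inner_folds = 4)
  expect_identical(as.data.frame(sig), as.data.frame(sig2))

  # an unreachable threshold empties the signature
  sig3 <- select_signature(rf$features, plan, "combined",
    frequency_threshold = 1.01, inner_folds = 4
  )
  expect_equal(nrow(sig3), 0)
})

test_that("null data rarely puts any column above the selection threshold", {
  rf <- random_features(200, 12, planted = 0, seed = 14)
  plan <- make_resample_plan(
    names(rf$labels)[rf$labels == 1][1:40], names(rf$labels),
    n_resamples = 20, master_seed = 4
  )
  sig <- select_signature(rf$features, plan, "combined", inner_folds = 5)
  expect_lte(nrow(sig), 1)
})
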