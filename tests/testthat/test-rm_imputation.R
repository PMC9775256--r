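# A dataset in which landmark 30 is, by construction, the exact midpoint of
# landmarks 1 and 2 in every specimen. Similarity transforms and GPA
# preserve midpoints, so the relation stays exactly linear in aligned space.
make_midpoint_dataset <- function(n = 150, seed = 13) {
  model <- default_population_model(seed = seed)
  ds <- generate_dataset(model, c(Italian = n), seed = seed)
  arr <- ds$coords
  arr[30, , ] <- (arr[1, , ] + arr[2, , ]) / 2
  landmark_dataset(arr, ds$roles, ds$meta, ds$labels)
}

test_that("an exact linear relation is recovered with leave-one-out error ~ 0", {
  ds <- make_midpoint_dataset(150)
  ids <- ds$meta$specimen_id
  for (target in ids[c(3, 77)]) {
    ref <- subset_dataset(ds, setdiff(ids, target))
    g <- gpa(ref)
    model <- fit_rm(g, 30L)
    expect_equal(model$predictor_reduction, "none")
    cfg <- get_configuration(ds, target)
    imp <- impute(model, damaged_configuration(cfg, 30L))
    pred <- imp$completed$coords
    expect_lt(max(abs(pred[30, ] - (pred[1, ] + pred[2, ]) / 2)), 1e-8)
    expect_lt(procrustes_distance(cfg$coords, pred), 1e-8)
  }
})

test_that("coefficients reproduce an independent normal-equations solve", {
  ds <- make_small_dataset(14, 6)
  g <- gpa(ds)
  missing <- c(4L, 5L, 7L)
  model <- fit_rm(g, missing)
  present <- model$present_indices
  # same design convention as documented (present-gauge coordinates); the
  # oracle checks the solver, not the construction
  des <- morphorec:::rm_design(g$aligned, g$consensus, present, missing)
  X <- des$X; Y <- des$Y
  n <- nrow(X)
  # independent oracle: ridgeless normal equations on the PCA-reduced design
  # (here 3*k_present + 1 = 82 >= n = 20, so reduction applies); compare
  # fitted values instead of raw coefficients, which are basis-dependent
  fitted_pkg <- sweep(X %*% model$coefficients, 2, model$intercept, "+")
  Xc <- scale(X, scale = FALSE)
  sv <- svd(Xc)
  ncomp <- ncol(model$coefficients) # placeholder, recompute below
  cumvar <- cumsum(sv$d^2) / sum(sv$d^2)
  ncomp <- min(n - 2, which(cumvar >= 0.99)[1], sum(sv$d > sv$d[1] * 1e-10))
  S <- sv$u[, 1:ncomp] %*% diag(sv$d[1:ncomp])
  S1 <- cbind(1, S)
  beta <- solve(crossprod(S1), crossprod(S1, Y))
  fitted_oracle <- S1 %*% beta
  expect_lt(max(abs(fitted_pkg - fitted_oracle)), 1e-8)
  expect_match(model$predictor_reduction, "pca")
})

test_that("plain OLS coefficients match lm() on a full-rank design", {
  ds <- make_small_dataset(100, 50, seed = 3)
  g <- gpa(ds)
  model <- fit_rm(g, c(1L, 2L))
  expect_equal(model$predictor_reduction, "none")
  present <- model$present_indices
  des <- morphorec:::rm_design(g$aligned, g$consensus, present, c(1L, 2L))
  X <- des$X; Y <- des$Y
  fit <- stats::lm.fit(cbind(1, X), Y)
  fitted_pkg <- sweep(X %*% model$coefficients, 2, model$intercept, "+")
  expect_lt(max(abs(fitted_pkg - fit$fitted.values)), 1e-8)
})

test_that("predictor reduction engages when predictors outnumber specimens", {
  ds <- make_small_dataset(20, 10, seed = 5)
  g <- gpa(ds)
  model <- fit_rm(g, c(1L, 2L))   # 3*28 + 1 = 85 predictors > n = 30
  expect_match(model$predictor_reduction, "pca\\([0-9]+ components\\)")
  cfg <- get_configuration(ds, 1)
  imp <- impute(model, damaged_configuration(cfg, c(1L, 2L)))
  expect_true(all(is.finite(imp$completed$coords)))
})

test_that("a damaged consensus is completed onto itself", {
  model_gen <- make_constant_model()
  ds <- generate_dataset(model_gen, c(Italian = 12), seed = 6)
  g <- gpa(ds)
  model <- fit_rm(g, c(1L, 2L))
  expect_equal(model$predictor_reduction, "intercept_only")
  cfg <- landmark_config("cons", g$consensus, ds$roles)
  imp <- impute(model, damaged_configuration(cfg, c(1L, 2L)))
  expect_lt(max(abs(imp$completed$coords - g$consensus)), 1e-6)
})

test_that("imputation is equivariant under similarity motion of the input", {
  ds <- make_small_dataset(30, 10, seed = 8)
  g <- gpa(ds)
  missing <- c(16L, 17L)
  model <- fit_rm(g, missing)
  cfg <- get_configuration(ds, 4)
  base <- impute(model, damaged_configuration(cfg, missing))$completed$coords
  set.seed(10)
  for (rep in 1:3) {
    R <- random_rotation_fix()
    s <- exp(rnorm(1, sd = 0.5))
    moved <- landmark_config(cfg$specimen_id,
                             s * cfg$coords %*% R + rep(rnorm(3, sd = 40),
                                                        each = 30),
                             cfg$roles)
    pred <- impute(model, damaged_configuration(moved, missing))$completed$coords
    expect_lt(max(abs(pred - base)), 1e-8)
  }
})

test_that("the missing set of model and specimen must agree", {
  ds <- make_small_dataset(10, 5)
  g <- gpa(ds)
  model <- fit_rm(g, c(1L, 2L))
  cfg <- get_configuration(ds, 1)
  expect_error(impute(model, damaged_configuration(cfg, c(4L, 5L))),
               "does not match")
  expect_error(fit_rm(g, integer(0)), "invalid missing")
  expect_error(fit_rm(g, 1:30), "invalid missing")
})

test_that("imputation error grows with contiguous damage extent", {
  ds <- cached_default_dataset()
  sizes <- list(c(16L, 17L), 16:19, 16:21)
  set.seed(30)
  targets <- sample(ds$meta$specimen_id, 30)
  means <- numeric(3); ses <- numeric(3)
  for (i in seq_along(sizes)) {
    rec <- run_case(ds, case_definition(paste0("m", i), sizes[[i]]),
                    n_targets = 30, seed = 1, targets = targets)
    means[i] <- mean(rec$d_true_pred)
    ses[i] <- stats::sd(rec$d_true_pred) / sqrt(nrow(rec))
  }
  expect_gte(means[2], means[1] - ses[1])
  expect_gte(means[3], means[2] - ses[2])
  expect_gt(means[3], means[1])
})
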