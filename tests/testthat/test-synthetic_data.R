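test_that("the template carries the 30-landmark scheme with clustered cases", {
  tpl <- default_zygomatic_template()
  expect_equal(nrow(tpl), 30L)
  roles <- zygomatic_landmark_roles()
  expect_equal(sum(roles == "fixed"), 7L)
  expect_equal(sum(roles == "surface_semilandmark"), 23L)
  expect_gt(centroid_size(tpl), 0)
  d <- as.matrix(dist(tpl))
  # index blocks mirroring the damage cases are spatially clustered
  expect_lt(d[16, 17], d[16, 1])
  expect_lt(d[1, 2], median(d[1, ]))
  expect_lt(max(d[c(4, 5, 7), c(4, 5, 7)]), median(d[4, ]))
  expect_lt(max(d[16:21, 16:21]), d[16, 3])
})

test_that("factor loadings interpolate between translation and white modes", {
  tpl <- default_zygomatic_template()
  k <- nrow(tpl)
  # length_scale >> diameter: the first mode is (numerically) uniform, so
  # any two landmarks load identically along the shared axis
  L_big <- spatial_factor_model(tpl, m = 3, length_scale = 1e6)
  mode_x <- L_big[1:k, 1]
  expect_lt(diff(range(mode_x)) / max(abs(mode_x)), 1e-4)
  # length_scale -> 0: kernel -> identity, implied landmark correlations
  # vanish off-diagonal
  L_small <- spatial_factor_model(tpl, m = 3, length_scale = 1e-4)
  S <- L_small %*% t(L_small)
  off <- S[1:k, 1:k]; diag(off) <- 0
  expect_lt(max(abs(off)), 1e-8)
  expect_error(spatial_factor_model(tpl, m = 3 * k + 1, length_scale = 10),
               "m must be")
})

test_that("sample covariance of factor draws matches the implied covariance", {
  tpl <- default_zygomatic_template()
  k <- nrow(tpl)
  L <- spatial_factor_model(tpl, m = 8, length_scale = 15)
  sds <- 3 * 0.6^(0:7)
  Sigma <- L %*% diag(sds^2) %*% t(L)
  set.seed(42)
  Z <- matrix(rnorm(8 * 20000), 8) * sds
  X <- t(L %*% Z)
  S_hat <- crossprod(X) / nrow(X) - tcrossprod(colMeans(X))
  rel <- norm(S_hat - Sigma, "F") / norm(Sigma, "F")
  expect_lt(rel, 0.05)
})

test_that("a zero-variance model reproduces the template exactly", {
  model <- make_constant_model()
  ds <- generate_dataset(model, c(Italian = 5), nuisance = FALSE, seed = 3)
  for (i in 1:5) {
    expect_equal(unname(ds$coords[, , i]),
                 unname(default_zygomatic_template()))
  }
})

test_that("generation is reproducible under the seed", {
  model <- default_population_model()
  a <- generate_dataset(model, c(Italian = 6, AfricanAmerican = 4), seed = 9)
  b <- generate_dataset(model, c(Italian = 6, AfricanAmerican = 4), seed = 9)
  cc <- generate_dataset(model, c(Italian = 6, AfricanAmerican = 4), seed = 10)
  expect_identical(a$coords, b$coords)
  expect_identical(a$meta, b$meta)
  expect_false(identical(a$coords, cc$coords))
  expect_error(generate_dataset(model, c(Martian = 5)), "unknown population")
})

test_that("nuisance transforms do not alter the shapes drawn", {
  model <- default_population_model()
  with_n <- generate_dataset(model, c(Italian = 8), nuisance = TRUE, seed = 4)
  without <- generate_dataset(model, c(Italian = 8), nuisance = FALSE, seed = 4)
  for (i in 1:8) {
    expect_lt(procrustes_distance(with_n$coords[, , i], without$coords[, , i]),
              1e-8)
  }
})

test_that("GPA of generated data recovers the generating mean shape", {
  # heuristic consensus-error bound ~ noise / sqrt(n), checked empirically
  tpl <- default_zygomatic_template()
  k <- nrow(tpl)
  cs <- centroid_size(tpl)
  L <- spatial_factor_model(tpl, m = 8, length_scale = 15)
  sigma <- 0.005 * cs
  model <- population_model(tpl, L, factor_sd = 3 * 0.6^(0:7),
                            noise_sd = sigma,
                            population_offsets = list(Italian = numeric(3 * k)),
                            size_log_sd = 0.05, noise_log_sd = 0)
  bound <- 3 * (sigma / cs) * sqrt(3 * k) / sqrt(150)
  for (r in 1:20) {
    ds <- generate_dataset(model, c(Italian = 150), seed = 500 + r)
    g <- gpa(ds)
    expect_lt(procrustes_distance(g$consensus, tpl), bound)
  }
})

test_that("aligned-shape covariance converges to the projected model covariance", {
  # GPA removes the similarity directions, so the comparison is made after
  # projecting the implied covariance off the similarity tangent space
  tpl <- default_zygomatic_template()
  k <- nrow(tpl)
  cs <- centroid_size(tpl)
  L <- spatial_factor_model(tpl, m = 8, length_scale = 15)
  sds <- 1.5 * 0.6^(0:7)
  model <- population_model(tpl, L, factor_sd = sds, noise_sd = 0,
                            population_offsets = list(Italian = numeric(3 * k)),
                            size_log_sd = 0, noise_log_sd = 0)
  ds <- generate_dataset(model, c(Italian = 5000), nuisance = FALSE, seed = 21)
  g <- gpa(ds, tol = 1e-8, max_iter = 50)
  # rotate the aligned sample onto the template frame and restore scale
  fit <- opa_superimpose(g$consensus, scale(tpl, scale = FALSE) / cs)
  X <- t(apply(g$aligned, 3, function(s) as.vector(cs * s %*% fit$rotation)))
  S_hat <- stats::cov(X) * (nrow(X) - 1) / nrow(X)
  # similarity tangent space at the (centered) template: translations,
  # infinitesimal rotations, scaling
  tc <- scale(tpl, scale = FALSE)
  basis <- cbind(
    as.vector(cbind(rep(1, k), 0, 0)), as.vector(cbind(0, rep(1, k), 0)),
    as.vector(cbind(0, 0, rep(1, k))),
    as.vector(cbind(-tc[, 2], tc[, 1], 0)), as.vector(cbind(-tc[, 3], 0, tc[, 1])),
    as.vector(cbind(0, -tc[, 3], tc[, 2])), as.vector(tc))
  Q <- qr.Q(qr(basis))
  P <- diag(3 * k) - Q %*% t(Q)
  Sigma_proj <- P %*% (L %*% diag(sds^2) %*% t(L)) %*% P
  rel <- norm(P %*% S_hat %*% P - Sigma_proj, "F") / norm(Sigma_proj, "F")
  expect_lt(rel, 0.10)
})
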