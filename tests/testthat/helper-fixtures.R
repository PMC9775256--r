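# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; nothing is read from disk except files the tests write
# themselves.

withr_tempfile <- function(fileext = "") tempfile(fileext = fileext)

# Small complete dataset built from the default generator.
make_small_dataset <- function(n_italian = 20, n_aa = 10, seed = 7,
                               nuisance = TRUE) {
  model <- default_population_model(seed = seed)
  n_per <- c(Italian = n_italian, AfricanAmerican = n_aa)
  generate_dataset(model, n_per[n_per > 0], nuisance = nuisance, seed = seed)
}

# A noiseless model: every specimen equals the template exactly.
make_constant_model <- function() {
  template <- default_zygomatic_template()
  k <- nrow(template)
  L <- spatial_factor_model(template, m = 2L, length_scale = 20)
  population_model(template, L, factor_sd = c(0, 0), noise_sd = 0,
                   population_offsets = list(Italian = numeric(3 * k)),
                   size_log_sd = 0, noise_log_sd = 0)
}

# Random proper rotation from a seeded RNG stream.
random_rotation_fix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Apply a random similarity transform (proper rotation + scale + translation)
# to every configuration of a dataset.
apply_random_similarity <- function(ds, seed) {
  arr <- ds$coords
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    for (i in seq_len(dim(arr)[3])) {
      R <- random_rotation_fix()
      s <- exp(rnorm(1, sd = 0.3))
      tr <- rnorm(3, sd = 50)
      arr[, , i] <- s * arr[, , i] %*% R + rep(tr, each = dim(arr)[1])
    }
  })
  landmark_dataset(arr, ds$roles, ds$meta, ds$labels)
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation from an angle-axis vector.
rodrigues <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  a <- w / th
  Kx <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * Kx + (1 - cos(th)) * (Kx %*% Kx)
}

# Independent brute-force superimposition oracle: minimize the residual over
# rotations (angle-axis parameterization) with closed-form optimal scale and
# translation, from many random starts plus local refinement.
brute_force_opa_residual <- function(source, target, allow_scale = TRUE,
                                     n_starts = 40) {
  Xc <- scale(source, scale = FALSE)
  Yc <- scale(target, scale = FALSE)
  resid_fn <- function(w) {
    R <- rodrigues(w)
    XR <- Xc %*% R
    # scale constrained non-negative: a negative scale with a proper
    # rotation would be an improper (reflecting) fit
    s <- if (allow_scale) max(0, sum(XR * Yc) / sum(XR^2)) else 1
    sum((s * XR - Yc)^2)
  }
  best <- Inf
  for (st in seq_len(n_starts)) {
    w0 <- runif(3, -pi, pi)
    opt <- optim(w0, resid_fn, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-14))
    if (opt$value < best) best <- opt$value
  }
  sqrt(max(0, best))
}

# Memoized expensive study runs shared across test files.
.study_cache <- new.env(parent = emptyenv())

cached_default_study <- function() {
  if (is.null(.study_cache$full)) {
    model <- default_population_model(seed = 7)
    ds <- generate_dataset(model, c(Italian = 119, AfricanAmerican = 31))
    .study_cache$full_dataset <- ds
    .study_cache$full <- run_study(ds, n_targets = 30, seed = 42)
  }
  .study_cache$full
}

cached_default_dataset <- function() {
  invisible(cached_default_study())
  .study_cache$full_dataset
}
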