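# Regression-based (RM) imputation of missing landmark coordinates: each
# missing coordinate is regressed on all present coordinates across the
# aligned, undamaged reference sample; the fitted model predicts the missing
# landmarks of a damaged specimen after superimposing its present landmarks
# onto the reference consensus.

# Regression design. Every reference specimen is re-superimposed onto the
# consensus BY ITS PRESENT SUBSET (full similarity OPA) before the design
# is built, and coordinates are expressed relative to the present-landmark
# centroid. A damaged specimen can only ever be aligned on its present
# landmarks, which places it in a different location/rotation gauge than
# full-configuration GPA puts the training sample; training in the
# prediction gauge makes every exact linear dependency of the training
# design one that prediction inputs satisfy too, so exact linear structure
# in the data is predicted exactly.
rm_design <- function(aligned, consensus, present, missing) {
  n <- dim(aligned)[3]
  k <- dim(aligned)[1]
  target_p <- consensus[present, , drop = FALSE]
  X <- matrix(NA_real_, n, 3L * length(present))
  Y <- matrix(NA_real_, n, 3L * length(missing))
  for (i in seq_len(n)) {
    fit <- opa_superimpose(aligned[present, , i, drop = FALSE][, , 1], target_p,
                           allow_scale = TRUE, specimen_id = i)
    full <- fit$scale * aligned[, , i] %*% fit$rotation +
      rep(fit$translation, each = k)
    pc <- colMeans(full[present, , drop = FALSE])
    X[i, ] <- as.vector(full[present, , drop = FALSE] -
                          rep(pc, each = length(present)))
    Y[i, ] <- as.vector(full[missing, , drop = FALSE] -
                          rep(pc, each = length(missing)))
  }
  list(X = X, Y = Y)
}

#' Mark landmarks of a configuration as missing
#'
#' @param config a \code{landmark_config} with full (true) coordinates.
#' @param missing_indices non-empty proper subset of 1-based landmark
#'   indices whose coordinates are to be treated as unknown.
#' @return object of class \code{damaged_configuration}.
#' @export
damaged_configuration <- function(config, missing_indices) {
  k <- nrow(config$coords)
  missing_indices <- sort(unique(as.integer(missing_indices)))
  if (length(missing_indices) == 0L) stop("missing set must be non-empty")
  if (any(missing_indices < 1L | missing_indices > k)) {
    stop("missing indices out of range 1..", k)
  }
  if (length(missing_indices) >= k) stop("missing set must be a proper subset")
  present <- setdiff(seq_len(k), missing_indices)
  if (length(present) < 3L) stop("need at least 3 present landmarks")
  sv <- svd(center_coords(config$coords[present, , drop = FALSE]))$d
  if (sv[2] < max(sv[1], 1) * 1e-12) {
    stop("present landmarks are collinear; superimposition impossible")
  }
  structure(list(base = config, missing_indices = missing_indices),
            class = "damaged_configuration")
}

#' Fit the RM model on an aligned reference sample
#'
#' Ordinary least squares (with intercept) of every missing coordinate on
#' all present coordinates of the reference's GPA-aligned (and typically
#' slid) shapes, solved by singular value decomposition of the centered
#' design. Covariates and responses are expressed relative to each
#' specimen's present-landmark centroid, so that training and prediction
#' inputs share the same exact design dependencies (see the package
#' vignette). When the predictor count \code{3 k_present + 1} reaches the
#' reference size, predictors are reduced to principal-component scores
#' retaining \code{min(n - 2, components explaining 99\% of variance)};
#' the reduction applied is recorded in \code{predictor_reduction}. A
#' zero-variance design degrades to an intercept-only model (prediction =
#' consensus coordinates).
#'
#' @param reference a \code{gpa_result} for the undamaged reference sample
#'   (post-sliding), with at least 10 specimens.
#' @param missing_indices 1-based indices of the landmarks to be predicted.
#' @return object of class \code{rm_model} with fields
#'   \code{reference_consensus}, \code{present_indices},
#'   \code{missing_indices}, \code{coefficients} (\code{3 k_p x 3 k_m}),
#'   \code{intercept}, \code{predictor_reduction}, \code{n_reference}.
#' @export
fit_rm <- function(reference, missing_indices) {
  stopifnot(inherits(reference, "gpa_result"))
  aligned <- reference$aligned
  k <- dim(aligned)[1]; n <- dim(aligned)[3]
  if (n < 10L) stop("reference sample too small (n < 10)")
  missing_indices <- sort(unique(as.integer(missing_indices)))
  if (length(missing_indices) == 0L || length(missing_indices) >= k ||
      any(missing_indices < 1L | missing_indices > k)) {
    stop("invalid missing index set")
  }
  present <- setdiff(seq_len(k), missing_indices)
  design <- rm_design(aligned, reference$consensus, present, missing_indices)
  X <- design$X; Y <- design$Y
  xbar <- colMeans(X); ybar <- colMeans(Y)
  Xc <- sweep(X, 2L, xbar); Yc <- sweep(Y, 2L, ybar)
  sv <- svd(Xc)
  # relative cutoff plus an absolute floor: aligned shapes are unit-size,
  # so design variation below ~1e-8 is GPA numerical residue, not signal
  rank <- sum(sv$d > max(sv$d[1] * 1e-10, sqrt(n) * 1e-8))
  p <- ncol(X)
  if (rank == 0L) {
    W <- matrix(0, p, ncol(Y))
    reduction <- "intercept_only"
  } else {
    if (p + 1L >= n) {
      cumvar <- cumsum(sv$d^2) / sum(sv$d^2)
      j99 <- which(cumvar >= 0.99)[1]
      ncomp <- min(n - 2L, j99, rank)
      reduction <- sprintf("pca(%d components)", ncomp)
    } else {
      ncomp <- rank
      reduction <- "none"
    }
    idx <- seq_len(ncomp)
    # OLS of Yc on scores U D: coef = D^-1 U' Yc; map back to x-space via V.
    coef_scores <- (t(sv$u[, idx, drop = FALSE]) %*% Yc) / sv$d[idx]
    W <- sv$v[, idx, drop = FALSE] %*% coef_scores
  }
  structure(list(reference_consensus = reference$consensus,
                 present_indices = present, missing_indices = missing_indices,
                 coefficients = W,
                 intercept = ybar - drop(xbar %*% W),
                 predictor_reduction = reduction,
                 n_reference = n,
                 roles = reference$roles),
            class = "rm_model")
}

#' Impute missing landmarks of a damaged configuration
#'
#' (1) Superimposes the damaged specimen's present landmarks onto the
#' corresponding subset of the reference consensus (full similarity OPA,
#' with scaling); (2) feeds the aligned present coordinates to the fitted
#' regression; (3) inserts the predicted coordinates. The completed
#' configuration is returned in reference-consensus space together with the
#' transform used, so it can be mapped back to original specimen space.
#'
#' @param model an \code{rm_model}.
#' @param damaged a \code{damaged_configuration} whose missing set equals
#'   the model's.
#' @return list with \code{completed} (a \code{landmark_config} in consensus
#'   space) and \code{alignment} (rotation, scale, translation such that
#'   \code{consensus_space = scale * original \%*\% rotation + translation}).
#' @export
impute <- function(model, damaged) {
  stopifnot(inherits(model, "rm_model"),
            inherits(damaged, "damaged_configuration"))
  if (!identical(model$missing_indices, damaged$missing_indices)) {
    stop("missing set of the damaged configuration does not match the model")
  }
  present <- model$present_indices
  P <- damaged$base$coords[present, , drop = FALSE]
  fit <- opa_superimpose(P, model$reference_consensus[present, , drop = FALSE],
                         allow_scale = TRUE,
                         specimen_id = damaged$base$specimen_id)
  pc <- colMeans(fit$aligned)
  xvec <- as.vector(fit$aligned - rep(pc, each = nrow(fit$aligned)))
  km <- length(model$missing_indices)
  pred <- matrix(drop(xvec %*% model$coefficients) + model$intercept,
                 km, 3L) + rep(pc, each = km)
  k <- nrow(damaged$base$coords)
  completed <- matrix(NA_real_, k, 3L)
  completed[present, ] <- fit$aligned
  completed[model$missing_indices, ] <- pred
  cfg <- landmark_config(damaged$base$specimen_id, completed,
                         damaged$base$roles, damaged$base$population,
                         damaged$base$sex, damaged$base$side)
  list(completed = cfg,
       alignment = list(rotation = fit$rotation, scale = fit$scale,
                        translation = fit$translation))
}
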