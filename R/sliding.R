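# Thin-plate-spline bending energy and tangent-plane sliding of surface
# semilandmarks.

#' Thin-plate-spline bending energy matrix
#'
#' Builds the k x k bending energy quadratic form of the 3D thin-plate
#' spline anchored on a reference configuration: the kernel matrix uses
#' U(r) = r with the sign convention that makes the form positive
#' semidefinite (kernel block -||p_i - p_j||), bordered by the affine block
#' \code{[1 | p]}; the upper-left k x k block of the inverse bordered system
#' is returned. Affine displacement fields lie in its null space.
#'
#' @param reference numeric \code{k x 3} matrix without duplicate landmarks.
#' @return list with \code{matrix} (k x k symmetric PSD) and
#'   \code{reference}.
#' @export
bending_energy_matrix <- function(reference) {
  p <- as.matrix(reference)
  k <- nrow(p)
  if (k < 5L) stop("bending energy needs at least 5 landmarks")
  D <- as.matrix(stats::dist(p))
  dup <- which(D < 1e-10 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup) > 0L) {
    stop("duplicate landmarks (singular TPS system): indices ",
         paste(apply(dup, 1L, paste, collapse = "/"), collapse = ", "))
  }
  K <- -D                       # CPD form of the 3D kernel U(r) = r
  Q <- cbind(1, p)              # k x 4 affine block
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4L, 4L)))
  Linv <- solve(L)
  B <- Linv[seq_len(k), seq_len(k)]
  B <- (B + t(B)) / 2
  list(matrix = B, reference = p)
}

#' Bending energy of a displacement field
#'
#' \code{trace(V' B V)}: the TPS quadratic form applied independently per
#' coordinate axis and summed.
#'
#' @param B bending energy matrix (k x k) or the list returned by
#'   \code{\link{bending_energy_matrix}}.
#' @param V numeric \code{k x 3} displacement field.
#' @return non-negative scalar (up to numerical tolerance).
#' @export
bending_energy <- function(B, V) {
  if (is.list(B)) B <- B$matrix
  sum(V * (B %*% V))
}

#' Estimate tangent planes at surface semilandmarks
#'
#' For each surface semilandmark, fits a plane through the centroid of the
#' landmark and its nearest neighbors (minimizing orthogonal residual, i.e.
#' the two leading principal axes of the local cloud) and returns two
#' orthonormal in-plane vectors. A collinear neighborhood falls back to a
#' doubled neighborhood before erroring.
#'
#' @param coords numeric \code{k x 3} matrix.
#' @param roles per-landmark roles; frames are estimated only where the role
#'   is \code{"surface_semilandmark"}.
#' @param neighbors number of nearest landmarks used (>= 4).
#' @return list with \code{semi_indices} (1-based) and \code{frames}, a
#'   \code{3 x 2 x n_semi} array of orthonormal tangent vectors.
#' @export
estimate_tangent_frames <- function(coords, roles, neighbors = 8L) {
  coords <- as.matrix(coords)
  if (neighbors < 4L) stop("neighbors must be >= 4")
  semi <- which(roles == "surface_semilandmark")
  if (length(semi) == 0L) stop("no surface semilandmarks in roles")
  nb <- neighbor_sets(coords, semi, neighbors)
  frames_from_neighbors(coords, semi, nb)
}

# Nearest-landmark neighbor sets (including the landmark itself) for each
# surface semilandmark; primary and doubled fallback sizes.
neighbor_sets <- function(coords, semi, neighbors) {
  k <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  lapply(semi, function(lm) {
    o <- order(D[lm, ])
    list(primary = o[seq_len(min(neighbors, k - 1L) + 1L)],
         fallback = o[seq_len(min(2L * neighbors, k - 1L) + 1L)])
  })
}

# Plane fit (two leading principal axes of the centered local cloud) for
# each semilandmark given precomputed neighbor sets.
frames_from_neighbors <- function(coords, semi, nb) {
  frames <- array(NA_real_, c(3L, 2L, length(semi)))
  for (j in seq_along(semi)) {
    ok <- FALSE
    for (idx in nb[[j]]) {
      cloud <- coords[idx, , drop = FALSE]
      cloud <- cloud - rep(colMeans(cloud), each = nrow(cloud))
      sv <- svd(cloud, nu = 0L)
      if (sv$d[2] > max(sv$d[1], 1e-300) * 1e-8) {
        frames[, , j] <- sv$v[, 1:2]
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("degenerate (collinear) neighborhood at landmark ", semi[j])
  }
  list(semi_indices = semi, frames = frames)
}

#' Slide surface semilandmarks to minimize bending energy
#'
#' Iteratively slides each specimen's surface semilandmarks within their
#' estimated tangent planes so as to minimize the thin-plate-spline bending
#' energy of the specimen's displacement from the current consensus. Each
#' iteration: (1) build the bending energy matrix on the consensus; (2) for
#' every specimen solve the exact linear least-squares problem for the
#' tangent offsets (fixed landmarks never move); (3) optionally re-run GPA
#' and recompute the consensus. The reported total energy never increases
#' across iterations: an iteration that would raise it (possible only through
#' the consensus/kernel update) is rejected and sliding stops.
#'
#' @param gpa_result a converged \code{\link{gpa}} result.
#' @param iterations maximum sliding iterations (default 3).
#' @param neighbors tangent-plane neighborhood size (default 8); frames are
#'   estimated on each specimen's own aligned coordinates.
#' @param ridge relative ridge added to a numerically singular tangent system
#'   (with a warning); default 1e-8.
#' @param tol early stop when the relative energy decrease within an
#'   iteration falls below this (default 1e-6).
#' @param recompute_gpa re-superimpose after each sliding pass (default
#'   \code{TRUE}); set \code{FALSE} to inspect the pure sliding step.
#' @return an updated \code{gpa_result} with an \code{energy_trace} data
#'   frame (iteration, energy_before, energy_after).
#' @export
slide_semilandmarks <- function(gpa_result, iterations = 3L, neighbors = 8L,
                                ridge = 1e-8, tol = 1e-6,
                                recompute_gpa = TRUE) {
  stopifnot(inherits(gpa_result, "gpa_result"))
  aligned <- gpa_result$aligned
  consensus <- gpa_result$consensus
  roles <- gpa_result$roles
  n <- dim(aligned)[3]
  trace <- data.frame(iteration = integer(0), energy_before = numeric(0),
                      energy_after = numeric(0))
  # Frames are estimated once, on each specimen's own input aligned
  # coordinates; per-iteration sliding displacements are far smaller than
  # the neighborhoods the planes are fitted to. Neighbor identity is taken
  # from the consensus (all aligned specimens are small deviations of it).
  semi <- which(roles == "surface_semilandmark")
  if (length(semi) == 0L) stop("no surface semilandmarks to slide")
  nb <- neighbor_sets(consensus, semi, neighbors)
  frames <- lapply(seq_len(n), function(i)
    frames_from_neighbors(aligned[, , i], semi, nb))
  prev_energy <- Inf
  for (it in seq_len(iterations)) {
    B <- bending_energy_matrix(consensus)$matrix
    e_before <- sum(vapply(seq_len(n), function(i)
      bending_energy(B, aligned[, , i] - consensus), numeric(1)))
    new_aligned <- aligned
    for (i in seq_len(n)) {
      new_aligned[, , i] <- slide_one(aligned[, , i], consensus, B,
                                      frames[[i]], ridge)
    }
    e_after <- sum(vapply(seq_len(n), function(i)
      bending_energy(B, new_aligned[, , i] - consensus), numeric(1)))
    if (e_after > prev_energy * (1 + 1e-9)) break  # reject energy increase
    trace <- rbind(trace, data.frame(iteration = it, energy_before = e_before,
                                     energy_after = e_after))
    aligned <- new_aligned
    prev_energy <- e_after
    if (recompute_gpa) {
      g <- gpa(aligned, tol = 1e-10, max_iter = 100L)
      aligned <- g$aligned
      consensus <- g$consensus
    } else {
      consensus <- gpa_result$consensus
    }
    if (e_before > 0 && (e_before - e_after) / e_before < tol) break
  }
  out <- gpa_result
  out$aligned <- aligned
  out$consensus <- consensus
  out$energy_trace <- trace
  out
}

#' Map a new specimen into a slid reference space
#'
#' Superimposes a complete configuration onto a reference consensus (full
#' similarity OPA) and slides its surface semilandmarks to minimize the
#' thin-plate-spline bending energy of its displacement from that consensus,
#' re-superimposing after each pass. This applies the same standardization
#' to an out-of-sample specimen that \code{\link{slide_semilandmarks}}
#' applies to the sample it was fitted on, without the specimen influencing
#' the reference in any way.
#'
#' @param coords numeric \code{k x 3} configuration.
#' @param consensus reference consensus (\code{k x 3}, unit centroid size).
#' @param roles per-landmark roles.
#' @param iterations,neighbors,ridge as in \code{\link{slide_semilandmarks}}.
#' @return the aligned, slid \code{k x 3} coordinates (consensus space).
#' @export
slide_to_reference <- function(coords, consensus, roles, iterations = 3L,
                               neighbors = 8L, ridge = 1e-8) {
  X <- opa_superimpose(coords, consensus, allow_scale = TRUE)$aligned
  if (iterations < 1L) return(X)
  B <- bending_energy_matrix(consensus)$matrix
  semi <- which(roles == "surface_semilandmark")
  if (length(semi) == 0L) stop("no surface semilandmarks to slide")
  nb <- neighbor_sets(consensus, semi, neighbors)
  fr <- frames_from_neighbors(X, semi, nb)
  for (it in seq_len(iterations)) {
    X <- slide_one(X, consensus, B, fr, ridge)
    X <- opa_superimpose(X, consensus, allow_scale = TRUE)$aligned
  }
  X
}

# One specimen's sliding step: minimize bending energy of (X - C + U t) over
# tangent offsets t, where U stacks the tangent directions of the surface
# semilandmarks. Exploits B~ = I_3 (x) B:
#   (U' B~ U)_{jl} = B[a_j, a_l] * (d_j . d_l),  (U' B~ y)_j = d_j . (B Y)[a_j, ]
slide_one <- function(X, C, B, tf, ridge) {
  semi <- tf$semi_indices
  m2 <- 2L * length(semi)
  la <- rep(semi, each = 2L)                       # landmark of each column
  Dir <- matrix(0, 3L, m2)                         # direction of each column
  Dir[, seq(1L, m2, 2L)] <- tf$frames[, 1L, ]
  Dir[, seq(2L, m2, 2L)] <- tf$frames[, 2L, ]
  M <- B[la, la] * crossprod(Dir)
  BY <- B %*% (X - C)
  rhs <- colSums(Dir * t(BY[la, , drop = FALSE]))
  t_off <- tryCatch(solve(M, -rhs), error = function(e) {
    warning("singular tangent system; ridge-regularizing (epsilon = ",
            format(ridge), " * mean diagonal)")
    solve(M + diag(ridge * mean(diag(M)), m2), -rhs)
  })
  shift <- Dir %*% diag(t_off, m2)
  out <- X
  for (j in seq_along(semi)) {
    out[semi[j], ] <- out[semi[j], ] +
      shift[, 2L * j - 1L] + shift[, 2L * j]
  }
  out
}
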