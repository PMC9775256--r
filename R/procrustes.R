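# Ordinary and generalized Procrustes analysis, centroid size, and
# Procrustes distances.

#' Centroid size of a configuration
#'
#' Square root of the summed squared deviations of the landmarks from their
#' centroid — the standard size measure removed by Procrustes scaling.
#'
#' @param coords numeric \code{k x 3} matrix (k >= 2).
#' @return positive scalar; 0 with a warning when all landmarks coincide.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("centroid size needs at least 2 landmarks")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  cs <- sqrt(sum(sweep(coords, 2L, colMeans(coords))^2))
  if (cs == 0) warning("degenerate shape: all landmarks coincident")
  cs
}

# Centered coordinates.
center_coords <- function(coords) {
  coords - rep(colMeans(coords), each = nrow(coords))
}

# Optimal proper rotation R (3x3) minimizing ||X %*% R - Y||_F for centered
# X, Y. Kabsch/SVD solution with the determinant forced to +1 (reflections
# are never introduced; antimeres are handled explicitly upstream).
kabsch_rotation <- function(Xc, Yc) {
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$u) * det(s$v))
  list(rotation = s$u %*% diag(c(1, 1, d)) %*% t(s$v),
       trace = sum(s$d * c(1, 1, d)))
}

#' Ordinary Procrustes superimposition of one configuration onto another
#'
#' Least-squares rigid (optionally with scale) superimposition via the SVD
#' solution; the rotation is always proper (determinant +1).
#'
#' @param source,target numeric \code{k x 3} matrices with the same k.
#' @param allow_scale if \code{TRUE} (default) a uniform scale is fitted.
#' @param specimen_id label used in error messages for degenerate inputs.
#' @return list with \code{aligned} (transformed source), \code{rotation},
#'   \code{scale}, \code{translation} (so that
#'   \code{aligned = scale * source \%*\% rotation + translation}, row-wise),
#'   and \code{residual} = sqrt(sum((aligned - target)^2)).
#' @export
opa_superimpose <- function(source, target, allow_scale = TRUE,
                            specimen_id = "source") {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!identical(dim(source), dim(target))) stop("dimension mismatch")
  cx <- colMeans(source); cy <- colMeans(target)
  Xc <- sweep(source, 2L, cx); Yc <- sweep(target, 2L, cy)
  sv <- svd(Xc)$d
  if (sv[2] < max(sv[1], 1) * 1e-12) {
    stop("degenerate (rank < 2) configuration: ", specimen_id)
  }
  kb <- kabsch_rotation(Xc, Yc)
  s <- if (allow_scale) kb$trace / sum(Xc^2) else 1
  translation <- cy - s * drop(cx %*% kb$rotation)
  aligned <- s * Xc %*% kb$rotation + rep(cy, each = nrow(Xc))
  list(aligned = aligned, rotation = kb$rotation, scale = s,
       translation = translation,
       residual = sqrt(sum((aligned - target)^2)))
}

#' Generalized Procrustes analysis
#'
#' Standardizes a sample of configurations by location, rotation and scale.
#' All configurations are centered and scaled to unit centroid size; the
#' consensus is initialized as the first specimen and the sample is
#' iteratively rotated onto it, the consensus recomputed as the renormalized
#' coordinate-wise mean, until the Procrustes distance between successive
#' consensus shapes falls below \code{tol}.
#'
#' @param x a \code{landmark_dataset} or a \code{k x 3 x n} array (n >= 2).
#' @param tol convergence tolerance on the consensus change (default 1e-10).
#' @param max_iter iteration cap; non-convergence returns a result with
#'   \code{converged = FALSE} and a warning.
#' @return object of class \code{gpa_result}: \code{aligned}
#'   (\code{k x 3 x n}, each centered with unit centroid size),
#'   \code{consensus} (\code{k x 3}, unit size), \code{centroid_sizes}
#'   (original scales), \code{iterations}, \code{final_change},
#'   \code{converged}, plus \code{roles}/\code{meta}/\code{labels} carried
#'   over from the dataset.
#' @export
gpa <- function(x, tol = 1e-10, max_iter = 100L) {
  if (inherits(x, "landmark_dataset")) {
    arr <- x$coords; roles <- x$roles; meta <- x$meta; labels <- x$labels
  } else {
    arr <- x
    roles <- zygomatic_landmark_roles(dim(arr)[1], min(7L, dim(arr)[1]))
    meta <- NULL; labels <- NULL
  }
  if (length(dim(arr)) != 3L || dim(arr)[3] < 2L) {
    stop("GPA needs at least 2 configurations")
  }
  k <- dim(arr)[1]; n <- dim(arr)[3]
  sizes <- numeric(n)
  aligned <- array(0, dim(arr), dimnames = dimnames(arr))
  for (i in seq_len(n)) {
    Xc <- center_coords(arr[, , i])
    sizes[i] <- sqrt(sum(Xc^2))
    if (sizes[i] == 0) stop("degenerate (zero-size) configuration ", i)
    aligned[, , i] <- Xc / sizes[i]
  }
  consensus <- aligned[, , 1]
  change <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      kb <- kabsch_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% kb$rotation
    }
    new_consensus <- rowMeans(aligned, dims = 2L)
    new_consensus <- center_coords(new_consensus)
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    # partial Procrustes distance between successive (unit-size) consensuses
    kb <- kabsch_rotation(consensus, new_consensus)
    change <- sqrt(sum((consensus %*% kb$rotation - new_consensus)^2))
    consensus <- new_consensus
    if (change < tol) break
  }
  converged <- change < tol
  if (!converged) warning("GPA did not converge within ", max_iter, " iterations")
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = sizes, iterations = iter,
                 final_change = change, converged = converged,
                 roles = roles, meta = meta, labels = labels),
            class = "gpa_result")
}

#' @export
print.gpa_result <- function(x, ...) {
  cat(sprintf("gpa_result: %d specimens, %d landmarks; %d iterations, final change %.2e%s\n",
              dim(x$aligned)[3], dim(x$aligned)[1], x$iterations,
              x$final_change, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' In \code{pairwise_opa} mode (the partial Procrustes distance used for all
#' accuracy reporting) both configurations are centered, scaled to unit
#' centroid size and optimally rotated onto each other; the root summed
#' squared difference is returned. In \code{common_space} mode the plain root
#' summed squared difference of already-aligned coordinates is returned.
#'
#' @param a,b numeric \code{k x 3} matrices with equal k.
#' @param mode \code{"pairwise_opa"} (default) or \code{"common_space"}.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b, mode = c("pairwise_opa", "common_space")) {
  mode <- match.arg(mode)
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) stop("dimension mismatch")
  if (mode == "common_space") return(sqrt(sum((a - b)^2)))
  Ac <- center_coords(a); Bc <- center_coords(b)
  sa <- sqrt(sum(Ac^2)); sb <- sqrt(sum(Bc^2))
  if (sa == 0 || sb == 0) stop("degenerate (zero-size) configuration")
  Ac <- Ac / sa; Bc <- Bc / sb
  kb <- kabsch_rotation(Ac, Bc)
  # explicit residual (not 2 - 2 tr) to avoid cancellation near zero
  sqrt(sum((Ac %*% kb$rotation - Bc)^2))
}
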