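# Principal coordinates analysis of between-assemblage distance matrices.

#' Principal coordinates analysis (classical scaling)
#'
#' Embeds a symmetric distance matrix into Euclidean coordinates via
#' [stats::cmdscale()] (Gower double-centering of -d^2/2 followed by a
#' symmetric eigendecomposition). Axes are retained for positive eigenvalues
#' only; per-axis variance explained is the eigenvalue divided by the sum of
#' *positive* eigenvalues. Nearest-taxon distances between nested
#' assemblages are typically non-Euclidean, producing negative eigenvalues:
#' no Cailliez/Lingoes correction is applied — they are dropped from the
#' coordinates and their total magnitude reported as
#' `negative_eigenvalue_mass`, matching the default behaviour of classical
#' scaling routines. For reproducibility each axis's sign is fixed so its
#' largest-magnitude coordinate is positive.
#'
#' @param adm symmetric non-negative distance matrix with zero diagonal
#'   (e.g. from [assemblage_distance_matrix()]), or a `dist`.
#' @return A `pcoa_result`: list with `eigenvalues` (all, descending),
#'   `coordinates` (points x retained axes, rownames preserved),
#'   `variance_explained` (fraction per retained axis, sums to <= 1) and
#'   `negative_eigenvalue_mass`.
#' @export
pcoa <- function(adm) {
  if (inherits(adm, "dist")) adm <- as.matrix(adm)
  stopifnot(is.matrix(adm))
  n <- nrow(adm)
  if (n < 2L) stop("PCoA needs at least 2 points", call. = FALSE)
  if (!isSymmetric(unname(adm), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(adm < 0)) stop("distances must be non-negative", call. = FALSE)
  adm <- (adm + t(adm)) / 2

  fit <- suppressWarnings(stats::cmdscale(adm, k = n - 1L, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- max(abs(eig), 0) * 1e-8
  pos <- which(eig > tol)

  pts <- fit$points
  if (length(pos)) {
    pts <- pts[, seq_along(pos), drop = FALSE]
    # sign convention: largest-|coordinate| entry positive on each axis
    for (j in seq_len(ncol(pts))) {
      m <- which.max(abs(pts[, j]))
      if (pts[m, j] < 0) pts[, j] <- -pts[, j]
    }
    colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  } else {
    pts <- matrix(0, nrow = n, ncol = 0L, dimnames = list(rownames(adm), NULL))
  }
  rownames(pts) <- rownames(adm)

  structure(list(
    eigenvalues = eig,
    coordinates = pts,
    variance_explained = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(0),
    negative_eigenvalue_mass = sum(abs(eig[eig < -tol]))
  ), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- ncol(x$coordinates)
  cat(sprintf("PCoA: %d points, %d retained axes\n", nrow(x$coordinates), k))
  if (k) {
    ve <- round(100 * x$variance_explained, 1)
    cat("  variance explained (%):", paste(ve, collapse = ", "), "\n")
  }
  if (x$negative_eigenvalue_mass > 0)
    cat(sprintf("  negative eigenvalue mass: %.4g (non-Euclidean input)\n",
                x$negative_eigenvalue_mass))
  invisible(x)
}

#' Between-assemblage nearest-taxon distance matrix
#'
#' Symmetric matrix of [comdistnt()] values between every pair of
#' assemblages, zero on the diagonal.
#'
#' @param dm patristic matrix.
#' @param assemblages named list of species-name vectors (tip labels).
#' @param exclude_conspecifics passed to [comdistnt()].
#' @return Symmetric numeric matrix with assemblage names as dimnames.
#' @export
assemblage_distance_matrix <- function(dm, assemblages,
                                       exclude_conspecifics = FALSE) {
  nms <- names(assemblages)
  stopifnot(!is.null(nms), !any(nms == ""))
  m <- matrix(0, length(nms), length(nms), dimnames = list(nms, nms))
  for (i in seq_along(nms)) for (j in seq_len(i - 1L)) {
    m[i, j] <- m[j, i] <- comdistnt(dm, assemblages[[i]], assemblages[[j]],
                                    exclude_conspecifics = exclude_conspecifics)
  }
  m
}
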