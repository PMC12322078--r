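#' Weighted brain network
#'
#' Container for a parcel-by-parcel weighted network: a symmetric
#' nonnegative matrix with a zero diagonal (streamline-density or similarity
#' units) plus parcel centroid coordinates and optional labels. This is the
#' common currency of the exposure, epicenter, SIR, and null-model
#' machinery.
#'
#' @param weights n x n symmetric numeric matrix, zero diagonal,
#'   nonnegative.
#' @param coordinates n x 3 matrix of parcel centroid positions (Euclidean).
#' @param labels optional character vector of parcel names.
#' @return an object of class `weighted_network` with elements `weights`,
#'   `coordinates`, `labels`.
#' @export
weighted_network <- function(weights, coordinates = NULL, labels = NULL) {
  weights <- as.matrix(weights)
  if (!is.null(coordinates)) {
    coordinates <- as.matrix(coordinates)
    storage.mode(coordinates) <- "double"
  }
  net <- structure(
    list(weights = weights, coordinates = coordinates, labels = labels),
    class = "weighted_network"
  )
  validate_network(net)
  net
}

#' Validate a weighted network
#'
#' Checks symmetry, zero diagonal, nonnegativity, finiteness, and (if
#' present) that coordinates align with the weight matrix.
#'
#' @param net a `weighted_network`.
#' @param tol tolerance for the symmetry check.
#' @return `net`, invisibly; errors describe the first violated invariant.
#' @export
validate_network <- function(net, tol = 1e-8) {
  w <- net$weights
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("weights must be a square matrix")
  if (any(!is.finite(w))) stop("weights contain non-finite values")
  if (max(abs(w - t(w))) > tol) stop("weights are not symmetric")
  if (any(diag(w) != 0)) stop("diagonal of weights must be exactly zero")
  if (any(w < 0)) stop("weights contain negative entries")
  if (!is.null(net$coordinates)) {
    if (nrow(net$coordinates) != nrow(w) || ncol(net$coordinates) != 3L) {
      stop("coordinates must be an n x 3 matrix matching the weight matrix")
    }
    if (any(!is.finite(net$coordinates))) stop("coordinates contain non-finite values")
  }
  if (!is.null(net$labels) && length(net$labels) != nrow(w)) {
    stop("labels length does not match the number of parcels")
  }
  invisible(net)
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Weighted network: %d parcels, %d edges, density %.3f%s\n",
              n, m, m / (n * (n - 1) / 2),
              if (is.null(x$coordinates)) "" else ", with coordinates"))
  invisible(x)
}

n_parcels <- function(net) nrow(net$weights)

#' Threshold a similarity matrix to a nonnegative network
#'
#' Interregional similarity matrices (e.g. Fisher-z correlation matrices)
#' carry negative entries that are excluded from all spreading analyses:
#' negative values are set to zero, the diagonal is zeroed, and positive
#' entries pass through unchanged.
#'
#' @param similarity square symmetric numeric matrix.
#' @param coordinates,labels passed through to [weighted_network()].
#' @param tol symmetry tolerance.
#' @return a `weighted_network`. Warns if no edges survive.
#' @export
threshold_positive <- function(similarity, coordinates = NULL, labels = NULL,
                               tol = 1e-8) {
  similarity <- as.matrix(similarity)
  if (nrow(similarity) != ncol(similarity)) stop("similarity matrix must be square")
  if (max(abs(similarity - t(similarity))) > tol) {
    stop("similarity matrix is asymmetric beyond tolerance")
  }
  w <- (similarity + t(similarity)) / 2   # symmetrize residual numeric noise
  w[w < 0] <- 0
  diag(w) <- 0
  if (all(w == 0)) warning("no positive entries: network has no edges")
  weighted_network(w, coordinates = coordinates, labels = labels)
}

#' Build an interregional similarity matrix from feature profiles
#'
#' Correlates parcel profiles (columns of a feature-by-parcel matrix) across
#' all parcel pairs and optionally applies the Fisher r-to-z transform, the
#' standard normalization for similarity networks. Correlations are clipped
#' to +/- (1 - 1e-7) before `atanh` so identical profiles give a large
#' finite similarity. Parcels with a constant profile have no defined
#' correlation; their rows and columns are set to `NA` with a warning.
#'
#' @param profiles feature x parcel numeric matrix, >= 3 features.
#' @param method correlation method (default `"pearson"`).
#' @param fisher apply the r-to-z transform (default `TRUE`).
#' @return parcel x parcel similarity matrix with a zero diagonal.
#' @export
build_similarity <- function(profiles, method = "pearson", fisher = TRUE) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 3L) stop("need at least 3 features per parcel")
  constant <- apply(profiles, 2, function(x) stats::sd(x) == 0)
  r <- suppressWarnings(stats::cor(profiles, method = method))
  if (any(constant)) {
    warning(sprintf("%d constant parcel profile(s): similarity set to NA", sum(constant)))
    r[constant, ] <- NA_real_
    r[, constant] <- NA_real_
  }
  s <- if (fisher) fisher_z(r) else r
  diag(s) <- 0
  s
}
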