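# Uniform random rotation of 3-space via a normalized quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Spin surrogates of a spherical parcel map
#'
#' Generates spatial-autocorrelation-preserving null maps by randomly
#' rotating the spherical parcel centroids and assigning each original
#' parcel the value of the nearest rotated centroid (Euclidean). Nearest
#' assignment may repeat or drop values, but preserves the value multiset
#' and the map's spatial smoothness while destroying its alignment with
#' other maps. Masked parcels (e.g. a medial wall) are never used as
#' donors: a parcel whose nearest rotated centroid is masked takes the next
#' closest unmasked parcel's value.
#'
#' @param coordinates n x 3 parcel centroids on the unit sphere (radius
#'   checked to 10% unless `project = TRUE`, which normalizes them).
#' @param values parcel map to spin.
#' @param n number of surrogates.
#' @param seed optional RNG seed.
#' @param mask optional logical vector marking parcels excluded as donors.
#' @param project project centroids onto the unit sphere instead of
#'   erroring when they are off it.
#' @return n_parcels x n matrix of surrogate maps.
#' @export
spin_surrogates <- function(coordinates, values, n, seed = NULL, mask = NULL,
                            project = FALSE) {
  coordinates <- as.matrix(coordinates)
  if (n < 1L) stop("n must be >= 1")
  if (length(values) != nrow(coordinates)) {
    stop("values length must match coordinates")
  }
  radius <- sqrt(rowSums(coordinates^2))
  if (project) {
    coordinates <- coordinates / radius
  } else if (any(abs(radius - 1) > 0.1)) {
    stop("centroids are not on the unit sphere; set project = TRUE to project them")
  }
  if (is.null(mask)) mask <- rep(FALSE, nrow(coordinates))
  if (all(mask)) stop("all parcels are masked")
  with_seed(seed, {
    out <- matrix(NA_real_, nrow(coordinates), n)
    sq <- rowSums(coordinates^2)
    for (s in seq_len(n)) {
      rot <- coordinates %*% t(random_rotation())
      # squared distance from each original parcel to each rotated centroid
      d2 <- outer(sq, rowSums(rot^2), "+") - 2 * tcrossprod(coordinates, rot)
      d2[, mask] <- Inf
      out[, s] <- values[max.col(-d2, ties.method = "first")]
    }
    out
  })
}

# Upper-triangular edge list (i < j) of a weighted network.
edge_list <- function(w) {
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  cbind(i = idx[, 1], j = idx[, 2], w = w[idx])
}

edges_to_matrix <- function(edges, n) {
  w <- matrix(0, n, n)
  w[edges[, 1:2, drop = FALSE]] <- edges[, 3]
  w[edges[, 2:1, drop = FALSE]] <- edges[, 3]
  w
}

# One attempted Maslov-Sneppen double-edge swap on an edge table; `binary`
# is the current adjacency used for multi-edge rejection. Returns the
# updated state and whether the swap succeeded.
try_swap <- function(edges, binary, e1, e2) {
  a <- edges[e1, 1]; b <- edges[e1, 2]
  c <- edges[e2, 1]; d <- edges[e2, 2]
  if (length(unique(c(a, b, c, d))) < 4L) return(NULL)
  # swap to (a,d), (c,b); reject self-loops (excluded above) and multi-edges
  if (binary[a, d] || binary[c, b]) return(NULL)
  list(new1 = sort(c(a, d)), new2 = sort(c(c, b)))
}

#' Degree-preserving network rewiring
#'
#' Randomizes network topology by Maslov-Sneppen double-edge swaps: two
#' edges (a,b) and (c,d) are replaced by (a,d) and (c,b) whenever this
#' creates no self-loop or duplicate edge. Edge weights travel with their
#' edges, so node count, edge count, binary degree sequence, and the weight
#' multiset are all preserved exactly. The attempted swap count is
#' `swaps_per_edge` times the edge count.
#'
#' @param network a `weighted_network`.
#' @param swaps_per_edge attempted swaps per edge (default 10).
#' @param seed optional RNG seed.
#' @return a rewired `weighted_network` with attribute `achieved_swaps`.
#'   Warns if no swap could be performed.
#' @export
rewire_degree_preserving <- function(network, swaps_per_edge = 10L, seed = NULL) {
  validate_network(network)
  n <- n_parcels(network)
  edges <- edge_list(network$weights)
  m <- nrow(edges)
  if (m < 2L) stop("need at least 2 edges to rewire")
  with_seed(seed, {
    binary <- network$weights > 0
    attempts <- as.integer(swaps_per_edge) * m
    achieved <- 0L
    for (k in seq_len(attempts)) {
      pick <- sample.int(m, 2L)
      sw <- try_swap(edges, binary, pick[1], pick[2])
      if (is.null(sw)) next
      old1 <- edges[pick[1], 1:2]; old2 <- edges[pick[2], 1:2]
      binary[old1[1], old1[2]] <- binary[old1[2], old1[1]] <- FALSE
      binary[old2[1], old2[2]] <- binary[old2[2], old2[1]] <- FALSE
      binary[sw$new1[1], sw$new1[2]] <- binary[sw$new1[2], sw$new1[1]] <- TRUE
      binary[sw$new2[1], sw$new2[2]] <- binary[sw$new2[2], sw$new2[1]] <- TRUE
      edges[pick[1], 1:2] <- sw$new1
      edges[pick[2], 1:2] <- sw$new2
      achieved <- achieved + 1L
    }
    if (achieved == 0L) warning("no valid swap found; network returned unchanged")
    out <- weighted_network(edges_to_matrix(edges, n),
                            coordinates = network$coordinates,
                            labels = network$labels)
    attr(out, "achieved_swaps") <- achieved
    out
  })
}

#' Degree- and edge-length-preserving rewiring
#'
#' The most conservative topology null: edges are categorized by Euclidean
#' centroid distance into bins (equal-count by default) and double-edge
#' swaps are only accepted when both replacement edges fall in the same
#' distance bin as the originals, so the per-bin edge counts — and hence
#' the edge-length distribution at bin resolution — are preserved exactly
#' along with the degree sequence. The total attempted swap count is the
#' number of regions times `swap_factor`.
#'
#' @param network a `weighted_network` with coordinates.
#' @param n_bins number of distance bins (default 10).
#' @param swap_factor attempted swaps per region (default 20).
#' @param equal_width use equal-width rather than equal-count bins.
#' @param seed optional RNG seed.
#' @return a rewired `weighted_network` with attributes `achieved_swaps`
#'   and `bin_breaks`. Bins with fewer than 2 edges are skipped with a
#'   warning.
#' @export
rewire_distance_binned <- function(network, n_bins = 10L, swap_factor = 20L,
                                   equal_width = FALSE, seed = NULL) {
  validate_network(network)
  if (is.null(network$coordinates)) stop("distance-binned rewiring needs coordinates")
  n <- n_parcels(network)
  edges <- edge_list(network$weights)
  m <- nrow(edges)
  if (m < 2L) stop("need at least 2 edges to rewire")
  d <- as.matrix(stats::dist(network$coordinates))
  len <- d[edges[, 1:2, drop = FALSE]]
  breaks <- if (equal_width) {
    seq(min(len), max(len), length.out = n_bins + 1L)
  } else {
    unique(stats::quantile(len, probs = seq(0, 1, length.out = n_bins + 1L)))
  }
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  bin <- cut(len, breaks, labels = FALSE)
  small <- setdiff(seq_len(length(breaks) - 1L), bin[duplicated(bin) | duplicated(bin, fromLast = TRUE)])
  if (length(small)) warning(sprintf("%d bin(s) with < 2 edges skipped", length(small)))
  with_seed(seed, {
    binary <- network$weights > 0
    attempts <- n * as.integer(swap_factor)
    achieved <- 0L
    eligible <- which(bin %in% bin[duplicated(bin) | duplicated(bin, fromLast = TRUE)])
    if (length(eligible) >= 2L) {
      for (k in seq_len(attempts)) {
        e1 <- eligible[sample.int(length(eligible), 1L)]
        same <- eligible[bin[eligible] == bin[e1] & eligible != e1]
        if (!length(same)) next
        e2 <- same[sample.int(length(same), 1L)]
        sw <- try_swap(edges, binary, e1, e2)
        if (is.null(sw)) next
        b1 <- cut(d[sw$new1[1], sw$new1[2]], breaks, labels = FALSE)
        b2 <- cut(d[sw$new2[1], sw$new2[2]], breaks, labels = FALSE)
        if (b1 != bin[e1] || b2 != bin[e1]) next
        old1 <- edges[e1, 1:2]; old2 <- edges[e2, 1:2]
        binary[old1[1], old1[2]] <- binary[old1[2], old1[1]] <- FALSE
        binary[old2[1], old2[2]] <- binary[old2[2], old2[1]] <- FALSE
        binary[sw$new1[1], sw$new1[2]] <- binary[sw$new1[2], sw$new1[1]] <- TRUE
        binary[sw$new2[1], sw$new2[2]] <- binary[sw$new2[2], sw$new2[1]] <- TRUE
        edges[e1, 1:2] <- sw$new1
        edges[e2, 1:2] <- sw$new2
        achieved <- achieved + 1L
      }
    }
    out <- weighted_network(edges_to_matrix(edges, n),
                            coordinates = network$coordinates,
                            labels = network$labels)
    attr(out, "achieved_swaps") <- achieved
    attr(out, "bin_breaks") <- breaks
    out
  })
}
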