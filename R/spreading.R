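#' Disease exposure: weighted mean atrophy of connected neighbours
#'
#' For every parcel i, computes
#' `D_i = sum_j d_j * c_ij / C_i`, the atrophy of i's directly connected
#' neighbours weighted by edge strength `c_ij`, with `C_i` the weighted
#' degree. Parcels with no connections (`C_i = 0`) get `NA`.
#'
#' @param network a `weighted_network`.
#' @param atrophy parcel-wise atrophy vector.
#' @return numeric exposure vector `D`.
#' @export
neighbour_exposure <- function(network, atrophy) {
  validate_network(network)
  if (length(atrophy) != n_parcels(network)) {
    stop("atrophy length must match the network")
  }
  C <- rowSums(network$weights)
  D <- as.vector(network$weights %*% atrophy) / C
  D[C == 0] <- NA_real_
  D
}

#' Node-neighbour atrophy correlation
#'
#' Correlates each parcel's atrophy with its disease exposure (the weighted
#' mean atrophy of its connected neighbours). A positive correlation is the
#' signature of network-shaped pathology. Parcels with undefined exposure
#' are excluded pairwise.
#'
#' @param network a `weighted_network`.
#' @param atrophy parcel-wise atrophy vector.
#' @param method correlation method (default `"pearson"`).
#' @return list with `r`, `atrophy`, and `exposure` (the paired vectors on
#'   the parcels entering the correlation).
#' @export
node_neighbour_correlation <- function(network, atrophy, method = "pearson") {
  exposure <- neighbour_exposure(network, atrophy)
  ok <- !is.na(exposure) & !is.na(atrophy)
  if (sum(ok) < 3L) stop("need at least 3 parcels with defined exposure")
  if (stats::sd(atrophy[ok]) == 0 || stats::sd(exposure[ok]) == 0) {
    stop("zero variance: node-neighbour correlation undefined")
  }
  list(r = stats::cor(atrophy[ok], exposure[ok], method = method),
       atrophy = atrophy[ok], exposure = exposure[ok])
}

#' Epicenter likelihood by dual ranking
#'
#' A disease epicenter is a parcel that is both highly atrophied and
#' connected to highly atrophied parcels. Parcels are ranked in ascending
#' order by their own atrophy (largest atrophy gets the largest rank) and,
#' separately, by their disease exposure; the epicenter likelihood of a
#' parcel is its mean rank in the two lists, so higher values indicate a
#' likelier epicenter. Ties receive average (fractional) ranks, and parcels
#' with undefined exposure are excluded (returned as `NA`).
#'
#' @param network a `weighted_network`.
#' @param atrophy parcel-wise atrophy vector.
#' @return an `epicenter_map`: `values` (mean ranks, in \[1, n\]), `method`
#'   `"ranking"`, plus the component `atrophy_rank` and `exposure_rank`.
#' @export
epicenter_rank <- function(network, atrophy) {
  exposure <- neighbour_exposure(network, atrophy)
  a <- atrophy
  a[is.na(exposure)] <- NA_real_
  tol <- 1e-10 * max(1, abs(a), na.rm = TRUE)
  if (stats::sd(a, na.rm = TRUE) <= tol && stats::sd(exposure, na.rm = TRUE) <= tol) {
    stop("all parcels tied in both atrophy and exposure: ranking undefined")
  }
  ra <- rank_ascending(a)
  re <- rank_ascending(exposure)
  structure(list(values = (ra + re) / 2, method = "ranking",
                 atrophy_rank = ra, exposure_rank = re),
            class = "epicenter_map")
}

#' @export
print.epicenter_map <- function(x, ...) {
  top <- order(x$values, decreasing = TRUE)[seq_len(min(3L, length(x$values)))]
  cat(sprintf("Epicenter map (%s method): %d parcels; top parcels: %s\n",
              x$method, length(x$values), paste(top, collapse = ", ")))
  invisible(x)
}

#' Does a second connectome improve atrophy prediction?
#'
#' Fits two nested OLS models of parcel atrophy: one on the exposure
#' computed from a reference network (typically the structural connectome),
#' and one adding the exposure computed from a second network (e.g. a
#' biological similarity network). The gain in adjusted R-squared is tested
#' against spin-matched null regressors with the same spatial organization:
#' each null replaces the second regressor by the exposure (under the
#' second network) of a spin-rotated copy of the atrophy map, and the
#' one-sided add-one p of the observed gain is reported.
#'
#' @param atrophy parcel-wise atrophy vector.
#' @param network_a reference `weighted_network` supplying regressor 1.
#' @param network_b candidate `weighted_network` supplying regressor 2.
#' @param coordinates spherical parcel centroids for the spin null; default
#'   taken from `network_a`.
#' @param n_spin number of spin surrogates.
#' @param seed optional RNG seed.
#' @return list with `adj_r2_a`, `adj_r2_ab`, `gain`, `p_spin`, and the
#'   `nulls` vector of null gains.
#' @export
joint_regression_gain <- function(atrophy, network_a, network_b,
                                  coordinates = network_a$coordinates,
                                  n_spin = 1000L, seed = NULL) {
  if (length(atrophy) < 10L) stop("need at least 10 parcels")
  ea <- neighbour_exposure(network_a, atrophy)
  eb <- neighbour_exposure(network_b, atrophy)
  ok <- stats::complete.cases(atrophy, ea, eb)
  if (sum(ok) < 5L) stop("insufficient parcels with defined exposure (need >= 5 for 2 regressors)")
  adj_r2 <- function(y, X) {
    fit <- stats::lm.fit(cbind(1, X), y)
    n <- length(y); k <- ncol(X)
    1 - (sum(fit$residuals^2) / (n - k - 1)) / (sum((y - mean(y))^2) / (n - 1))
  }
  if (abs(stats::cor(ea[ok], eb[ok])) > 0.999) {
    warning("regressors are collinear; gain is not identifiable")
  }
  r2a <- adj_r2(atrophy[ok], cbind(ea[ok]))
  r2ab <- adj_r2(atrophy[ok], cbind(ea[ok], eb[ok]))
  gain <- r2ab - r2a
  spins <- spin_surrogates(coordinates, atrophy, n = n_spin, seed = seed)
  nulls <- apply(spins, 2, function(rotated) {
    enull <- neighbour_exposure(network_b, rotated)
    okn <- ok & !is.na(enull)
    adj_r2(atrophy[okn], cbind(ea[okn], enull[okn])) - adj_r2(atrophy[okn], cbind(ea[okn]))
  })
  list(adj_r2_a = r2a, adj_r2_ab = r2ab, gain = gain,
       p_spin = nonparametric_p(gain, nulls, "one_sided_greater",
                                method = "spin")$p_value,
       nulls = nulls)
}
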