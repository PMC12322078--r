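#' Voxel-level morphometry cohort
#'
#' Holds per-subject voxel (or parcel) morphometry values on a
#' Jacobian-determinant scale together with the covariates used by the
#' normative model: age in years, sex coded 0/1, imaging-site stratum, and
#' a control/patient flag.
#'
#' @param values subject x voxel numeric matrix, finite.
#' @param age numeric vector of ages.
#' @param sex binary 0/1 vector.
#' @param site character or factor site identifiers.
#' @param group 0 (control) / 1 (patient) vector.
#' @return a `voxel_cohort` object.
#' @export
voxel_cohort <- function(values, age, sex, site, group) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (length(age) != n || length(sex) != n || length(site) != n || length(group) != n) {
    stop("covariate lengths must match the number of subjects")
  }
  if (any(!is.finite(values))) stop("values contain non-finite entries")
  if (any(is.na(age)) || any(is.na(sex)) || any(is.na(site)) || any(is.na(group))) {
    stop("covariates must not contain missing values")
  }
  if (!all(sex %in% c(0, 1))) stop("sex must be coded 0/1")
  if (!all(group %in% c(0, 1))) stop("group must be coded 0 (control) / 1 (patient)")
  structure(list(values = values, age = as.numeric(age), sex = as.numeric(sex),
                 site = as.character(site), group = as.integer(group)),
            class = "voxel_cohort")
}

#' @export
print.voxel_cohort <- function(x, ...) {
  cat(sprintf("Voxel cohort: %d subjects (%d controls, %d patients), %d voxels, %d site(s)\n",
              nrow(x$values), sum(x$group == 0), sum(x$group == 1),
              ncol(x$values), length(unique(x$site))))
  invisible(x)
}

#' Fit the normative morphometry model on controls
#'
#' For every site stratum and voxel, fits an ordinary least squares model of
#' control values on age, sex, and an intercept; the residual standard
#' deviation of those controls (divisor `n - 1`) is the normative scale for
#' w-scores. Voxels whose controls fit exactly (residual SD 0) are flagged
#' degenerate and later propagate missing w-scores. Sites whose control
#' design is rank deficient (fewer than 3 controls, or a single sex) are an
#' error naming the stratum.
#'
#' @param cohort a [voxel_cohort()]; only subjects with `group == 0` are
#'   used.
#' @return a `normative_model`: per-site lists of `beta` (3 x voxel matrix,
#'   rows age/sex/intercept), `residual_sd`, and a `degenerate` logical
#'   per-site-voxel flag.
#' @export
fit_normative_model <- function(cohort) {
  stopifnot(inherits(cohort, "voxel_cohort"))
  ctrl <- cohort$group == 0L
  sites <- sort(unique(cohort$site))
  fits <- lapply(sites, function(s) {
    idx <- ctrl & cohort$site == s
    if (sum(idx) < 3L) stop(sprintf("site '%s' has fewer than 3 controls", s))
    X <- cbind(age = cohort$age[idx], sex = cohort$sex[idx], intercept = 1)
    if (qr(X)$rank < 3L) {
      stop(sprintf("rank-deficient control design in site '%s' (e.g. single-sex)", s))
    }
    fit <- stats::lm.fit(X, cohort$values[idx, , drop = FALSE])
    res <- as.matrix(fit$residuals)
    rsd <- sqrt(colSums(res^2) / (sum(idx) - 1))
    list(beta = as.matrix(fit$coefficients), residual_sd = rsd,
         degenerate = rsd < .Machine$double.eps^0.5 * max(1, max(abs(cohort$values[idx, ]))))
  })
  names(fits) <- sites
  structure(list(sites = fits, n_voxels = ncol(cohort$values)),
            class = "normative_model")
}

#' Compute sign-inverted w-score atrophy maps
#'
#' The w-score of a subject's voxel is the deviation of the observed value
#' from its normative expectation (site-specific age + sex + intercept OLS
#' fit on controls), standardized by the control residual SD, then
#' multiplied by -1 so larger values mean more atrophy. Degenerate voxels
#' (zero control residual SD) yield `NA`.
#'
#' @param cohort a [voxel_cohort()].
#' @param model a `normative_model` fitted on the same voxel space.
#' @param target_group subjects to score: 1 (patients, default), 0
#'   (controls), or `NULL` for everyone.
#' @return a `wscore_map`: `values` (subject x voxel inverted w-scores) and
#'   `subjects` (row indices into the cohort).
#' @export
compute_wscores <- function(cohort, model, target_group = 1L) {
  stopifnot(inherits(cohort, "voxel_cohort"), inherits(model, "normative_model"))
  if (ncol(cohort$values) != model$n_voxels) {
    stop("model was fitted on a different voxel space")
  }
  keep <- if (is.null(target_group)) seq_len(nrow(cohort$values)) else
    which(cohort$group == target_group)
  missing_sites <- setdiff(unique(cohort$site[keep]), names(model$sites))
  if (length(missing_sites)) {
    stop(sprintf("site(s) absent from the normative model: %s",
                 paste(missing_sites, collapse = ", ")))
  }
  w <- matrix(NA_real_, length(keep), model$n_voxels,
              dimnames = list(rownames(cohort$values)[keep], colnames(cohort$values)))
  for (s in unique(cohort$site[keep])) {
    fit <- model$sites[[s]]
    rows <- which(cohort$site[keep] == s)
    idx <- keep[rows]
    X <- cbind(cohort$age[idx], cohort$sex[idx], 1)
    expected <- X %*% fit$beta
    sdv <- fit$residual_sd
    sdv[fit$degenerate] <- NA_real_
    w[rows, ] <- -sweep(cohort$values[idx, , drop = FALSE] - expected, 2, sdv, "/")
  }
  structure(list(values = w, subjects = keep), class = "wscore_map")
}

#' Aggregate voxel values to parcels
#'
#' Reduces voxel-level values to one value per parcel using an integer
#' label image (0 = background, excluded). Parcels with no member voxels
#' return `NA`.
#'
#' @param voxel_values numeric vector (one map) or subject x voxel matrix.
#' @param labels nonnegative integer label per voxel.
#' @param reduction summary function applied within each parcel (default
#'   mean).
#' @param n_parcels number of parcels in the output; defaults to
#'   `max(labels)`.
#' @return parcel vector, or subject x parcel matrix for matrix input.
#' @export
parcellate <- function(voxel_values, labels, reduction = mean,
                       n_parcels = max(labels)) {
  labels <- as.integer(labels)
  if (any(labels < 0L)) stop("labels must be nonnegative integers")
  one <- is.null(dim(voxel_values))
  vals <- if (one) matrix(voxel_values, nrow = 1) else as.matrix(voxel_values)
  if (ncol(vals) != length(labels)) stop("labels length must match the voxel dimension")
  out <- matrix(NA_real_, nrow(vals), n_parcels,
                dimnames = list(rownames(vals), NULL))
  for (p in seq_len(n_parcels)) {
    members <- which(labels == p)
    if (length(members)) {
      out[, p] <- apply(vals[, members, drop = FALSE], 1, reduction)
    }
  }
  if (one) drop(out) else out
}

#' Cytoarchitectonic class enrichment of a parcel map
#'
#' Computes the mean map value within each class of parcels and tests each
#' class mean against spatial-autocorrelation-preserving spin surrogates:
#' the one-sided p is the add-one probability that a surrogate's class mean
#' reaches the observed one, followed by Benjamini-Hochberg correction
#' across classes.
#'
#' @param parcel_map numeric parcel vector.
#' @param class_labels class assignment per parcel (factor or character).
#' @param coordinates n x 3 spherical parcel centroids for the spin test.
#' @param n_spin number of spin surrogates (>= 100).
#' @param seed optional RNG seed.
#' @return data.frame with one row per class: `class`, `n_parcels`, `mean`,
#'   `p_spin`, `p_fdr`.
#' @export
class_enrichment <- function(parcel_map, class_labels, coordinates,
                             n_spin = 1000L, seed = NULL) {
  class_labels <- as.character(class_labels)
  if (length(class_labels) != length(parcel_map)) {
    stop("class_labels must cover all parcels")
  }
  if (n_spin < 100L) stop("n_spin must be >= 100")
  classes <- sort(unique(class_labels))
  if (any(!classes %in% class_labels)) stop("empty class")
  obs <- vapply(classes, function(cl) mean(parcel_map[class_labels == cl]), 0)
  spins <- spin_surrogates(coordinates, parcel_map, n = n_spin, seed = seed)
  p <- vapply(seq_along(classes), function(i) {
    nulls <- colMeans(spins[class_labels == classes[i], , drop = FALSE])
    nonparametric_p(obs[i], nulls, "one_sided_greater", method = "spin")$p_value
  }, 0)
  data.frame(class = classes,
             n_parcels = as.integer(table(class_labels)[classes]),
             mean = unname(obs), p_spin = p, p_fdr = fdr_bh(p),
             row.names = NULL)
}

#' Per-tract atrophy test
#'
#' Averages each subject's inverted w-scores within each tract and tests
#' the subject means against zero with a one-sample t-test (two-sided by
#' default; w-scores already encode deviation from the control norm), with
#' Benjamini-Hochberg correction across tracts. A two-sample variant
#' (patients vs controls on the same tract means) is available since the
#' choice between the two is an interpretation.
#'
#' @param wscores a `wscore_map` (subject x voxel inverted w-scores).
#' @param tract_labels integer tract label per voxel, 0 = background.
#' @param control_wscores optional second `wscore_map`; when supplied a
#'   two-sample (Welch) test of patients vs controls is run instead.
#' @return data.frame with `tract`, `mean`, `t`, `p`, `p_fdr`.
#' @export
tract_atrophy_test <- function(wscores, tract_labels, control_wscores = NULL) {
  stopifnot(inherits(wscores, "wscore_map"))
  if (nrow(wscores$values) < 3L) stop("need at least 3 subjects")
  tm <- parcellate(wscores$values, tract_labels)
  tm <- as.matrix(tm)
  tracts <- seq_len(ncol(tm))
  res <- lapply(tracts, function(tr) {
    x <- tm[, tr]
    if (all(is.na(x))) return(c(NA, NA, NA))
    if (stats::sd(x, na.rm = TRUE) == 0 && is.null(control_wscores)) {
      stop(sprintf("tract %d has zero variance across subjects", tr))
    }
    if (is.null(control_wscores)) {
      ht <- stats::t.test(x)
    } else {
      y <- as.matrix(parcellate(control_wscores$values, tract_labels))[, tr]
      ht <- stats::t.test(x, y)
    }
    c(mean(x, na.rm = TRUE), unname(ht$statistic), ht$p.value)
  })
  res <- do.call(rbind, res)
  data.frame(tract = tracts, mean = res[, 1], t = res[, 2], p = res[, 3],
             p_fdr = fdr_bh(res[, 3]))
}
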