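#' Configuration for the synthetic ground-truth generators
#'
#' Bundles every knob of the synthetic-data module: network size and
#' geometry, the planted spreading process, cohort composition, and the
#' planted brain-behaviour latent factor. Defaults describe a desk-scale
#' study: a 100-parcel spherical connectome at 20% density, spreading that
#' dominates the atrophy map (`spread_weight` 0.7) over modest measurement
#' noise (`noise_sd` 0.1), a multi-site cohort, and a moderately coupled
#' clinical latent factor (`latent_corr` 0.6).
#'
#' @param n_parcels number of parcels (>= 10 for network generation).
#' @param density target edge density in (0, 1].
#' @param distance_decay nonnegative decay rate of edge probability per unit
#'   inter-centroid distance (centroids live on the unit sphere, so chord
#'   distances span \[0, 2\]).
#' @param seed_region index of the parcel used as the planted disease seed.
#' @param spread_weight mixing weight in \[0, 1\] between seed-diffusion and
#'   the seed indicator in the planted atrophy map.
#' @param noise_sd standard deviation of additive Gaussian noise used by the
#'   map, clinical, and expression generators.
#' @param n_controls,n_patients cohort sizes (>= 1).
#' @param n_sites number of imaging sites.
#' @param n_measures number of clinical/behavioural measures.
#' @param latent_corr correlation in \[0, 1\] between the brain and
#'   behaviour latent scores.
#' @param rng_seed integer seed making every generator a pure function of
#'   (config, seed).
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_parcels = 100L, density = 0.2, distance_decay = 1.5,
                         seed_region = 1L, spread_weight = 0.7, noise_sd = 0.1,
                         n_controls = 60L, n_patients = 40L, n_sites = 3L,
                         n_measures = 20L, latent_corr = 0.6, rng_seed = 1L) {
  cfg <- list(n_parcels = as.integer(n_parcels), density = density,
              distance_decay = distance_decay, seed_region = as.integer(seed_region),
              spread_weight = spread_weight, noise_sd = noise_sd,
              n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
              n_sites = as.integer(n_sites), n_measures = as.integer(n_measures),
              latent_corr = latent_corr, rng_seed = as.integer(rng_seed))
  counts <- c("n_parcels", "n_controls", "n_patients", "n_sites", "n_measures")
  for (f in counts) {
    if (cfg[[f]] < 1L) stop(sprintf("%s must be >= 1", f))
  }
  if (cfg$density <= 0 || cfg$density > 1) stop("density must lie in (0, 1]")
  if (cfg$distance_decay < 0) stop("distance_decay must be nonnegative")
  if (cfg$spread_weight < 0 || cfg$spread_weight > 1) stop("spread_weight must lie in [0, 1]")
  if (cfg$latent_corr < 0 || cfg$latent_corr > 1) stop("latent_corr must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (cfg$seed_region < 1L || cfg$seed_region > cfg$n_parcels) {
    stop("seed_region must index a parcel")
  }
  structure(cfg, class = "synth_config")
}

# Uniform points on the unit sphere.
sample_sphere <- function(n) {
  x <- matrix(stats::rnorm(3 * n), ncol = 3)
  x / sqrt(rowSums(x^2))
}

#' Generate a spatially embedded random connectome
#'
#' Parcel centroids are sampled uniformly on the unit sphere (so spin tests
#' are exact rotations of the embedding); edge probability decays
#' exponentially with inter-centroid Euclidean distance at rate
#' `distance_decay` and is rescaled so the expected density matches
#' `config$density`; surviving edges receive log-normal positive weights.
#' Disconnected realizations are regenerated; the realized density is
#' required to fall within 20% of the target.
#'
#' @param config a [synth_config()].
#' @param max_tries regenerations allowed before giving up.
#' @return a `weighted_network` with `coordinates` on the unit sphere.
#' @export
make_spatial_connectome <- function(config, max_tries = 50L) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_parcels < 10L) stop("network generation requires n_parcels >= 10")
  with_seed(config$rng_seed, {
    n <- config$n_parcels
    for (try in seq_len(max_tries)) {
      coords <- sample_sphere(n)
      d <- as.matrix(stats::dist(coords))
      base <- exp(-config$distance_decay * d)
      ut <- upper.tri(base)
      # solve for the scale putting expected density on target (clipped at 1)
      f <- function(logc) mean(pmin(exp(logc) * base[ut], 1)) - config$density
      logc <- stats::uniroot(f, c(-20, 20), extendInt = "upX")$root
      p <- pmin(exp(logc) * base, 1)
      edges <- matrix(0L, n, n)
      edges[ut] <- stats::rbinom(sum(ut), 1L, p[ut])
      edges <- edges + t(edges)
      m <- sum(edges[ut])
      realized <- m / sum(ut)
      if (abs(realized - config$density) > 0.2 * config$density) next
      w <- matrix(0, n, n)
      w[ut][edges[ut] == 1L] <- stats::rlnorm(m, meanlog = 0, sdlog = 0.5)
      w <- w + t(w)
      comp <- connected_component(w > 0)
      if (!all(comp)) next
      return(weighted_network(w, coordinates = coords,
                              labels = sprintf("P%03d", seq_len(n))))
    }
    stop(sprintf(paste0("could not realize a connected network at density %.3g ",
                        "with distance_decay %.3g after %d tries"),
                 config$density, config$distance_decay, max_tries))
  })
}

# Breadth-first reachability from node 1 on an adjacency matrix.
connected_component <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' Plant an atrophy map spread from a known seed
#'
#' The noiseless truth mixes a k-step lazy diffusion of a unit mass placed
#' at the seed parcel (`spread_weight`) with the seed indicator
#' (`1 - spread_weight`); Gaussian noise is added and the result clipped at
#' zero. The lazy walk `((I + P) / 2)^k`, with `P` the row-normalized weight
#' matrix, guarantees the seed retains at least `2^-k` of the mass, so in
#' the noiseless case the map always peaks at the seed. The diffusion
#' profile is rescaled to unit maximum before mixing, so `noise_sd` is
#' expressed relative to peak atrophy rather than to total injected mass.
#'
#' @param network a `weighted_network`.
#' @param seed_region seed parcel index.
#' @param spread_weight mixing weight in \[0, 1\].
#' @param noise_sd additive Gaussian noise SD.
#' @param k_steps number of diffusion steps (default 3).
#' @param seed optional RNG seed.
#' @return list with `map` (noisy, clipped at 0), `truth` (noiseless), and
#'   `seed_region`.
#' @export
make_planted_atrophy <- function(network, seed_region, spread_weight,
                                 noise_sd, k_steps = 3L, seed = NULL) {
  validate_network(network)
  n <- n_parcels(network)
  if (seed_region < 1L || seed_region > n) stop("seed_region must index a parcel")
  if (spread_weight < 0 || spread_weight > 1) stop("spread_weight must lie in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  deg <- rowSums(network$weights)
  if (deg[seed_region] == 0) stop("seed_region is isolated: nothing can spread")
  P <- network$weights / ifelse(deg > 0, deg, 1)
  P[deg == 0, ] <- 0
  diag(P)[deg == 0] <- 1
  lazy <- (diag(n) + P) / 2
  mass <- numeric(n)
  mass[seed_region] <- 1
  for (i in seq_len(k_steps)) mass <- as.vector(mass %*% lazy)
  mass <- mass / max(mass)   # unit peak, so noise_sd is relative to peak atrophy
  indicator <- numeric(n)
  indicator[seed_region] <- 1
  truth <- spread_weight * mass + (1 - spread_weight) * indicator
  map <- with_seed(seed, pmax(truth + stats::rnorm(n, sd = noise_sd), 0))
  list(map = map, truth = truth, seed_region = seed_region)
}

#' Generate a multi-site voxel-level morphometry cohort
#'
#' Each subject's voxel values follow a site intercept plus linear age and
#' sex effects; patients additionally carry a parcel-wise atrophy effect
#' (subtracted, mirroring tissue loss on a Jacobian-determinant scale).
#' Ages are drawn from N(57, 10), sexes are balanced 0/1, and sites are
#' assigned round-robin so each site stratum holds enough controls to fit a
#' normative model.
#'
#' @param config a [synth_config()].
#' @param effect_map parcel-wise atrophy effect (length = number of distinct
#'   nonzero labels' parcels; indexed by label value).
#' @param parcel_labels integer label per voxel, 0 = background.
#' @param effect_scale multiplier applied to `effect_map` for patients.
#' @param beta_age,beta_sex linear covariate effects.
#' @param voxel_noise_sd residual noise SD per voxel.
#' @return a `voxel_cohort` object: `values` (subject x voxel), `age`,
#'   `sex`, `site`, `group` (0 control / 1 patient).
#' @export
make_voxel_cohort <- function(config, effect_map, parcel_labels,
                              effect_scale = 0.15, beta_age = -0.003,
                              beta_sex = 0.02, voxel_noise_sd = 0.05) {
  stopifnot(inherits(config, "synth_config"))
  parcel_labels <- as.integer(parcel_labels)
  used <- parcel_labels[parcel_labels > 0L]
  if (length(used) && max(used) > length(effect_map)) {
    stop("parcel_labels reference parcels beyond effect_map")
  }
  n_sub <- config$n_controls + config$n_patients
  if (floor(config$n_controls / config$n_sites) < 3L) {
    stop("each site needs >= 3 controls to fit a normative model")
  }
  with_seed(config$rng_seed + 1L, {
    group <- c(rep(0L, config$n_controls), rep(1L, config$n_patients))
    site <- rep_len(sprintf("site%02d", seq_len(config$n_sites)), n_sub)
    age <- stats::rnorm(n_sub, 57, 10)
    sex <- sample(rep_len(c(0L, 1L), n_sub))   # balanced, unconfounded with site
    site_intercept <- 1 + seq_len(config$n_sites) * 0.02
    names(site_intercept) <- sprintf("site%02d", seq_len(config$n_sites))
    n_vox <- length(parcel_labels)
    voxel_effect <- ifelse(parcel_labels > 0L, effect_map[pmax(parcel_labels, 1L)], 0)
    expected <- site_intercept[site] + beta_age * age + beta_sex * sex
    values <- matrix(expected, n_sub, n_vox) -
      outer(group * effect_scale, voxel_effect) +
      matrix(stats::rnorm(n_sub * n_vox, sd = voxel_noise_sd), n_sub, n_vox)
    voxel_cohort(values, age = age, sex = sex, site = site, group = group)
  })
}

#' Generate subject epicenter maps and clinical measures sharing a latent
#' factor
#'
#' Each subject carries a latent score; subject brain maps load on a fixed
#' unit-norm parcel pattern scaled by that score, and clinical measures load
#' on a fixed unit-norm measure pattern scaled by a second latent whose
#' correlation with the first is `latent_corr` (so the planted value is, by
#' construction, the population brain-behaviour score correlation).
#' Independent Gaussian noise with SD `noise_sd` is added featurewise, and
#' missingness can be injected into the clinical table.
#'
#' @param config a [synth_config()] with `n_patients >= 20`.
#' @param missing_rate fraction of clinical cells set missing.
#' @return list with `brain` (subject x parcel matrix), `clinical` (a
#'   [clinical_table()]), and `truth` (seed region, unit-norm planted weight
#'   vectors, empty planted category).
#' @export
make_clinical_latent <- function(config, missing_rate = 0) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_patients < 20L) stop("make_clinical_latent requires n_patients >= 20")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  with_seed(config$rng_seed + 2L, {
    n <- config$n_patients
    p <- config$n_parcels
    q <- config$n_measures
    u <- stats::rnorm(p); u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(q); v <- v / sqrt(sum(v^2))
    z <- stats::rnorm(n)
    z_b <- config$latent_corr * z + sqrt(1 - config$latent_corr^2) * stats::rnorm(n)
    brain <- tcrossprod(z, u) + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
    clin <- tcrossprod(z_b, v) + matrix(stats::rnorm(n * q, sd = config$noise_sd), n, q)
    if (missing_rate > 0) {
      drop <- matrix(stats::runif(n * q) < missing_rate, n, q)
      # never blank out a whole measure
      for (j in seq_len(q)) if (all(drop[, j])) drop[1L, j] <- FALSE
      clin[drop] <- NA_real_
    }
    colnames(clin) <- sprintf("measure%02d", seq_len(q))
    rownames(clin) <- rownames(brain) <- sprintf("sub%03d", seq_len(n))
    colnames(brain) <- sprintf("P%03d", seq_len(p))
    truth <- list(seed_region = config$seed_region,
                  latent_brain_weights = u, latent_behavior_weights = v,
                  planted_category = character(0))
    list(brain = brain,
         clinical = clinical_table(clin, group = rep("patient", n)),
         truth = truth)
  })
}

#' Smooth isotropic random field on parcel coordinates
#'
#' Sum of Gaussian radial bumps centred at uniformly random points on the
#' unit sphere with standard-normal amplitudes: an isotropic, spatially
#' autocorrelated field whose distribution is invariant under rotations of
#' the coordinate frame — exactly the class of map a spherical spin test is
#' calibrated for. The returned map is z-scored.
#'
#' @param coordinates n x 3 matrix of points on (or near) the unit sphere.
#' @param n_bumps number of radial basis bumps.
#' @param length_scale bump width in chord-distance units.
#' @param seed optional RNG seed.
#' @return numeric vector of length n.
#' @export
make_autocorrelated_map <- function(coordinates, n_bumps = 20L,
                                    length_scale = 0.7, seed = NULL) {
  with_seed(seed, {
    centers <- sample_sphere(n_bumps)
    amp <- stats::rnorm(n_bumps)
    d2 <- outer(rowSums(coordinates^2), rowSums(centers^2), "+") -
      2 * tcrossprod(coordinates, centers)
    as.vector(scale(exp(-pmax(d2, 0) / (2 * length_scale^2)) %*% amp))
  })
}

#' Generate a gene-by-parcel expression atlas with a planted category
#'
#' Background genes share a low-rank spatial basis of smooth isotropic
#' fields (so every gene map is spatially autocorrelated); genes in the
#' planted category instead load on the supplied phenotype with strength
#' `planted_strength`. Differential-stability values are assigned so a
#' stated fraction of background genes falls below the conventional 0.1
#' inclusion threshold, while planted genes always survive it. Decoy
#' categories of background genes are included so enrichment has something
#' to rank against.
#'
#' @param config a [synth_config()].
#' @param phenotype parcel-wise phenotype map (length `n_parcels`).
#' @param coordinates n x 3 parcel coordinates for the spatial basis.
#' @param n_genes total gene count.
#' @param planted_size genes in the planted category.
#' @param planted_strength loading of planted genes on the phenotype, in
#'   (0, 1\]; background-level noise makes up the rest of the variance.
#' @param ds_below_fraction fraction of background genes assigned
#'   differential stability below 0.1.
#' @param n_decoy_categories,decoy_size decoy category layout.
#' @return list with `atlas` (an `expression_atlas`: `expression`,
#'   `gene_symbols`, `differential_stability`), `categories` (named list of
#'   gene-symbol vectors), and `truth` (planted category symbols).
#' @export
make_expression_atlas <- function(config, phenotype, coordinates,
                                  n_genes = 200L, planted_size = 15L,
                                  planted_strength = 0.5,
                                  ds_below_fraction = 0.3,
                                  n_decoy_categories = 10L, decoy_size = 15L) {
  stopifnot(inherits(config, "synth_config"))
  if (length(phenotype) != config$n_parcels) {
    stop("phenotype length must equal n_parcels")
  }
  if (planted_size >= n_genes) stop("planted category larger than the gene pool")
  with_seed(config$rng_seed + 3L, {
    n <- config$n_parcels
    basis <- sapply(seq_len(8L), function(i)
      make_autocorrelated_map(coordinates, n_bumps = 15L, length_scale = 0.6))
    phen <- as.vector(scale(phenotype))
    expr <- matrix(NA_real_, n_genes, n,
                   dimnames = list(sprintf("G%04d", seq_len(n_genes)), NULL))
    planted <- seq_len(planted_size)
    for (g in seq_len(n_genes)) {
      if (g %in% planted) {
        expr[g, ] <- planted_strength * phen +
          sqrt(1 - planted_strength^2) * stats::rnorm(n, sd = 1)
      } else {
        coef <- stats::rnorm(ncol(basis), sd = 1 / sqrt(ncol(basis)))
        expr[g, ] <- as.vector(basis %*% coef) + stats::rnorm(n, sd = config$noise_sd)
      }
    }
    ds <- stats::runif(n_genes, 0.1, 1)
    n_low <- round(ds_below_fraction * (n_genes - planted_size))
    low <- sample(setdiff(seq_len(n_genes), planted), n_low)
    ds[low] <- stats::runif(n_low, 0, 0.0999)
    ds[planted] <- stats::runif(planted_size, 0.5, 1)
    symbols <- rownames(expr)
    categories <- c(
      list(planted = symbols[planted]),
      stats::setNames(
        lapply(seq_len(n_decoy_categories), function(i)
          sample(symbols[-planted], decoy_size)),
        sprintf("decoy%02d", seq_len(n_decoy_categories)))
    )
    atlas <- structure(
      list(expression = expr, gene_symbols = symbols, differential_stability = ds),
      class = "expression_atlas")
    list(atlas = atlas, categories = categories,
         truth = list(planted_category = symbols[planted]))
  })
}
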