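# Shared fixture builders: tiny hand-checkable networks and cohorts.

# Path graph 1-2-3 with configurable weights.
path3_network <- function(w12 = 1, w23 = 1) {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- w12
  w[2, 3] <- w[3, 2] <- w23
  weighted_network(w)
}

# Small connected random network with spherical coordinates.
small_connectome <- function(n = 50, density = 0.2, seed = 1) {
  make_spatial_connectome(synth_config(n_parcels = n, density = density,
                                       rng_seed = seed))
}

# Two-node network with a single symmetric edge.
pair_network <- function(w = 1) {
  m <- matrix(c(0, w, w, 0), 2, 2)
  weighted_network(m)
}

# Parcel-resolution cohort: values constant within parcel are just parcel
# values themselves (one voxel per parcel).
parcel_cohort <- function(n_controls = 30, n_patients = 10, n_parcels = 20,
                          seed = 1, effect = NULL, noise_sd = 0.05) {
  set.seed(seed)
  n <- n_controls + n_patients
  group <- c(rep(0L, n_controls), rep(1L, n_patients))
  age <- rnorm(n, 57, 10)
  sex <- rep_len(c(0L, 1L, 1L, 0L), n)   # both sexes within each site
  site <- rep_len(c("s1", "s2"), n)
  if (is.null(effect)) effect <- rep(0, n_parcels)
  base <- 1 + 0.01 * (site == "s2") - 0.003 * age + 0.02 * sex
  values <- matrix(base, n, n_parcels) - outer(group, effect) +
    matrix(rnorm(n * n_parcels, sd = noise_sd), n, n_parcels)
  voxel_cohort(values, age, sex, site, group)
}
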