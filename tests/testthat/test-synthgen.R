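test_that("spatial connectome honours size, symmetry, density, and connectivity", {
  cfg <- synth_config(n_parcels = 50, density = 0.2, rng_seed = 11)
  net <- make_spatial_connectome(cfg)
  w <- net$weights
  expect_identical(dim(w), c(50L, 50L))
  expect_identical(w, t(w))
  expect_identical(diag(w), rep(0, 50))
  expect_true(all(w >= 0))
  m <- sum(w[upper.tri(w)] > 0)
  expect_lt(abs(m / choose(50, 2) - 0.2), 0.2 * 0.2 + 1e-12)  # ~245 edges +/- 20%
  # full connectivity
  reach <- atrophynet:::connected_component(w > 0)
  expect_true(all(reach))
  # determinism: pure function of (config, seed)
  expect_identical(net$weights, make_spatial_connectome(cfg)$weights)
})

test_that("edge probability decays with distance at the configured rate", {
  fit_slope <- function(decay) {
    cfg <- synth_config(n_parcels = 80, density = 0.25, distance_decay = decay,
                        rng_seed = 21)
    net <- make_spatial_connectome(cfg)
    d <- as.matrix(dist(net$coordinates))
    ut <- upper.tri(d)
    fit <- suppressWarnings(
      glm((net$weights[ut] > 0) ~ d[ut], family = binomial()))
    summary(fit)$coefficients[2, c("Estimate", "z value")]
  }
  flat <- fit_slope(0)
  expect_lt(abs(flat["z value"]), 3)      # no detectable distance effect
  steep <- fit_slope(2)
  expect_lt(steep["Estimate"], 0)
  expect_lt(steep["z value"], -3)         # clearly negative logistic slope
})

test_that("unreachable density/decay combinations fail with a named error", {
  cfg <- synth_config(n_parcels = 12, density = 0.05, rng_seed = 2)
  expect_error(make_spatial_connectome(cfg, max_tries = 3),
               "density.*distance_decay|could not realize")
})

test_that("planted atrophy degenerates to the seed indicator and peaks at the seed", {
  net <- small_connectome(seed = 3)
  ind <- make_planted_atrophy(net, 7, spread_weight = 0, noise_sd = 0)
  expect_equal(ind$map, replace(numeric(50), 7, 1))
  for (w in c(0.3, 0.7, 1)) {
    pa <- make_planted_atrophy(net, 7, spread_weight = w, noise_sd = 0)
    expect_identical(which.max(pa$map), 7L)
  }
  # isolated seed is an error
  wm <- net$weights
  wm[5, ] <- wm[, 5] <- 0
  iso <- weighted_network(wm, net$coordinates)
  expect_error(make_planted_atrophy(iso, 5, 0.5, 0), "isolated")
})

test_that("planted maps are network-correlated: node-neighbour r > 0 across replicates", {
  rs <- vapply(1:50, function(i) {
    cfg <- synth_config(rng_seed = 100 + i, seed_region = (i %% 100) + 1)
    net <- make_spatial_connectome(cfg)
    pa <- make_planted_atrophy(net, cfg$seed_region, cfg$spread_weight,
                               cfg$noise_sd, seed = 900 + i)
    node_neighbour_correlation(net, pa$map)$r
  }, 0)
  expect_true(all(rs > 0))
})

test_that("voxel cohort generator matches its linear model", {
  cfg <- synth_config(n_parcels = 20, n_controls = 30, n_patients = 10,
                      n_sites = 2, rng_seed = 5)
  labels <- rep(1:20, each = 3)
  effect <- seq(0, 1, length.out = 20)
  # zero noise, zero effect: every patient w-score is exactly 0
  co0 <- make_voxel_cohort(cfg, effect, labels, effect_scale = 0, voxel_noise_sd = 0)
  ws0 <- compute_wscores(co0, suppressWarnings(fit_normative_model(co0)))
  expect_true(all(is.na(ws0$values) | abs(ws0$values) < 1e-10))
  # group term is never applied to controls: changing the effect scale
  # leaves control rows untouched
  co_a <- make_voxel_cohort(cfg, effect, labels, effect_scale = 0.1)
  co_b <- make_voxel_cohort(cfg, effect, labels, effect_scale = 0.9)
  ctrl <- co_a$group == 0
  expect_identical(co_a$values[ctrl, ], co_b$values[ctrl, ])
  expect_false(identical(co_a$values[!ctrl, ], co_b$values[!ctrl, ]))
  # OLS on generated controls recovers beta_age within 3 SE
  co <- make_voxel_cohort(cfg, effect, labels, beta_age = -0.003)
  idx <- co$group == 0 & co$site == "site01"
  X <- cbind(age = co$age[idx], sex = co$sex[idx], 1)
  y <- rowMeans(co$values[idx, ])
  beta <- solve(crossprod(X), crossprod(X, y))   # normal-equations oracle
  resid <- y - X %*% beta
  se <- sqrt(sum(resid^2) / (sum(idx) - 3) * solve(crossprod(X))[1, 1])
  expect_lt(abs(beta[1] - (-0.003)), 3 * se)
})

test_that("clinical latent generator plants a recoverable rank-1 structure", {
  cfg1 <- synth_config(n_patients = 40, latent_corr = 1, noise_sd = 1e-8,
                       rng_seed = 6)
  d1 <- make_clinical_latent(cfg1)
  m1 <- fit_pls(d1$brain, d1$clinical$values, scaling = "center")
  expect_gt(m1$cov_explained[1], 1 - 1e-6)
  expect_error(synth_config(latent_corr = 1.2), "latent_corr")
  # unit-norm planted weights
  expect_equal(sum(d1$truth$latent_brain_weights^2), 1)
  expect_equal(sum(d1$truth$latent_behavior_weights^2), 1)
  # determinism and missingness injection
  cfg <- synth_config(n_patients = 30, rng_seed = 7)
  expect_identical(make_clinical_latent(cfg)$brain, make_clinical_latent(cfg)$brain)
  dm <- make_clinical_latent(cfg, missing_rate = 0.2)
  frac <- mean(is.na(dm$clinical$values))
  expect_gt(frac, 0.1); expect_lt(frac, 0.3)
  expect_true(all(colSums(!is.na(dm$clinical$values)) >= 1))
})

test_that("expression atlas plants signal genes and autocorrelated backgrounds", {
  skip_if_not_installed("ape")
  cfg <- synth_config(n_parcels = 60, rng_seed = 8)
  net <- make_spatial_connectome(cfg)
  phen <- make_planted_atrophy(net, 1, 0.7, 0.1, seed = 1)$truth
  ea <- make_expression_atlas(cfg, phen, net$coordinates, n_genes = 100,
                              planted_size = 10, planted_strength = 1)
  # planted_strength = 1 clones the (standardized) phenotype
  expect_equal(cor(ea$atlas$expression[1, ], phen), 1, tolerance = 1e-10)
  # differential stability: planted genes always pass the 0.1 filter
  expect_true(all(ea$atlas$differential_stability[1:10] >= 0.1))
  expect_equal(mean(ea$atlas$differential_stability[-(1:10)] < 0.1), 0.3,
               tolerance = 0.05)
  # background genes carry positive spatial autocorrelation (Moran's I)
  wdist <- 1 / as.matrix(dist(net$coordinates)); diag(wdist) <- 0
  moran <- vapply(51:60, function(g)
    ape::Moran.I(ea$atlas$expression[g, ], wdist)$observed, 0)
  expect_true(all(moran > 0))
  expect_error(
    make_expression_atlas(cfg, phen, net$coordinates, n_genes = 10,
                          planted_size = 10),
    "larger than the gene pool")
})
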