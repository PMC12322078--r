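test_that("normative fit recovers exact linear and constant control data", {
  set.seed(1)
  age <- rnorm(20, 57, 10); sex <- rep_len(c(0, 1), 20)
  # voxel 1: exactly 2 + 0.01 * age; voxel 2: constant 5
  values <- cbind(2 + 0.01 * age, 5)
  co <- voxel_cohort(values, age, sex, rep("s1", 20), rep(0L, 20))
  nm <- fit_normative_model(co)
  b <- nm$sites$s1$beta
  expect_equal(unname(b[, 1]), c(0.01, 0, 2), tolerance = 1e-10)
  expect_equal(unname(b[, 2]), c(0, 0, 5), tolerance = 1e-10)
  expect_equal(unname(nm$sites$s1$residual_sd), c(0, 0), tolerance = 1e-10)
  expect_true(all(nm$sites$s1$degenerate))
  # degenerate voxels propagate missing w-scores
  ws <- compute_wscores(co, nm, target_group = 0)
  expect_true(all(is.na(ws$values)))
})

test_that("normative coefficients match a normal-equations oracle", {
  co <- parcel_cohort(seed = 2)
  nm <- fit_normative_model(co)
  for (s in c("s1", "s2")) {
    idx <- co$group == 0 & co$site == s
    X <- cbind(co$age[idx], co$sex[idx], 1)
    beta <- solve(crossprod(X), crossprod(X, co$values[idx, ]))
    expect_equal(unname(nm$sites[[s]]$beta), unname(beta), tolerance = 1e-8)
    res <- co$values[idx, ] - X %*% beta
    expect_equal(unname(nm$sites[[s]]$residual_sd),
                 unname(sqrt(colSums(res^2) / (sum(idx) - 1))), tolerance = 1e-8)
  }
  # rank-deficient stratum (single sex) errors naming the site
  co_bad <- co
  co_bad$sex[co_bad$site == "s1"] <- 0
  expect_error(fit_normative_model(co_bad), "s1")
})

test_that("w-scores equal the direct deviation formula, sign-inverted", {
  co <- parcel_cohort(seed = 3, effect = seq(0, 0.5, length.out = 20))
  nm <- fit_normative_model(co)
  ws <- compute_wscores(co, nm)
  # direct elementwise evaluation: w = -(obs - expected) / residual_sd
  pat <- which(co$group == 1)
  direct <- matrix(NA_real_, length(pat), 20)
  for (i in seq_along(pat)) {
    s <- co$site[pat[i]]
    expd <- c(co$age[pat[i]], co$sex[pat[i]], 1) %*% nm$sites[[s]]$beta
    direct[i, ] <- -(co$values[pat[i], ] - expd) / nm$sites[[s]]$residual_sd
  }
  expect_equal(unname(ws$values), direct, tolerance = 1e-10)
  # unit deviation: one residual SD below expectation gives inverted w = +1
  co2 <- co
  s <- co$site[pat[1]]
  expd <- c(co$age[pat[1]], co$sex[pat[1]], 1) %*% nm$sites[[s]]$beta
  co2$values[pat[1], ] <- expd - nm$sites[[s]]$residual_sd
  ws2 <- compute_wscores(co2, nm)
  expect_equal(unname(ws2$values[1, ]), rep(1, 20), tolerance = 1e-10)
  # subject from an unknown site fails
  co3 <- co; co3$site[pat[1]] <- "elsewhere"
  expect_error(compute_wscores(co3, nm), "elsewhere")
})

test_that("control w-scores have exact mean 0 and SD 1 per site and voxel", {
  co <- parcel_cohort(seed = 4)
  nm <- fit_normative_model(co)
  ws <- compute_wscores(co, nm, target_group = 0)
  for (s in c("s1", "s2")) {
    rows <- co$site[ws$subjects] == s
    expect_lt(max(abs(colMeans(ws$values[rows, ]))), 1e-10)
    expect_lt(max(abs(apply(ws$values[rows, ], 2, sd) - 1)), 1e-10)
  }
})

test_that("w-scores are invariant under uniform rescaling of input values", {
  co <- parcel_cohort(seed = 5, effect = runif(20))
  nm <- fit_normative_model(co)
  ws <- compute_wscores(co, nm)
  co_scaled <- co
  co_scaled$values <- co$values * 3.7
  ws_scaled <- compute_wscores(co_scaled, fit_normative_model(co_scaled))
  expect_equal(ws$values, ws_scaled$values, tolerance = 1e-8)
})

test_that("parcellate averages member voxels and respects background", {
  labels <- c(0, 1, 1, 2, 2, 2, 0, 3)
  v <- c(99, 4, 6, 1, 2, 3, -99, 7)
  expect_equal(parcellate(v, labels), c(5, 2, 7))
  # matrix input equals a group-by-mean oracle
  set.seed(6)
  M <- matrix(rnorm(5 * 8), 5, 8)
  got <- parcellate(M, labels)
  oracle <- t(apply(M, 1, function(row) tapply(row[labels > 0], labels[labels > 0], mean)))
  expect_equal(unname(got), unname(oracle))
  # empty parcels yield NA, mismatched lengths fail
  expect_true(is.na(parcellate(v, labels, n_parcels = 4)[4]))
  expect_error(parcellate(v, labels[-1]), "length")
})

test_that("parcellating voxel w-scores matches parcel-level computation", {
  co <- parcel_cohort(n_parcels = 10, seed = 7, effect = runif(10))
  # blow each parcel up into 3 identical voxels
  labels <- rep(1:10, each = 3)
  co_vox <- voxel_cohort(co$values[, labels], co$age, co$sex, co$site, co$group)
  ws_vox <- compute_wscores(co_vox, fit_normative_model(co_vox))
  ws_par <- compute_wscores(co, fit_normative_model(co))
  expect_equal(unname(parcellate(ws_vox$values, labels)),
               unname(ws_par$values), tolerance = 1e-10)
})

test_that("class enrichment flags an elevated class and keeps shape", {
  net <- small_connectome(n = 100, seed = 8)
  classes <- rep(sprintf("c%d", 1:5), each = 20)
  # constant map: all class means equal, nothing significant
  const <- class_enrichment(rep(1, 100), classes, net$coordinates,
                            n_spin = 100, seed = 1)
  expect_equal(const$mean, rep(1, 5))
  expect_true(all(const$p_spin == 1))
  # seven classes in, seven rows out
  cl7 <- rep(sprintf("k%d", 1:7), length.out = 100)
  out7 <- class_enrichment(rnorm(100), cl7, net$coordinates, n_spin = 100, seed = 2)
  expect_identical(nrow(out7), 7L)
  # a class elevated by +1 SD is detected by the spin test
  hits <- vapply(1:20, function(i) {
    set.seed(300 + i)
    m <- rnorm(100)
    m[classes == "c2"] <- m[classes == "c2"] + sd(m)
    res <- class_enrichment(m, classes, net$coordinates, n_spin = 1000,
                            seed = 400 + i)
    res$p_spin[res$class == "c2"] < 0.05
  }, TRUE)
  expect_gte(sum(hits), 18)
})

test_that("tract test behaves like a one-sample t on subject tract means", {
  # symmetric subject means (-1, 0, +1) give t = 0, p = 1
  vals <- matrix(c(-1, 0, 1), 3, 4)
  ws <- structure(list(values = vals, subjects = 1:3), class = "wscore_map")
  res <- tract_atrophy_test(ws, rep(1L, 4))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  # sign flip negates t, preserves p
  set.seed(9)
  vals2 <- matrix(rnorm(30 * 6, 1), 30, 6)
  ws2 <- structure(list(values = vals2, subjects = 1:30), class = "wscore_map")
  lab <- rep(1:2, each = 3)
  a <- tract_atrophy_test(ws2, lab)
  ws2n <- ws2; ws2n$values <- -ws2$values
  b <- tract_atrophy_test(ws2n, lab)
  expect_equal(b$t, -a$t)
  expect_equal(b$p, a$p)
  # t for N(1,1) subject means is within 3 Monte-Carlo SEs of sqrt(30)
  t_mc <- replicate(500, {
    x <- rnorm(30, 1)
    mean(x) / (sd(x) / sqrt(30))
  })
  expect_lt(abs(a$t[1] - sqrt(30)), 3 * sd(t_mc))
})
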