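test_that("spin surrogates draw from the original value multiset, deterministically", {
  net <- small_connectome(n = 60, seed = 1)
  v <- make_autocorrelated_map(net$coordinates, seed = 2)
  s <- spin_surrogates(net$coordinates, v, n = 20, seed = 3)
  expect_identical(dim(s), c(60L, 20L))
  expect_true(all(s %in% v))
  expect_identical(s, spin_surrogates(net$coordinates, v, n = 20, seed = 3))
  # off-sphere coordinates fail unless projected
  expect_error(spin_surrogates(net$coordinates * 3, v, n = 2, seed = 1), "sphere")
  expect_silent(spin_surrogates(net$coordinates * 3, v, n = 2, seed = 1,
                                project = TRUE))
})

test_that("masked parcels are never donors", {
  net <- small_connectome(n = 40, seed = 4)
  v <- rnorm(40)
  mask <- seq_len(40) <= 5
  v[mask] <- 999
  s <- spin_surrogates(net$coordinates, v, n = 50, seed = 5, mask = mask)
  expect_false(any(s == 999))
})

test_that("spin surrogates preserve spatial autocorrelation (binned variogram)", {
  net <- small_connectome(n = 80, seed = 6)
  v <- make_autocorrelated_map(net$coordinates, seed = 7)
  s <- spin_surrogates(net$coordinates, v, n = 100, seed = 8)
  d <- as.matrix(dist(net$coordinates))
  ut <- upper.tri(d)
  bins <- cut(d[ut], quantile(d[ut], seq(0, 1, 0.25)), include.lowest = TRUE)
  vgram <- function(x) {
    g <- 0.5 * (outer(x, x, "-")^2)[ut]
    tapply(g, bins, mean)
  }
  obs <- vgram(v)
  sur <- rowMeans(apply(s, 2, vgram))
  expect_lt(max(abs(sur - obs) / obs), 0.3)
  # near/far contrast (the autocorrelation signature) is preserved
  expect_lt(sur[1], sur[4])
})

test_that("degree-preserving rewiring keeps degrees and weights exactly", {
  net <- small_connectome(n = 40, seed = 9)
  rw <- rewire_degree_preserving(net, seed = 10)
  expect_identical(colSums(rw$weights > 0), colSums(net$weights > 0))
  expect_identical(sort(rw$weights[upper.tri(rw$weights) & rw$weights > 0]),
                   sort(net$weights[upper.tri(net$weights) & net$weights > 0]))
  expect_gt(attr(rw, "achieved_swaps"), 0)
  # topology actually changed
  expect_false(identical(rw$weights > 0, net$weights > 0))
})

test_that("rewired 6-node graphs stay within the enumerated degree class", {
  set.seed(11)
  w <- matrix(0, 6, 6)
  pairs <- which(upper.tri(w))
  on <- sample(pairs, 8)
  w[on] <- runif(8, 0.5, 2); w <- w + t(w)
  net <- weighted_network(w)
  deg <- colSums(w > 0)
  # brute-force enumeration of all graphs with this degree sequence
  keys <- character(0)
  for (code in 0:(2^15 - 1)) {
    bits <- as.integer(intToBits(code))[1:15]
    if (sum(bits) != 8) next
    a <- matrix(0L, 6, 6); a[upper.tri(a)] <- bits; a <- a + t(a)
    if (all(colSums(a) == deg)) keys <- c(keys, paste(a[upper.tri(a)], collapse = ""))
  }
  for (i in 1:50) {
    rw <- rewire_degree_preserving(net, seed = 100 + i)
    key <- paste(as.integer(rw$weights[upper.tri(rw$weights)] > 0), collapse = "")
    expect_true(key %in% keys)
  }
})

test_that("distance-binned rewiring preserves per-bin edge counts and degrees", {
  net <- small_connectome(n = 60, seed = 12)
  rw <- rewire_distance_binned(net, seed = 13)
  expect_identical(colSums(rw$weights > 0), colSums(net$weights > 0))
  breaks <- attr(rw, "bin_breaks")
  d <- as.matrix(dist(net$coordinates))
  bin_counts <- function(w) {
    e <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
    table(cut(d[e], breaks, labels = FALSE))
  }
  expect_identical(bin_counts(rw$weights), bin_counts(net$weights))
  expect_gt(attr(rw, "achieved_swaps"), 0)
  # per-bin mean edge length stays inside the original bin envelope
  e_new <- which(upper.tri(rw$weights) & rw$weights > 0, arr.ind = TRUE)
  len_new <- d[e_new]
  bin_new <- cut(len_new, breaks, labels = FALSE)
  e_old <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  len_old <- d[e_old]
  bin_old <- cut(len_old, breaks, labels = FALSE)
  for (b in unique(bin_old)) {
    expect_gte(mean(len_new[bin_new == b]), min(len_old[bin_old == b]) - 1e-12)
    expect_lte(mean(len_new[bin_new == b]), max(len_old[bin_old == b]) + 1e-12)
  }
})

test_that("add-one p-values follow the (k+1)/(n+1) convention", {
  expect_equal(nonparametric_p(5, rep(0, 1000))$p_value, 1 / 1001)
  expect_equal(nonparametric_p(-1, rep(0, 1000))$p_value, 1)
  set.seed(14)
  nulls <- c(runif(950, 0, 1), runif(49, 2, 3))
  expect_equal(nonparametric_p(1.5, nulls)$p_value, 0.05)
  # two-sided counts exceedances in absolute value about the center
  expect_equal(nonparametric_p(1, c(-2, -0.5, 0.5, 2), "two_sided")$p_value,
               3 / 5)
  expect_error(nonparametric_p(1, c(0.2, NaN)), "non-finite")
})

test_that("p-values never drop below the add-one floor", {
  set.seed(15)
  for (n in c(1, 10, 999)) {
    p <- nonparametric_p(100, rnorm(n))$p_value
    expect_gte(p, 1 / (n + 1))
    expect_lte(p, 1)
  }
})

test_that("BH adjustment matches hand arithmetic and a step-up oracle", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.123), 0.123)
  # independent step-up implementation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(16)
  p <- runif(37)
  expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  expect_true(all(fdr_bh(p) >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})
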