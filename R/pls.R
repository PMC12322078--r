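# Column-standardize a matrix, erroring (or signalling) on zero-variance
# columns; scaling = "zscore" | "center" | "none".
pls_preprocess <- function(M, scaling, what) {
  M <- as.matrix(M)
  if (scaling == "none") return(M)
  mu <- colMeans(M)
  M <- sweep(M, 2, mu)
  if (scaling == "zscore") {
    s <- apply(M, 2, stats::sd)
    if (any(s == 0)) {
      bad <- which(s == 0)
      nm <- colnames(M)[bad]
      if (is.null(nm)) nm <- as.character(bad)
      stop(sprintf("zero-variance %s column(s) under z-scoring: %s",
                   what, paste(nm, collapse = ", ")))
    }
    M <- sweep(M, 2, s, "/")
  }
  M
}

# SVD of the cross-covariance of preprocessed X and Y, with the package
# sign convention: the largest-magnitude element of each left singular
# vector is positive (the matching right vector is flipped with it).
pls_svd <- function(Xp, Yp) {
  R <- crossprod(Xp, Yp) / (nrow(Xp) - 1)
  sv <- svd(R)
  L <- length(sv$d)
  for (k in seq_len(L)) {
    i <- which.max(abs(sv$u[, k]))
    if (sv$u[i, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  sv
}

#' Behavioural partial least squares
#'
#' Relates a subject-by-parcel brain matrix to a subject-by-measure
#' behaviour matrix via singular value decomposition of their
#' cross-covariance, `X'Y = U S V'`. Each latent variable pairs a brain
#' pattern (column of U) with a behavioural pattern (column of V); the
#' covariance explained by latent variable k is `s_k^2 / sum(s^2)`.
#' Subject brain and behaviour scores are the projections `X U` and `Y V`.
#' Columns are z-scored by default before the decomposition; singular
#' vector signs follow a deterministic convention (largest-magnitude brain
#' weight positive), so results are reproducible across platforms.
#'
#' @param X subject x parcel brain matrix (>= 3 subjects).
#' @param Y subject x measure behaviour matrix, same subjects.
#' @param scaling `"zscore"` (default), `"center"`, or `"none"`.
#' @return a `pls_model` with `U`, `V`, `S`, `cov_explained`,
#'   `brain_scores`, `behavior_scores`, the preprocessed matrices `Xp`,
#'   `Yp`, and `scaling`.
#' @export
fit_pls <- function(X, Y, scaling = c("zscore", "center", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of subjects")
  if (nrow(X) < 3L) stop("need at least 3 subjects")
  if (anyNA(X) || anyNA(Y)) stop("X and Y must be complete; impute first (impute_median)")
  Xp <- pls_preprocess(X, scaling, "brain")
  Yp <- pls_preprocess(Y, scaling, "behavior")
  sv <- pls_svd(Xp, Yp)
  structure(list(U = sv$u, V = sv$v, S = sv$d,
                 cov_explained = sv$d^2 / sum(sv$d^2),
                 brain_scores = Xp %*% sv$u,
                 behavior_scores = Yp %*% sv$v,
                 Xp = Xp, Yp = Yp, scaling = scaling),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d subjects, %d brain x %d behaviour features\n",
              nrow(x$Xp), ncol(x$Xp), ncol(x$Yp)))
  cat("covariance explained:",
      paste(sprintf("%.1f%%", 100 * utils::head(x$cov_explained, 5)), collapse = ", "),
      if (length(x$cov_explained) > 5) "...\n" else "\n")
  invisible(x)
}

#' Permutation test for PLS latent variables
#'
#' Rows of the brain matrix are randomly permuted (breaking the
#' subject-level link to behaviour while preserving both marginals), the
#' cross-covariance SVD is recomputed, and each latent variable's singular
#' value is compared with its null distribution at the same index; p-values
#' use the add-one convention `(k + 1) / (n + 1)`.
#'
#' @param model a fitted [fit_pls()] model.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional RNG seed.
#' @return list with `p` (per latent variable) and `null_singular_values`
#'   (n_perm x L).
#' @export
permute_pls <- function(model, n_perm = 1000L, seed = NULL) {
  stopifnot(inherits(model, "pls_model"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  n <- nrow(model$Xp)
  L <- length(model$S)
  with_seed(seed, {
    nulls <- matrix(NA_real_, n_perm, L)
    for (b in seq_len(n_perm)) {
      svp <- svd(crossprod(model$Xp[sample.int(n), , drop = FALSE], model$Yp) / (n - 1))
      nulls[b, ] <- svp$d
    }
    p <- vapply(seq_len(L), function(k) {
      (sum(nulls[, k] >= model$S[k]) + 1) / (n_perm + 1)
    }, 0)
    list(p = p, null_singular_values = nulls)
  })
}

#' Bootstrap stability of PLS weights
#'
#' Subjects are resampled with replacement, the PLS decomposition is
#' recomputed on each resample (re-standardizing within the resample), and
#' each resample's singular vectors are sign-aligned to the original by
#' correlation. The bootstrap ratio of a feature is its original singular
#' vector weight divided by the bootstrap standard error; large ratios mark
#' features that contribute strongly and consistently.
#'
#' @param model a fitted [fit_pls()] model.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional RNG seed.
#' @param max_retries redraws allowed when a resample has a zero-variance
#'   column.
#' @return list with `brain_bsr` (parcel x L) and `behavior_bsr`
#'   (measure x L) bootstrap ratios, plus the bootstrap standard errors.
#' @export
bootstrap_pls <- function(model, n_boot = 1000L, seed = NULL, max_retries = 100L) {
  stopifnot(inherits(model, "pls_model"))
  if (n_boot < 1L) stop("n_boot must be >= 1")
  n <- nrow(model$Xp)
  L <- length(model$S)
  with_seed(seed, {
    u_boot <- array(NA_real_, c(nrow(model$U), L, n_boot))
    v_boot <- array(NA_real_, c(nrow(model$V), L, n_boot))
    for (b in seq_len(n_boot)) {
      for (r in seq_len(max_retries)) {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- model$Xp[idx, , drop = FALSE]
        Yb <- model$Yp[idx, , drop = FALSE]
        ok <- tryCatch({
          if (model$scaling == "zscore") {
            Xb <- pls_preprocess(Xb, "zscore", "brain")
            Yb <- pls_preprocess(Yb, "zscore", "behavior")
          }
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
        if (r == max_retries) stop("could not draw a resample without zero-variance columns")
      }
      sv <- svd(crossprod(Xb, Yb) / (n - 1))
      for (k in seq_len(L)) {
        flip <- sign(sum(sv$u[, k] * model$U[, k]))
        if (flip == 0) flip <- 1
        u_boot[, k, b] <- flip * sv$u[, k]
        v_boot[, k, b] <- flip * sv$v[, k]
      }
    }
    u_se <- apply(u_boot, c(1, 2), stats::sd)
    v_se <- apply(v_boot, c(1, 2), stats::sd)
    list(brain_bsr = model$U / u_se, behavior_bsr = model$V / v_se,
         brain_se = u_se, behavior_se = v_se)
  })
}

# One split-half evaluation: fit on a random half, project the held-out
# half onto the training weights, return the test-set LV score correlation.
crossval_once <- function(X, Y, lv, scaling) {
  n <- nrow(X)
  train <- sample.int(n, floor(n / 2))
  test <- setdiff(seq_len(n), train)
  mx <- colMeans(X[train, , drop = FALSE]); my <- colMeans(Y[train, , drop = FALSE])
  Xtr <- sweep(X[train, , drop = FALSE], 2, mx); Ytr <- sweep(Y[train, , drop = FALSE], 2, my)
  Xte <- sweep(X[test, , drop = FALSE], 2, mx); Yte <- sweep(Y[test, , drop = FALSE], 2, my)
  if (scaling == "zscore") {
    sx <- apply(Xtr, 2, stats::sd); sy <- apply(Ytr, 2, stats::sd)
    sx[sx == 0] <- 1; sy[sy == 0] <- 1
    Xtr <- sweep(Xtr, 2, sx, "/"); Ytr <- sweep(Ytr, 2, sy, "/")
    Xte <- sweep(Xte, 2, sx, "/"); Yte <- sweep(Yte, 2, sy, "/")
  }
  sv <- pls_svd(Xtr, Ytr)
  stats::cor(Xte %*% sv$u[, lv], Yte %*% sv$v[, lv])[1]
}

#' Split-half cross-validation of the PLS brain-behaviour correlation
#'
#' Repeatedly splits the cohort in half, fits the PLS decomposition on the
#' training half, projects the held-out half onto the training singular
#' vectors, and correlates the held-out brain and behaviour scores for the
#' chosen latent variable. Significance is assessed by shuffling the rows
#' of the brain matrix and repeating the whole split procedure, comparing
#' median out-of-sample correlations with the add-one convention.
#'
#' @param X,Y subject x feature matrices (>= 8 subjects; test halves must
#'   hold >= 3 subjects).
#' @param n_splits random half-splits (default 100).
#' @param n_perm row-shuffle permutations for the null (default 100; 0
#'   skips the permutation test).
#' @param lv latent variable evaluated (default 1).
#' @param scaling as in [fit_pls()].
#' @param seed optional RNG seed.
#' @return list with `correlations` (length `n_splits`), `median_r`, and,
#'   when `n_perm > 0`, `p` and `null_medians`.
#' @export
crossval_pls <- function(X, Y, n_splits = 100L, n_perm = 100L, lv = 1L,
                         scaling = c("zscore", "center", "none"), seed = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) < 8L) stop("cross-validation needs at least 8 subjects")
  if (floor(nrow(X) / 2) < 3L || nrow(X) - floor(nrow(X) / 2) < 3L) {
    stop("test half would hold fewer than 3 subjects")
  }
  with_seed(seed, {
    r_obs <- replicate(n_splits, crossval_once(X, Y, lv, scaling))
    out <- list(correlations = r_obs, median_r = stats::median(r_obs))
    if (n_perm > 0) {
      null_med <- replicate(n_perm, {
        Xs <- X[sample.int(nrow(X)), , drop = FALSE]
        stats::median(replicate(n_splits, crossval_once(Xs, Y, lv, scaling)))
      })
      out$p <- (sum(null_med >= out$median_r) + 1) / (n_perm + 1)
      out$null_medians <- null_med
    }
    out
  })
}
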