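#' @useDynLib atrophynet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd lm lm.fit p.adjust pt qnorm rbinom rnorm runif
#'   median quantile complete.cases wilcox.test var
NULL

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG
# state afterwards; with seed = NULL the current stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Fisher r-to-z transform with clipping
#'
#' Correlations are clipped to +/- (1 - 1e-7) before `atanh` so that perfect
#' correlations map to a large finite value rather than infinity.
#'
#' @param r numeric vector or matrix of correlation coefficients.
#' @param clip clipping bound applied to `abs(r)` before `atanh`.
#' @return transformed values, same shape as `r`.
#' @export
fisher_z <- function(r, clip = 1 - 1e-7) {
  atanh(pmin(pmax(r, -clip), clip))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Thin wrapper around [stats::p.adjust()] with `method = "BH"`, the
#' package-wide multiple-testing convention. `NA` entries are preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, monotone and capped at 1.
#' @export
fdr_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Nonparametric p-value from a null ensemble
#'
#' Computes the add-one exceedance p-value `(k + 1) / (n + 1)`, where `k`
#' counts null statistics at least as extreme as the observed one. With 1000
#' nulls and no exceedance this floors at 1/1001 = 9.99e-4, the smallest
#' p-value a 1000-draw ensemble can support. One-sided counts
#' `null >= observed`; two-sided counts `|null - center| >= |observed -
#' center|` (default center 0).
#'
#' @param observed observed scalar statistic.
#' @param nulls numeric vector of null statistics (finite, non-empty).
#' @param sidedness `"one_sided_greater"` or `"two_sided"`.
#' @param center reference point for the two-sided comparison.
#' @param method optional tag recording how the ensemble was generated.
#' @return an object of class `surrogate_ensemble` with elements `observed`,
#'   `nulls`, `method`, `sidedness`, `p_value`.
#' @export
nonparametric_p <- function(observed, nulls,
                            sidedness = c("one_sided_greater", "two_sided"),
                            center = 0, method = NA_character_) {
  sidedness <- match.arg(sidedness)
  if (length(nulls) < 1L) stop("null ensemble is empty")
  if (any(!is.finite(nulls))) stop("null ensemble contains non-finite values")
  if (!is.finite(observed)) stop("observed statistic is not finite")
  k <- if (sidedness == "one_sided_greater") {
    sum(nulls >= observed)
  } else {
    sum(abs(nulls - center) >= abs(observed - center))
  }
  structure(
    list(observed = observed, nulls = nulls, method = method,
         sidedness = sidedness,
         p_value = (k + 1) / (length(nulls) + 1)),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("Surrogate ensemble (%s, %s): observed = %.4g, n_null = %d, p = %.4g\n",
              if (is.na(x$method)) "unspecified" else x$method,
              x$sidedness, x$observed, length(x$nulls), x$p_value))
  invisible(x)
}

# Fractional (average-tie) ranks, ascending: largest value -> largest rank.
rank_ascending <- function(x) rank(x, ties.method = "average", na.last = "keep")

#' Read and write parcel-indexed TSV matrices
#'
#' Square networks, map vectors, and feature-by-parcel matrices are
#' exchanged as plain tab-separated files with a header row of parcel (or
#' column) identifiers and row names in the first column.
#'
#' @param x matrix (or vector, written as a 1-column matrix) to write.
#' @param path file path.
#' @return `read_tsv_matrix` returns a numeric matrix with dimnames.
#' @export
write_tsv_matrix <- function(x, path) {
  if (is.null(dim(x))) x <- cbind(value = x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}
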