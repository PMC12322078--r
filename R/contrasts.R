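#' Clinical measures table
#'
#' Subject-by-measure matrix of clinical/behavioural scores with missing
#' markers (`NA`), unique measure names, and a per-subject group label
#' (e.g. spinal/bulbar onset).
#'
#' @param values subject x measure numeric matrix, `NA` for missing.
#' @param group per-subject group labels.
#' @param measure_names unique measure names (default: column names).
#' @return a `clinical_table`.
#' @export
clinical_table <- function(values, group, measure_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(measure_names)) measure_names <- sprintf("measure%02d", seq_len(ncol(values)))
  if (anyDuplicated(measure_names)) stop("measure names must be unique")
  if (length(group) != nrow(values)) stop("group labels must match subjects")
  colnames(values) <- measure_names
  structure(list(values = values, group = as.character(group),
                 measure_names = measure_names),
            class = "clinical_table")
}

#' @export
print.clinical_table <- function(x, ...) {
  cat(sprintf("Clinical table: %d subjects x %d measures, %.1f%% missing; groups: %s\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values)),
              paste(names(table(x$group)), collapse = ", ")))
  invisible(x)
}

#' Median imputation of missing clinical measures
#'
#' Missing cells are replaced by the observed median of their measure;
#' observed cells are untouched. An imputation mask is returned alongside.
#'
#' @param table a [clinical_table()].
#' @return list with `table` (imputed) and `mask` (logical matrix of
#'   imputed cells). Fully missing measures are an error.
#' @export
impute_median <- function(table) {
  stopifnot(inherits(table, "clinical_table"))
  v <- table$values
  all_missing <- colSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop(sprintf("measure(s) with no observed values: %s",
                 paste(table$measure_names[all_missing], collapse = ", ")))
  }
  mask <- is.na(v)
  med <- unname(apply(v, 2, stats::median, na.rm = TRUE))
  for (j in seq_len(ncol(v))) v[mask[, j], j] <- med[j]
  list(table = clinical_table(v, table$group, table$measure_names), mask = mask)
}

#' Parcelwise t-contrast of subject map stacks
#'
#' Compares two groups of subjects at every parcel of a subject-by-parcel
#' map stack (e.g. individual epicenter likelihood maps) with an
#' independent two-sample t-test (group a minus group b; pooled-variance
#' Student by default, Welch optionally), two-sided p-values, and
#' Benjamini-Hochberg correction across parcels. Parcels with zero
#' variance in both groups return `NA`.
#'
#' @param maps subject x parcel matrix.
#' @param group per-subject group labels.
#' @param group_a,group_b labels of the two groups (each >= 3 subjects).
#' @param var_equal pooled-variance Student t (default) or Welch.
#' @return data.frame with `parcel`, `t`, `p`, `p_fdr`.
#' @export
parcelwise_ttest <- function(maps, group, group_a, group_b, var_equal = TRUE) {
  maps <- as.matrix(maps)
  if (length(group) != nrow(maps)) stop("group labels must match map rows")
  ia <- group == group_a
  ib <- group == group_b
  if (sum(ia) < 3L || sum(ib) < 3L) stop("each group needs >= 3 subjects")
  res <- t(apply(maps, 2, function(x) {
    xa <- x[ia]; xb <- x[ib]
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) return(c(NA_real_, NA_real_))
    ht <- stats::t.test(xa, xb, var.equal = var_equal)
    c(unname(ht$statistic), ht$p.value)
  }))
  data.frame(parcel = seq_len(ncol(maps)), t = res[, 1], p = res[, 2],
             p_fdr = fdr_bh(res[, 2]))
}

#' Behavioural contrast between patient subtypes
#'
#' Compares each clinical measure between two groups with a two-sided
#' Mann-Whitney U test on observed values only (missing cells are simply
#' dropped), followed by Benjamini-Hochberg correction across measures.
#' The exact distribution is used for small tie-free samples (both groups
#' <= 8), the normal approximation with tie correction otherwise.
#' Measures observed in fewer than `min_observed` subjects across the two
#' groups are excluded and reported.
#'
#' @param table a [clinical_table()].
#' @param group_a,group_b group labels to compare.
#' @param min_observed minimum observed subjects for a measure to enter
#'   (default 20).
#' @return data.frame with `measure`, `n_a`, `n_b`, `U`, `p`, `p_fdr`;
#'   excluded measures are listed in attribute `"excluded"`.
#' @export
behavioral_contrast <- function(table, group_a, group_b, min_observed = 20L) {
  stopifnot(inherits(table, "clinical_table"))
  ia <- table$group == group_a
  ib <- table$group == group_b
  rows <- lapply(seq_len(ncol(table$values)), function(j) {
    xa <- table$values[ia, j]; xa <- xa[!is.na(xa)]
    xb <- table$values[ib, j]; xb <- xb[!is.na(xb)]
    list(measure = table$measure_names[j], n_a = length(xa), n_b = length(xb),
         xa = xa, xb = xb)
  })
  observed <- vapply(rows, function(r) r$n_a + r$n_b, 0L)
  excluded <- vapply(rows, function(r) r$measure, "")[observed < min_observed]
  rows <- rows[observed >= min_observed]
  if (!length(rows)) stop("no measure meets the observation threshold")
  for (r in rows) {
    if (r$n_a < 2L || r$n_b < 2L) {
      stop(sprintf("measure '%s' has fewer than 2 observed values in a group", r$measure))
    }
  }
  stat <- t(vapply(rows, function(r) {
    exact <- max(r$n_a, r$n_b) <= 8L &&
      !anyDuplicated(c(r$xa, r$xb))
    ht <- suppressWarnings(stats::wilcox.test(r$xa, r$xb, exact = exact,
                                              correct = !exact))
    c(unname(ht$statistic), ht$p.value)
  }, c(0, 0)))
  out <- data.frame(measure = vapply(rows, `[[`, "", "measure"),
                    n_a = vapply(rows, `[[`, 0L, "n_a"),
                    n_b = vapply(rows, `[[`, 0L, "n_b"),
                    U = stat[, 1], p = stat[, 2], p_fdr = fdr_bh(stat[, 2]),
                    row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}
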