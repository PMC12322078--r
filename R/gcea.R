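#' Gene-by-parcel expression atlas
#'
#' @param expression gene x parcel numeric matrix.
#' @param gene_symbols unique gene identifiers (default: rownames).
#' @param differential_stability per-gene across-donor consistency in
#'   \[-1, 1\], used as an inclusion filter.
#' @return an `expression_atlas`.
#' @export
expression_atlas <- function(expression, gene_symbols = rownames(expression),
                             differential_stability) {
  expression <- as.matrix(expression)
  if (is.null(gene_symbols)) stop("gene_symbols are required")
  if (length(gene_symbols) != nrow(expression)) {
    stop("gene_symbols must match expression rows")
  }
  if (length(differential_stability) != nrow(expression)) {
    stop("differential_stability must match expression rows")
  }
  if (anyNA(expression)) stop("expression must not contain missing parcels")
  structure(list(expression = expression, gene_symbols = as.character(gene_symbols),
                 differential_stability = differential_stability),
            class = "expression_atlas")
}

# Collapse duplicate gene symbols by averaging their expression rows (and
# differential stability), deterministically by symbol order of first
# appearance.
collapse_duplicates <- function(atlas) {
  if (!anyDuplicated(atlas$gene_symbols)) return(atlas)
  sym <- factor(atlas$gene_symbols, levels = unique(atlas$gene_symbols))
  expr <- rowsum(atlas$expression, sym, reorder = FALSE) /
    as.vector(table(sym)[levels(sym)])
  ds <- as.vector(rowsum(atlas$differential_stability, sym, reorder = FALSE)) /
    as.vector(table(sym)[levels(sym)])
  expression_atlas(expr, levels(sym), ds)
}

#' Correlate every gene's expression map with a phenotype
#'
#' Genes with differential stability below `ds_threshold` are removed (the
#' conventional 0.1 cut), duplicate symbols are averaged, each surviving
#' gene's parcel-wise expression is Pearson-correlated with the phenotype
#' map, and the Fisher r-to-z transform is applied (clipped so perfect
#' correlations stay finite). Constant gene maps are dropped with a
#' warning.
#'
#' @param atlas an [expression_atlas()].
#' @param phenotype parcel-wise phenotype map.
#' @param ds_threshold differential-stability inclusion threshold.
#' @return named numeric vector of z-transformed correlations.
#' @export
gene_map_correlations <- function(atlas, phenotype, ds_threshold = 0.1) {
  stopifnot(inherits(atlas, "expression_atlas"))
  if (ncol(atlas$expression) != length(phenotype)) {
    stop("phenotype length must match the atlas parcels")
  }
  atlas <- collapse_duplicates(atlas)
  keep <- atlas$differential_stability >= ds_threshold
  expr <- atlas$expression[keep, , drop = FALSE]
  syms <- atlas$gene_symbols[keep]
  constant <- apply(expr, 1, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning(sprintf("%d constant gene map(s) dropped", sum(constant)))
    expr <- expr[!constant, , drop = FALSE]
    syms <- syms[!constant]
  }
  r <- as.vector(stats::cor(t(expr), phenotype))
  stats::setNames(fisher_z(r), syms)
}

#' Category scores from per-gene correlations
#'
#' The c-score of a category is the mean z-transformed correlation of its
#' member genes (those matched in the per-gene vector). Categories with no
#' matched gene are excluded with a warning; unmatched symbols are
#' reported.
#'
#' @param gene_z named vector from [gene_map_correlations()].
#' @param categories named list mapping category labels to gene-symbol
#'   vectors.
#' @return list with `scores` (named c-score vector), `n_matched` (genes
#'   per category), and `unmatched` (per-category unmatched symbols).
#' @export
category_scores <- function(gene_z, categories) {
  if (is.null(names(gene_z))) stop("gene_z must be a named vector")
  matched <- lapply(categories, function(g) intersect(unique(g), names(gene_z)))
  empty <- lengths(matched) == 0L
  if (any(empty)) {
    warning(sprintf("category(ies) with no matched genes excluded: %s",
                    paste(names(categories)[empty], collapse = ", ")))
  }
  keep <- !empty
  list(scores = vapply(matched[keep], function(g) mean(gene_z[g]), 0),
       n_matched = lengths(matched[keep]),
       unmatched = lapply(categories, function(g) setdiff(unique(g), names(gene_z))))
}

#' Ensemble-null gene category enrichment
#'
#' Tests whether gene categories are more correlated with a phenotype map
#' than with spatially matched random maps. The phenotype is spun
#' `n_null` times (spatial-autocorrelation-preserving surrogates on the
#' parcel centroids); for the observed and every surrogate map, each
#' gene's expression is correlated and z-transformed and category c-scores
#' are formed as member means; the positive-sided add-one p compares each
#' observed c-score against its surrogate ensemble, with
#' Benjamini-Hochberg correction across categories.
#'
#' @param atlas an [expression_atlas()].
#' @param phenotype parcel-wise phenotype map.
#' @param categories named list of gene-symbol vectors.
#' @param coordinates n x 3 spherical parcel centroids.
#' @param n_null number of surrogate maps (>= 100; publication-scale analyses
#'   use far more, but the add-one convention keeps any size valid).
#' @param ds_threshold differential-stability inclusion threshold.
#' @param seed optional RNG seed.
#' @return data.frame sorted by c-score: `category`, `n_genes`, `c_score`,
#'   `p`, `p_fdr`.
#' @export
gcea_test <- function(atlas, phenotype, categories, coordinates,
                      n_null = 1000L, ds_threshold = 0.1, seed = NULL) {
  if (n_null < 100L) stop("n_null must be >= 100")
  gene_z <- gene_map_correlations(atlas, phenotype, ds_threshold)
  obs <- category_scores(gene_z, categories)
  spins <- spin_surrogates(coordinates, phenotype, n = n_null, seed = seed)
  # z-transformed correlation of every surviving gene with every surrogate
  atlas2 <- collapse_duplicates(atlas)
  keep <- atlas2$gene_symbols %in% names(gene_z)
  expr <- atlas2$expression[keep, , drop = FALSE]
  syms <- atlas2$gene_symbols[keep]
  null_z <- fisher_z(stats::cor(t(expr), spins))
  rownames(null_z) <- syms
  cats <- names(obs$scores)
  p <- vapply(cats, function(cl) {
    members <- intersect(unique(categories[[cl]]), syms)
    nulls <- colMeans(null_z[members, , drop = FALSE])
    (sum(nulls >= obs$scores[[cl]]) + 1) / (n_null + 1)
  }, 0)
  res <- data.frame(category = cats, n_genes = as.integer(obs$n_matched),
                    c_score = unname(obs$scores), p = unname(p),
                    p_fdr = unname(fdr_bh(p)), row.names = NULL)
  res[order(res$c_score, decreasing = TRUE), , drop = FALSE]
}
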