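#' Gene expression matrix
#'
#' Genes-by-regions expression table aligned with the model's region
#' ordering.
#'
#' @param values genes x regions numeric matrix
#' @param gene_ids character vector of gene labels
#' @param region_ids character vector of region labels
#' @return an object of class `expression_matrix`
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              region_ids = colnames(values)) {
  values <- as.matrix(values)
  if (nrow(values) < 2)
    pmfm_stop("need at least 2 genes", "pmfm_invalid_input")
  if (!all(is.finite(values)))
    pmfm_stop("expression values must be finite", "pmfm_invalid_input")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(values)))
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(ncol(values)))
  dimnames(values) <- list(gene_ids, region_ids)
  structure(list(values = values, gene_ids = as.character(gene_ids),
                 region_ids = as.character(region_ids)),
            class = "expression_matrix")
}

#' Parcel centroids on the unit sphere
#'
#' @param xyz N x 3 matrix of unit vectors (one per region)
#' @param region_ids optional labels
#' @return an object of class `parcel_centroids`
#' @export
parcel_centroids <- function(xyz, region_ids = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) pmfm_stop("centroids must be N x 3", "pmfm_shape_error")
  norms <- sqrt(rowSums(xyz^2))
  if (any(abs(norms - 1) > 1e-9))
    pmfm_stop("centroids must have unit norm (tolerance 1e-9)",
              "pmfm_validation_error")
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(xyz)))
  structure(list(xyz = xyz, region_ids = as.character(region_ids)),
            class = "parcel_centroids")
}

# z-score across regions
zscore <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    pmfm_stop("degenerate normalization: zero variance", "pmfm_invalid_input")
  (v - mean(v)) / s
}

#' Differential expression map of two genes
#'
#' Z-normalises each gene's expression across regions and returns the
#' per-region difference gene_a - gene_b (e.g. the PVALB - SST contrast).
#'
#' @param expr an [expression_matrix()]
#' @param gene_a,gene_b gene identifiers present in `expr`
#' @return a [spatial_map()]
#' @export
differential_expression_map <- function(expr, gene_a, gene_b) {
  for (g in c(gene_a, gene_b))
    if (!g %in% expr$gene_ids)
      pmfm_stop(sprintf("gene '%s' not found", g), "pmfm_missing_gene")
  if (ncol(expr$values) < 2)
    pmfm_stop("degenerate normalization: need >= 2 regions", "pmfm_invalid_input")
  a <- zscore(expr$values[gene_a, ])
  b <- zscore(expr$values[gene_b, ])
  spatial_map(a - b, name = paste0(gene_a, "-", gene_b),
              region_ids = expr$region_ids)
}

#' Correlation between two spatial maps
#'
#' @param map_a,map_b [spatial_map()] objects (or plain numeric vectors) of
#'   equal length >= 3
#' @return Pearson correlation
#' @export
map_correlation <- function(map_a, map_b) {
  a <- if (inherits(map_a, "spatial_map")) map_a$values else as.numeric(map_a)
  b <- if (inherits(map_b, "spatial_map")) map_b$values else as.numeric(map_b)
  if (length(a) != length(b) || length(a) < 3)
    pmfm_stop("maps must have equal length >= 3", "pmfm_shape_error")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    pmfm_stop("zero-variance map", "pmfm_invalid_input")
  stats::cor(a, b)
}

# uniform random rotation matrix: QR of a Gaussian matrix with sign fix,
# reflected if needed so det = +1
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Spin test for spatial map correlations
#'
#' Permutation test that preserves spatial autocorrelation: the parcellation
#' is randomly rotated on the sphere `n_rot` times; after each rotation
#' every parcel inherits the `map_b` value of the nearest rotated parcel,
#' and the correlation with `map_a` is recomputed, yielding a null
#' distribution. The two-sided p-value uses the add-one estimator
#' p = (1 + #\{|null| >= |observed|\}) / (1 + n_rot).
#'
#' @param map_a,map_b [spatial_map()] objects
#' @param centroids a [parcel_centroids()] object
#' @param n_rot number of random rotations
#' @param seed RNG seed
#' @return list with `observed`, `null` (length n_rot) and `p`
#' @export
spin_test <- function(map_a, map_b, centroids, n_rot = 1000, seed = NULL) {
  if (n_rot < 1) pmfm_stop("n_rot must be >= 1", "pmfm_invalid_input")
  xyz <- centroids$xyz
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  if (min(d) < 1e-9)
    pmfm_stop("degenerate centroids: duplicates present", "pmfm_validation_error")
  if (!is.null(seed)) set.seed(seed)
  observed <- map_correlation(map_a, map_b)
  b <- if (inherits(map_b, "spatial_map")) map_b$values else as.numeric(map_b)
  null <- vapply(seq_len(n_rot), function(k) {
    R <- random_rotation()
    rotated <- xyz %*% t(R)
    # each parcel takes the value of the nearest rotated parcel
    idx <- max.col(xyz %*% t(rotated), ties.method = "first")
    map_correlation(map_a, b[idx])
  }, numeric(1))
  list(observed = observed, null = null,
       p = (1 + sum(abs(null) >= abs(observed))) / (1 + n_rot))
}

#' Random-gene-pair specificity test
#'
#' Null distribution of correlations between `map_a` and differential
#' expression maps of randomly drawn distinct gene pairs (the reference pair
#' is excluded from the draw, in either order). The observed statistic is
#' the correlation of `map_a` with the reference pair's difference map.
#' Two-sided add-one p-value as in [spin_test()].
#'
#' @param map_a a [spatial_map()]
#' @param expr an [expression_matrix()] with >= 3 genes
#' @param n_pairs number of random pairs
#' @param seed RNG seed
#' @param reference_pair character vector of 2 gene ids (observed contrast;
#'   excluded from the null draws)
#' @return list with `observed`, `null` (length n_pairs) and `p`
#' @export
random_gene_pair_test <- function(map_a, expr, n_pairs = 1000, seed = NULL,
                                  reference_pair) {
  if (length(expr$gene_ids) < 3)
    pmfm_stop("need at least 3 genes", "pmfm_invalid_input")
  if (n_pairs < 1) pmfm_stop("n_pairs must be >= 1", "pmfm_invalid_input")
  if (!is.null(seed)) set.seed(seed)
  observed <- map_correlation(
    map_a, differential_expression_map(expr, reference_pair[1], reference_pair[2]))
  genes <- expr$gene_ids
  null <- numeric(n_pairs)
  k <- 0L
  while (k < n_pairs) {
    pair <- sample(genes, 2)
    if (setequal(pair, reference_pair)) next
    k <- k + 1L
    null[k] <- map_correlation(
      map_a, differential_expression_map(expr, pair[1], pair[2]))
  }
  list(observed = observed, null = null,
       p = (1 + sum(abs(null) >= abs(observed))) / (1 + n_pairs))
}

#' First principal component of gene expression
#'
#' Principal-component scores across regions of the gene-standardised
#' expression matrix (each gene z-scored across regions). The sign is fixed
#' so the score correlates nonnegatively with the mean standardised
#' expression profile.
#'
#' @param expr an [expression_matrix()] with >= 2 genes and >= 3 regions
#' @return a [spatial_map()] of PC1 scores; the share of variance explained
#'   is attached as attribute `"var_explained"`
#' @export
expression_pc1_map <- function(expr) {
  X <- expr$values
  if (ncol(X) < 3) pmfm_stop("need at least 3 regions", "pmfm_invalid_input")
  Xz <- t(apply(X, 1, zscore))
  pc <- stats::prcomp(t(Xz), center = FALSE, scale. = FALSE)
  if (pc$sdev[1] < 1e-12) pmfm_stop("rank-0 expression matrix", "pmfm_invalid_input")
  scores <- pc$x[, 1]
  ref <- colMeans(Xz)
  s <- sum(scores * ref)
  if (s < 0 || (s == 0 && scores[1] < 0)) scores <- -scores
  out <- spatial_map(as.numeric(scores), name = "expression_pc1",
                     region_ids = expr$region_ids)
  attr(out, "var_explained") <- pc$sdev[1]^2 / sum(pc$sdev^2)
  out
}
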