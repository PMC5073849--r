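#' PCA of samples in DE-gene expression space
#'
#' Principal component analysis of the samples using the log2 intensities of
#' a chosen gene set (typically the union of all DE genes). Genes are
#' centered but not scaled, so the components are linear combinations of
#' log2 expression with DE selection already controlling scale. The
#' pairwise Euclidean distance matrix between samples in the full
#' (centered) DE-gene space is returned alongside the scores.
#'
#' @param ds An [ExpressionDataset].
#' @param genes Gene ids to use (e.g. from [union_de_over_stages]); must be
#'   non-empty and present in the dataset.
#' @param center Center genes before decomposition (default `TRUE`).
#' @return A `PCAResult`: list with `scores` (samples x components),
#'   `loadings` (genes x components, orthonormal), `var_explained`
#'   (fractions, non-increasing), `center` (per-gene means), and `dist`
#'   (samples x samples Euclidean distance matrix).
#' @export
pca_on_de_genes <- function(ds, genes, center = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (length(genes) == 0L) stop("empty gene set")
  absent <- setdiff(genes, rownames(ds$values))
  if (length(absent) > 0L)
    stop("genes absent from dataset: ",
         paste(utils::head(absent, 5L), collapse = ", "))
  if (ncol(ds$values) < 2L) stop("need >= 2 samples")
  x <- t(log2(ds$values[genes, , drop = FALSE]))  # samples x genes
  pc <- stats::prcomp(x, center = center, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  d <- as.matrix(stats::dist(x))
  structure(list(scores = pc$x, loadings = pc$rotation,
                 var_explained = ve,
                 center = if (center) pc$center else rep(0, ncol(x)),
                 dist = d),
            class = "PCAResult")
}

#' Write PCA tables (scores, loadings, variance, distances)
#'
#' @param pca A `PCAResult`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_pca <- function(pca, dir, prefix = "pca") {
  stopifnot(inherits(pca, "PCAResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name, rowlab) {
    p <- file.path(dir, paste0(prefix, "_", name, ".tsv"))
    utils::write.table(data.frame(id = rownames(x), x, check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(w(pca$scores, "scores"),
             w(pca$loadings, "loadings"),
             w(pca$dist, "euclidean_distances"))
  vp <- file.path(dir, paste0(prefix, "_variance_explained.tsv"))
  utils::write.table(
    data.frame(component = seq_along(pca$var_explained),
               fraction = pca$var_explained),
    vp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, vp))
}

#' Hierarchical clustering of gene profiles
#'
#' Agglomerative clustering of per-gene standardized log2 profiles under
#' Euclidean distance (the heatmap-style gene dendrogram). Leaf order is
#' the deterministic order produced by the agglomeration.
#'
#' @param mat Genes x samples (or populations) matrix of linear
#'   intensities, >= 2 genes.
#' @param linkage Agglomeration method (default "average").
#' @param standardize Row-standardize log2 profiles first (default `TRUE`),
#'   so shape rather than level drives the tree.
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster_genes <- function(mat, linkage = "average",
                                       standardize = TRUE) {
  if (nrow(mat) < 2L) stop("need >= 2 genes")
  z <- if (standardize) standardize_profiles(mat) else log2(mat)
  stats::hclust(stats::dist(z), method = linkage)
}

#' Export a gene dendrogram as Newick text
#'
#' @param hc An `hclust` object (e.g. from [hierarchical_cluster_genes]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_dendrogram_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
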