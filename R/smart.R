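#' Configuration for the SMART split-merge clusterer
#'
#' SMART (splitting-merging awareness tactics) clusters gene profiles
#' without a user-fixed cluster number: starting from a single cluster it
#' repeatedly bisects the most dispersed cluster with a seeded 2-means and
#' keeps a split only when the data support it, then merges cluster pairs
#' whose centroids are nearly collinear. Run many times with different seeds
#' it feeds the consensus stage.
#'
#' @param n_runs Number of ensemble runs (default 100).
#' @param max_merges Maximum merges per run (default 10).
#' @param merge_corr_threshold Pearson correlation between cluster centroids
#'   at or above which two clusters are merged (default 0.9).
#' @param split_alpha Significance level of the split test: a 2-means
#'   bisection is kept only if the Anderson-Darling test rejects Gaussianity
#'   of the cluster's projection onto the separation axis at this level.
#'   Smaller values split more conservatively.
#' @param max_k Safety cap on the number of clusters.
#' @param min_split_size Clusters smaller than this are never split (the
#'   split test needs enough points).
#' @param seed_base First seed of the ensemble; run i uses `seed_base + i - 1`.
#' @return A `SmartConfig` list.
#' @export
smart_config <- function(n_runs = 100, max_merges = 10,
                         merge_corr_threshold = 0.9, split_alpha = 1e-3,
                         max_k = 20, min_split_size = 8, seed_base = 1) {
  stopifnot(n_runs >= 1, max_merges >= 0, merge_corr_threshold > 0,
            merge_corr_threshold < 1, split_alpha > 0, split_alpha < 1,
            max_k >= 1, min_split_size >= 8)
  structure(list(n_runs = as.integer(n_runs),
                 max_merges = as.integer(max_merges),
                 merge_corr_threshold = merge_corr_threshold,
                 split_alpha = split_alpha,
                 max_k = as.integer(max_k),
                 min_split_size = as.integer(min_split_size),
                 seed_base = as.integer(seed_base)),
            class = "SmartConfig")
}

# Row-standardize log2 profiles: zero mean, unit variance per gene. For
# standardized rows Euclidean distance is a monotone function of
# (1 - Pearson correlation), so 2-means on these rows is 2-means under
# correlation distance. Flat (zero-variance) genes map to the zero vector.
standardize_profiles <- function(profiles) {
  m <- log2(profiles)
  mu <- rowMeans(m)
  sdev <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sdev > 0, sdev, 1)
  z[sdev == 0, ] <- 0
  z
}

# Within-cluster dispersion: total squared distance to the centroid.
cluster_wss <- function(z, idx) {
  if (length(idx) < 2L) return(0)
  sub <- z[idx, , drop = FALSE]
  sum(sweep(sub, 2L, colMeans(sub))^2)
}

# Attempt to bisect one cluster. Returns NULL if the split is not supported:
# the cluster's projection onto the axis joining the two 2-means centroids
# must be detectably non-Gaussian (Anderson-Darling) for the split to stand.
try_split <- function(z, idx, cfg) {
  sub <- z[idx, , drop = FALSE]
  if (nrow(unique(sub)) < 2L) return(NULL)
  km <- NULL
  for (attempt in 1:5) {   # re-draw centers if kmeans drew duplicate rows
    km <- tryCatch(stats::kmeans(sub, centers = 2L, nstart = 1L),
                   error = function(e) NULL)
    if (!is.null(km)) break
  }
  if (is.null(km) || length(unique(km$cluster)) < 2L) return(NULL)
  v <- km$centers[1L, ] - km$centers[2L, ]
  vn <- sqrt(sum(v^2))
  if (vn == 0) return(NULL)
  proj <- as.vector(sub %*% (v / vn))
  if (stats::sd(proj) == 0) return(NULL)
  ad <- tryCatch(nortest::ad.test(proj), error = function(e) NULL)
  if (is.null(ad) || is.na(ad$p.value) || ad$p.value >= cfg$split_alpha)
    return(NULL)
  list(a = idx[km$cluster == 1L], b = idx[km$cluster == 2L])
}

#' One SMART clustering run
#'
#' Clusters the rows of a population-profile matrix (typically restricted to
#' the DE genes of one dataset). Profiles are log2-transformed and
#' row-standardized internally, so cluster shape rather than expression
#' level drives the result. The run is deterministic given `seed`.
#'
#' @param profiles Genes x populations matrix of linear intensities (e.g.
#'   from [collapse_to_population_medians]), >= 2 genes and >= 2 populations.
#' @param config A [smart_config()].
#' @param seed Integer seed for this run.
#' @return A `Partition`: list with `labels` (named integer vector, values
#'   1..k), `k`, `n_merges`, `seed`.
#' @export
smart_run <- function(profiles, config = smart_config(), seed = 1) {
  stopifnot(inherits(config, "SmartConfig"))
  if (nrow(profiles) < 2L) stop("need >= 2 genes to cluster")
  if (ncol(profiles) < 2L) stop("need >= 2 populations")
  z <- standardize_profiles(profiles)
  set.seed(seed)

  clusters <- list(seq_len(nrow(z)))
  splittable <- TRUE
  # SPLIT phase: repeatedly bisect the most dispersed splittable cluster
  while (any(splittable) && length(clusters) < config$max_k) {
    wss <- vapply(clusters, function(idx) cluster_wss(z, idx), numeric(1L))
    cand <- order(-wss)                       # ties: lowest index first
    cand <- cand[splittable[cand] &
                   lengths(clusters)[cand] >= config$min_split_size &
                   wss[cand] > 0]
    if (length(cand) == 0L) break
    i <- cand[1L]
    sp <- try_split(z, clusters[[i]], config)
    if (is.null(sp)) {
      splittable[i] <- FALSE
    } else {
      clusters[[i]] <- sp$a
      clusters[[length(clusters) + 1L]] <- sp$b
      splittable[i] <- TRUE
      splittable[length(clusters)] <- TRUE
    }
  }

  # MERGE phase: join the most correlated centroid pair, up to max_merges
  n_merges <- 0L
  while (n_merges < config$max_merges && length(clusters) > 1L) {
    cent <- t(vapply(clusters,
                     function(idx) colMeans(z[idx, , drop = FALSE]),
                     numeric(ncol(z))))
    if (any(apply(cent, 1L, stats::sd) == 0)) break
    cc <- stats::cor(t(cent))
    diag(cc) <- -Inf
    best <- which(cc == max(cc), arr.ind = TRUE)[1L, ]
    if (cc[best[1L], best[2L]] < config$merge_corr_threshold) break
    i <- min(best); j <- max(best)
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    n_merges <- n_merges + 1L
  }

  # renumber by smallest member index for determinism
  ord <- order(vapply(clusters, min, integer(1L)))
  labels <- integer(nrow(z))
  for (k in seq_along(ord)) labels[clusters[[ord[k]]]] <- k
  names(labels) <- rownames(profiles)
  structure(list(labels = labels, k = length(clusters),
                 n_merges = n_merges, seed = as.integer(seed)),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat("Partition:", length(x$labels), "genes in", x$k, "clusters (seed",
      x$seed, ")\n")
  invisible(x)
}

#' Run SMART repeatedly to build an ensemble
#'
#' Runs [smart_run] `config$n_runs` times with seeds `seed_base`,
#' `seed_base + 1`, ... The whole ensemble is reproducible from
#' `config$seed_base`.
#'
#' @param profiles Genes x populations matrix of linear intensities.
#' @param config A [smart_config()].
#' @return List of `Partition` objects of length `config$n_runs`.
#' @export
smart_ensemble <- function(profiles, config = smart_config()) {
  stopifnot(inherits(config, "SmartConfig"))
  lapply(seq_len(config$n_runs) - 1L,
         function(i) smart_run(profiles, config, seed = config$seed_base + i))
}

#' Write an ensemble of partitions to disk
#'
#' One tab-separated gene -> cluster table per run, plus a manifest listing
#' seed, k and merges used per run.
#'
#' @param ensemble List of `Partition` objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_partitions <- function(ensemble, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(ensemble)) {
    p <- ensemble[[i]]
    utils::write.table(
      data.frame(gene = names(p$labels), cluster = unname(p$labels)),
      file.path(dir, sprintf("partition_%03d.tsv", i)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(
    run = seq_along(ensemble),
    seed = vapply(ensemble, `[[`, integer(1L), "seed"),
    k = vapply(ensemble, `[[`, integer(1L), "k"),
    n_merges = vapply(ensemble, `[[`, integer(1L), "n_merges"))
  mp <- file.path(dir, "runs_manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mp)
}
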