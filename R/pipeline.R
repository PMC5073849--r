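#' Ordered population design per dataset
#'
#' Derives, from a sample sheet, the ordered population labels of each
#' dataset after applying exclusions (the adult design, for instance, drops
#' SEM-F d12 to keep an odd number - 11 - of population points).
#'
#' @param sheet Sample-sheet data frame with columns `dataset` and
#'   `population` (order of first appearance is kept).
#' @param exclusions Named list: dataset -> character vector of population
#'   labels to omit. Naming an unknown population is an error.
#' @return Named list of ordered population-label vectors, one per dataset.
#' @export
assemble_sample_design <- function(sheet, exclusions = list()) {
  stopifnot(all(c("dataset", "population") %in% names(sheet)))
  datasets <- unique(sheet$dataset)
  unknown_ds <- setdiff(names(exclusions), datasets)
  if (length(unknown_ds) > 0L)
    stop("exclusions name unknown dataset(s): ",
         paste(unknown_ds, collapse = ", "))
  out <- lapply(datasets, function(d) {
    pops <- unique(sheet$population[sheet$dataset == d])
    excl <- exclusions[[d]]
    unknown <- setdiff(excl, pops)
    if (length(unknown) > 0L)
      stop("cannot exclude unknown population(s) in dataset '", d, "': ",
           paste(unknown, collapse = ", "))
    setdiff(pops, excl)
  })
  names(out) <- datasets
  out
}

#' Configuration for the full consensus pipeline
#'
#' @param control_genes Control genes for [normalize_by_controls].
#' @param criteria DE selection thresholds ([de_criteria()]).
#' @param exclusions Population exclusions per dataset (see
#'   [assemble_sample_design]).
#' @param smart A [smart_config()]; its `seed_base` is overridden from
#'   `seed` at run time.
#' @param delta Bi-CoPaM binarisation tuning parameter (default 0: one
#'   cluster per gene).
#' @param min_cols Minimum Bimax columns; `NULL` (default) means the number
#'   of input datasets, so consensus clusters must span every dataset.
#' @param min_rows Minimum Bimax rows (default 2).
#' @param min_cluster_size Size threshold for the final (strict) cluster
#'   filter; default 30, i.e. clusters of more than 30 genes are reported.
#' @param cluster_universe Genes fed to SMART: `"de"` (default; the union
#'   of DE genes per dataset) or `"expressed"` (all expression-filtered
#'   genes).
#' @param seed Master seed; all per-run SMART seeds derive from it.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(control_genes = c("ACTB", "PAFAH1B2"),
                            criteria = de_criteria(),
                            exclusions = list(),
                            smart = smart_config(),
                            delta = 0,
                            min_cols = NULL,
                            min_rows = 2L,
                            min_cluster_size = 30,
                            cluster_universe = c("de", "expressed"),
                            seed = 1) {
  cluster_universe <- match.arg(cluster_universe)
  stopifnot(inherits(criteria, "DESelectionCriteria"),
            inherits(smart, "SmartConfig"), delta >= 0, min_rows >= 1)
  structure(list(control_genes = control_genes, criteria = criteria,
                 exclusions = exclusions, smart = smart, delta = delta,
                 min_cols = min_cols, min_rows = as.integer(min_rows),
                 min_cluster_size = min_cluster_size,
                 cluster_universe = cluster_universe,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

# expand a binary membership to a larger gene universe (zero rows for genes
# the dataset did not cluster)
expand_membership <- function(bin, universe) {
  out <- matrix(0L, nrow = length(universe), ncol = ncol(bin),
                dimnames = list(universe, colnames(bin)))
  common <- intersect(rownames(bin), universe)
  out[common, ] <- unclass(bin)[common, , drop = FALSE]
  class(out) <- c("BinaryMembership", class(out))
  out
}

#' Run the full cross-dataset consensus analysis
#'
#' End-to-end orchestration: control-gene normalisation, expression
#' filtering, per-dataset DE union over all stage pairs, replicate-median
#' population profiles, SMART x n_runs per dataset, Bi-CoPaM consensus and
#' delta-binarisation, cross-dataset Bimax, the strict >`min_cluster_size`
#' filter, and PCA / gene dendrogram views. Fully deterministic given
#' `config$seed`: dataset d (1-based) uses SMART seeds
#' `seed + (d-1) * n_runs + (0 .. n_runs-1)`.
#'
#' @param datasets Named list of [ExpressionDataset] objects (one per cell
#'   source), or of `c(matrix_path, sample_sheet_path)` pairs to read.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all stage outputs
#'   are written as tab-separated text / gene-set files and the manifest
#'   records their MD5 hashes.
#' @return A list with per-stage results: `design`, `de_genes`, `profiles`,
#'   `ensembles`, `copams`, `memberships`, `cross`, `biclusters`,
#'   `consensus_clusters`, `consensus_clusters_filtered`, `pca`,
#'   `dendrograms`, and `manifest` (parameters, seeds, per-stage counts,
#'   and file hashes when `out_dir` is used).
#' @export
run_pipeline <- function(datasets, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"), length(datasets) >= 1L)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("ds", seq_along(datasets))
  datasets <- lapply(datasets, function(d) {
    if (inherits(d, "ExpressionDataset")) d else read_expression(d[1L], d[2L])
  })
  stage <- "normalize"
  res <- list()
  tryCatch({
    datasets <- lapply(datasets, normalize_by_controls,
                       control_genes = config$control_genes)

    stage <- "design"
    sheet_all <- do.call(rbind, lapply(datasets, `[[`, "samples"))
    res$design <- assemble_sample_design(sheet_all, config$exclusions)

    stage <- "de"
    res$de_genes <- lapply(names(datasets), function(d) {
      if (config$cluster_universe == "expressed")
        expression_filter(datasets[[d]], config$criteria$expr_min)
      else
        union_de_over_stages(datasets[[d]], config$criteria,
                             populations = res$design[[d]])
    })
    names(res$de_genes) <- names(datasets)

    stage <- "profiles"
    res$profiles <- lapply(names(datasets), function(d) {
      excl <- config$exclusions[[d]]
      if (is.null(excl)) excl <- character()
      prof <- collapse_to_population_medians(datasets[[d]], exclude = excl)
      prof[res$de_genes[[d]], , drop = FALSE]
    })
    names(res$profiles) <- names(datasets)

    stage <- "smart"
    res$ensembles <- lapply(seq_along(datasets), function(i) {
      sc <- config$smart
      sc$seed_base <- config$seed + (i - 1L) * sc$n_runs
      smart_ensemble(res$profiles[[i]], sc)
    })
    names(res$ensembles) <- names(datasets)

    stage <- "bicopam"
    res$copams <- lapply(res$ensembles,
                         function(e) build_copam(align_partitions(e)))
    res$memberships <- lapply(res$copams, binarise_dtb, delta = config$delta)

    stage <- "consensus"
    universe <- rownames(datasets[[1L]]$values)
    expanded <- lapply(res$memberships, expand_membership,
                       universe = universe)
    res$cross <- assemble_cross_matrix(expanded)
    min_cols <- if (is.null(config$min_cols)) length(datasets) else
      config$min_cols
    res$biclusters <- bimax(res$cross, min_rows = config$min_rows,
                            min_cols = min_cols)
    res$consensus_clusters <- extract_consensus_clusters(res$biclusters,
                                                         res$cross)
    res$consensus_clusters_filtered <-
      filter_clusters_by_size(res$consensus_clusters,
                              min_size = config$min_cluster_size)

    stage <- "explore"
    res$pca <- lapply(names(datasets), function(d) {
      g <- res$de_genes[[d]]
      if (length(g) == 0L) return(NULL)
      pca_on_de_genes(datasets[[d]], g)
    })
    names(res$pca) <- names(datasets)
    res$dendrograms <- lapply(names(datasets), function(d) {
      if (nrow(res$profiles[[d]]) < 2L) return(NULL)
      hierarchical_cluster_genes(res$profiles[[d]])
    })
    names(res$dendrograms) <- names(datasets)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("erythroclust")),
    seed = config$seed,
    parameters = list(
      criteria = unclass(config$criteria),
      smart = unclass(config$smart),
      delta = config$delta,
      min_cols = if (is.null(config$min_cols)) length(datasets) else
        config$min_cols,
      min_rows = config$min_rows,
      min_cluster_size = config$min_cluster_size,
      cluster_universe = config$cluster_universe),
    counts = list(
      genes_in = vapply(datasets, function(d) nrow(d$values), integer(1L)),
      de_genes = lengths(res$de_genes),
      smart_k = lapply(res$ensembles, function(e)
        vapply(e, `[[`, integer(1L), "k")),
      clusters_per_dataset = vapply(res$memberships,
                                    function(m) sum(colSums(m) > 0),
                                    numeric(1L)),
      consensus_clusters = length(res$consensus_clusters),
      consensus_clusters_filtered = length(res$consensus_clusters_filtered)))

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    for (d in names(res$memberships)) {
      utils::write.table(
        data.frame(gene = rownames(res$copams[[d]]), res$copams[[d]],
                   check.names = FALSE),
        file.path(out_dir, paste0(d, "_copam.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_sets(cluster_sets(res$memberships[[d]]),
                      file.path(out_dir, paste0(d, "_clusters.gmt")))
      if (!is.null(res$dendrograms[[d]]))
        write_dendrogram_newick(res$dendrograms[[d]],
                                file.path(out_dir,
                                          paste0(d, "_dendrogram.nwk")))
      if (!is.null(res$pca[[d]]))
        write_pca(res$pca[[d]], out_dir, prefix = paste0(d, "_pca"))
    }
    write_gene_sets(res$consensus_clusters,
                    file.path(out_dir, "consensus_clusters.gmt"))
    write_gene_sets(res$consensus_clusters_filtered,
                    file.path(out_dir, "consensus_clusters_gt30.gmt"))
    files <- list.files(out_dir, full.names = TRUE)
    manifest$file_md5 <- tools::md5sum(files)
  }
  res$manifest <- manifest
  res
}
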