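#' Configuration for the synthetic three-dataset simulator
#'
#' Describes a simulated version of the three-source erythroid study design:
#' three datasets over a shared gene universe (11 adult, 3 cord-blood and 3
#' hiPSC population points by default, 3 replicates each), with planted
#' co-expression clusters that are either shared by all datasets or specific
#' to one dataset, two constant high-intensity control genes (ACTB and
#' PAFAH1B2), a floor of non-expressed genes below the expression filter,
#' and multiplicative log-normal measurement noise.
#'
#' @param n_genes Number of non-control genes in the universe.
#' @param n_clusters_shared Number of planted clusters shared by all datasets.
#' @param n_clusters_specific Number of planted clusters specific to each
#'   dataset (each dataset gets its own block of genes).
#' @param cluster_size Genes per planted cluster.
#' @param populations_per_dataset Named list of ordered population labels,
#'   one element per dataset.
#' @param replicates Replicates per population (>= 2; the study used 3).
#' @param noise_sd_log2 SD of the additive Gaussian noise on log2 intensities
#'   (multiplicative log-normal on the linear scale).
#' @param de_fraction Either `NULL` (derived from the cluster layout) or 0 to
#'   switch off all planted structure (every gene flat).
#' @param amplitude_log2 Peak-to-trough amplitude of the planted profile
#'   templates, in log2 units (default 2, i.e. 4-fold swings).
#' @param baseline_log2 log2 baseline intensity of profiled and flat
#'   expressed genes (default 9, i.e. 512).
#' @param floor_intensity Linear intensity of the non-expressed floor genes;
#'   default 50, below the canonical 100 filter.
#' @param floor_fraction Fraction of the non-cluster genes placed at the
#'   floor (the rest are flat but expressed).
#' @param control_intensity Linear intensity of the two control genes.
#' @param seed Integer seed; all randomness is derived from it.
#' @return A validated `SimulationConfig` list.
#' @export
simulation_config <- function(n_genes = 500,
                              n_clusters_shared = 4,
                              n_clusters_specific = 2,
                              cluster_size = 40,
                              populations_per_dataset = NULL,
                              replicates = 3,
                              noise_sd_log2 = 0.25,
                              de_fraction = NULL,
                              amplitude_log2 = 2,
                              baseline_log2 = 9,
                              floor_intensity = 50,
                              floor_fraction = 0.5,
                              control_intensity = 5000,
                              seed = 1) {
  if (is.null(populations_per_dataset))
    populations_per_dataset <- default_population_design()
  stopifnot(n_genes >= 0, n_clusters_shared >= 0, n_clusters_specific >= 0,
            cluster_size >= 1, replicates >= 2, noise_sd_log2 >= 0,
            floor_intensity > 0, floor_fraction >= 0, floor_fraction <= 1,
            control_intensity > 0, length(populations_per_dataset) >= 1)
  if (is.null(names(populations_per_dataset)) ||
      anyDuplicated(names(populations_per_dataset)))
    stop("'populations_per_dataset' must be a uniquely named list")
  if (!is.null(de_fraction)) {
    stopifnot(de_fraction >= 0, de_fraction <= 1)
    if (de_fraction == 0) {
      n_clusters_shared <- 0L
      n_clusters_specific <- 0L
    }
  }
  n_ds <- length(populations_per_dataset)
  n_profiled <- (n_clusters_shared + n_ds * n_clusters_specific) * cluster_size
  if (n_profiled > n_genes)
    stop("cluster layout needs ", n_profiled, " genes but n_genes = ", n_genes)
  n_shapes <- n_clusters_shared + n_clusters_specific
  if (n_shapes > length(shape_bank()))
    stop("at most ", length(shape_bank()),
         " distinct profile shapes are available; reduce cluster counts")
  structure(list(n_genes = as.integer(n_genes),
                 n_clusters_shared = as.integer(n_clusters_shared),
                 n_clusters_specific = as.integer(n_clusters_specific),
                 cluster_size = as.integer(cluster_size),
                 populations_per_dataset = populations_per_dataset,
                 replicates = as.integer(replicates),
                 noise_sd_log2 = noise_sd_log2,
                 amplitude_log2 = amplitude_log2,
                 baseline_log2 = baseline_log2,
                 floor_intensity = floor_intensity,
                 floor_fraction = floor_fraction,
                 control_intensity = control_intensity,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' The published three-source population design
#'
#' Ordered population labels per dataset: 11 adult population points (the
#' 12th, SEM-F d12, is omitted), and 3 points each (d0, d7, d14) for cord
#' blood and hiPSC.
#'
#' @return Named list of character vectors.
#' @export
default_population_design <- function() {
  list(
    adult = c("d0", "SEMF_d4", "SEMI_d4", "SEMF_d7minus", "SEMF_d7plus",
              "SEMF_d7_BEADS", "SEMI_d7_BEADS", "SEMF_d10", "SEMF_d14_BEADS",
              "SEMF_d14", "SEMI_d14"),
    cord = c("d0", "d7", "d14"),
    hipsc = c("d0", "d7", "d14")
  )
}

# Template shape functions over pseudotime t in [0, 1]. Shapes are chosen so
# that any two standardized templates correlate below the 0.9 SMART merge
# threshold even when sampled at only 3 population points.
shape_bank <- function() {
  list(
    up = function(t) t,
    down = function(t) 1 - t,
    peak = function(t) 1 - 2 * abs(t - 0.5),
    dip = function(t) 2 * abs(t - 0.5),
    late_up = function(t) pmax(0, 2 * (t - 0.5)),
    early_down = function(t) pmax(0, 1 - 2 * t)
  )
}

# log2 template for one cluster in one dataset: baseline + amplitude * shape
# evaluated at equally spaced pseudotimes over the dataset's populations.
cluster_template <- function(shape_idx, n_pops, cfg) {
  t <- if (n_pops == 1L) 0.5 else seq(0, 1, length.out = n_pops)
  cfg$baseline_log2 + cfg$amplitude_log2 * shape_bank()[[shape_idx]](t)
}

#' Simulate the three-dataset study
#'
#' Generates one replicate-level [ExpressionDataset] per dataset plus the
#' planted ground truth. Gene blocks are laid out deterministically: first
#' the shared clusters (identical membership and template shape in every
#' dataset), then one block of dataset-specific clusters per dataset (flat in
#' the other datasets), then flat expressed genes, then floor genes below the
#' expression filter; the controls ACTB and PAFAH1B2 are appended at high
#' constant intensity. Noise is additive Gaussian on log2 intensities.
#' Output is deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `datasets` (named list of [ExpressionDataset]) and
#'   `truth` (class `GroundTruth`): per-dataset gene -> cluster assignment,
#'   `shared_cluster_ids`, and per-dataset log2 templates per cluster.
#' @export
simulate_datasets <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)
  ds_names <- names(cfg$populations_per_dataset)
  n_ds <- length(ds_names)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  all_genes <- c(genes, "ACTB", "PAFAH1B2")

  # cluster ids: s1..s_nshared shared, then <ds>_k1.. specific
  shared_ids <- if (cfg$n_clusters_shared > 0)
    paste0("shared", seq_len(cfg$n_clusters_shared)) else character()
  gene_ptr <- 0L
  take <- function(n) {
    idx <- gene_ptr + seq_len(n); gene_ptr <<- gene_ptr + n; genes[idx]
  }
  members <- list()
  for (cid in shared_ids) members[[cid]] <- take(cfg$cluster_size)
  specific_ids <- list()
  for (d in ds_names) {
    ids <- if (cfg$n_clusters_specific > 0)
      paste0(d, "_specific", seq_len(cfg$n_clusters_specific)) else character()
    specific_ids[[d]] <- ids
    for (cid in ids) members[[cid]] <- take(cfg$cluster_size)
  }
  n_rest <- cfg$n_genes - gene_ptr
  n_floor <- round(n_rest * cfg$floor_fraction)
  flat_genes <- if (n_rest - n_floor > 0) take(n_rest - n_floor) else character()
  floor_genes <- if (n_floor > 0) take(n_floor) else character()

  # per-dataset assignment table
  assignment <- matrix(NA_character_, nrow = length(all_genes), ncol = n_ds,
                       dimnames = list(all_genes, ds_names))
  for (d in ds_names) {
    for (cid in c(shared_ids, specific_ids[[d]]))
      assignment[members[[cid]], d] <- cid
  }

  templates <- list()
  datasets <- list()
  for (d in ds_names) {
    pops <- cfg$populations_per_dataset[[d]]
    n_pops <- length(pops)
    n_samp <- n_pops * cfg$replicates
    sample_ids <- as.vector(t(outer(pops, seq_len(cfg$replicates),
                                    function(p, r) paste(d, p, r, sep = "_"))))
    sheet <- data.frame(
      sample_id = sample_ids,
      dataset = d,
      population = rep(pops, each = cfg$replicates),
      day = rep(sub(".*d", "", sub("_BEADS|minus|plus", "", pops)),
                each = cfg$replicates),
      medium = rep(ifelse(grepl("SEMI", pops), "SEM-i", "SEM-F"),
                   each = cfg$replicates),
      replicate = rep(seq_len(cfg$replicates), times = n_pops),
      stringsAsFactors = FALSE)

    log2mean <- matrix(cfg$baseline_log2, nrow = length(all_genes),
                       ncol = n_pops, dimnames = list(all_genes, pops))
    templates[[d]] <- list()
    cluster_ids_d <- c(shared_ids, specific_ids[[d]])
    for (i in seq_along(cluster_ids_d)) {
      cid <- cluster_ids_d[i]
      shape_idx <- if (cid %in% shared_ids) match(cid, shared_ids) else
        cfg$n_clusters_shared + match(cid, specific_ids[[d]])
      tmpl <- cluster_template(shape_idx, n_pops, cfg)
      templates[[d]][[cid]] <- stats::setNames(tmpl, pops)
      log2mean[members[[cid]], ] <- matrix(tmpl, nrow = cfg$cluster_size,
                                           ncol = n_pops, byrow = TRUE)
    }
    if (length(floor_genes) > 0)
      log2mean[floor_genes, ] <- log2(cfg$floor_intensity)
    log2mean[c("ACTB", "PAFAH1B2"), ] <- log2(cfg$control_intensity)

    expanded <- log2mean[, rep(seq_len(n_pops), each = cfg$replicates),
                         drop = FALSE]
    noise <- matrix(stats::rnorm(length(expanded), sd = cfg$noise_sd_log2),
                    nrow = nrow(expanded))
    vals <- 2^(expanded + noise)
    colnames(vals) <- sample_ids
    datasets[[d]] <- ExpressionDataset(vals, sheet)
  }

  truth <- structure(list(assignment = assignment,
                          members = members,
                          shared_cluster_ids = shared_ids,
                          specific_cluster_ids = specific_ids,
                          flat_genes = flat_genes,
                          floor_genes = floor_genes,
                          templates = templates),
                     class = "GroundTruth")
  list(datasets = datasets, truth = truth)
}

#' Write a simulated dataset (and optionally the ground truth) to disk
#'
#' Serialises an [ExpressionDataset] with [write_expression] so it
#' round-trips through [read_expression].
#'
#' @param ds An [ExpressionDataset].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the written paths.
#' @export
write_fixture <- function(ds, dir, prefix = "dataset") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "_matrix.tsv"))
  sp <- file.path(dir, paste0(prefix, "_samples.tsv"))
  write_expression(ds, mp, sp)
  invisible(c(matrix = mp, samples = sp))
}

#' Write the planted gene-to-cluster table
#'
#' @param truth A `GroundTruth` from [simulate_datasets].
#' @param path Output path for the tab-separated gene -> cluster table
#'   (one column per dataset; empty string means unassigned).
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  tab <- data.frame(gene = rownames(truth$assignment),
                    truth$assignment, check.names = FALSE,
                    stringsAsFactors = FALSE)
  tab[is.na(tab)] <- ""
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
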