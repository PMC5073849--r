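#' Replicate-level expression dataset
#'
#' Bundles a genes x samples matrix of strictly positive linear-scale
#' intensities with its per-sample metadata. This is the unit every other
#' function in the package consumes: one `ExpressionDataset` per cell source
#' (e.g. adult blood, cord blood, hiPSC).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids). All entries must be finite and
#'   strictly positive so that log2 is defined.
#' @param sample_info Data frame with one row per sample, in column order of
#'   `values`, holding at least the columns `sample_id`, `dataset`,
#'   `population`, `day`, `medium`, `replicate`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` and `samples`.
#' @examples
#' m <- matrix(2^rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' sheet <- data.frame(sample_id = paste0("s", 1:4), dataset = "ds",
#'                     population = rep(c("d0", "d7"), each = 2),
#'                     day = rep(c(0, 7), each = 2), medium = "SEM-F",
#'                     replicate = rep(1:2, 2))
#' ds <- ExpressionDataset(m, sheet)
#' @export
ExpressionDataset <- function(values, sample_info) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  genes <- rownames(values)
  samples <- colnames(values)
  if (nrow(values) > 0L && is.null(genes))
    stop("'values' must have gene ids as rownames")
  if (is.null(samples)) stop("'values' must have sample ids as colnames")
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive or non-numeric intensity at gene '",
         genes[bad[1L, 1L]], "', sample '", samples[bad[1L, 2L]],
         "' (all intensities must be > 0; log2 must be defined)")
  required <- c("sample_id", "dataset", "population", "day", "medium",
                "replicate")
  missing_cols <- setdiff(required, names(sample_info))
  if (length(missing_cols) > 0L)
    stop("sample sheet is missing columns: ",
         paste(missing_cols, collapse = ", "))
  sample_info <- as.data.frame(sample_info)
  if (!identical(as.character(sample_info$sample_id), samples))
    stop("sample sheet rows must match matrix columns (same ids, same order)")
  rownames(sample_info) <- NULL
  structure(list(values = values, samples = sample_info),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat("ExpressionDataset:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$samples$population)), "populations\n")
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$values)

#' Read an expression matrix and its sample sheet
#'
#' Reads a tab-separated intensity matrix (first column gene id, remaining
#' columns one per sample) together with a tab-separated sample sheet
#' (`sample_id`, `dataset`, `population`, `day`, `medium`, `replicate`) and
#' validates them into an [ExpressionDataset]. File order is preserved.
#'
#' @param matrix_path Path to the tab-separated intensity matrix.
#' @param sample_sheet_path Path to the tab-separated sample sheet.
#' @return An [ExpressionDataset].
#' @export
read_expression <- function(matrix_path, sample_sheet_path) {
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  if (!file.exists(sample_sheet_path))
    stop("no such file: ", sample_sheet_path)
  tab <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  sheet <- utils::read.delim(sample_sheet_path, check.names = FALSE,
                             stringsAsFactors = FALSE)
  if (ncol(tab) < 1L) stop("matrix file has no columns: ", matrix_path)
  gene_ids <- as.character(tab[[1L]])
  vals <- tab[, -1L, drop = FALSE]
  non_num <- names(vals)[!vapply(vals, is.numeric, logical(1L))]
  if (length(non_num) > 0L)
    stop("non-numeric intensity column(s): ", paste(non_num, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  sheet_ids <- as.character(sheet$sample_id)
  missing_in_matrix <- setdiff(sheet_ids, colnames(m))
  if (length(missing_in_matrix) > 0L)
    stop("sample sheet lists samples absent from the matrix: ",
         paste(missing_in_matrix, collapse = ", "))
  missing_in_sheet <- setdiff(colnames(m), sheet_ids)
  if (length(missing_in_sheet) > 0L)
    stop("matrix has samples absent from the sample sheet: ",
         paste(missing_in_sheet, collapse = ", "))
  # keep matrix column order authoritative
  sheet <- sheet[match(colnames(m), sheet_ids), , drop = FALSE]
  ExpressionDataset(m, sheet)
}

#' Write an expression dataset as tab-separated text
#'
#' Inverse of [read_expression]: writes the intensity matrix (first column
#' `gene`) and the sample sheet so that reading them back reproduces the
#' dataset to full double precision.
#'
#' @param ds An [ExpressionDataset].
#' @param matrix_path Output path for the matrix.
#' @param sample_sheet_path Output path for the sample sheet.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(ds, matrix_path, sample_sheet_path) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  tab <- data.frame(gene = rownames(ds$values),
                    format(ds$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(ds$values) == 0L) {
    tab <- data.frame(matrix(nrow = 0L, ncol = 1L + ncol(ds$values)))
    names(tab) <- c("gene", colnames(ds$values))
  }
  utils::write.table(tab, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$samples, sample_sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, sample_sheet_path))
}

#' Normalise intensities to constant control genes
#'
#' Scales each sample so that the geometric mean of the control genes (ACTB
#' and PAFAH1B2 in the erythropoiesis design, chosen because they are
#' consistently expressed throughout differentiation) equals the grand
#' geometric mean of those controls across all samples. After normalisation
#' the controls are (near-)constant across samples; applying the function
#' twice is a no-op up to float tolerance.
#'
#' @param ds An [ExpressionDataset].
#' @param control_genes Character vector of control gene ids; all must be
#'   present in the dataset.
#' @return A normalised [ExpressionDataset].
#' @export
normalize_by_controls <- function(ds,
                                  control_genes = c("ACTB", "PAFAH1B2")) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  absent <- setdiff(control_genes, rownames(ds$values))
  if (length(absent) > 0L)
    stop("control gene(s) missing from dataset: ",
         paste(absent, collapse = ", "))
  ctrl <- log2(ds$values[control_genes, , drop = FALSE])
  per_sample <- colMeans(ctrl)           # log2 geometric mean per sample
  grand <- mean(per_sample)              # log2 grand geometric mean
  scale_log2 <- grand - per_sample
  vals <- sweep(log2(ds$values), 2L, scale_log2, `+`)
  ExpressionDataset(2^vals, ds$samples)
}

#' Filter genes on a minimum expression level
#'
#' Retains genes reaching at least `threshold` linear intensity in all
#' replicates of at least one population group (the sample groups of the
#' sample sheet). The boundary is inclusive: a gene at exactly `threshold`
#' in every replicate of a population is retained.
#'
#' @param ds An [ExpressionDataset].
#' @param threshold Minimum linear intensity (default 100).
#' @return Character vector of retained gene ids, in dataset order.
#' @export
expression_filter <- function(ds, threshold = 100) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  pops <- unique(ds$samples$population)
  keep <- rep(FALSE, nrow(ds$values))
  for (p in pops) {
    cols <- ds$samples$population == p
    keep <- keep | apply(ds$values[, cols, drop = FALSE] >= threshold, 1L, all)
  }
  rownames(ds$values)[keep]
}

#' Collapse replicates to per-population medians
#'
#' Takes the median of the replicate intensities within each population and
#' returns the genes x populations profile matrix used for clustering.
#' Populations appear in order of first occurrence in the sample sheet;
#' populations named in `exclude` are dropped (the adult design, for
#' instance, omits SEM-F d12 to keep 11 population points).
#'
#' @param ds An [ExpressionDataset].
#' @param exclude Character vector of population labels to omit.
#' @return A numeric matrix (class `PopulationProfileMatrix`) of per-population
#'   median intensities, genes in rows.
#' @export
collapse_to_population_medians <- function(ds, exclude = character()) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  pops <- unique(ds$samples$population)
  unknown <- setdiff(exclude, pops)
  if (length(unknown) > 0L)
    stop("cannot exclude unknown population(s): ",
         paste(unknown, collapse = ", "))
  pops <- setdiff(pops, exclude)
  if (length(pops) == 0L) stop("no populations left after exclusion")
  prof <- vapply(pops, function(p) {
    cols <- which(ds$samples$population == p)
    if (length(cols) == 0L) stop("population with zero samples: ", p)
    apply(ds$values[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(ds$values)))
  if (nrow(ds$values) == 1L) prof <- matrix(prof, nrow = 1L)
  if (!is.matrix(prof)) prof <- matrix(prof, ncol = length(pops))
  dimnames(prof) <- list(rownames(ds$values), pops)
  class(prof) <- c("PopulationProfileMatrix", class(prof))
  prof
}
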