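#' Crisp partition as a 0/1 membership matrix
#'
#' @param partition A `Partition` from [smart_run].
#' @param K Number of columns (>= partition k; extra columns are empty,
#'   used to pad ensembles with differing cluster counts).
#' @return Genes x K 0/1 matrix with gene rownames.
#' @export
partition_to_membership <- function(partition, K = partition$k) {
  stopifnot(inherits(partition, "Partition"), K >= partition$k)
  m <- matrix(0L, nrow = length(partition$labels), ncol = K,
              dimnames = list(names(partition$labels),
                              paste0("C", seq_len(K))))
  m[cbind(seq_along(partition$labels), partition$labels)] <- 1L
  m
}

# canonical labelling: clusters numbered by their smallest member index.
# Makes alignment (and hence the CoPaM) independent of the arbitrary labels
# the clusterer happened to emit, even when overlap ties would otherwise let
# the assignment step pick label-dependent optima.
canonicalize_partition <- function(partition) {
  first_member <- vapply(seq_len(partition$k),
                         function(k) min(which(partition$labels == k)),
                         integer(1L))
  relabel <- integer(partition$k)
  relabel[order(first_member)] <- seq_len(partition$k)
  partition$labels[] <- relabel[partition$labels]
  partition
}

#' Align an ensemble of partitions onto common cluster labels
#'
#' Relabels every partition's clusters onto the labels of the reference
#' partition (the first run) by maximum-overlap one-to-one matching: the
#' assignment of clusters to reference clusters that maximises the total
#' number of shared genes, solved exactly as a linear assignment problem.
#' Partitions with fewer clusters than the ensemble maximum are padded with
#' empty clusters, so all returned matrices have K = max k columns.
#'
#' @param partitions List of `Partition` objects over the same gene universe.
#' @return List of genes x K 0/1 membership matrices with aligned columns.
#' @export
align_partitions <- function(partitions) {
  stopifnot(length(partitions) >= 1L)
  genes <- names(partitions[[1L]]$labels)
  for (p in partitions) {
    if (!identical(names(p$labels), genes))
      stop("all partitions must be over the same gene universe, in order")
  }
  partitions <- lapply(partitions, canonicalize_partition)
  K <- max(vapply(partitions, `[[`, integer(1L), "k"))
  ref <- partition_to_membership(partitions[[1L]], K)
  out <- vector("list", length(partitions))
  out[[1L]] <- ref
  if (length(partitions) > 1L) {
    for (i in seq(2L, length(partitions))) {
      m <- partition_to_membership(partitions[[i]], K)
      overlap <- crossprod(ref, m)        # K x K shared-gene counts
      perm <- solve_assignment(-t(overlap))  # rows = m's clusters
      # m's cluster j goes to reference label perm[j]
      aligned <- m
      aligned[, perm] <- m
      out[[i]] <- aligned
    }
  }
  out
}

#' Build the fuzzy consensus partition matrix (CoPaM)
#'
#' Element-wise mean of aligned crisp membership matrices. Rows are
#' row-stochastic (sum to 1) and every entry is a multiple of 1/n_runs.
#'
#' @param aligned List of aligned genes x K 0/1 matrices (from
#'   [align_partitions]).
#' @return A `CoPaM`: genes x K numeric matrix with attribute `n_runs`.
#' @export
build_copam <- function(aligned) {
  if (length(aligned) == 0L) stop("empty ensemble")
  dims <- dim(aligned[[1L]])
  for (m in aligned)
    if (!identical(dim(m), dims)) stop("aligned matrices must share a shape")
  copam <- Reduce(`+`, lapply(aligned, function(m) m * 1.0)) / length(aligned)
  attr(copam, "n_runs") <- length(aligned)
  class(copam) <- c("CoPaM", class(copam))
  copam
}

#' Binarise a CoPaM by the difference-threshold rule
#'
#' Assigns each gene to its maximum-membership cluster when the gap between
#' the largest and second-largest membership exceeds `delta`; otherwise the
#' gene is left unassigned (all-zero row). At `delta = 0` this implements
#' "a gene is assigned to only one cluster": the unique argmax wins and
#' exact ties unassign the gene rather than picking arbitrarily.
#'
#' @param copam Genes x K fuzzy membership matrix.
#' @param delta Non-negative tuning parameter (default 0).
#' @param tol Absolute tolerance for membership comparisons.
#' @return `BinaryMembership`: genes x K 0/1 matrix; each row has at most
#'   one 1.
#' @export
binarise_dtb <- function(copam, delta = 0, tol = 1e-12) {
  stopifnot(delta >= 0)
  m <- unclass(copam)
  out <- matrix(0L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  if (nrow(m) == 0L || ncol(m) == 0L) return(out)
  for (g in seq_len(nrow(m))) {
    row <- m[g, ]
    top <- which.max(row)
    second <- if (ncol(m) > 1L) max(row[-top]) else 0
    gap <- row[top] - second
    if (gap > max(delta - tol, tol)) out[g, top] <- 1L
  }
  class(out) <- c("BinaryMembership", class(out))
  out
}

#' Gene sets induced by a binary membership matrix
#'
#' @param bin A `BinaryMembership` (or any 0/1 genes x clusters matrix).
#' @return Named list of character vectors, one per non-empty column, named
#'   by column; pairwise disjoint when `bin` came from delta = 0
#'   binarisation.
#' @export
cluster_sets <- function(bin) {
  m <- unclass(bin)
  sets <- lapply(seq_len(ncol(m)), function(j) rownames(m)[m[, j] == 1L])
  names(sets) <- colnames(m)
  sets[lengths(sets) > 0L]
}

#' Write gene sets in GMT-like text format
#'
#' One line per set: set id, size, then the member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], length(sets[[i]]), sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
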