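#' Assemble the cross-dataset binary membership matrix
#'
#' Column-binds the per-dataset binary memberships (all over the identical
#' gene universe) and records, per column, the dataset of origin and the
#' within-dataset cluster id. With delta = 0 inputs each gene carries at
#' most one 1 among any single dataset's columns, so any bicluster with at
#' least as many columns as datasets uses exactly one column per dataset.
#'
#' @param bin_memberships Named list of genes x K 0/1 matrices with
#'   identical rownames (same genes, same order).
#' @return A `CrossDatasetMatrix`: 0/1 matrix with attribute `col_info`
#'   (data frame: `dataset`, `cluster`).
#' @export
assemble_cross_matrix <- function(bin_memberships) {
  stopifnot(length(bin_memberships) >= 1L)
  if (is.null(names(bin_memberships)))
    names(bin_memberships) <- paste0("ds", seq_along(bin_memberships))
  genes <- rownames(bin_memberships[[1L]])
  for (nm in names(bin_memberships)) {
    if (!identical(rownames(bin_memberships[[nm]]), genes))
      stop("gene universe mismatch in dataset '", nm,
           "' (same genes in the same order are required)")
  }
  mats <- lapply(bin_memberships, unclass)
  cross <- do.call(cbind, mats)
  col_info <- do.call(rbind, lapply(names(mats), function(nm) {
    data.frame(dataset = nm,
               cluster = colnames(mats[[nm]]),
               stringsAsFactors = FALSE)
  }))
  colnames(cross) <- paste(col_info$dataset, col_info$cluster, sep = ".")
  attr(cross, "col_info") <- col_info
  class(cross) <- c("CrossDatasetMatrix", class(cross))
  cross
}

#' Bimax: enumerate inclusion-maximal all-ones submatrices
#'
#' Exact biclustering of a 0/1 matrix: returns every submatrix (row set x
#' column set) that is all ones and cannot be extended by any row or column
#' without breaking that property, subject to minimum row and column
#' counts. Maximal all-ones submatrices correspond one-to-one to closed
#' column sets (a column set together with the rows supporting it, closed
#' under adding columns common to all those rows); they are enumerated by
#' depth-first prefix-preserving closure extension, which visits each closed
#' set exactly once. Output order is deterministic: lexicographic by column
#' index set, then by row index set.
#'
#' @param mat 0/1 matrix (logical or numeric).
#' @param min_rows Minimum number of rows per bicluster (default 2).
#' @param min_cols Minimum number of columns per bicluster (default 3, the
#'   number of datasets in the three-source design).
#' @return List of `Bicluster` objects: lists with `rows` and `cols`
#'   (integer indices), plus `row_names`/`col_names` when dimnames exist.
#' @export
bimax <- function(mat, min_rows = 2L, min_cols = 3L) {
  stopifnot(min_rows >= 1L, min_cols >= 1L)
  m <- unclass(mat) != 0
  nr <- nrow(m); nc <- ncol(m)
  found <- list()
  if (nr < min_rows || nc < min_cols)
    return(found)

  closure_of <- function(rows) {
    # columns that are all ones over 'rows' (logical row mask)
    unname(which(colSums(m[rows, , drop = FALSE]) == sum(rows)))
  }

  record <- function(cols, rows) {
    if (length(cols) >= min_cols && sum(rows) >= min_rows)
      found[[length(found) + 1L]] <<- list(rows = unname(which(rows)),
                                           cols = cols)
  }

  recurse <- function(cols, rows, last) {
    # cols: current closed column set; rows: logical support mask
    record(cols, rows)
    for (j in seq_len(nc)) {
      if (j <= last || j %in% cols) next
      new_rows <- rows & m[, j]
      if (sum(new_rows) < min_rows) next
      new_cols <- closure_of(new_rows)
      # prefix-preserving check: the closure must add no column before j
      # that is outside the current set, else this set is reached elsewhere
      if (any(new_cols < j & !(new_cols %in% cols))) next
      recurse(new_cols, new_rows, j)
    }
  }

  all_rows <- rep(TRUE, nr)
  root_cols <- closure_of(all_rows)
  recurse(root_cols, all_rows, 0L)

  # deterministic order: lexicographic by column set, then row set
  keys <- vapply(found, function(b)
    paste(formatC(b$cols, width = 6, flag = "0"), collapse = ","),
    character(1L))
  rkeys <- vapply(found, function(b)
    paste(formatC(b$rows, width = 8, flag = "0"), collapse = ","),
    character(1L))
  found <- found[order(keys, rkeys)]
  lapply(found, function(b) {
    out <- b
    if (!is.null(rownames(m))) out$row_names <- rownames(m)[b$rows]
    if (!is.null(colnames(m))) out$col_names <- colnames(m)[b$cols]
    class(out) <- "Bicluster"
    out
  })
}

#' Consensus clusters from cross-dataset biclusters
#'
#' Turns each Bimax bicluster of the cross-dataset matrix into a consensus
#' cluster: its row (gene) set. With delta = 0 binarisation and `min_cols`
#' equal to the number of datasets, each bicluster necessarily spans exactly
#' one cluster column per dataset, so its genes co-express consistently in
#' every dataset; a bicluster using two columns of one dataset indicates
#' corrupted input and raises an error.
#'
#' @param biclusters List of `Bicluster` objects from [bimax] run on a
#'   [assemble_cross_matrix] result.
#' @param cross_matrix The `CrossDatasetMatrix` the biclusters came from.
#' @return Named list of character vectors (`consensus1`, `consensus2`,
#'   ...), deterministically ordered as the biclusters are.
#' @export
extract_consensus_clusters <- function(biclusters, cross_matrix) {
  col_info <- attr(cross_matrix, "col_info")
  if (is.null(col_info)) stop("'cross_matrix' lacks column metadata")
  genes <- rownames(cross_matrix)
  sets <- vector("list", length(biclusters))
  for (i in seq_along(biclusters)) {
    b <- biclusters[[i]]
    ds <- col_info$dataset[b$cols]
    if (anyDuplicated(ds))
      stop("bicluster ", i, " spans two columns of dataset '",
           ds[anyDuplicated(ds)], "': inputs are not delta = 0 memberships")
    sets[[i]] <- genes[b$rows]
  }
  names(sets) <- if (length(sets) > 0L)
    paste0("consensus", seq_along(sets)) else character()
  sets
}

#' Filter gene clusters by size
#'
#' The canonical analysis examines clusters containing more than 30 genes;
#' the boundary is strict by default (a 30-gene cluster is dropped, a
#' 31-gene cluster kept).
#'
#' @param clusters Named list of character vectors.
#' @param min_size Size threshold (default 30).
#' @param strict If `TRUE` (default) keep sizes > `min_size`, else >=.
#' @return The surviving clusters, names preserved.
#' @export
filter_clusters_by_size <- function(clusters, min_size = 30, strict = TRUE) {
  keep <- if (strict) lengths(clusters) > min_size else
    lengths(clusters) >= min_size
  clusters[keep]
}
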