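# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# minimal ExpressionDataset: values is genes x samples, populations recycle
toy_dataset <- function(values, populations, dataset = "toy",
                        replicates_per_pop = NULL) {
  n <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("s", seq_len(n))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  if (is.null(replicates_per_pop))
    replicates_per_pop <- n / length(populations)
  pop <- rep(populations, each = replicates_per_pop)
  sheet <- data.frame(sample_id = colnames(values), dataset = dataset,
                      population = pop, day = match(pop, populations),
                      medium = "SEM-F",
                      replicate = rep(seq_len(replicates_per_pop),
                                      times = length(populations)),
                      stringsAsFactors = FALSE)
  ExpressionDataset(values, sheet)
}

# null dataset: n_genes x (2 * reps), all from one log-normal distribution
null_dataset <- function(n_genes, reps = 3, sd_log2 = 0.3, base_log2 = 9,
                         seed = 1) {
  set.seed(seed)
  m <- matrix(2^(base_log2 + rnorm(n_genes * 2 * reps, sd = sd_log2)),
              nrow = n_genes)
  toy_dataset(m, populations = c("A", "B"), replicates_per_pop = reps)
}

# crisp Partition object from a label vector
make_partition <- function(labels, genes = NULL, seed = 0L) {
  if (is.null(genes)) genes <- paste0("g", seq_along(labels))
  labels <- as.integer(labels)
  stopifnot(all(sort(unique(labels)) == seq_len(max(labels))))
  structure(list(labels = stats::setNames(labels, genes),
                 k = max(labels), n_merges = 0L, seed = as.integer(seed)),
            class = "Partition")
}

# random crisp partition over n genes with up to kmax clusters (labels made
# contiguous)
random_partition <- function(n, kmax) {
  labs <- sample(seq_len(sample(2:kmax, 1)), n, replace = TRUE)
  labs <- as.integer(factor(labs))
  make_partition(labs)
}

# brute-force enumeration of inclusion-maximal all-ones submatrices of a
# 0/1 matrix, by scanning all column subsets; the independent Bimax oracle
brute_force_biclusters <- function(m, min_rows, min_cols) {
  m <- m != 0
  nc <- ncol(m)
  out <- list()
  seen <- character()
  for (code in seq_len(2^nc) - 1L) {
    cols <- which(bitwAnd(code, 2^(seq_len(nc) - 1L)) > 0)
    if (length(cols) < min_cols) next
    rows <- unname(which(rowSums(m[, cols, drop = FALSE]) == length(cols)))
    if (length(rows) < min_rows) next
    # closure: columns all-ones over these rows
    closed <- unname(which(colSums(m[rows, , drop = FALSE]) == length(rows)))
    if (!identical(closed, cols)) next   # not column-maximal for these rows
    key <- paste(cols, collapse = ",")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(rows = rows, cols = cols)
    }
  }
  out
}

# canonical string form of a bicluster list, for set comparison
bicluster_key_set <- function(bcs) {
  sort(vapply(bcs, function(b)
    paste(paste(b$cols, collapse = ","), paste(b$rows, collapse = ","),
          sep = "|"), character(1L)))
}

# adjusted Rand index between two label vectors (independent of mclust so
# the oracle has no optional dependency)
ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
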