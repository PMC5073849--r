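test_that("dataset validation catches malformed inputs", {
  m <- matrix(c(1, 2, 3, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sheet <- data.frame(sample_id = c("s1", "s2"), dataset = "d",
                      population = c("p", "p"), day = 0, medium = "m",
                      replicate = 1:2)
  expect_s3_class(ExpressionDataset(m, sheet), "ExpressionDataset")

  m_dup <- m; rownames(m_dup) <- c("g1", "g1")
  expect_error(ExpressionDataset(m_dup, sheet), "duplicate gene")

  m_zero <- m; m_zero[2, 1] <- 0
  expect_error(ExpressionDataset(m_zero, sheet), "gene 'g2', sample 's1'")

  expect_error(ExpressionDataset(m, sheet[, -3]), "population")
})

test_that("reader rejects inconsistent matrix / sheet pairs", {
  dir <- withr::local_tempdir()
  mp <- file.path(dir, "m.tsv"); sp <- file.path(dir, "s.tsv")
  write.table(data.frame(gene = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4)),
              mp, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- data.frame(sample_id = c("s1", "s2", "s3"), dataset = "d",
                      population = "p", day = 0, medium = "m",
                      replicate = 1:3)
  write.table(sheet, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mp, sp), "absent from the matrix.*s3")

  write.table(sheet[1:2, ], sp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_s3_class(read_expression(mp, sp), "ExpressionDataset")

  write.table(data.frame(gene = c("g1", "g2"), s1 = c(1, 0), s2 = c(3, 4)),
              mp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(mp, sp), "gene 'g2', sample 's1'")
})

test_that("control normalisation matches hand-computed scale factors", {
  # 3 genes x 2 samples, controls g1 and g2; scale factors computed by hand:
  # sample geometric means of controls: s1 = sqrt(4*16) = 8, s2 = sqrt(9*4)=6
  # grand geometric mean = sqrt(8*6); s1 factor = sqrt(48)/8, s2 = sqrt(48)/6
  m <- matrix(c(4, 16, 10,
                9, 4, 20), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  ds <- toy_dataset(m, populations = c("A", "B"), replicates_per_pop = 1)
  norm <- normalize_by_controls(ds, c("g1", "g2"))
  f1 <- sqrt(48) / 8; f2 <- sqrt(48) / 6
  expect_equal(norm$values[, "s1"], m[, "s1"] * f1, tolerance = 1e-12)
  expect_equal(norm$values[, "s2"], m[, "s2"] * f2, tolerance = 1e-12)
  # controls become constant across samples
  expect_equal(prod(norm$values["g1", ] * norm$values["g2", ]) ^ 0.25,
               sqrt(48), tolerance = 1e-12)
})

test_that("normalisation is identity on constant controls, undoes sample scaling, and is idempotent", {
  set.seed(1)
  m <- matrix(2^(8 + rnorm(40, sd = 0.5)), nrow = 10)
  m[1:2, ] <- 500                       # constant controls
  rownames(m) <- c("ACTB", "PAFAH1B2", paste0("g", 1:8))
  ds <- toy_dataset(m, populations = c("A", "B"))
  expect_equal(normalize_by_controls(ds)$values, ds$values,
               tolerance = 1e-12)

  # corrupting one sample by factor 2 is undone up to the global anchor:
  # the grand geometric mean moves by 2^(1/n_samples), nothing else changes
  m2 <- m; m2[, 2] <- m2[, 2] * 2
  ds2 <- toy_dataset(m2, populations = c("A", "B"))
  expect_equal(normalize_by_controls(ds2)$values, ds$values * 2^(1 / 4),
               tolerance = 1e-12)

  set.seed(2)
  m3 <- m * 2^matrix(rnorm(40, sd = 0.1), nrow = 10)   # noisy controls
  ds3 <- toy_dataset(m3, populations = c("A", "B"))
  once <- normalize_by_controls(ds3)
  twice <- normalize_by_controls(once)
  expect_equal(twice$values, once$values, tolerance = 1e-10)

  expect_error(normalize_by_controls(ds, c("ACTB", "GAPDH")), "GAPDH")
})

test_that("expression filter keeps genes at threshold in all replicates of one population", {
  m <- rbind(g1 = c(100, 100, 100, 1, 1, 1),   # boundary: retained
             g2 = c(99, 150, 150, 99, 150, 150), # 99 in one rep everywhere
             g3 = c(150, 150, 150, 200, 200, 200))
  colnames(m) <- paste0("s", 1:6)
  ds <- toy_dataset(m, populations = c("A", "B"))
  kept <- expression_filter(ds, 100)
  expect_setequal(kept, c("g1", "g3"))
  # monotone in threshold: raising it never adds genes
  for (thr in c(50, 100, 151, 500)) {
    expect_true(all(expression_filter(ds, thr + 1) %in%
                      expression_filter(ds, thr)))
  }
})

test_that("expression filter recovers the planted expressed set", {
  sim <- simulate_datasets(simulation_config(n_genes = 200,
                                             n_clusters_shared = 2,
                                             n_clusters_specific = 0,
                                             cluster_size = 20,
                                             noise_sd_log2 = 0.2,
                                             floor_fraction = 0.5,
                                             seed = 8))
  ds <- sim$datasets$adult
  kept <- expression_filter(ds, 100)
  floor_genes <- sim$truth$floor_genes
  expect_length(intersect(kept, floor_genes), 0L)
  expressed <- setdiff(rownames(ds$values), floor_genes)
  expect_gt(length(intersect(kept, expressed)) / length(expressed), 0.99)
})

test_that("median collapsing matches direct recomputation and ignores replicate order", {
  m <- rbind(g1 = c(1, 3, 100, 5, 5, 5))
  colnames(m) <- paste0("s", 1:6)
  ds <- toy_dataset(m, populations = c("A", "B"))
  prof <- collapse_to_population_medians(ds)
  expect_equal(unname(prof["g1", ]), c(3, 5))

  # single replicate: identity
  m1 <- matrix(c(7, 9), 1, 2, dimnames = list("g1", c("s1", "s2")))
  ds1 <- toy_dataset(m1, populations = c("A", "B"), replicates_per_pop = 1)
  expect_equal(unname(collapse_to_population_medians(ds1)["g1", ]), c(7, 9))

  # permuting replicates leaves medians unchanged
  set.seed(3)
  mm <- matrix(2^rnorm(60, 8), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  ds_a <- toy_dataset(mm, populations = c("A", "B"))
  perm <- c(3, 1, 2, 6, 4, 5)
  ds_b <- toy_dataset(mm[, perm], populations = c("A", "B"))
  expect_equal(collapse_to_population_medians(ds_a),
               collapse_to_population_medians(ds_b))
})

test_that("the adult design collapses to 11 populations when SEM-F d12 is excluded", {
  pops12 <- c(default_population_design()$adult[1:8], "SEMF_d12",
              default_population_design()$adult[9:11])
  set.seed(4)
  m <- matrix(2^rnorm(36 * 5, 8), nrow = 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:36)))
  ds <- toy_dataset(m, populations = pops12)
  prof <- collapse_to_population_medians(ds, exclude = "SEMF_d12")
  expect_equal(ncol(prof), 11)
  expect_false("SEMF_d12" %in% colnames(prof))
  expect_error(collapse_to_population_medians(ds, exclude = "nope"),
               "unknown population")
})
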