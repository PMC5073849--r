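# helper: two-population dataset from a log2 matrix (3 + 3 replicates)
de_fixture <- function(log2mat, reps = 3) {
  toy_dataset(2^log2mat, populations = c("A", "B"),
              replicates_per_pop = reps)
}

test_that("identical groups give zero fold change, t = 0, p = 1", {
  set.seed(10)
  lm2 <- matrix(rnorm(60, 9, 0.4), nrow = 10)
  lm2[1, ] <- rep(c(8, 9, 10), 2)      # gene 1 identical across groups
  ds <- de_fixture(lm2)
  de <- moderated_de(ds, "A", "B")
  expect_equal(de$logFC[1], 0)
  expect_equal(de$t[1], 0)
  expect_equal(de$p_value[1], 1)
  expect_true(all(de$p_value >= 0 & de$p_value <= 1))
  expect_true(all(is.finite(de$B)))
})

test_that("posterior variance is the stated convex combination of prior and sample variance", {
  set.seed(11)
  # heterogeneous true variances so the prior df is finite
  sds <- runif(50, 0.1, 1)
  lm2 <- matrix(rnorm(300, 9, rep(sds, 6)), nrow = 50)
  ds <- de_fixture(lm2)
  de <- moderated_de(ds, "A", "B")
  d0 <- attr(de, "d0"); s0_2 <- attr(de, "s0_2"); dg <- attr(de, "df_residual")
  expect_true(is.finite(d0))
  expect_equal(de$s2_post, (d0 * s0_2 + dg * de$s2) / (d0 + dg),
               tolerance = 1e-12)
  # s2_post lies between s0^2 and s2 for every gene
  lo <- pmin(de$s2, s0_2); hi <- pmax(de$s2, s0_2)
  expect_true(all(de$s2_post >= lo - 1e-12 & de$s2_post <= hi + 1e-12))
})

test_that("forcing prior df to zero recovers ordinary two-sample t statistics", {
  set.seed(12)
  lm2 <- matrix(rnorm(60, 9, 0.5), nrow = 10)
  lm2[1:3, 4:6] <- lm2[1:3, 4:6] + 2
  ds <- de_fixture(lm2)
  de <- moderated_de(ds, "A", "B", prior_df = 0)
  # oracle: pooled-variance two-sample t computed directly per gene
  for (g in 1:10) {
    tt <- stats::t.test(lm2[g, 4:6], lm2[g, 1:3], var.equal = TRUE)
    expect_equal(de$t[g], unname(tt$statistic), tolerance = 1e-6)
    expect_equal(de$p_value[g], tt$p.value, tolerance = 1e-6)
  }
})

test_that("moderated p-values approach ordinary ones as the prior df vanishes", {
  set.seed(13)
  lm2 <- matrix(rnorm(600, 9, 0.5), nrow = 100)
  ds <- de_fixture(lm2)
  de0 <- moderated_de(ds, "A", "B", prior_df = 1e-8)
  ord <- apply(lm2, 1L, function(x)
    stats::t.test(x[4:6], x[1:3], var.equal = TRUE)$p.value)
  expect_lt(max(abs(de0$p_value - ord) / ord), 0.1)
})

test_that("the B threshold 2.945 encodes 95 % posterior probability of DE", {
  b <- 2.945
  expect_equal(exp(b) / (1 + exp(b)), 0.95, tolerance = 1e-3)
  # and B is strictly increasing in |t| at fixed df
  set.seed(14)
  lm2 <- matrix(rnorm(1200, 9, 0.4), nrow = 200)
  lm2[1:40, 4:6] <- lm2[1:40, 4:6] + rep(seq(0.5, 3, length.out = 40), 3)
  ds <- de_fixture(lm2)
  de <- moderated_de(ds, "A", "B")
  # genes share u2 and df; sort by |t| and check B follows
  ord <- order(abs(de$t))
  b_by_t <- de$B[ord]
  # B must be non-decreasing in |t| up to numerical tie tolerance
  expect_true(all(diff(b_by_t) > -1e-8))
})

test_that("moderated statistics agree with an independent empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(15)
  # heterogeneous gene variances: finite prior df exercises the shrinkage
  sds <- exp(rnorm(300, log(0.4), 0.5))
  lm2 <- matrix(rnorm(1800, 9, rep(sds, 6)), nrow = 300)
  lm2[1:30, 4:6] <- lm2[1:30, 4:6] + 1.5
  ds <- de_fixture(lm2)
  de <- moderated_de(ds, "A", "B", p_de = 0.01)

  design <- cbind(1, rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(lm2, design), proportion = 0.01)
  expect_equal(unname(de$logFC), unname(fit$coefficients[, 2]),
               tolerance = 1e-8)
  expect_equal(attr(de, "d0"), fit$df.prior, tolerance = 1e-4)
  expect_equal(attr(de, "s0_2"), fit$s2.prior, tolerance = 1e-4)
  expect_equal(unname(de$t), unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(de$p_value), unname(fit$p.value[, 2]),
               tolerance = 1e-6)
  expect_equal(unname(de$B), unname(fit$lods[, 2]), tolerance = 1e-3)
})

test_that("selection honours the printed boundary semantics", {
  # construct a DEResult by hand around an all-expressed dataset
  m <- matrix(150, nrow = 4, ncol = 6,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  ds <- toy_dataset(m, populations = c("A", "B"))
  de <- data.frame(gene = paste0("g", 1:4),
                   logFC = c(1, 1, 1, 0.99),
                   s2 = 0.1, s2_post = 0.1,
                   t = 5,
                   p_value = c(0.009, 0.009, 0.011, 0.009),
                   B = c(2.946, 2.945, 3.5, 3.5),
                   stringsAsFactors = FALSE)
  class(de) <- c("DEResult", "data.frame")
  sel <- select_de(de, ds, de_criteria())
  expect_identical(sel$gene, "g1")  # p<=0.01 ok, FC=2 ok (>=), B>2.945 strict
  # g2 fails strict B, g3 fails p, g4 fails FC

  # expression boundary: gene below 100 everywhere is never selected
  m2 <- m; m2["g1", ] <- 99
  ds2 <- toy_dataset(m2, populations = c("A", "B"))
  expect_length(select_de(de, ds2, de_criteria())$gene, 0L)
})

test_that("shrinking any threshold never shrinks the selected set", {
  set.seed(16)
  lm2 <- matrix(rnorm(1200, 9, 0.4), nrow = 200)
  lm2[1:50, 4:6] <- lm2[1:50, 4:6] + rep(runif(50, 0.5, 2.5), 3)
  ds <- de_fixture(lm2)
  de <- moderated_de(ds, "A", "B")
  base <- select_de(de, ds, de_criteria())$gene
  looser <- list(de_criteria(p_max = 0.05),
                 de_criteria(fc_min = 1.5),
                 de_criteria(b_min = 0),
                 de_criteria(expr_min = 10))
  for (cr in looser)
    expect_true(all(base %in% select_de(de, ds, cr)$gene))
})

test_that("zero-noise planted four-fold changes are selected exactly", {
  cfg <- simulation_config(n_genes = 200, n_clusters_shared = 2,
                           n_clusters_specific = 0, cluster_size = 20,
                           noise_sd_log2 = 0, amplitude_log2 = 2, seed = 21)
  sim <- simulate_datasets(cfg)
  ds <- sim$datasets$cord
  planted <- rownames(sim$truth$assignment)[
    !is.na(sim$truth$assignment[, "cord"])]
  de <- union_de_over_stages(ds)
  expect_setequal(de, planted)
})

test_that("union over stages equals an independent pairwise loop", {
  sim <- simulate_datasets(simulation_config(n_genes = 150,
                                             n_clusters_shared = 2,
                                             n_clusters_specific = 1,
                                             cluster_size = 15,
                                             noise_sd_log2 = 0.25,
                                             seed = 22))
  ds <- sim$datasets$hipsc
  pops <- unique(ds$samples$population)
  manual <- character()
  for (i in seq_len(length(pops) - 1)) {
    for (j in seq(i + 1, length(pops))) {
      de <- moderated_de(ds, pops[i], pops[j])
      manual <- union(manual, select_de(de, ds)$gene)
    }
  }
  expect_setequal(union_de_over_stages(ds), manual)
  # two populations: union equals the single-pair selection
  de2 <- moderated_de(ds, pops[1], pops[2])
  expect_setequal(union_de_over_stages(ds, populations = pops[1:2]),
                  select_de(de2, ds)$gene)
})

test_that("consecutive DE counts track planted transient profiles", {
  # peak-shaped cluster rises then falls across the 3-point design;
  # amplitude 3 makes even half-swing transitions clear the FC >= 2 filter
  cfg <- simulation_config(n_genes = 100, n_clusters_shared = 3,
                           n_clusters_specific = 0, cluster_size = 10,
                           noise_sd_log2 = 0.1, amplitude_log2 = 3,
                           seed = 23)
  sim <- simulate_datasets(cfg)
  ds <- sim$datasets$cord
  counts <- consecutive_de_counts(ds)
  expect_named(counts, c("from", "to", "up", "down"))
  expect_equal(nrow(counts), 2)
  # d0 -> d7: shared1 (up) and shared3 (peak) rise, shared2 (down) falls;
  # d7 -> d14: shared1 rises, shared2 and shared3 fall
  expect_gte(counts$up[1], 15)
  expect_gte(counts$down[1], 8)
  expect_gte(counts$up[2], 8)
  expect_gte(counts$down[2], 15)

  # single population: empty result
  one_pop <- toy_dataset(matrix(150, 2, 3,
                                dimnames = list(c("g1", "g2"),
                                                paste0("s", 1:3))),
                         populations = "A")
  expect_equal(nrow(consecutive_de_counts(one_pop)), 0L)
})

test_that("null data yield near-zero consecutive DE counts", {
  ds <- null_dataset(500, seed = 24)
  counts <- consecutive_de_counts(ds)
  expect_true(all(counts$up + counts$down <= 1))
})

test_that("shared-DE table reproduces hand-computed sharing percentages", {
  mk <- function(genes) data.frame(gene = genes, transition = "d0-d7",
                                   direction = "up",
                                   stringsAsFactors = FALSE)
  # identical sets: 100 % both ways
  tab <- shared_de_table(list(AB = mk(paste0("g", 1:5)),
                              CB = mk(paste0("g", 1:5))))
  expect_equal(tab$pct_shared_other, c(100L, 100L))
  # disjoint: 0 %
  tab <- shared_de_table(list(AB = mk(paste0("g", 1:5)),
                              CB = mk(paste0("h", 1:5))))
  expect_equal(tab$pct_shared_other, c(0L, 0L))
  # A = g1..g10, B = g1..g6: A row shows 60 % shared, B row 100 %
  tab <- shared_de_table(list(AB = mk(paste0("g", 1:10)),
                              CB = mk(paste0("g", 1:6))))
  expect_equal(tab$n[tab$source == "AB"], 10L)
  expect_equal(tab$pct_shared_other[tab$source == "AB"], 60L)
  expect_equal(tab$pct_shared_other[tab$source == "CB"], 100L)
  # direction matters: same genes, opposite direction, shares nothing
  down <- mk(paste0("g", 1:10)); down$direction <- "down"
  tab <- shared_de_table(list(AB = mk(paste0("g", 1:10)), CB = down))
  expect_equal(tab$pct_shared_other, c(0L, 0L))
  # universe violation is an error
  expect_error(shared_de_table(list(AB = mk("g1"), CB = mk("g2")),
                               universe = "g1"), "outside")
})
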