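#' Selection thresholds for differentially expressed genes
#'
#' The joint DE filter used throughout: p <= p_max, linear fold change >=
#' fc_min, log-odds B strictly > b_min, and linear expression >= expr_min in
#' all replicates of at least one population. Defaults are the canonical
#' thresholds p <= 0.01, FC >= 2, B > 2.945 (ln 19, i.e. 95 % posterior
#' probability of differential expression), expression >= 100.
#'
#' @param p_max Maximum p-value (inclusive).
#' @param fc_min Minimum linear fold change (inclusive).
#' @param b_min Log-odds threshold (strict: B must exceed it).
#' @param expr_min Minimum linear expression for the expression filter.
#' @return A `DESelectionCriteria` list.
#' @export
de_criteria <- function(p_max = 0.01, fc_min = 2, b_min = 2.945,
                        expr_min = 100) {
  stopifnot(p_max > 0, fc_min >= 1, expr_min > 0)
  structure(list(p_max = p_max, fc_min = fc_min, b_min = b_min,
                 expr_min = expr_min),
            class = "DESelectionCriteria")
}

# Newton inversion of the trigamma function, used by the moment-matching
# estimator of the prior degrees of freedom.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

# Moment-matching fit of the scaled inverse-chi-square prior on gene
# variances: log s^2 ~ log s0^2 + log chi^2 terms; the spread of log s^2 in
# excess of trigamma(df/2) identifies the prior df d0, the mean identifies
# s0^2. All genes share the same residual df here (balanced two-group case).
fit_variance_prior <- function(s2, df) {
  z <- log(s2)
  evar <- stats::var(z) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # variances no more dispersed than chi-square sampling alone: infinite
    # prior df, all genes share the average variance
    d0 <- Inf
    s0_2 <- mean(s2)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(z) - digamma(df / 2) + log(df / 2) +
                  digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_2 = s0_2)
}

# Estimate v0, the prior variance of the log2 fold change for DE genes, from
# the top-quantile of the moderated t statistics (a mixture-deconvolution
# argument: the largest |t| are enriched for true DE genes, and their
# expected quantiles under the alternative identify the variance inflation).
estimate_v0 <- function(tstat, df, u2, p_de) {
  n <- length(tstat)
  ntarget <- ceiling(p_de / 2 * n)
  if (ntarget < 1L) return(0)
  p <- max(ntarget / n, p_de)
  ts <- sort(abs(tstat), decreasing = TRUE)[seq_len(ntarget)]
  r <- seq_len(ntarget)
  p0 <- 2 * stats::pt(ts, df = df, lower.tail = FALSE)
  ptarget <- ((r - 0.5) / n - (1 - p) * p0) / p
  v0 <- numeric(ntarget)
  pos <- ptarget > p0
  if (any(pos)) {
    qtarget <- stats::qt(ptarget[pos] / 2, df = df, lower.tail = FALSE)
    v0[pos] <- u2 * ((ts[pos] / qtarget)^2 - 1)
  }
  mean(pmax(v0, 0))
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Fits, per gene, the two-group linear model on log2 intensities and
#' computes moderated statistics under the standard hierarchical model:
#' gene variances are shrunk towards a common prior variance s0^2 with prior
#' degrees of freedom d0 (both estimated by moment-matching on log s^2), the
#' moderated t uses the posterior variance with d0 + d_g degrees of freedom,
#' and B is the log posterior odds of differential expression assuming a
#' prior DE proportion `p_de` and a fold-change prior variance v0 estimated
#' from the upper tail of the t statistics.
#'
#' The log2 fold change is `mean(group_b) - mean(group_a)`, i.e. positive
#' when expression is higher in `group_b` (conventionally the later stage).
#'
#' @param ds An [ExpressionDataset].
#' @param group_a,group_b Population labels; each must have >= 2 replicates.
#' @param p_de Assumed prior proportion of DE genes (default 0.01).
#' @param prior_df Optional override of the estimated prior df d0; `0` gives
#'   ordinary (unmoderated) two-sample t statistics.
#' @param var_floor Variances below this are floored before shrinkage so
#'   degenerate zero-variance genes cannot produce infinite t.
#' @return A `DEResult` data frame with columns `gene`, `logFC`, `s2`,
#'   `s2_post`, `t`, `p_value`, `B`, and attributes `d0`, `s0_2`, `v0`,
#'   `p_de`, `df_residual`, `df_total`, `groups`.
#' @export
moderated_de <- function(ds, group_a, group_b, p_de = 0.01,
                         prior_df = NULL, var_floor = 1e-8) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  ia <- which(ds$samples$population == group_a)
  ib <- which(ds$samples$population == group_b)
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs >= 2 replicates (", group_a, ": ", length(ia),
         ", ", group_b, ": ", length(ib), ")")
  la <- log2(ds$values[, ia, drop = FALSE])
  lb <- log2(ds$values[, ib, drop = FALSE])
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  logFC <- mb - ma
  ssa <- rowSums((la - ma)^2)
  ssb <- rowSums((lb - mb)^2)
  df <- na + nb - 2L
  s2 <- pmax((ssa + ssb) / df, var_floor)

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, df)
  } else {
    stopifnot(prior_df >= 0)
    prior <- list(d0 = prior_df,
                  s0_2 = exp(mean(log(s2)) - digamma(df / 2) + log(df / 2)))
  }
  d0 <- prior$d0; s0_2 <- prior$s0_2
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else
    (d0 * s0_2 + df * s2) / (d0 + df)
  u2 <- 1 / na + 1 / nb
  tstat <- logFC / sqrt(s2_post * u2)
  df_total <- min(d0 + df, 1e6)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)

  # v0 is on the unscaled-coefficient scale (same units as u2), so the
  # variance inflation for DE genes is constant across genes
  v0 <- estimate_v0(tstat, df_total, u2, p_de)
  r <- (u2 + v0) / u2
  # log posterior odds of differential expression
  t2 <- tstat^2
  kernel <- (1 + df_total) / 2 * log((t2 + df_total) / (t2 / r + df_total))
  B <- log(p_de / (1 - p_de)) - log(r) / 2 + kernel

  out <- data.frame(gene = rownames(ds$values), logFC = logFC, s2 = s2,
                    s2_post = s2_post, t = tstat, p_value = p, B = B,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "v0") <- v0
  attr(out, "p_de") <- p_de
  attr(out, "df_residual") <- df
  attr(out, "df_total") <- df_total
  attr(out, "groups") <- c(group_a, group_b)
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Apply the joint DE selection rule
#'
#' Selects genes passing all of: the expression filter (>= `expr_min` in all
#' replicates of at least one population), p <= `p_max`, |linear fold
#' change| >= `fc_min` (i.e. |log2FC| >= log2(fc_min)), and B strictly >
#' `b_min`. The B boundary is strict while p and FC are inclusive, matching
#' the printed inequality directions of the canonical thresholds.
#'
#' @param de A `DEResult` from [moderated_de].
#' @param ds The [ExpressionDataset] the result was computed on (used for
#'   the expression filter).
#' @param criteria A [de_criteria()] list.
#' @return Data frame with columns `gene` and `direction` ("up" when logFC >
#'   0, i.e. higher in group_b).
#' @export
select_de <- function(de, ds, criteria = de_criteria()) {
  stopifnot(inherits(de, "DEResult"))
  expressed <- expression_filter(ds, criteria$expr_min)
  pass <- de$gene %in% expressed &
    de$p_value <= criteria$p_max &
    abs(de$logFC) >= log2(criteria$fc_min) &
    de$B > criteria$b_min
  data.frame(gene = de$gene[pass],
             direction = ifelse(de$logFC[pass] > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Union of DE genes over all population pairs
#'
#' Runs [moderated_de] + [select_de] for every unordered pair of populations
#' and returns the union of selected genes ("DE between any two stages").
#'
#' @param ds An [ExpressionDataset].
#' @param criteria A [de_criteria()] list.
#' @param populations Ordered population labels; defaults to sample-sheet
#'   order.
#' @return Character vector of gene ids, in dataset order.
#' @export
union_de_over_stages <- function(ds, criteria = de_criteria(),
                                 populations = NULL) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(populations)) populations <- unique(ds$samples$population)
  if (length(populations) < 2L) stop("need >= 2 populations")
  hits <- character()
  for (i in seq_len(length(populations) - 1L)) {
    for (j in seq(i + 1L, length(populations))) {
      de <- moderated_de(ds, populations[i], populations[j])
      hits <- c(hits, select_de(de, ds, criteria)$gene)
    }
  }
  intersect(rownames(ds$values), unique(hits))
}

#' DE counts between consecutive populations
#'
#' For each adjacent pair of the ordered populations, counts selected DE
#' genes split by direction ("up" = higher in the later population).
#'
#' @param ds An [ExpressionDataset].
#' @param populations Ordered population labels; defaults to sample-sheet
#'   order.
#' @param criteria A [de_criteria()] list.
#' @return Data frame with columns `from`, `to`, `up`, `down`; zero rows if
#'   fewer than two populations.
#' @export
consecutive_de_counts <- function(ds, populations = NULL,
                                  criteria = de_criteria()) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (is.null(populations)) populations <- unique(ds$samples$population)
  n <- length(populations)
  if (n < 2L)
    return(data.frame(from = character(), to = character(),
                      up = integer(), down = integer(),
                      stringsAsFactors = FALSE))
  res <- lapply(seq_len(n - 1L), function(i) {
    de <- moderated_de(ds, populations[i], populations[i + 1L])
    sel <- select_de(de, ds, criteria)
    data.frame(from = populations[i], to = populations[i + 1L],
               up = sum(sel$direction == "up"),
               down = sum(sel$direction == "down"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Cross-source shared-DE summary table
#'
#' For two sources (e.g. adult and cord blood) with DE calls per transition
#' and direction, tabulates per (source, transition, direction) the number
#' of DE genes and the percentage of them that are DE in the same direction
#' and transition in the other source (integer-rounded), mirroring the
#' "n (xx % shared)" presentation.
#'
#' @param de_sets Named list of exactly two elements (one per source); each
#'   element is a data frame with columns `gene`, `transition`, `direction`.
#' @param universe Optional gene universe; both sources' genes must lie in
#'   it.
#' @return Data frame with columns `source`, `transition`, `direction`, `n`,
#'   `pct_shared_other`.
#' @export
shared_de_table <- function(de_sets, universe = NULL) {
  if (length(de_sets) != 2L || is.null(names(de_sets)))
    stop("'de_sets' must be a named list of exactly two sources")
  for (s in names(de_sets)) {
    need <- c("gene", "transition", "direction")
    if (!all(need %in% names(de_sets[[s]])))
      stop("source '", s, "' must have columns gene, transition, direction")
    if (!is.null(universe)) {
      out <- setdiff(de_sets[[s]]$gene, universe)
      if (length(out) > 0L)
        stop("source '", s, "' has genes outside the shared universe: ",
             paste(utils::head(out, 5L), collapse = ", "))
    }
  }
  srcs <- names(de_sets)
  rows <- list()
  for (si in 1:2) {
    this <- de_sets[[srcs[si]]]
    other <- de_sets[[srcs[3L - si]]]
    combos <- unique(this[, c("transition", "direction")])
    for (k in seq_len(nrow(combos))) {
      tr <- combos$transition[k]; dir <- combos$direction[k]
      g <- this$gene[this$transition == tr & this$direction == dir]
      g_other <- other$gene[other$transition == tr & other$direction == dir]
      rows[[length(rows) + 1L]] <- data.frame(
        source = srcs[si], transition = tr, direction = dir,
        n = length(g),
        pct_shared_other = as.integer(round(
          100 * mean(g %in% g_other))),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
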