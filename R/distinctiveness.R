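# Evolutionary distinctiveness of multi-beneficial species: median-ED
# subset tests against two null pools, and chi-square contribution tests.

#' SES of the median evolutionary distinctiveness of a species subset
#'
#' Per tree, fair-proportion ED is computed for all tips; the observed
#' statistic is the median ED of the subset, and nulls are medians of
#' size-matched random draws from the pool. The median (not the mean) is
#' used because ED distributions are strongly right-skewed. Per-tree SES
#' values are aggregated with the CI rule of [aggregate_ses()].
#'
#' @param trees a `tree_distribution` (or single `phylo`).
#' @param subset character vector of tip labels (>= 1), a strict subset of
#'   `pool`.
#' @param pool null pool of tip labels (defaults to all tips: the "entire
#'   phylogeny" pool).
#' @param n_null null draws per tree.
#' @param seed optional integer seed (reset per tree, as in
#'   [ses_pd_per_benefit()]).
#' @param alphas,ci_method passed to [aggregate_ses()].
#' @return an `aggregated_ses`; `subset == pool` (or an ED-constant pool)
#'   yields degenerate per-tree results, flagged rather than an error.
#' @export
median_ed_ses <- function(trees, subset, pool = NULL, n_null = 999,
                          seed = NULL, alphas = c(0.05, 0.01, 0.001),
                          ci_method = "normal") {
  tl <- as_tree_list(trees)
  if (length(subset) < 1) stopf("'subset' must be non-empty")
  per_tree <- vapply(tl, function(tr) {
    ed <- fair_proportion_ed(tr)
    pl <- pool %||% tr$tip.label
    if (!all(subset %in% pl)) stopf("'subset' must be contained in 'pool'")
    if (!all(pl %in% names(ed))) {
      stopf("pool tips missing from tree: %s",
            paste(setdiff(pl, names(ed)), collapse = ", "))
    }
    obs <- median(ed[subset])
    k <- length(subset)
    ed_pool <- ed[pl]
    nulls <- with_seed(seed, {
      vapply(seq_len(n_null), function(i) median(sample(ed_pool, k)),
             numeric(1))
    })
    ses_result(obs, nulls)$ses
  }, numeric(1))
  aggregate_ses(per_tree, alphas, ci_method)
}

#' Median-ED tests across multi-beneficial thresholds and both null pools
#'
#' For each threshold k, the subset of species providing at least k benefit
#' types is tested against (i) the entire phylogeny and (ii) the pool of
#' beneficial species. Thresholds yielding an empty subset, or a subset
#' equal to its pool, are skipped with a logged reason.
#'
#' @param trees a `tree_distribution` (or single `phylo`).
#' @param matrix a species-level `benefit_matrix` whose rows occur among
#'   the tree tips.
#' @param thresholds ascending integer thresholds (default 3:8).
#' @param n_null,seed,alphas passed to [median_ed_ses()].
#' @return data.frame (threshold, pool, n_subset, mean_ses, ci_low,
#'   ci_high, call) with a `skipped` attribute.
#' @export
run_ed_battery <- function(trees, matrix, thresholds = 3:8, n_null = 999,
                           seed = NULL, alphas = c(0.05, 0.01, 0.001)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stopf("'thresholds' must be strictly ascending")
  }
  tl <- as_tree_list(trees)
  reconcile_taxa(matrix, tl[[1]])
  beneficial <- rownames(matrix)
  pools <- list(entire_phylogeny = NULL, beneficial_species = beneficial)
  rows <- list()
  skipped <- character(0)
  for (k in thresholds) {
    subset <- multibeneficial_subset(matrix, k)
    for (pn in names(pools)) {
      key <- sprintf("threshold %d, pool %s", k, pn)
      if (length(subset) == 0) {
        skipped[key] <- "empty subset"
        message("skipping ", key, ": empty subset")
        next
      }
      pool_tips <- pools[[pn]] %||% tl[[1]]$tip.label
      if (length(subset) >= length(pool_tips)) {
        skipped[key] <- "subset not strictly smaller than pool"
        message("skipping ", key, ": subset is the whole pool")
        next
      }
      agg <- median_ed_ses(tl, subset, pool = pools[[pn]], n_null = n_null,
                           seed = seed, alphas = alphas)
      rows[[key]] <- data.frame(threshold = k, pool = pn,
                                n_subset = length(subset),
                                mean_ses = agg$mean, ci_low = agg$ci_low,
                                ci_high = agg$ci_high,
                                call = unname(agg$calls[1]),
                                flagged = agg$flagged ||
                                  all(!is.finite(agg$values)),
                                stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows) %||% data.frame()
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  res
}

#' Chi-square benefit-contribution test for a species subset
#'
#' Under the null, a subset comprising a proportion p of the species pool
#' contributes a proportion p of the records of every benefit type. Per
#' benefit with N total records and x from the subset, a one-degree-of-
#' freedom chi-square compares the two-cell partition (x, N - x) with the
#' expectation (pN, (1-p)N). Benefits with no records are skipped; results
#' with an expected cell below 5 are flagged low-count. Bonferroni and BH
#' adjusted p-values are emitted alongside but calls are per-type.
#'
#' @param matrix a species-level `benefit_matrix`.
#' @param subset character vector of species (subset of the matrix rows).
#' @return data.frame (benefit, observed, expected, chi2, df, p_value,
#'   p_bonferroni, p_bh, direction, low_count).
#' @export
benefit_contribution_chisq <- function(matrix, subset) {
  m <- unclass(matrix)
  if (!all(subset %in% rownames(m))) {
    stopf("subset species missing from matrix: %s",
          paste(setdiff(subset, rownames(m)), collapse = ", "))
  }
  p <- length(subset) / nrow(m)
  rows <- lapply(colnames(m), function(b) {
    N <- sum(m[, b])
    if (N == 0) return(NULL)
    x <- sum(m[subset, b])
    expected <- p * N
    if (p >= 1) {
      stat <- 0; pval <- 1
    } else {
      ct <- suppressWarnings(chisq.test(c(x, N - x), p = c(p, 1 - p),
                                        correct = FALSE))
      stat <- unname(ct$statistic); pval <- unname(ct$p.value)
    }
    data.frame(benefit = b, observed = x, expected = expected,
               chi2 = stat, df = 1L, p_value = pval,
               direction = if (x > expected) "over" else "under",
               low_count = min(expected, N - expected) < 5,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows) %||% data.frame()
  if (nrow(res)) {
    res$p_bonferroni <- p.adjust(res$p_value, "bonferroni")
    res$p_bh <- p.adjust(res$p_value, "BH")
  }
  rownames(res) <- NULL
  res
}
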