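# SES Faith PD under tip-draw null models, aggregated across a tree
# distribution with the confidence-interval significance rule.

# Batch PD for many tip sets at once. `inc` is a sets x tips 0/1 matrix
# whose columns align with tree$tip.label; returns one PD value per row.
pd_batch <- function(tree, inc, include_root = TRUE, E = NULL) {
  if (is.null(E)) E <- edge_tip_incidence(tree)
  len <- tree$edge.length
  counts <- tcrossprod(inc, E)              # sets x edges: inc %*% t(E)
  if (include_root) {
    as.vector((counts > 0) %*% len)
  } else {
    k <- rowSums(inc)
    as.vector(((counts > 0) & (counts < k)) %*% len)
  }
}

ses_result <- function(m_obs, null_values, n_null = length(null_values)) {
  m_null <- mean(null_values)
  sd_null <- sd(null_values)                 # sample (n-1) convention
  degenerate <- !is.finite(sd_null) || sd_null == 0
  structure(list(m_obs = m_obs, m_null = m_null, sd_null = sd_null,
                 ses = if (degenerate) NA_real_ else (m_obs - m_null) / sd_null,
                 n_null = n_null, degenerate = degenerate,
                 null_values = null_values),
            class = "ses_result")
}

#' @export
print.ses_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("SES result (degenerate): obs = %.6g, null SD = 0\n", x$m_obs))
  } else {
    cat(sprintf("SES = %.4f (obs = %.6g, null = %.6g +/- %.6g, n = %d)\n",
                x$ses, x$m_obs, x$m_null, x$sd_null, x$n_null))
  }
  invisible(x)
}

#' Standardized effect size of Faith PD for a focal tip set
#'
#' The null distribution is built from uniform without-replacement draws of
#' `length(focal)` tips from the null pool (all tree tips by default);
#' SES = (M_obs - M_null) / SD_null with the sample (n-1) standard
#' deviation. Negative SES indicates phylogenetic clustering, positive SES
#' overdispersion.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param focal character vector of focal tip labels (>= 2).
#' @param n_null number of null draws (>= 99; 999 is conventional).
#' @param seed optional integer seed.
#' @param include_root PD root-inclusion convention (see [faith_pd()]).
#' @param pool optional character vector to draw nulls from (defaults to
#'   all tips of the tree).
#' @return a `ses_result`; when the focal set exhausts the pool the result
#'   is flagged degenerate (SD_null = 0) rather than erroring.
#' @export
ses_pd <- function(tree, focal, n_null = 999, seed = NULL,
                   include_root = TRUE, pool = NULL) {
  validate_phylogeny(tree)
  if (length(focal) < 2) stopf("'focal' must contain at least 2 tips")
  if (n_null < 99) stopf("'n_null' must be >= 99")
  fidx <- tip_index(tree, focal, "focal tip")
  pool <- pool %||% tree$tip.label
  pidx <- tip_index(tree, pool, "pool tip")
  if (!all(fidx %in% pidx)) stopf("'focal' must be a subset of 'pool'")
  k <- length(fidx)
  if (k > length(pidx)) stopf("focal set larger than the null pool")

  ntip <- length(tree$tip.label)
  E <- edge_tip_incidence(tree)
  obs_inc <- matrix(0, 1, ntip); obs_inc[1, fidx] <- 1
  m_obs <- pd_batch(tree, obs_inc, include_root, E)

  null_inc <- matrix(0, n_null, ntip)
  with_seed(seed, {
    for (i in seq_len(n_null)) null_inc[i, sample(pidx, k)] <- 1
  })
  nulls <- pd_batch(tree, null_inc, include_root, E)
  ses_result(m_obs, nulls)
}

#' Aggregate per-tree SES values with the CI significance rule
#'
#' Computes the mean SES across phylogenetic hypotheses, a 95% confidence
#' interval (normal approximation `mean +/- 1.96 sd/sqrt(n)` by default, or
#' percentile), and one significance call per nominal alpha: "higher" only
#' when the whole CI lies above the two-tailed standard-normal threshold
#' for that alpha, "lower" when entirely below its negative, otherwise
#' "ns".
#'
#' @param values numeric vector of per-tree SES scores (>= 2 finite values
#'   for a CI; fewer are flagged).
#' @param alphas nominal two-tailed alpha levels.
#' @param ci_method `"normal"` or `"percentile"`.
#' @param conf CI coverage (0.95 by default).
#' @return an `aggregated_ses`: mean, ci_low, ci_high, per-alpha calls and
#'   the raw values.
#' @export
aggregate_ses <- function(values, alphas = c(0.05, 0.01, 0.001),
                          ci_method = c("normal", "percentile"), conf = 0.95) {
  ci_method <- match.arg(ci_method)
  vals <- values[is.finite(values)]
  n <- length(vals)
  m <- if (n) mean(vals) else NA_real_
  if (n < 2) {
    ci <- c(NA_real_, NA_real_)
    flagged <- TRUE
  } else {
    flagged <- FALSE
    if (ci_method == "normal") {
      z <- qnorm(1 - (1 - conf) / 2)
      half <- z * sd(vals) / sqrt(n)
      ci <- c(m - half, m + half)
    } else {
      ci <- unname(quantile(vals, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
    }
  }
  calls <- vapply(alphas, function(a) {
    thr <- qnorm(1 - a / 2)
    if (flagged || anyNA(ci)) return(NA_character_)
    if (ci[1] > thr) "higher" else if (ci[2] < -thr) "lower" else "ns"
  }, character(1))
  names(calls) <- paste0("alpha_", alphas)
  structure(list(values = values, mean = m, ci_low = ci[1], ci_high = ci[2],
                 n = n, alphas = alphas, calls = calls,
                 ci_method = ci_method, flagged = flagged),
            class = "aggregated_ses")
}

#' @export
print.aggregated_ses <- function(x, ...) {
  cat(sprintf("mean SES = %.4f, %s CI [%.4f, %.4f] over %d trees\n",
              x$mean, x$ci_method, x$ci_low, x$ci_high, x$n))
  cat("calls:", paste(names(x$calls), x$calls, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) list(trees)
  else if (inherits(trees, "tree_distribution")) trees$trees
  else if (is.list(trees)) trees
  else stopf("'trees' must be a phylo, a list of them, or a tree_distribution")
}

#' SES PD per benefit type across a tree distribution
#'
#' For each benefit column with at least two taxa on the tree, computes a
#' per-tree [ses_pd()] and aggregates across trees. The null-draw seed is
#' reset per tree, so variation across the distribution reflects
#' phylogenetic uncertainty only.
#'
#' @param trees a `tree_distribution` (or single `phylo`).
#' @param matrix a `benefit_matrix` whose rows occur among the tree tips.
#' @param n_null,seed,include_root,alphas,ci_method passed through.
#' @return data.frame with one row per analysed benefit (benefit, n_taxa,
#'   mean_ses, ci_low, ci_high, call) plus attributes `aggregated` (the
#'   full objects) and `skipped` (benefits with < 2 taxa and the reason).
#' @export
ses_pd_per_benefit <- function(trees, matrix, n_null = 999, seed = NULL,
                               include_root = TRUE,
                               alphas = c(0.05, 0.01, 0.001),
                               ci_method = "normal") {
  tl <- as_tree_list(trees)
  reconcile_taxa(matrix, tl[[1]])
  benefits <- colnames(matrix)
  agg <- list()
  skipped <- character(0)
  for (b in benefits) {
    taxa <- rownames(matrix)[unclass(matrix)[, b] == 1]
    if (length(taxa) < 2) {
      skipped[b] <- sprintf("only %d taxon/taxa carry '%s'", length(taxa), b)
      message("skipping benefit '", b, "': ", skipped[b])
      next
    }
    per_tree <- vapply(tl, function(tr) {
      ses_pd(tr, taxa, n_null = n_null, seed = seed,
             include_root = include_root)$ses
    }, numeric(1))
    agg[[b]] <- aggregate_ses(per_tree, alphas, ci_method)
  }
  res <- data.frame(
    benefit = names(agg),
    n_taxa = vapply(names(agg), function(b) sum(unclass(matrix)[, b]), numeric(1)),
    mean_ses = vapply(agg, function(a) a$mean, numeric(1)),
    ci_low = vapply(agg, function(a) a$ci_low, numeric(1)),
    ci_high = vapply(agg, function(a) a$ci_high, numeric(1)),
    call = vapply(agg, function(a) unname(a$calls[1]), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "aggregated") <- agg
  attr(res, "skipped") <- skipped
  res
}

#' Whole-set SES PD across a tree distribution
#'
#' SES PD of all matrix taxa as one focal set, per tree, aggregated.
#'
#' @inheritParams ses_pd_per_benefit
#' @return an `aggregated_ses`.
#' @export
ses_pd_whole_set <- function(trees, matrix, n_null = 999, seed = NULL,
                             include_root = TRUE,
                             alphas = c(0.05, 0.01, 0.001),
                             ci_method = "normal") {
  tl <- as_tree_list(trees)
  reconcile_taxa(matrix, tl[[1]])
  taxa <- rownames(matrix)
  per_tree <- vapply(tl, function(tr) {
    ses_pd(tr, taxa, n_null = n_null, seed = seed,
           include_root = include_root)$ses
  }, numeric(1))
  aggregate_ses(per_tree, alphas, ci_method)
}
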