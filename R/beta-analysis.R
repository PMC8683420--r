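# Sorensen-family dissimilarity, taxonomic and phylogenetic (PhyloSor),
# pairwise and multiple-site, partitioned into turnover and nestedness,
# with permutation nulls and non-parametric effect sizes.

beta_partition <- function(sor, sim, mode, arity) {
  nes <- sor - sim
  structure(list(beta_sor = sor, beta_sim = sim, beta_nes = nes,
                 mode = mode, arity = arity),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("%s %s dissimilarity: beta_sor = %.4f, beta_sim = %.4f, beta_nes = %.4f\n",
              x$arity, x$mode, x$beta_sor, x$beta_sim, x$beta_nes))
  invisible(x)
}

# Partition from shared/unique components a (shared), b, c (unique).
partition_from_abc <- function(a, b, c, mode, arity = "pairwise") {
  if (a + b + c == 0) return(beta_partition(0, 0, mode, arity))
  sor <- (b + c) / (2 * a + b + c)
  mn <- min(b, c)
  sim <- if (a + mn == 0) 0 else mn / (a + mn)
  beta_partition(sor, sim, mode, arity)
}

#' Pairwise phylogenetic beta-diversity partition (PhyloSor family)
#'
#' With shared branch length a and unique lengths b, c from
#' [branch_overlap()]: total dissimilarity beta_sor = (b+c)/(2a+b+c)
#' (1 - PhyloSor), turnover beta_sim = min(b,c)/(a+min(b,c)), nestedness
#' beta_nes = beta_sor - beta_sim.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param set1,set2 non-empty tip-label sets.
#' @param include_root root-inclusion convention shared with [faith_pd()].
#' @return a `beta_partition` (mode "phylogenetic", arity "pairwise").
#' @export
pairwise_phylo_partition <- function(tree, set1, set2, include_root = TRUE) {
  ov <- branch_overlap(tree, set1, set2, include_root)
  partition_from_abc(ov$a, ov$b, ov$c, "phylogenetic")
}

#' Pairwise taxonomic Sorensen partition
#'
#' Same partition as [pairwise_phylo_partition()] with set cardinalities in
#' place of branch lengths.
#'
#' @param set1,set2 non-empty element sets (character vectors).
#' @return a `beta_partition` (mode "taxonomic", arity "pairwise").
#' @export
pairwise_sorensen <- function(set1, set2) {
  if (length(set1) == 0 || length(set2) == 0) stopf("both sets must be non-empty")
  set1 <- unique(set1); set2 <- unique(set2)
  a <- length(intersect(set1, set2))
  partition_from_abc(a, length(setdiff(set1, set2)),
                     length(setdiff(set2, set1)), "taxonomic")
}

# Multiple-site Sorensen-family partition from a sites x elements incidence
# matrix with element weights w (1 for taxonomic, branch lengths for
# phylogenetic). Si = weighted per-site richness, ST = pooled, b_ij =
# weight unique to site i relative to j.
multisite_from_incidence <- function(IN, w, mode) {
  IN <- (IN > 0) + 0
  if (nrow(IN) < 2) stopf("at least 2 sites are required")
  if (any(rowSums(IN) == 0)) stopf("every site must be non-empty")
  Si <- as.vector(IN %*% w)
  ST <- sum(w[colSums(IN) > 0])
  W <- sweep(IN, 2, w, `*`)
  B <- W %*% t(1 - IN)            # B[i, j] = weight unique to i vs j
  up <- upper.tri(B)
  mins <- pmin(B, t(B))[up]
  maxs <- pmax(B, t(B))[up]
  excess <- sum(Si) - ST
  sim <- if (excess + sum(mins) == 0) 0 else sum(mins) / (excess + sum(mins))
  denom <- 2 * excess + sum(mins) + sum(maxs)
  sor <- if (denom == 0) 0 else (sum(mins) + sum(maxs)) / denom
  beta_partition(sor, sim, mode, "multisite")
}

#' Multiple-site Sorensen-family dissimilarity partition
#'
#' Generalizes the pairwise partition over more than two sites; with two
#' sites it coincides with the pairwise value. Taxonomic mode uses element
#' counts; phylogenetic mode uses branch lengths on `tree` (sites are tip
#' sets).
#'
#' @param sites named list of non-empty element sets (tip labels in
#'   phylogenetic mode).
#' @param mode `"taxonomic"` or `"phylogenetic"`.
#' @param tree required in phylogenetic mode.
#' @param include_root root-inclusion convention (phylogenetic mode).
#' @return a `beta_partition` with arity "multisite".
#' @export
multisite_partition <- function(sites, mode = c("taxonomic", "phylogenetic"),
                                tree = NULL, include_root = TRUE) {
  mode <- match.arg(mode)
  if (length(sites) < 2) stopf("at least 2 sites are required")
  if (any(lengths(sites) == 0)) stopf("every site must have a non-empty element set")
  if (mode == "taxonomic") {
    elements <- sort(unique(unlist(sites)))
    IN <- t(vapply(sites, function(s) as.numeric(elements %in% s),
                   numeric(length(elements))))
    return(multisite_from_incidence(IN, rep(1, length(elements)), mode))
  }
  if (is.null(tree)) stopf("phylogenetic mode requires 'tree'")
  validate_phylogeny(tree)
  E <- edge_tip_incidence(tree)
  IN <- t(vapply(sites, function(s) {
    idx <- tip_index(tree, s)
    counts <- rowSums(E[, idx, drop = FALSE])
    if (include_root) as.numeric(counts > 0)
    else as.numeric(counts > 0 & counts < length(idx))
  }, numeric(nrow(E))))
  multisite_from_incidence(IN, tree$edge.length, mode)
}

#' Non-parametric effect size from a null distribution
#'
#' P = (number of nulls below the observation + half the ties) divided by
#' (n_null + 1); ES = 2 (P - 0.5), in [-1, 1]. Used where null
#' distributions are too far from normality for SES scores.
#'
#' @param observed observed statistic.
#' @param null_values non-empty numeric vector of null statistics.
#' @return an `es_result`: list with `p`, `es`, `observed`, `n_null`.
#' @export
es_score <- function(observed, null_values) {
  if (length(null_values) == 0) stopf("'null_values' must be non-empty")
  n <- length(null_values)
  p <- (sum(null_values < observed) + sum(null_values == observed) / 2) / (n + 1)
  structure(list(p = p, es = 2 * (p - 0.5), observed = observed, n_null = n),
            class = "es_result")
}

#' @export
print.es_result <- function(x, ...) {
  cat(sprintf("ES = %.4f (P = %.4f, obs = %.6g, %d nulls)\n",
              x$es, x$p, x$observed, x$n_null))
  invisible(x)
}

#' SES of pairwise phylogenetic turnover between two benefit types
#'
#' The observed pairwise pbeta_sim between the carriers of the two benefits
#' is compared to a null built by shuffling taxon labels across the tips
#' that represent beneficial taxa (compositional dissimilarity is
#' preserved; phylogenetic distances are randomized). An all-tips shuffle
#' is available for sensitivity checks.
#'
#' @param tree a rooted `phylo`.
#' @param matrix a `benefit_matrix` whose rows occur among the tree tips.
#' @param benefit1,benefit2 benefit column names (each with >= 1 carrier).
#' @param n_null number of label permutations.
#' @param seed optional integer seed.
#' @param shuffle_pool `"beneficial"` (default) or `"all"` tips.
#' @param include_root root-inclusion convention.
#' @return a `ses_result` for pbeta_sim (degenerate-flagged if the null has
#'   zero spread).
#' @export
ses_pbsim_pairwise <- function(tree, matrix, benefit1, benefit2,
                               n_null = 999, seed = NULL,
                               shuffle_pool = c("beneficial", "all"),
                               include_root = TRUE) {
  shuffle_pool <- match.arg(shuffle_pool)
  validate_phylogeny(tree)
  reconcile_taxa(matrix, tree)
  m <- unclass(matrix)
  for (b in c(benefit1, benefit2)) {
    if (!b %in% colnames(m)) stopf("unknown benefit: %s", b)
    if (sum(m[, b]) < 1) stopf("benefit '%s' has no carriers", b)
  }
  carriers1 <- rownames(m)[m[, benefit1] == 1]
  carriers2 <- rownames(m)[m[, benefit2] == 1]
  obs <- pairwise_phylo_partition(tree, carriers1, carriers2, include_root)$beta_sim

  pool_labels <- if (shuffle_pool == "beneficial") rownames(m) else tree$tip.label
  pool_idx <- tip_index(tree, pool_labels)
  pos1 <- match(carriers1, pool_labels)
  pos2 <- match(carriers2, pool_labels)

  ntip <- length(tree$tip.label)
  INC1 <- matrix(0, n_null, ntip)
  INC2 <- matrix(0, n_null, ntip)
  with_seed(seed, {
    for (i in seq_len(n_null)) {
      perm <- sample(pool_idx)
      INC1[i, perm[pos1]] <- 1
      INC2[i, perm[pos2]] <- 1
    }
  })
  E <- edge_tip_incidence(tree)
  len <- tree$edge.length
  C1 <- tcrossprod(INC1, E)
  C2 <- tcrossprod(INC2, E)
  if (include_root) {
    in1 <- C1 > 0; in2 <- C2 > 0
  } else {
    in1 <- C1 > 0 & C1 < length(carriers1)
    in2 <- C2 > 0 & C2 < length(carriers2)
  }
  a <- as.vector((in1 & in2) %*% len)
  b <- as.vector((in1 & !in2) %*% len)
  cc <- as.vector((!in1 & in2) %*% len)
  mn <- pmin(b, cc)
  sim <- ifelse(a + mn == 0, 0, mn / (a + mn))
  ses_result(obs, sim)
}

#' All pairwise turnover SES values between benefit types
#'
#' Runs [ses_pbsim_pairwise()] for every pair of benefit columns on each
#' tree of a distribution and aggregates per pair.
#'
#' @param trees a `tree_distribution` (or single `phylo`).
#' @param matrix a `benefit_matrix`.
#' @param n_null,seed,shuffle_pool,include_root,alphas passed through.
#' @return data.frame (benefit1, benefit2, mean_ses, ci_low, ci_high, call).
#' @export
ses_pbsim_matrix <- function(trees, matrix, n_null = 999, seed = NULL,
                             shuffle_pool = "beneficial", include_root = TRUE,
                             alphas = c(0.05, 0.01, 0.001)) {
  tl <- as_tree_list(trees)
  benefits <- colnames(matrix)[colSums(unclass(matrix)) >= 1]
  pairs <- utils::combn(benefits, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    b1 <- pairs[1, j]; b2 <- pairs[2, j]
    per_tree <- vapply(tl, function(tr) {
      ses_pbsim_pairwise(tr, matrix, b1, b2, n_null = n_null, seed = seed,
                         shuffle_pool = shuffle_pool,
                         include_root = include_root)$ses
    }, numeric(1))
    agg <- aggregate_ses(per_tree, alphas)
    data.frame(benefit1 = b1, benefit2 = b2, mean_ses = agg$mean,
               ci_low = agg$ci_low, ci_high = agg$ci_high,
               call = unname(agg$calls[1]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- within-clade compositional dissimilarity --------------------------------

clade_members <- function(matrix, taxonomy, rank) {
  cl <- clade_of(taxonomy, rownames(matrix), rank)
  split(rownames(unclass(matrix)), cl)
}

#' Multiple-site benefit dissimilarity within genera or families
#'
#' Treats congeneric (or confamiliar) species as "sites" and benefits as
#' "species": per clade with >= 2 beneficial members, the taxonomic
#' multiple-site partition over the members' benefit profiles. beta_sor = 0
#' means every member provides the same benefits (maximum redundancy);
#' high beta_nes flags members that stand out as multi-beneficial.
#' Single-member clades are excluded (two sites are required).
#'
#' @param matrix a species-level `benefit_matrix`.
#' @param taxonomy a `taxonomy_map`.
#' @param rank `"genus"` or `"family"`.
#' @return data.frame (clade, rank, n_members, beta_sor, beta_sim, beta_nes).
#' @export
within_clade_beta <- function(matrix, taxonomy, rank = c("genus", "family")) {
  rank <- match.arg(rank)
  groups <- clade_members(matrix, taxonomy, rank)
  groups <- groups[lengths(groups) >= 2]
  m <- unclass(matrix)
  rows <- lapply(names(groups), function(cl) {
    part <- multisite_from_incidence(m[groups[[cl]], , drop = FALSE],
                                     rep(1, ncol(m)), "taxonomic")
    data.frame(clade = cl, rank = rank, n_members = length(groups[[cl]]),
               beta_sor = part$beta_sor, beta_sim = part$beta_sim,
               beta_nes = part$beta_nes, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame()
}

#' Effect sizes for within-clade dissimilarity against species-pool nulls
#'
#' Per clade, compares the observed multiple-site beta_sor / beta_sim /
#' beta_nes of its members' benefit profiles against nulls built by drawing
#' the same number of species at random from the whole pool of beneficial
#' species. Effect sizes use the non-parametric [es_score()] because the
#' null distributions are typically far from normal.
#'
#' @param matrix a species-level `benefit_matrix`.
#' @param taxonomy a `taxonomy_map`.
#' @param rank `"genus"` or `"family"`.
#' @param n_null number of null draws.
#' @param seed optional integer seed.
#' @return data.frame (clade, rank, n_species, obs_sor, obs_sim, obs_nes,
#'   es_sor, es_sim, es_nes).
#' @export
within_clade_es <- function(matrix, taxonomy, rank = c("genus", "family"),
                            n_null = 999, seed = NULL) {
  rank <- match.arg(rank)
  groups <- clade_members(matrix, taxonomy, rank)
  groups <- groups[lengths(groups) >= 2]
  m <- unclass(matrix)
  npool <- nrow(m)
  w <- rep(1, ncol(m))
  seeds <- derive_seeds(seed, length(groups))
  rows <- lapply(seq_along(groups), function(gi) {
    members <- groups[[gi]]
    k <- length(members)
    if (k > npool) stopf("clade larger than the species pool")
    obs <- multisite_from_incidence(m[members, , drop = FALSE], w, "taxonomic")
    nulls <- with_seed(seeds[[gi]], {
      vapply(seq_len(n_null), function(i) {
        p <- multisite_from_incidence(m[sample.int(npool, k), , drop = FALSE],
                                      w, "taxonomic")
        c(p$beta_sor, p$beta_sim, p$beta_nes)
      }, numeric(3))
    })
    data.frame(clade = names(groups)[gi], rank = rank, n_species = k,
               obs_sor = obs$beta_sor, obs_sim = obs$beta_sim,
               obs_nes = obs$beta_nes,
               es_sor = es_score(obs$beta_sor, nulls[1, ])$es,
               es_sim = es_score(obs$beta_sim, nulls[2, ])$es,
               es_nes = es_score(obs$beta_nes, nulls[3, ])$es,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows) %||% data.frame()
}
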