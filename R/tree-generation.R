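# Generation of phylogeny distributions under taxonomic uncertainty:
# pure-birth simulation, constraint-clade grafting, infrageneric resolution.

#' Simulate an ultrametric pure-birth (Yule) tree
#'
#' Speciation-only branching at rate 1 (the absolute rate is irrelevant
#' after rescaling), conditioned on the number of extant tips. The same
#' seed always yields the same tree.
#'
#' @param n_tips number of tips (>= 1).
#' @param seed optional integer seed.
#' @return an ultrametric, rooted, binary `phylo` with tips `t1..tn`.
#' @export
simulate_yule <- function(n_tips, seed = NULL) {
  if (!is.numeric(n_tips) || n_tips < 1) stopf("'n_tips' must be >= 1")
  n_tips <- as.integer(n_tips)
  if (n_tips == 1L) {
    depth <- with_seed(seed, rexp(1))
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "t1",
                          edge.length = depth, Nnode = 1L),
                     class = "phylo"))
  }
  with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
}

#' Graft a new tip into a constraint clade
#'
#' Attaches `new_tip` at a point chosen uniformly (length-weighted) along
#' the branches of the clade spanned by `constraint_clade`, including that
#' clade's stem branch unless `include_stem = FALSE`. The new tip's depth
#' equals the tree depth, so ultrametric trees stay ultrametric; depths of
#' pre-existing tips are never altered.
#'
#' @param tree a rooted ultrametric `phylo`.
#' @param new_tip label for the grafted tip (must not already exist).
#' @param constraint_clade tip labels whose MRCA defines the clade that most
#'   certainly contains the new taxon.
#' @param seed optional integer seed.
#' @param include_stem allow attachment on the clade's stem branch?
#' @return a `phylo` with one extra tip.
#' @export
graft_taxon <- function(tree, new_tip, constraint_clade, seed = NULL,
                        include_stem = TRUE) {
  validate_phylogeny(tree)
  if (new_tip %in% tree$tip.label) stopf("tip '%s' already present", new_tip)
  cidx <- tip_index(tree, constraint_clade, "constraint")
  ntip <- length(tree$tip.label)
  depth <- tree_depth(tree)
  dpt <- node_depths(tree)

  if (length(unique(cidx)) == 1L) {
    mrca <- cidx[1]
  } else {
    mrca <- ape::getMRCA(tree, unique(cidx))
  }
  # candidate edges: all edges inside the clade, plus its stem edge.
  # an edge is inside the clade iff every tip below it belongs to the clade
  # and it is not the stem edge itself.
  E <- edge_tip_incidence(tree)
  if (mrca > ntip) {
    stem_row <- match(mrca, tree$edge[, 2])
    clade_tips <- if (is.na(stem_row)) seq_len(ntip) else which(E[stem_row, ] > 0)
  } else {
    clade_tips <- mrca
  }
  below <- rowSums(E[, clade_tips, drop = FALSE])
  cand <- which(below == rowSums(E) & tree$edge[, 2] != mrca)
  stem_edge <- match(mrca, tree$edge[, 2])
  if (include_stem && !is.na(stem_edge)) cand <- c(cand, stem_edge)
  cand <- unique(cand)
  lens <- tree$edge.length[cand]
  if (length(cand) == 0 || sum(lens) <= 0) {
    stopf("no positive-length attachment branch available in the constraint clade")
  }

  with_seed(seed, {
    e <- cand[sample.int(length(cand), 1, prob = lens)]
    u <- runif(1)
  })
  child <- tree$edge[e, 2]
  attach_depth <- dpt[tree$edge[e, 1]] + u * tree$edge.length[e]
  tiptree <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                            tip.label = new_tip,
                            edge.length = depth - attach_depth, Nnode = 1L),
                       class = "phylo")
  ape::bind.tree(tree, tiptree, where = child,
                 position = dpt[child] - attach_depth)
}

#' Species-count table for infrageneric resolution
#'
#' @param genus character vector of genus names (matching genus-level tips).
#' @param count positive integer species counts.
#' @param labels optional list of species-label vectors per genus; defaults
#'   to the `Genus-1, Genus-2, ...` alpha-numerical scheme.
#' @return a `species_count_table` data.frame.
#' @export
species_count_table <- function(genus, count, labels = NULL) {
  genus <- as.character(genus)
  count <- as.integer(count)
  if (any(count < 1)) stopf("species counts must be positive")
  if (anyDuplicated(genus)) stopf("duplicate genus names")
  if (is.null(labels)) {
    labels <- lapply(seq_along(genus),
                     function(i) paste0(genus[i], "-", seq_len(count[i])))
  }
  if (length(labels) != length(genus) ||
      any(lengths(labels) != count)) {
    stopf("'labels' must provide exactly 'count' labels per genus")
  }
  all_labs <- unlist(labels)
  if (anyDuplicated(all_labs)) stopf("species labels must be unique across genera")
  structure(data.frame(genus = genus, count = count,
                       stringsAsFactors = FALSE),
            labels = labels, class = c("species_count_table", "data.frame"))
}

#' Read a species-count table from CSV (header `genus,count`)
#' @param path CSV path.
#' @return a `species_count_table`.
#' @export
read_species_counts_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  species_count_table(df$genus, df$count)
}

count_labels <- function(counts) {
  labs <- attr(counts, "labels")
  names(labs) <- counts$genus
  labs
}

#' Resolve genus-level tips into species-level pure-birth subtrees
#'
#' Every genus tip with a species count n > 1 is replaced by a Yule subtree
#' of n tips whose crown depth is `crown_fraction` of that genus's terminal
#' branch length; tips with n = 1 are only relabelled. All species tips end
#' at the original tree depth, preserving ultrametricity.
#'
#' @param tree genus-level `phylo`; every tip must appear in `counts`.
#' @param counts a [species_count_table()].
#' @param crown_fraction fraction (0, 1) of the genus terminal branch placed
#'   below the simulated genus crown node.
#' @param seed optional integer seed.
#' @return a species-level `phylo` with `sum(counts$count)` tips.
#' @export
expand_genus_tips <- function(tree, counts, crown_fraction = 0.5, seed = NULL) {
  validate_phylogeny(tree)
  if (!(crown_fraction > 0 && crown_fraction < 1)) {
    stopf("'crown_fraction' must be in (0, 1)")
  }
  missing <- setdiff(tree$tip.label, counts$genus)
  if (length(missing)) {
    stopf("genus tips missing from counts: %s", paste(missing, collapse = ", "))
  }
  labs <- count_labels(counts)
  genera <- tree$tip.label
  seeds <- derive_seeds(seed, length(genera))
  out <- tree
  for (i in seq_along(genera)) {
    g <- genera[i]
    n <- counts$count[match(g, counts$genus)]
    where <- match(g, out$tip.label)
    if (n == 1L) {
      out$tip.label[where] <- labs[[g]][1]
      next
    }
    e <- match(where, out$edge[, 2])
    L <- out$edge.length[e]
    if (L <= 0) stopf("genus '%s' has a zero-length terminal branch; cannot expand", g)
    crown <- crown_fraction * L
    sub <- simulate_yule(n, seeds[[i]])
    sub$edge.length <- sub$edge.length * (crown / tree_depth(sub))
    sub$tip.label <- labs[[g]]
    out$edge.length[e] <- L - crown
    out <- ape::bind.tree(out, sub, where = match(g, out$tip.label))
  }
  out
}

# ---- tree distributions ------------------------------------------------------

#' Bundle phylogenies into a tree distribution
#'
#' @param trees list of `phylo` objects sharing one tip-label set, all
#'   ultrametric within tolerance.
#' @param meta optional list of generation metadata (seeds, base indices).
#' @return a `tree_distribution`.
#' @export
tree_distribution <- function(trees, meta = list()) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0) stopf("empty tree distribution")
  lapply(trees, validate_phylogeny)
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), ref)) {
      stopf("tree %d has a different tip-label set", i)
    }
    chk <- check_ultrametric(trees[[i]])
    if (!chk$ultrametric) {
      warnf("tree %d deviates from ultrametricity by %.3g", i, chk$max_deviation)
    }
  }
  structure(list(trees = trees, meta = meta), class = "tree_distribution")
}

#' @export
length.tree_distribution <- function(x) length(x$trees)

#' @export
`[[.tree_distribution` <- function(x, i) x$trees[[i]]

#' @export
print.tree_distribution <- function(x, ...) {
  cat(sprintf("tree distribution: %d trees, %d tips each\n",
              length(x$trees), length(x$trees[[1]]$tip.label)))
  invisible(x)
}

#' Build a distribution of species-level trees from genus-level base trees
#'
#' Applies [expand_genus_tips()] `trees_per_base` times to each base tree.
#' The species labelling is identical across all members, so per-species
#' results can be aggregated across the distribution.
#'
#' @param base_trees list of genus-level `phylo` objects with identical tip
#'   sets (or a single tree).
#' @param counts a [species_count_table()].
#' @param trees_per_base replicates per base tree (>= 1).
#' @param seed optional root seed; per-tree streams are derived from it.
#' @param crown_fraction passed to [expand_genus_tips()].
#' @return a `tree_distribution` of `length(base_trees) * trees_per_base`
#'   trees; `meta$base` records each member's base-tree index.
#' @export
build_tree_distribution <- function(base_trees, counts, trees_per_base = 100,
                                    seed = NULL, crown_fraction = 0.5) {
  if (inherits(base_trees, "phylo")) base_trees <- list(base_trees)
  if (trees_per_base < 1) stopf("'trees_per_base' must be >= 1")
  ref <- sort(base_trees[[1]]$tip.label)
  for (i in seq_along(base_trees)) {
    if (!identical(sort(base_trees[[i]]$tip.label), ref)) {
      stopf("base tree %d has an inconsistent genus tip set", i)
    }
  }
  nb <- length(base_trees)
  seeds <- derive_seeds(seed, nb * trees_per_base)
  trees <- vector("list", nb * trees_per_base)
  base_idx <- integer(nb * trees_per_base)
  k <- 0L
  for (i in seq_len(nb)) {
    for (j in seq_len(trees_per_base)) {
      k <- k + 1L
      trees[[k]] <- expand_genus_tips(base_trees[[i]], counts,
                                      crown_fraction, seeds[[k]])
      base_idx[k] <- i
    }
  }
  tree_distribution(trees, meta = list(seed = seed, base = base_idx,
                                       trees_per_base = trees_per_base))
}

#' Subsample trees from each base family of a distribution
#'
#' Mirrors the step of randomly picking a handful of trees from each
#' per-base distribution before running the analyses.
#'
#' @param dist a `tree_distribution` with `meta$base`.
#' @param k trees to keep per base tree.
#' @param seed optional integer seed.
#' @return a smaller `tree_distribution`.
#' @export
subsample_trees <- function(dist, k, seed = NULL) {
  base <- dist$meta$base %||% rep(1L, length(dist))
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_along(base), base), function(ix) {
      if (length(ix) < k) stopf("fewer than %d trees in a base family", k)
      sort(sample(ix, k))
    }), use.names = FALSE)
  })
  tree_distribution(dist$trees[keep],
                    meta = list(seed = seed, base = base[keep], parent = dist$meta))
}

#' Write a tree distribution as a multi-tree Newick file (one per line)
#' @param dist a `tree_distribution`.
#' @param path output path.
#' @export
write_tree_distribution <- function(dist, path) {
  writeLines(vapply(dist$trees, write_newick, character(1)), path)
  invisible(path)
}

#' Read a multi-tree Newick file into a tree distribution
#' @param path input path (one Newick string per line).
#' @return a `tree_distribution`.
#' @export
read_tree_distribution <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  tree_distribution(lapply(lines, parse_newick))
}
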