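# Brute-force oracles, kept deliberately independent of the package's
# incidence-matrix implementation: everything here works by explicit
# root-path enumeration with ape::nodepath.

# random rooted tree with branch lengths (not necessarily ultrametric)
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# edge ids (rows of tree$edge) on the path from `from` node to `to` node
path_edges <- function(tree, from, to) {
  nodes <- ape::nodepath(tree, from, to)
  if (length(nodes) < 2) return(integer(0))
  vapply(seq_len(length(nodes) - 1), function(i) {
    which(tree$edge[, 1] == nodes[i] & tree$edge[, 2] == nodes[i + 1])
  }, integer(1))
}

root_node <- function(tree) length(tree$tip.label) + 1L

# branch set spanned by a tip set, as edge ids
branch_set_oracle <- function(tree, tips, include_root = TRUE) {
  idx <- match(tips, tree$tip.label)
  top <- if (include_root || length(unique(idx)) == 1) {
    if (include_root) root_node(tree) else idx[1]
  } else {
    ape::getMRCA(tree, unique(idx))
  }
  if (!include_root && length(unique(idx)) == 1) {
    return(integer(0))
  }
  sort(unique(unlist(lapply(idx, function(i) path_edges(tree, top, i)))))
}

pd_oracle <- function(tree, tips, include_root = TRUE) {
  sum(tree$edge.length[branch_set_oracle(tree, tips, include_root)])
}

overlap_oracle <- function(tree, s1, s2, include_root = TRUE) {
  e1 <- branch_set_oracle(tree, s1, include_root)
  e2 <- branch_set_oracle(tree, s2, include_root)
  list(a = sum(tree$edge.length[intersect(e1, e2)]),
       b = sum(tree$edge.length[setdiff(e1, e2)]),
       c = sum(tree$edge.length[setdiff(e2, e1)]))
}

sorensen_oracle <- function(s1, s2) {
  a <- length(intersect(s1, s2))
  b <- length(setdiff(s1, s2))
  c <- length(setdiff(s2, s1))
  sor <- if (a + b + c == 0) 0 else (b + c) / (2 * a + b + c)
  sim <- if (a + min(b, c) == 0) 0 else min(b, c) / (a + min(b, c))
  list(sor = sor, sim = sim, nes = sor - sim)
}

# multiple-site Sorensen family by naive double loops over site pairs;
# elements weighted by `w` (named vector; 1s for taxonomic)
multisite_oracle <- function(sites, w = NULL) {
  elements <- sort(unique(unlist(sites)))
  if (is.null(w)) w <- structure(rep(1, length(elements)), names = elements)
  S <- vapply(sites, function(s) sum(w[unique(s)]), numeric(1))
  ST <- sum(w[elements])
  summin <- 0; summax <- 0
  ns <- length(sites)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      bij <- sum(w[setdiff(sites[[i]], sites[[j]])])
      bji <- sum(w[setdiff(sites[[j]], sites[[i]])])
      summin <- summin + min(bij, bji)
      summax <- summax + max(bij, bji)
    }
  }
  excess <- sum(S) - ST
  sim <- if (excess + summin == 0) 0 else summin / (excess + summin)
  den <- 2 * excess + summin + summax
  sor <- if (den == 0) 0 else (summin + summax) / den
  list(sor = sor, sim = sim, nes = sor - sim)
}

# small helper: a benefit matrix from a named list of carrier sets over a
# fixed species universe (rows restricted to carriers of >= 1 benefit)
matrix_from_carriers <- function(carriers, species) {
  m <- vapply(carriers, function(cb) as.integer(species %in% cb),
              integer(length(species)))
  rownames(m) <- species
  benefit_matrix(m[rowSums(m) > 0, , drop = FALSE], "species")
}

balanced_taxonomy <- function(tree, genus_size = 2, genera_per_family = 2) {
  n <- length(tree$tip.label)
  gn <- ceiling(seq_len(n) / genus_size)
  taxonomy_map(tip = tree$tip.label,
               genus = sprintf("g%02d", gn),
               family = sprintf("f%02d", ceiling(gn / genera_per_family)))
}
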