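# ---- internal tree machinery -------------------------------------------------

# Validate the structural invariants every analysis relies on: a rooted
# tree, branch lengths present and non-negative, unique non-empty tip labels.
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) {
    stopf("expected a 'phylo' object, got %s", class(tree)[1])
  }
  if (is.null(tree$edge.length)) {
    stopf("tree has no branch lengths; all edges must carry lengths")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stopf("branch lengths must be present and non-negative")
  }
  labs <- tree$tip.label
  if (any(!nzchar(labs))) stopf("tip labels must be non-empty")
  if (anyDuplicated(labs)) {
    stopf("duplicate tip labels: %s",
          paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  # structural rootedness: exactly one node with no parent (basal
  # polytomies are allowed, unlike ape::is.rooted's degree-based test)
  roots <- unique(tree$edge[, 1][!(tree$edge[, 1] %in% tree$edge[, 2])])
  if (length(roots) != 1) {
    stopf("tree must have exactly one root (found %d)", length(roots))
  }
  invisible(tree)
}

# Edge x tip incidence: E[e, t] = 1 iff tip t descends from edge e
# (equivalently, edge e lies on the path from t to the root). Rows follow
# tree$edge order, columns are named by tip label. This single matrix powers
# PD, ED and branch-overlap computations, including vectorised null models.
edge_tip_incidence <- function(tree) {
  n <- length(tree$tip.label)
  node_tips <- matrix(0, n + tree$Nnode, n)
  node_tips[cbind(seq_len(n), seq_len(n))] <- 1
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(po))) {
    node_tips[po[r, 1], ] <- node_tips[po[r, 1], ] + node_tips[po[r, 2], ]
  }
  E <- node_tips[tree$edge[, 2], , drop = FALSE]
  colnames(E) <- tree$tip.label
  E
}

# Depth (distance from the root) of every node; tips first, ape order.
node_depths <- function(tree) ape::node.depth.edgelength(tree)

#' Total depth of a tree (maximum root-to-tip distance)
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return numeric scalar, in the branch-length units of the tree (Myr for
#'   time-calibrated trees).
#' @export
tree_depth <- function(tree) {
  validate_phylogeny(tree)
  max(node_depths(tree)[seq_along(tree$tip.label)])
}

tip_index <- function(tree, tips, what = "tip") {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stopf("unknown %s label(s): %s", what,
          paste(tips[is.na(idx)], collapse = ", "))
  }
  idx
}

# ---- Newick I/O --------------------------------------------------------------

#' Parse a Newick string into a phylogeny
#'
#' Accepts quoted labels; square-bracket comments are discarded. All edges
#' must carry branch lengths (a root edge is optional). Polytomies are
#' allowed.
#'
#' @param text a single Newick string.
#' @return a rooted `phylo` object.
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1) {
    stopf("'text' must be a single Newick string")
  }
  text <- gsub("\\[[^]]*\\]", "", text)
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stopf("malformed Newick: unmatched ')' at character %d", i)
    }
  }
  if (depth != 0L) {
    stopf("malformed Newick: %d unclosed '(' at end of string", depth)
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) stopf("malformed Newick string (unparseable)")
  # standard Newick single-quoted labels: strip the surrounding quotes
  tree$tip.label <- sub("^'(.*)'$", "\\1", tree$tip.label)
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to a Newick string or file
#'
#' @param tree a `phylo` object with branch lengths.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a phylogeny from a Newick file
#'
#' @param path path to a Newick file (first tree is returned).
#' @return a rooted `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

# ---- branch-length primitives ------------------------------------------------

#' Faith's phylogenetic diversity of a tip set
#'
#' Sum of branch lengths on the union of paths connecting the tips. With
#' `include_root = TRUE` (the default) every path is extended to the root;
#' otherwise paths stop at the most recent common ancestor of the set, so a
#' single tip has PD 0.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param tips character vector of tip labels (non-empty).
#' @param include_root extend the spanning path to the root?
#' @return numeric scalar (branch-length units).
#' @export
faith_pd <- function(tree, tips, include_root = TRUE) {
  validate_phylogeny(tree)
  if (length(tips) == 0) stopf("'tips' must be non-empty")
  idx <- tip_index(tree, tips)
  E <- edge_tip_incidence(tree)
  counts <- rowSums(E[, idx, drop = FALSE])
  if (include_root) {
    sum(tree$edge.length[counts > 0])
  } else {
    sum(tree$edge.length[counts > 0 & counts < length(idx)])
  }
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch's length is divided equally among its descendant tips; a
#' tip's ED is the sum of its shares along its root path. ED values sum to
#' the total branch length of the tree (any root edge is ignored).
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @return named numeric vector, one ED value per tip.
#' @export
fair_proportion_ed <- function(tree) {
  validate_phylogeny(tree)
  E <- edge_tip_incidence(tree)
  share <- tree$edge.length / rowSums(E)
  ed <- as.vector(crossprod(E, share))
  names(ed) <- tree$tip.label
  ed
}

#' Shared and unique branch length between two tip sets
#'
#' Decomposes the branch sets spanned by two tip samples into length
#' ancestral to both (`a`), unique to the first (`b`) and unique to the
#' second (`c`), under a common root-inclusion convention. These are the
#' evolutionary units entering the PhyloSor index.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param set1,set2 character vectors of tip labels.
#' @param include_root extend paths to the root (see [faith_pd()])?
#' @return an object of class `branch_overlap`: list with `a`, `b`, `c`.
#' @export
branch_overlap <- function(tree, set1, set2, include_root = TRUE) {
  validate_phylogeny(tree)
  if (length(set1) == 0 || length(set2) == 0) {
    stopf("both tip sets must be non-empty")
  }
  i1 <- tip_index(tree, set1)
  i2 <- tip_index(tree, set2)
  E <- edge_tip_incidence(tree)
  len <- tree$edge.length
  c1 <- rowSums(E[, i1, drop = FALSE])
  c2 <- rowSums(E[, i2, drop = FALSE])
  if (include_root) {
    in1 <- c1 > 0
    in2 <- c2 > 0
  } else {
    in1 <- c1 > 0 & c1 < length(i1)
    in2 <- c2 > 0 & c2 < length(i2)
  }
  structure(list(a = sum(len[in1 & in2]),
                 b = sum(len[in1 & !in2]),
                 c = sum(len[!in1 & in2]),
                 include_root = include_root),
            class = "branch_overlap")
}

#' @export
print.branch_overlap <- function(x, ...) {
  cat(sprintf("branch overlap: a = %.6g, b = %.6g, c = %.6g (%s)\n",
              x$a, x$b, x$c,
              if (x$include_root) "root-inclusive" else "root-exclusive"))
  invisible(x)
}

#' Prune a tree to a subset of tips
#'
#' Returns the induced subtree. With `suppress_unifurcations = TRUE`
#' (default) degree-two nodes created by pruning are removed and their edge
#' lengths summed, so root-to-tip depths of the kept tips are unchanged.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param keep character vector of tip labels to retain (non-empty subset).
#' @param suppress_unifurcations merge unifurcating edges?
#' @return a `phylo` object.
#' @export
prune_to_tips <- function(tree, keep, suppress_unifurcations = TRUE) {
  validate_phylogeny(tree)
  if (length(keep) == 0) stopf("'keep' must be non-empty")
  idx <- tip_index(tree, keep)
  if (length(idx) == length(tree$tip.label)) return(tree)
  if (length(idx) == 1) {
    d <- node_depths(tree)[idx]
    return(structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = tree$tip.label[idx],
                          edge.length = d, Nnode = 1L),
                     class = "phylo"))
  }
  out <- ape::drop.tip(tree, setdiff(tree$tip.label, keep),
                       collapse.singles = FALSE)
  if (suppress_unifurcations) out <- collapse_singles_keep_root(out)
  out
}

# Merge unifurcating edges (summing lengths) but keep the original root
# position, so root-to-tip depths and root-inclusive PD are unchanged.
# The pruned tree's root may retain a single child edge down to the MRCA
# of the kept tips.
collapse_singles_keep_root <- function(tree) {
  repeat {
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    outdeg <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
    singles <- setdiff(which(outdeg == 1L), c(seq_len(ntip), root))
    singles <- singles[singles %in% tree$edge[, 2]]
    if (!length(singles)) return(tree)
    v <- singles[1]
    e_in <- which(tree$edge[, 2] == v)
    e_out <- which(tree$edge[, 1] == v)
    tree$edge[e_in, 2] <- tree$edge[e_out, 2]
    tree$edge.length[e_in] <- tree$edge.length[e_in] + tree$edge.length[e_out]
    tree$edge <- tree$edge[-e_out, , drop = FALSE]
    tree$edge.length <- tree$edge.length[-e_out]
    tree$edge[tree$edge > v] <- tree$edge[tree$edge > v] - 1L
    tree$Nnode <- tree$Nnode - 1L
  }
}

#' Check whether a tree is ultrametric
#'
#' All root-to-tip depths must agree within `rel_tolerance` of the maximum
#' depth. Published calibrated trees carry rounding noise, so callers should
#' treat failure as a warning condition, not necessarily an error.
#'
#' @param tree a rooted `phylo` tree with branch lengths.
#' @param rel_tolerance relative tolerance (fraction of the maximum depth).
#' @return list with `ultrametric` (logical) and `max_deviation` (numeric).
#' @export
check_ultrametric <- function(tree, rel_tolerance = 1e-6) {
  validate_phylogeny(tree)
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  dev <- max(d) - min(d)
  list(ultrametric = dev <= rel_tolerance * max(max(d), .Machine$double.eps),
       max_deviation = dev)
}
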