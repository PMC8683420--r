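test_that("pure-birth simulation honours its contract", {
  one <- simulate_yule(1, seed = 3)
  expect_equal(length(one$tip.label), 1)

  cherry <- simulate_yule(2, seed = 4)
  term <- cherry$edge.length[match(1:2, cherry$edge[, 2])]
  expect_equal(term[1], term[2])               # ultrametricity forces equality

  a <- write_newick(simulate_yule(64, seed = 123))
  b <- write_newick(simulate_yule(64, seed = 123))
  expect_identical(a, b)

  tr <- simulate_yule(40, seed = 9)
  expect_equal(length(tr$tip.label), 40)
  expect_equal(tr$Nnode, 39)                   # binary
  expect_true(check_ultrametric(tr, 1e-6)$ultrametric)
  expect_error(simulate_yule(0), ">= 1")
})

test_that("grafting attaches inside the constraint clade and preserves depths", {
  for (i in 1:20) {
    tr <- simulate_yule(16, seed = 100 + i)
    clade_tips <- ape::extract.clade(tr, 16 + 3)$tip.label
    before <- sort(ape::node.depth.edgelength(tr)[1:16])
    g <- graft_taxon(tr, "newtip", clade_tips, seed = i)
    expect_equal(length(g$tip.label), 17)
    expect_true(check_ultrametric(g, 1e-6)$ultrametric)
    # MRCA of constraint + new tip is the constraint MRCA or its parent
    mr_old <- ape::getMRCA(g, clade_tips)
    mr_new <- ape::getMRCA(g, c(clade_tips, "newtip"))
    parent_old <- g$edge[match(mr_old, g$edge[, 2]), 1]
    expect_true(mr_new %in% c(mr_old, parent_old))
    # pre-existing tip depths unchanged
    keep <- match(tr$tip.label, g$tip.label)
    after <- sort(ape::node.depth.edgelength(g)[keep])
    expect_equal(after, before, tolerance = 1e-9)
  }
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  expect_error(graft_taxon(tr, "Z", "C", include_stem = FALSE),
               "attachment")
})

test_that("graft attachment points are length-weighted across clade branches", {
  tr <- parse_newick("((A:1,B:1):2,C:3);")
  # constraint clade {A,B}: candidate branches A (1), B (1), stem (2)
  n_reps <- 10000
  sisters <- vapply(seq_len(n_reps), function(i) {
    g <- graft_taxon(tr, "Z", c("A", "B"), seed = i)
    # classify the attachment branch by Z's parent clade
    zi <- match("Z", g$tip.label)
    pz <- g$edge[match(zi, g$edge[, 2]), 1]
    below <- ape::extract.clade(g, pz)$tip.label
    if (setequal(below, c("Z", "A"))) "A"
    else if (setequal(below, c("Z", "B"))) "B"
    else "stem"
  }, character(1))
  freq <- table(factor(sisters, levels = c("A", "B", "stem"))) / n_reps
  half <- 2.576 * sqrt(0.25 * 0.75 / n_reps)
  expect_lt(abs(freq[["A"]] - 0.25), half)
  expect_lt(abs(freq[["B"]] - 0.25), half)
  expect_lt(abs(freq[["stem"]] - 0.5), 2.576 * sqrt(0.5 * 0.5 / n_reps))
})

test_that("genus expansion resolves counts, depths and crown placement", {
  base <- parse_newick("((gA:4,gB:4):6,gC:10);")
  counts <- species_count_table(c("gA", "gB", "gC"), c(3, 1, 2))
  sp <- expand_genus_tips(base, counts, crown_fraction = 0.5, seed = 5)
  expect_equal(sort(sp$tip.label),
               sort(c("gA-1", "gA-2", "gA-3", "gB-1", "gC-1", "gC-2")))
  d <- ape::node.depth.edgelength(sp)[seq_along(sp$tip.label)]
  expect_equal(unname(d), rep(10, 6), tolerance = 1e-9)
  # crown of gA sits crown_fraction * terminal(4) = 2 below the tips
  crown_depth <- ape::node.depth.edgelength(sp)[
    ape::getMRCA(sp, c("gA-1", "gA-2", "gA-3"))]
  expect_equal(crown_depth, 10 - 2, tolerance = 1e-9)

  # all counts 1: relabel only
  c1 <- species_count_table(c("gA", "gB", "gC"), c(1, 1, 1))
  r <- expand_genus_tips(base, c1, seed = 1)
  expect_equal(sort(r$tip.label), c("gA-1", "gB-1", "gC-1"))
  expect_equal(sum(r$edge.length), sum(base$edge.length))

  expect_error(expand_genus_tips(base, species_count_table("gA", 2)),
               "missing from counts")
})

test_that("tree distributions have consistent labels and reproduce by seed", {
  base <- simulate_yule(6, 31)
  base$tip.label <- paste0("g", 1:6)
  counts <- species_count_table(paste0("g", 1:6), c(2, 1, 3, 1, 2, 2))
  d1 <- build_tree_distribution(list(base, base), counts,
                                trees_per_base = 3, seed = 77)
  expect_equal(length(d1), 6)
  labs <- lapply(d1$trees, function(t) sort(t$tip.label))
  expect_true(all(vapply(labs, identical, logical(1), labs[[1]])))
  expect_equal(length(labs[[1]]), sum(counts$count))
  for (t in d1$trees) expect_true(check_ultrametric(t, 1e-6)$ultrametric)

  d2 <- build_tree_distribution(list(base, base), counts,
                                trees_per_base = 3, seed = 77)
  expect_identical(vapply(d1$trees, write_newick, character(1)),
                   vapply(d2$trees, write_newick, character(1)))

  sub <- subsample_trees(d1, 2, seed = 5)
  expect_equal(length(sub), 4)
  expect_equal(unname(table(sub$meta$base)), c(2L, 2L), ignore_attr = TRUE)

  base2 <- base
  base2$tip.label[1] <- "other"
  expect_error(build_tree_distribution(list(base, base2), counts, 2),
               "inconsistent")
})

test_that("tree distributions round-trip through multi-tree newick files", {
  base <- simulate_yule(4, 8)
  base$tip.label <- paste0("g", 1:4)
  counts <- species_count_table(paste0("g", 1:4), c(2, 2, 1, 3))
  d <- build_tree_distribution(base, counts, trees_per_base = 3, seed = 2)
  f <- tempfile(fileext = ".nwk")
  write_tree_distribution(d, f)
  back <- read_tree_distribution(f)
  expect_equal(length(back), 3)
  expect_equal(vapply(back$trees, write_newick, character(1)),
               vapply(d$trees, write_newick, character(1)))
})
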