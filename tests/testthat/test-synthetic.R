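test_that("labelled trees have monophyletic families and full taxonomy", {
  spec <- scenario_spec(n_families = 4, genera_per_family = 1,
                        species_per_genus = 4, injection = list(count = 0))
  lt <- generate_labeled_tree(spec, seed = 41)
  tr <- lt$tree
  expect_equal(length(tr$tip.label), 16)
  expect_true(check_ultrametric(tr, 1e-6)$ultrametric)
  expect_setequal(lt$taxonomy$tip, tr$tip.label)
  for (fam in unique(lt$taxonomy$family)) {
    tips <- tips_in_clade(lt$taxonomy, fam, "family")
    mrca <- ape::getMRCA(tr, tips)
    expect_setequal(ape::extract.clade(tr, mrca)$tip.label, tips)
  }
  lt2 <- generate_labeled_tree(spec, seed = 41)
  expect_identical(write_newick(lt$tree), write_newick(lt2$tree))
})

test_that("assignment rules produce the advertised structures", {
  spec <- scenario_spec(injection = list(count = 0))
  lt <- generate_labeled_tree(spec, seed = 55)
  # clustered with n = genus size fills exactly one genus
  cl <- assign_benefit(lt$tree, lt$taxonomy, "clustered", 5, seed = 2)
  genera <- unique(lt$taxonomy$genus[match(cl, lt$taxonomy$tip)])
  expect_length(genera, 1)
  # overdispersed with n = number of families picks one tip per family on a
  # balanced tree whose family splits dwarf the family crowns
  toy <- fig2_toy("B")
  ov <- assign_benefit(toy$tree, toy$taxonomy, "overdispersed", 4, seed = 2)
  fams <- toy$taxonomy$family[match(ov, toy$taxonomy$tip)]
  expect_setequal(fams, unique(toy$taxonomy$family))
  # determinism and size
  rd <- assign_benefit(lt$tree, lt$taxonomy, "random", 20, seed = 9)
  expect_length(rd, 20)
  expect_identical(rd, assign_benefit(lt$tree, lt$taxonomy, "random", 20,
                                      seed = 9))
})

test_that("injection stretches terminals, raising ED monotonically", {
  sc0 <- generate_scenario(scenario_spec(injection = list(count = 0)),
                           seed = 3)
  m <- sc0$matrix
  tr <- sc0$tree
  no_stretch <- inject_multibeneficial(tr, m, count = 4, benefits_each = 4,
                                       stretch = 1, seed = 5)
  expect_identical(write_newick(no_stretch$tree), write_newick(tr))
  expect_true(all(rowSums(unclass(no_stretch$matrix)[no_stretch$species, ]) >= 4))

  ed0 <- fair_proportion_ed(tr)
  eds <- lapply(c(2, 4), function(st) {
    r <- inject_multibeneficial(tr, m, count = 4, benefits_each = 4,
                                stretch = st, seed = 5)
    expect_true(check_ultrametric(r$tree, 1e-6)$ultrametric)
    fair_proportion_ed(r$tree)[r$species]
  })
  sp <- names(eds[[1]])
  expect_true(all(eds[[1]] > ed0[sp]))
  expect_true(all(eds[[2]] > eds[[1]]))

  # an explicit species whose stretched terminal would pass the root errors
  long_sp <- intersect(rownames(m), tr$tip.label)
  term <- tr$edge.length[match(match(long_sp, tr$tip.label), tr$edge[, 2])]
  target <- long_sp[which.max(term)]
  big <- 2 * tree_depth(tr) / max(term)
  expect_error(inject_multibeneficial(tr, m, benefits_each = 4,
                                      stretch = big, seed = 5,
                                      species = target),
               "incompatible|stretched")
})

test_that("generated scenarios pass all structural validators", {
  sc <- generate_scenario(scenario_spec(), seed = 8, n_trees = 3)
  for (t in sc$trees$trees) {
    expect_true(check_ultrametric(t, 1e-6)$ultrametric)
  }
  expect_true(all(unclass(sc$matrix) %in% 0:1))
  expect_true(all(rownames(sc$matrix) %in% sc$taxonomy$tip))
  expect_true(all(rowSums(unclass(sc$matrix)) >= 1))
  expect_true(all(rowSums(unclass(sc$matrix)[sc$injected, ]) >= 5))
})

test_that("the four-benefit toy reproduces its printed probabilities", {
  toy <- fig2_toy("B")
  expect_equal(length(toy$tree$tip.label), 16)
  # each benefit's carriers are two confamiliar species
  m <- unclass(toy$matrix)
  for (b in colnames(m)) {
    cb <- rownames(m)[m[, b] == 1]
    expect_length(cb, 2)
    fams <- unique(toy$taxonomy$family[match(cb, toy$taxonomy$tip)])
    expect_length(fams, 1)
  }
  pd <- capture_probability(toy$tree, toy$matrix, toy$taxonomy,
                            "pdmax_one_per_family", 4)
  expect_equal(pd$probability, 0.5^4)
  rnd <- capture_probability(toy$tree, toy$matrix, toy$taxonomy,
                             "uniform_random", 4)
  expect_equal(rnd$n_total, choose(16, 4))
  expect_equal(rnd$n_favorable, 16)
  expect_equal(rnd$probability, 16 / 1820)
})

test_that("the dyestuffs/fodder toy has the advertised structure", {
  toy <- fig2_toy("A")
  m <- unclass(toy$matrix)
  dye <- rownames(m)[m[, "tannins/dyestuffs"] == 1]
  fams <- unique(toy$taxonomy$family[match(dye, toy$taxonomy$tip)])
  expect_length(fams, 4)                       # overdispersed across families
  fodder <- rownames(m)[m[, "fodder"] == 1]
  gen <- unique(toy$taxonomy$genus[match(fodder, toy$taxonomy$tip)])
  expect_length(gen, 1)                        # one genus only
})

test_that("a ubiquitous benefit is always captured", {
  toy <- fig2_toy("B")
  m <- matrix(1L, 16, 1, dimnames = list(toy$tree$tip.label, "everywhere"))
  bm <- benefit_matrix(m)
  for (strat in c("pdmax_one_per_family", "uniform_random")) {
    p <- capture_probability(toy$tree, bm, toy$taxonomy, strat, 4)
    expect_equal(p$probability, 1)
  }
})

test_that("uniform-random capture equals an independent enumeration", {
  toy <- fig2_toy("A")
  p <- capture_probability(toy$tree, toy$matrix, toy$taxonomy,
                           "uniform_random", 3)
  m <- unclass(toy$matrix)
  carriers <- lapply(colnames(m), function(b) rownames(m)[m[, b] == 1])
  subsets <- combn(toy$tree$tip.label, 3, simplify = FALSE)
  fav <- sum(vapply(subsets, function(s) {
    all(vapply(carriers, function(cb) length(intersect(cb, s)) > 0,
               logical(1)))
  }, logical(1)))
  expect_equal(p$n_favorable, fav)
  expect_equal(p$probability, fav / length(subsets))
})

test_that("the census-driven matrix realises the published row-sum counts", {
  m <- simulate_census_matrix(seed = 12)
  expect_equal(nrow(m), 9521)
  expect_equal(ncol(m), 25)
  census <- reference_benefit_census()
  rs <- rowSums(unclass(m))
  expect_equal(unname(table(factor(rs, levels = census$n_benefits))),
               census$n_species, ignore_attr = TRUE)
  # printed per-threshold subset sizes fall out of the census
  expect_equal(length(multibeneficial_subset(m, 3)), 1548)
  expect_equal(length(multibeneficial_subset(m, 4)), 666)
  expect_equal(length(multibeneficial_subset(m, 8)), 39)
})
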