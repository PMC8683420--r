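test_that("pairwise phylogenetic partition matches the worked decomposition", {
  tt <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  idp <- pairwise_phylo_partition(tt, c("A", "B"), c("A", "B"))
  expect_equal(c(idp$beta_sor, idp$beta_sim, idp$beta_nes), c(0, 0, 0))

  disjoint <- pairwise_phylo_partition(tt, c("A", "B"), c("C", "D"),
                                       include_root = FALSE)
  expect_equal(disjoint$beta_sor, 1)

  p <- pairwise_phylo_partition(tt, c("A", "B"), c("A", "C"))
  expect_equal(p$beta_sor, 3 / 7)
  expect_equal(p$beta_sim, 1 / 3)
  expect_equal(p$beta_nes, 3 / 7 - 1 / 3)
})

test_that("partition components always satisfy their algebraic constraints", {
  for (i in 1:100) {
    tr <- random_tree(sample(4:12, 1), seed = 6000 + i)
    n <- length(tr$tip.label)
    s1 <- sample(tr$tip.label, sample(1:n, 1))
    s2 <- sample(tr$tip.label, sample(1:n, 1))
    p <- pairwise_phylo_partition(tr, s1, s2)
    expect_true(p$beta_sim >= 0 && p$beta_sim <= p$beta_sor)
    expect_lte(p$beta_sor, 1)
    expect_equal(p$beta_sor, p$beta_sim + p$beta_nes, tolerance = 1e-12)
  }
})

test_that("taxonomic Sorensen agrees with the set-arithmetic oracle", {
  universe <- letters
  for (i in 1:100) {
    set.seed(7000 + i)
    s1 <- sample(universe, sample(1:10, 1))
    s2 <- sample(universe, sample(1:10, 1))
    p <- pairwise_sorensen(s1, s2)
    o <- sorensen_oracle(s1, s2)
    expect_equal(p$beta_sor, o$sor, tolerance = 1e-12)
    expect_equal(p$beta_sim, o$sim, tolerance = 1e-12)
    expect_equal(p$beta_nes, o$nes, tolerance = 1e-12)
  }
})

test_that("multiple-site partitions collapse to pairwise with two sites", {
  for (i in 1:100) {
    set.seed(8000 + i)
    s1 <- sample(letters, sample(2:10, 1))
    s2 <- sample(letters, sample(2:10, 1))
    m2 <- multisite_partition(list(a = s1, b = s2), "taxonomic")
    pw <- pairwise_sorensen(s1, s2)
    expect_equal(m2$beta_sor, pw$beta_sor, tolerance = 1e-12)
    expect_equal(m2$beta_sim, pw$beta_sim, tolerance = 1e-12)
  }
  for (i in 1:50) {
    tr <- random_tree(sample(5:12, 1), seed = 8500 + i)
    n <- length(tr$tip.label)
    s1 <- sample(tr$tip.label, sample(2:n, 1))
    s2 <- sample(tr$tip.label, sample(2:n, 1))
    m2 <- multisite_partition(list(a = s1, b = s2), "phylogenetic", tree = tr)
    pw <- pairwise_phylo_partition(tr, s1, s2)
    expect_equal(m2$beta_sor, pw$beta_sor, tolerance = 1e-12)
    expect_equal(m2$beta_sim, pw$beta_sim, tolerance = 1e-12)
  }
})

test_that("multiple-site partitions match the brute-force formulas", {
  tri <- multisite_partition(list(s1 = c("a", "b"), s2 = c("b", "c"),
                                  s3 = c("c", "a")), "taxonomic")
  orc <- multisite_oracle(list(c("a", "b"), c("b", "c"), c("c", "a")))
  expect_equal(tri$beta_sor, orc$sor, tolerance = 1e-12)
  expect_equal(tri$beta_sim, orc$sim, tolerance = 1e-12)

  ident <- multisite_partition(list(x = c("a", "b"), y = c("a", "b"),
                                    z = c("a", "b")), "taxonomic")
  expect_equal(c(ident$beta_sor, ident$beta_sim, ident$beta_nes), c(0, 0, 0))

  for (i in 1:60) {
    set.seed(9000 + i)
    ns <- sample(3:5, 1)
    sites <- replicate(ns, sample(letters[1:12], sample(1:6, 1)),
                       simplify = FALSE)
    names(sites) <- paste0("s", seq_len(ns))
    p <- multisite_partition(sites, "taxonomic")
    o <- multisite_oracle(sites)
    expect_equal(p$beta_sor, o$sor, tolerance = 1e-12)
    expect_equal(p$beta_sim, o$sim, tolerance = 1e-12)
    expect_equal(p$beta_nes, o$nes, tolerance = 1e-12)
  }
  # phylogenetic mode against the oracle with branch-length weights
  for (i in 1:40) {
    tr <- random_tree(sample(5:10, 1), seed = 9500 + i)
    n <- length(tr$tip.label)
    sites <- replicate(3, sample(tr$tip.label, sample(2:n, 1)),
                       simplify = FALSE)
    names(sites) <- paste0("s", 1:3)
    p <- multisite_partition(sites, "phylogenetic", tree = tr)
    esets <- lapply(sites, branch_set_oracle, tree = tr, include_root = TRUE)
    w <- structure(tr$edge.length, names = as.character(seq_along(tr$edge.length)))
    o <- multisite_oracle(lapply(esets, as.character), w)
    expect_equal(p$beta_sor, o$sor, tolerance = 1e-12)
    expect_equal(p$beta_sim, o$sim, tolerance = 1e-12)
  }
  expect_error(multisite_partition(list(a = "x"), "taxonomic"), "2 sites")
  expect_error(multisite_partition(list(a = "x", b = character(0)),
                                   "taxonomic"), "non-empty")
})

test_that("non-parametric ES follows the tie-corrected probability formula", {
  nulls <- runif(999)
  expect_equal(es_score(2, nulls)$es, 0.998)
  expect_equal(es_score(-1, nulls)$es, -1)
  allsame <- es_score(0.5, rep(0.5, 999))
  expect_equal(allsame$p, 0.4995)
  expect_equal(allsame$es, -0.001)
  for (i in 1:25) {
    set.seed(i)
    e <- es_score(rnorm(1), rnorm(sample(10:500, 1)))
    expect_true(e$es >= -1 && e$es <= 1)
    expect_true(e$p >= 0 && e$p <= 1)
  }
})

test_that("tip-shuffle turnover nulls preserve compositional structure", {
  # on a star tree every pairwise pbeta_sim between singleton benefits is 1
  # whatever the labelling, so a composition-preserving shuffle must give a
  # zero-spread null (degenerate)
  star <- parse_newick("(A:1,B:1,C:1,D:1,E:1);")
  m <- matrix_from_carriers(list(b1 = "A", b2 = "B"),
                            c("A", "B", "C", "D", "E"))
  s <- ses_pbsim_pairwise(star, m, "b1", "b2", n_null = 99, seed = 1)
  expect_true(s$degenerate)
  expect_equal(s$m_obs, 1)
  expect_true(all(s$null_values == 1))
})

test_that("benefits tiling deep sister clades show high turnover SES", {
  tr <- simulate_yule(32, 13)
  root_children <- tr$edge[tr$edge[, 1] == 33, 2]
  c1 <- ape::extract.clade(tr, root_children[1])$tip.label
  c2 <- ape::extract.clade(tr, root_children[2])$tip.label
  m <- matrix_from_carriers(list(b1 = c1, b2 = c2), tr$tip.label)
  pos <- vapply(1:20, function(s) {
    ses_pbsim_pairwise(tr, m, "b1", "b2", n_null = 199, seed = s)$ses > 0
  }, logical(1))
  expect_gte(sum(pos), 19)
})

test_that("identical benefit columns give zero observed turnover", {
  tr <- simulate_yule(16, 2)
  cb <- tr$tip.label[c(1, 5, 9, 13)]
  m <- matrix_from_carriers(list(b1 = cb, b2 = cb), tr$tip.label)
  s <- ses_pbsim_pairwise(tr, m, "b1", "b2", n_null = 99, seed = 3)
  expect_equal(s$m_obs, 0)
  expect_true(s$degenerate || s$ses <= 0)
})

test_that("within-clade dissimilarity separates redundancy from nestedness", {
  species <- paste0("sp", 1:7)
  tax <- taxonomy_map(tip = species,
                      genus = c("G1", "G1", "G1", "G2", "G2", "G2", "G3"),
                      family = rep("F1", 7))
  m <- benefit_matrix(rbind(
    sp1 = c(1L, 0L, 0L, 0L), sp2 = c(1L, 0L, 0L, 0L), sp3 = c(1L, 0L, 0L, 0L),
    sp4 = c(1L, 0L, 0L, 0L), sp5 = c(1L, 0L, 0L, 0L), sp6 = c(1L, 1L, 1L, 1L),
    sp7 = c(0L, 1L, 0L, 0L)) |>
      (\(x) { colnames(x) <- c("f", "t", "mm", "o"); x })())
  res <- within_clade_beta(m, tax, "genus")
  expect_equal(sort(res$clade), c("G1", "G2"))          # singleton G3 absent
  g1 <- res[res$clade == "G1", ]
  expect_equal(g1$beta_sor, 0)                          # identical profiles
  g2 <- res[res$clade == "G2", ]                        # {f},{f},{f,t,mm,o}
  expect_equal(g2$beta_sim, 0)
  expect_gt(g2$beta_nes, g2$beta_sim)
  expect_equal(g2$beta_sor, 0.6, tolerance = 1e-12)     # hand evaluation
})

test_that("within-clade effect sizes detect redundancy and stay calibrated", {
  set.seed(77)
  n <- 40
  species <- paste0("sp", 1:n)
  profiles <- matrix(rbinom(n * 8, 1, 0.35), n, 8,
                     dimnames = list(species, paste0("b", 1:8)))
  profiles[rowSums(profiles) == 0, 1] <- 1L
  # one genus of 4 identical-profile species inside a diverse pool
  profiles[1:4, ] <- rep(c(1L, 0L, 1L, 0L, 0L, 0L, 0L, 0L), each = 4)
  tax <- taxonomy_map(tip = species,
                      genus = c(rep("Gsame", 4),
                                paste0("G", rep(1:18, each = 2))),
                      family = rep("F1", n))
  m <- benefit_matrix(profiles)
  res <- within_clade_es(m, tax, "genus", n_null = 199, seed = 3)
  expect_true(all(abs(res$es_sor) <= 1))
  same <- res[res$clade == "Gsame", ]
  expect_lt(same$es_sor, -0.9)                          # near-total redundancy

  # clades drawn by the null process itself: mean ES about 0
  pool <- benefit_matrix(profiles[5:n, ])
  es_vals <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    members <- sample(rownames(pool), 4)
    tax_i <- taxonomy_map(tip = rownames(pool),
                          genus = ifelse(rownames(pool) %in% members,
                                         "Gx", paste0("Z", seq_len(nrow(pool)))),
                          family = rep("F1", nrow(pool)))
    within_clade_es(pool, tax_i, "genus", n_null = 99, seed = i)$es_sor
  }, numeric(1))
  expect_lt(abs(mean(es_vals)), 0.15)
})
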