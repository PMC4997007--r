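test_that("species tree constructors validate and expose the design", {
  m <- three_species_tree()
  expect_s3_class(m, "species_tree_model")
  ages <- max(ape::node.depth.edgelength(m$tree)) -
    ape::node.depth.edgelength(m$tree)
  expect_equal(sort(unique(round(ages, 6))), c(0, 4000, 8000))
  # internal branch: t0 - t1 = 4000 generations; 2 coalescent units at Ne=2000
  internal <- m$tree$edge.length[m$tree$edge[, 2] > ape::Ntip(m$tree)]
  expect_equal(internal, 4000)
  expect_error(three_species_tree(t1 = 9000, t0 = 8000), "t1")

  y <- simulate_yule_species_tree(10, depth = 20000, ne = 2000, seed = 2)
  expect_equal(ape::Ntip(y$tree), 10L)
  expect_equal(y$tree$Nnode, 9L)
  expect_true(ape::is.ultrametric(y$tree, tol = 1e-6))
  expect_equal(max(ape::node.depth.edgelength(y$tree)), 20000)
  # a 2-species tree is forced to the requested depth by rescaling
  y2 <- simulate_yule_species_tree(2, depth = 123, ne = 10, seed = 3)
  expect_equal(max(ape::node.depth.edgelength(y2$tree)), 123)
})

test_that("Yule node times have the pure-birth spacing distribution", {
  # With k lineages the wait to the next speciation is Exp(k * rate). After
  # rescaling by the (random) sampling time, the rate-weighted spacings
  # between successive speciations are iid exponentials up to a common
  # factor, so their normalized partial sums pooled over replicates are
  # uniform order statistics.
  set.seed(79)
  u <- unlist(lapply(1:300, function(r) {
    m <- simulate_yule_species_tree(8, depth = 1, ne = 1,
                                    seed = 30000 + r)
    ages <- max(ape::node.depth.edgelength(m$tree)) -
      ape::node.depth.edgelength(m$tree)
    times <- sort(1 - ages[(ape::Ntip(m$tree) + 1):(2 * ape::Ntip(m$tree) - 1)])
    gaps <- diff(times) * (seq_along(times)[-1])  # rate-weighted spacings
    cumsum(gaps)[seq_len(length(gaps) - 1)] / sum(gaps)
  }))
  expect_gt(stats::ks.test(u, "punif")$p.value, 0.01)
})

test_that("single-population coalescent times and topologies are calibrated", {
  m <- species_tree_model(ape::read.tree(text = "(one:1);"), ne = 500)
  d <- simulate_gene_trees(m, samples_per_species = 2, n_loci = 4000,
                           seed = 11)
  tmrca <- vapply(d$gene_trees, function(t) {
    max(ape::node.depth.edgelength(t))
  }, numeric(1))
  # mean pairwise coalescence time = Ne generations under the 1/Ne rate
  expect_equal(mean(tmrca), 500, tolerance = 4 * 500 / sqrt(4000) / 500)

  d3 <- simulate_gene_trees(m, samples_per_species = 3, n_loci = 3000,
                            seed = 12)
  tab <- count_triplets(d3$gene_trees)
  freq <- tab$counts[1, ] / sum(tab$counts[1, ])
  expect_true(all(abs(freq - 1 / 3) < 3.5 * sqrt((1 / 3) * (2 / 3) / 3000)))
})

test_that("triplet congruence tracks 1 - (2/3) exp(-lambda)", {
  for (lam in c(0.5, 2)) {
    m <- three_species_tree(ne = 4000 / lam)
    d <- simulate_gene_trees(m, samples_per_species = 1, n_loci = 3000,
                             seed = 130 + lam * 10)
    tab <- count_triplets(d$gene_trees)
    p <- 1 - (2 / 3) * exp(-lam)
    # slot 1 is sp1_1/sp2_1 together: the species-tree topology
    expect_equal(tab$counts[1, 1] / sum(tab$counts[1, ]), p,
                 tolerance = 4 * sqrt(p * (1 - p) / 3000) / p)
  }
})

test_that("gene trees are binary, complete, and reproducible under a seed", {
  m <- simulate_yule_species_tree(5, depth = 10000, ne = 1000, seed = 21)
  d1 <- simulate_gene_trees(m, samples_per_species = 3, n_loci = 4, seed = 22)
  d2 <- simulate_gene_trees(m, samples_per_species = 3, n_loci = 4, seed = 22)
  expect_identical(lapply(d1$gene_trees, write_newick),
                   lapply(d2$gene_trees, write_newick))
  for (t in d1$gene_trees) {
    expect_setequal(t$tip.label, names(d1$truth))
    expect_equal(t$Nnode, ape::Ntip(t) - 1L)
  }
  expect_equal(sort(unique(unname(d1$truth))), paste0("sp", 1:5))
})

test_that("nonmonophyly spans its limits with divergence depth", {
  # essentially complete lineage sorting: tiny Ne relative to branch lengths
  deep <- simulate_gene_trees(three_species_tree(ne = 20),
                              samples_per_species = 5, n_loci = 40, seed = 31)
  expect_lt(nonmonophyly_proportion(deep), 0.05)
  # panmixia in disguise: negligible divergence times
  flat <- simulate_gene_trees(three_species_tree(t1 = 1e-9, t0 = 2e-9,
                                                 ne = 5000),
                              samples_per_species = 10, n_loci = 40,
                              seed = 32)
  expect_gt(nonmonophyly_proportion(flat), 0.9)
})

test_that("match statistics count exact block recoveries", {
  ten <- stats::setNames(rep(1:10, each = 2), paste0("x", 1:20))
  expect_equal(match_statistics(ten, ten),
               list(n_estimated_species = 10, n_exact_matches = 10))
  one <- stats::setNames(rep(1, 20), paste0("x", 1:20))
  expect_equal(match_statistics(one, ten),
               list(n_estimated_species = 1, n_exact_matches = 0))
  truth <- list(c("a", "b"), c("c", "d"))
  est <- list(c("a", "b"), "c", "d")
  expect_equal(match_statistics(est, truth),
               list(n_estimated_species = 3, n_exact_matches = 1))
  expect_error(match_statistics(list(c("a", "b")), truth), "differ")
})
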