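test_that("tiny trees come out with the expected heights and Newick form", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_identical(to_newick(t2), "(A:0.2,B:0.2);")
  d3 <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_identical(to_newick(t3), "((A:0.1,B:0.1):0.2,C:0.3);")
  # round trip through Newick preserves the tree
  back <- ape::read.tree(text = to_newick(t3))
  expect_true(ape::all.equal.phylo(back, t3))
  expect_equal(cophenetic(back)[c("A", "B", "C"), c("A", "B", "C")],
               cophenetic(t3)[c("A", "B", "C"), c("A", "B", "C")])
})

test_that("upgma agrees with average-linkage hclust on random tie-free matrices", {
  set.seed(201)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    dm <- random_dist(n)
    tree <- upgma(dm)
    hc <- hclust(as.dist(dm), method = "average")
    # identical cophenetic distances <=> identical topology and heights
    labs <- rownames(dm)
    expect_equal(cophenetic(tree)[labs, labs],
                 as.matrix(cophenetic(hc))[labs, labs],
                 tolerance = 1e-10)
  }
})

test_that("trees are ultrametric with non-decreasing merge heights", {
  set.seed(202)
  for (rep in 1:20) {
    dm <- random_dist(sample(4:12, 1))
    tree <- upgma(dm)
    depths <- leaf_depths(tree)
    expect_lt(max(depths) - min(depths), 1e-9)
    expect_true(ape::is.ultrametric(tree, tol = 1e-9))
    # node heights (root-to-node depth subtracted from leaf depth) are
    # non-increasing towards the tips, i.e. merges happened in
    # non-decreasing height order
    nd <- ape::node.depth.edgelength(tree)
    heights <- max(depths) - nd
    for (e in seq_len(nrow(tree$edge))) {
      expect_gte(heights[tree$edge[e, 1]], heights[tree$edge[e, 2]] - 1e-12)
    }
  }
})

test_that("exact ties merge the lexicographically smallest label pair", {
  labs <- c("B", "D", "A", "C")
  dm <- matrix(0.5, 4, 4, dimnames = list(labs, labs))
  diag(dm) <- 0
  # everything ties at 0.5: first merge must be A+B, then (A,B)+C, then D
  tree <- upgma(dm)
  expect_identical(to_newick(tree),
                   "(((A:0.25,B:0.25):0,C:0.25):0,D:0.25);")
})

test_that("degenerate and invalid distance inputs are refused", {
  m <- matrix(c(0, .2, .3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(m), "not symmetric")
  neg <- matrix(c(0, -.1, -.1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(upgma(neg), "negative")
  one <- matrix(0, 1, 1, dimnames = list("A", "A"))
  expect_error(upgma(one), "at least 2")
})

test_that("bipartition sets match topology", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_length(tree_bipartitions(upgma(d2)), 0L)
  cat4 <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  expect_identical(tree_bipartitions(cat4), c("C|D", "D"))
  set.seed(203)
  dm <- random_dist(8)
  expect_identical(tree_bipartitions(upgma(dm)), tree_bipartitions(upgma(dm)))
})

test_that("bootstrap support is reproducible, bounded, and saturates on clean splits", {
  set.seed(204)
  # two strongly differentiated populations: many diagnostic bands
  cfg <- sim_config(n_populations = 4, samples_per_population = 6,
                    bands_per_system = c(RAPD = 80, ISSR = 60, REMAP = 60),
                    differentiation = 0.4, diagnostic_fraction = 0.3,
                    monomorphic_fraction = 0, seed = 2041)
  sim <- simulate_markers(cfg)
  t1 <- bootstrap_support(sim$matrix, sim$table, replicates = 50, seed = 99)
  t2 <- bootstrap_support(sim$matrix, sim$table, replicates = 50, seed = 99)
  expect_identical(to_newick(t1), to_newick(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # single replicate: supports are all-or-nothing
  t3 <- bootstrap_support(sim$matrix, sim$table, replicates = 1, seed = 1)
  s3 <- suppressWarnings(as.numeric(t3$node.label))
  expect_true(all(s3[!is.na(s3)] %in% c(0, 100)))
  expect_error(bootstrap_support(sim$matrix, sim$table, replicates = 0),
               "replicates")
})

test_that("a well-separated two-population split earns near-total support", {
  cfg <- sim_config(n_populations = 2, samples_per_population = 8,
                    bands_per_system = c(RAPD = 100, ISSR = 60, REMAP = 40),
                    differentiation = 0.5, diagnostic_fraction = 0.2,
                    monomorphic_fraction = 0.1, seed = 2042)
  sim <- simulate_markers(cfg)
  # individual-level tree: the populations should split with >= 95% support
  tree <- bootstrap_support(sim$matrix, table = NULL, replicates = 100,
                            seed = 5)
  keys <- markerdiv:::node_bipartitions(tree)
  pops <- sim$table$population
  side <- sort(sim$table$sample_id[pops == "Pop02"])
  want <- paste(side, collapse = "|")
  # both children of the root induce the same unrooted split, so the key
  # can legitimately appear on one or two internal nodes
  hit <- which(keys == want)
  expect_gte(length(hit), 1L)
  support <- as.numeric(tree$node.label[hit])
  expect_true(all(support >= 95))
})

test_that("bootstrap supports are equivariant under population relabeling", {
  set.seed(205)
  cfg <- sim_config(n_populations = 3, samples_per_population = 5,
                    bands_per_system = c(RAPD = 40, ISSR = 20, REMAP = 10),
                    differentiation = 0.3, seed = 77)
  sim <- simulate_markers(cfg)
  t1 <- bootstrap_support(sim$matrix, sim$table, replicates = 30, seed = 42)
  # rename populations without changing content
  map <- c(Pop01 = "North", Pop02 = "South", Pop03 = "East")
  tab2 <- sim$table
  tab2$population <- unname(map[tab2$population])
  t2 <- bootstrap_support(sim$matrix, tab2, replicates = 30, seed = 42)
  relabel <- function(tree) {
    tree$tip.label <- ifelse(tree$tip.label %in% names(map),
                             unname(map[tree$tip.label]), tree$tip.label)
    tree
  }
  expect_true(ape::all.equal.phylo(relabel(t1), t2, use.edge.length = FALSE))
  # supports follow their clades
  k1 <- markerdiv:::node_bipartitions(relabel(t1))
  k2 <- markerdiv:::node_bipartitions(t2)
  expect_identical(t1$node.label[match(k2, k1)], t2$node.label)
})
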