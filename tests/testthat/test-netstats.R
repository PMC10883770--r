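test_that("co-evolution networks are built from significant pairs with isolated nodes retained", {
  ref <- simulate_reference_tree(16, seed = 1)
  cfg <- sim_config(n_taxa = 16, n_genes = 6,
                    groups = list(list(members = sprintf("g%d", 1:3), rho = 1),
                                  list(members = sprintf("g%d", 4:5), rho = 1)),
                    sigma = 0.5, dropout = 0, seed = 2,
                    gene_ids = sprintf("g%d", 1:6))
  sim <- simulate_gene_trees(ref, cfg)
  tab <- erc_scan(sim$trees, ref_tree = ref)
  net <- build_network(tab)
  expect_setequal(igraph::V(net)$name, sprintf("g%d", 1:6))
  # every node's degree equals its count of significant partners
  sig <- tab[!is.na(tab$significant) & tab$significant, ]
  for (g in igraph::V(net)$name) {
    expect_equal(unname(igraph::degree(net, g)),
                 sum(sig$gene_a == g) + sum(sig$gene_b == g))
  }

  # no significant pairs -> edgeless network over all scanned genes
  none <- tab
  none$significant <- FALSE
  net0 <- build_network(none)
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(igraph::vcount(net0), 6)

  # all pairs significant -> complete graph
  all_sig <- tab
  all_sig$significant <- TRUE
  expect_equal(igraph::ecount(build_network(all_sig)), 15)
})

test_that("edge Jaccard index is computed on the common node set", {
  a <- labeled_network(data.frame(x = c("A", "B", "C"), y = c("B", "C", "D")))
  expect_equal(jaccard_edges(a, a), 1.0)

  b <- labeled_network(data.frame(x = c("A", "C", "D"),
                                  y = c("B", "D", "E")))
  # common nodes A..D: edge DE drops with node E; intersection {AB, CD},
  # union {AB, BC, CD} -> 2/3
  expect_equal(jaccard_edges(a, b), 2 / 3)
  expect_equal(jaccard_edges(b, a), 2 / 3)

  disj <- labeled_network(data.frame(x = c("A", "C"), y = c("C", "B")))
  expect_equal(jaccard_edges(
    labeled_network(data.frame(x = "A", y = "B"), nodes = c("A", "B", "C")),
    disj), 0)

  e1 <- labeled_network(nodes = c("A", "B"))
  expect_error(jaccard_edges(e1, e1), class = "ratecov_undefined_index")
  expect_error(labeled_network(data.frame(x = "A", y = "A")), "self-loop")
})

test_that("jaccard permutation null matches exhaustive enumeration and is reproducible", {
  nodes <- c("n1", "n2", "n3", "n4", "n5")
  a <- labeled_network(data.frame(x = c("n1", "n2", "n3"),
                                  y = c("n2", "n3", "n4")), nodes = nodes)
  b <- labeled_network(data.frame(x = c("n1", "n2", "n4"),
                                  y = c("n2", "n5", "n5")), nodes = nodes)
  obs <- jaccard_edges(a, b)

  # oracle: enumerate all C(10, 3) equal-size edge sets over 5 nodes
  allp <- utils::combn(nodes, 2)
  keys <- paste(allp[1, ], allp[2, ], sep = "|")
  eb <- c("n1|n2", "n2|n5", "n4|n5")
  sets <- utils::combn(length(keys), 3)
  js <- apply(sets, 2, function(ix) {
    inter <- sum(keys[ix] %in% eb)
    inter / (6 - inter)
  })
  exact_tail <- mean(js >= obs)

  pt <- jaccard_permutation_test(a, b, n_perm = 4000, seed = 99)
  expect_equal(pt$observed, obs)
  # Monte-Carlo error: 4 sigma of a binomial proportion plus the +1 bias
  mc_err <- 4 * sqrt(exact_tail * (1 - exact_tail) / 4000) + 1 / 4001
  expect_lt(abs(pt$p_empirical - exact_tail), mc_err + 1e-9)

  # reproducibility and +1-corrected p bounds
  pt2 <- jaccard_permutation_test(a, b, n_perm = 4000, seed = 99)
  expect_identical(pt$null_values, pt2$null_values)
  expect_gte(pt$p_empirical, 1 / 4001)
  expect_lte(pt$p_empirical, 1)

  # identical networks: observed is maximal, p minimal unless a shuffle
  # reproduces the network exactly
  self <- jaccard_permutation_test(a, a, n_perm = 200, seed = 5)
  expect_equal(self$observed, 1)
  expect_lte(self$p_empirical, (1 + sum(self$null_values == 1)) / 201)

  expect_error(jaccard_permutation_test(a, b, n_perm = 0, seed = 1),
               class = "ratecov_parameter_error")

  # degree-preserving variant keeps the degree sequence
  ptd <- jaccard_permutation_test(a, b, n_perm = 5, seed = 7,
                                  method = "degree")
  expect_length(ptd$null_values, 5)
})

test_that("nominal assortativity matches the mixing-matrix definition and igraph", {
  expect_equal(nominal_assortativity(two_clique_graph()), 1.0)
  expect_equal(nominal_assortativity(k22_graph()), -1.0)

  # 6-node mixed graph: cross-check against igraph's implementation
  ed <- data.frame(x = c("a1", "a2", "a1", "b1", "b2", "a3"),
                   y = c("a2", "a3", "b1", "b2", "a3", "b2"))
  lab <- data.frame(gene = c("a1", "a2", "a3", "b1", "b2"),
                    label = c("A", "A", "A", "B", "B"))
  g <- labeled_network(ed, labels = lab)
  r_own <- nominal_assortativity(g)
  r_ig <- igraph::assortativity_nominal(
    g, types = as.integer(factor(igraph::V(g)$label)))
  expect_equal(r_own, r_ig, tolerance = 1e-12)

  mono <- labeled_network(data.frame(x = "a1", y = "a2"),
                          labels = data.frame(gene = c("a1", "a2"),
                                              label = c("A", "A")))
  expect_error(nominal_assortativity(mono), class = "ratecov_validation_error")
  expect_error(nominal_assortativity(labeled_network(ed)), "label")
})

test_that("assortativity permutation test is seeded and detects structure", {
  # two disjoint 5-cliques: only 2 of the C(10,5) label arrangements give
  # perfect assortativity, so the empirical p can get close to its floor
  cl <- function(pre) t(utils::combn(paste0(pre, 1:5), 2))
  g <- labeled_network(
    as.data.frame(rbind(cl("a"), cl("b"))),
    labels = data.frame(gene = c(paste0("a", 1:5), paste0("b", 1:5)),
                        label = rep(c("A", "B"), each = 5)))
  at <- assortativity_permutation_test(g, n_perm = 500, seed = 42)
  expect_equal(at$observed, 1.0)
  expect_lt(at$p_empirical, 0.05)
  at2 <- assortativity_permutation_test(g, n_perm = 500, seed = 42)
  expect_identical(at$null_values, at2$null_values)

  # labels assigned independently of edges: the mean observed value over
  # replicates sits at the finite-size null expectation -1/(n-1) (labels
  # are drawn without replacement, so same-class pairs are slightly
  # under-represented among node pairs)
  obs <- vapply(1:100, function(s) {
    ratecov:::with_seed(s, {
      ed <- data.frame(x = sample(letters[1:10], 30, TRUE),
                       y = sample(letters[1:10], 30, TRUE))
      ed <- ed[ed$x != ed$y, ]
      lab <- data.frame(gene = letters[1:10],
                        label = sample(rep(c("X", "Y"), 5)))
      g <- labeled_network(ed, labels = lab)
    })
    nominal_assortativity(g)
  }, numeric(1))
  se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - (-1 / 9)), 4 * se)
})

test_that("co-fitness edges follow the two-cutoff call rule", {
  pairs <- data.frame(
    gene_a = c("g1", "g1", "g2", "g2", "g3"),
    gene_b = c("g2", "g3", "g3", "g4", "g4"),
    cofitness = c(0.80, 0.65, 0.65, 0.60, 0.76),
    conserved = c(FALSE, TRUE, FALSE, TRUE, FALSE)
  )
  net <- cofitness_edges(pairs)
  keys <- ratecov:::.edge_keys(net)
  expect_setequal(keys, c("g1|g2", "g1|g3", "g3|g4"))
  # (0.80, not conserved) -> edge; (0.65, conserved) -> edge;
  # (0.65, not conserved) -> none; (0.60, conserved) -> strict, none
  expect_false("g2|g3" %in% keys)
  expect_false("g2|g4" %in% keys)

  bad <- pairs
  bad$cofitness[1] <- 1.2
  expect_error(cofitness_edges(bad), class = "ratecov_validation_error")
})

test_that("labeled subnetwork keeps only unambiguously labeled nodes", {
  ed <- data.frame(x = c("a", "b", "c"), y = c("b", "c", "d"))
  full_lab <- data.frame(gene = letters[1:4], label = c("X", "X", "Y", "Y"))
  g <- labeled_network(ed, labels = full_lab)
  expect_equal(igraph::vcount(labeled_subnetwork(g)), 4)

  # ambiguous (two labels) and missing nodes are dropped, edges with them too
  part_lab <- data.frame(gene = c("a", "b", "b", "c"),
                         label = c("X", "X", "Y", "Y"))
  sub <- labeled_subnetwork(labeled_network(ed, labels = part_lab))
  expect_setequal(igraph::V(sub)$name, c("a", "c"))
  expect_equal(igraph::ecount(sub), 0)

  none <- labeled_network(ed, labels = data.frame(gene = "z", label = "X"))
  expect_equal(igraph::vcount(labeled_subnetwork(none)), 0)
})

test_that("networks round-trip through TSV edge lists", {
  g <- labeled_network(data.frame(x = c("a", "b"), y = c("b", "c")),
                       nodes = c("a", "b", "c", "iso"))
  f <- file.path(temp_dir(), "net.tsv")
  write_network(g, f)
  back <- read_network(f)
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_setequal(ratecov:::.edge_keys(back), ratecov:::.edge_keys(g))
})
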