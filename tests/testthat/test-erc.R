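test_that("branch normalization against the reference behaves on identity, scaling, and pruning", {
  ref <- random_tree(9, 1)
  expect_true(all(normalize_branches(ref, ref) == 1))
  gene2 <- scaled_gene_tree(ref, rep(2, length(ref$edge.length)))
  expect_true(all(normalize_branches(gene2, ref) == 2))

  # gene missing one taxon vs a 6-taxon reference: the reference is pruned,
  # merged branches summed; ratios checked against hand-computed path sums
  ref6 <- parse_newick("(((A:1,B:2):1,(C:1,D:1):2):1,(E:2,F:3):1);")
  gene5 <- parse_newick("(((A:2,B:2):3,(C:3,D:4):2):1,F:7);")
  v <- normalize_branches(gene5, ref6)
  # pruning E from ref6: F edge 3 + stem 1 = 4, then merged with the other
  # root-adjacent edge (1) on the unrooted view -> F split length 5; the
  # gene's F split is 7 + its root stem 1 = 8
  expected <- c("B" = 1, "C" = 3, "C|D" = 1, "C|D|F" = 3, "D" = 4,
                "F" = 8 / 5, "B|C|D|F" = 2)
  expect_equal(v[names(expected)], expected)

  # topology conflict is an incongruence error naming a split
  conflict <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")
  ref4 <- parse_newick(nwk_quartet)
  expect_error(normalize_branches(conflict, ref4),
               class = "ratecov_incongruence_error")

  # zero-length reference branch (on a non-root edge): dropped with warning
  ref0 <- parse_newick("((A:0,B:1):1,(C:1,D:1):1);")
  expect_warning(v0 <- normalize_branches(ref4, ref0), "zero-length")
  expect_length(v0, 4L)
})

test_that("outlier filtering removes a branch from both vectors when either exceeds the threshold", {
  a <- c(s1 = 1, s2 = 6, s3 = 2)
  b <- c(s1 = 1, s2 = 1, s3 = 1)
  flt <- filter_outlier_branches(a, b)
  expect_named(flt$a, c("s1", "s3"))
  expect_named(flt$b, c("s1", "s3"))

  ok <- filter_outlier_branches(a[c(1, 3)], b[c(1, 3)])
  expect_equal(ok$a, a[c(1, 3)])

  all_out <- filter_outlier_branches(a + 10, b)
  expect_length(all_out$a, 0L)
})

test_that("Z-transform centers and scales with the sample-SD convention", {
  expect_equal(unname(z_transform(c(1, 2, 3))), c(-1, 0, 1))
  v <- z_transform(rnorm(20) * 3 + 5)
  expect_lt(abs(mean(v)), 1e-12)
  expect_equal(sd(v), 1)
  expect_error(z_transform(c(4, 4, 4)), class = "ratecov_skip")
})

test_that("erc_pair matches an independent closed-form Pearson/t computation and applies the outlier filter", {
  ref <- random_tree(8, 5) # 14 rooted edges, 13 unrooted splits
  root_edges <- which(ref$edge[, 1] == length(ref$tip.label) + 1)
  ne <- length(ref$edge.length)
  fa <- ratecov:::with_seed(21, runif(ne, 0.3, 3))
  fb <- ratecov:::with_seed(22, runif(ne, 0.3, 3))
  # equal factors on the two root-adjacent edges so the merged unrooted
  # branch keeps a well-defined normalized value
  fa[root_edges] <- fa[root_edges[1]]
  fb[root_edges] <- fb[root_edges[1]]
  non_root <- setdiff(seq_len(ne), root_edges)
  fa[non_root[1]] <- 6 # outlier: this split must be dropped from BOTH
  res <- erc_pair(scaled_gene_tree(ref, fa), scaled_gene_tree(ref, fb), ref,
                  gene_a = "ga", gene_b = "gb")
  expect_identical(res$n_branches, 12L)

  # oracle over the 13 splits (root pair merged), paired by edge identity
  fa_s <- c(fa[non_root], fa[root_edges[1]])
  fb_s <- c(fb[non_root], fb[root_edges[1]])
  keep <- fa_s <= 5 & fb_s <= 5
  oracle <- pearson_oracle(fa_s[keep], fb_s[keep])
  expect_equal(res$r, oracle$r, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
})

test_that("erc_pair is symmetric, detects self-correlation, and rejects negative covariation", {
  ref <- random_tree(10, 2)
  ne <- length(ref$edge.length)
  fa <- ratecov:::with_seed(31, runif(ne, 0.4, 2.5))
  fb <- ratecov:::with_seed(32, runif(ne, 0.4, 2.5))
  ga <- scaled_gene_tree(ref, fa)
  gb <- scaled_gene_tree(ref, fb)
  ab <- erc_pair(ga, gb, ref, gene_a = "a", gene_b = "b")
  ba <- erc_pair(gb, ga, ref, gene_a = "b", gene_b = "a")
  expect_identical(ab, ba)

  self <- erc_pair(ga, ga, ref, gene_a = "a", gene_b = "a2")
  expect_equal(self$r, 1.0)

  # deviations exactly opposite around the reference: r < 0 and the pair
  # is never called co-evolving, whatever its p-value
  d <- ratecov:::with_seed(33, runif(ne, -0.4, 0.4))
  up <- scaled_gene_tree(ref, 1 + d)
  dn <- scaled_gene_tree(ref, 1 - d)
  res <- finalize_erc_table(erc_pair(up, dn, ref, gene_a = "u", gene_b = "d"))
  expect_lt(res$r, 0)
  expect_false(res$significant)
})

test_that("rate covariation is invariant to per-gene global rescaling", {
  ref <- random_tree(10, 7)
  ne <- length(ref$edge.length)
  fa <- ratecov:::with_seed(41, runif(ne, 0.4, 2.5))
  fb <- ratecov:::with_seed(42, runif(ne, 0.4, 2.5))
  base <- erc_pair(scaled_gene_tree(ref, fa), scaled_gene_tree(ref, fb), ref)
  # scale chosen to keep normalized lengths below the outlier threshold:
  # the Z-transform removes scale exactly, but the >5 filter is applied on
  # the normalized (scale-carrying) values
  scaled <- erc_pair(scaled_gene_tree(ref, fa * 1.8),
                     scaled_gene_tree(ref, fb), ref)
  expect_equal(scaled$r, base$r, tolerance = 1e-12)
  expect_equal(scaled$p, base$p, tolerance = 1e-12)
  expect_identical(scaled$n_branches, base$n_branches)
})

test_that("erc_scan enumerates the comparison family and accounts for every pair", {
  ref <- simulate_reference_tree(20, seed = 9)
  cfg <- sim_config(n_taxa = 20, n_genes = 11, sigma = 0.5, dropout = 0,
                    seed = 10, gene_ids = sprintf("g%02d", 1:11))
  sim <- simulate_gene_trees(ref, cfg)

  tab <- erc_scan(sim$trees, ref_tree = ref)
  expect_equal(nrow(tab), 55L) # 11 * 10 / 2
  expect_identical(attr(tab, "family_size"), 55L)

  two <- erc_scan(sim$trees[1:2], ref_tree = ref)
  expect_equal(nrow(two), 1L)

  dup <- sim$trees[c(1, 1, 2)]
  names(dup) <- c("g01", "g01", "g02")
  expect_error(erc_scan(dup, ref_tree = ref), "duplicate")

  # a gene identical to the reference yields zero-variance skips that stay
  # in the family count: significant + non-significant + skipped = m
  trees2 <- c(sim$trees[1:4], list(flat = ref))
  tab2 <- erc_scan(trees2, ref_tree = ref)
  expect_equal(nrow(tab2), 10L)
  expect_equal(sum(tab2$skip_reason == "zero_variance", na.rm = TRUE), 4L)
  expect_equal(sum(tab2$significant, na.rm = TRUE) +
                 sum(!tab2$significant & is.na(tab2$skip_reason), na.rm = TRUE) +
                 sum(!is.na(tab2$skip_reason)),
               attr(tab2, "family_size"))

  # cross-scan family size |A| x |B|
  cross <- erc_scan(sim$trees[1:3], sim$trees[4:7], ref_tree = ref)
  expect_equal(nrow(cross), 12L)
  expect_error(erc_scan(sim$trees[1:3], sim$trees[3:5], ref_tree = ref),
               "disjoint")
})

test_that("scan tables round-trip through TSV with family size intact", {
  ref <- simulate_reference_tree(16, seed = 3)
  cfg <- sim_config(n_taxa = 16, n_genes = 5, sigma = 0.5, dropout = 0.1,
                    seed = 4, gene_ids = sprintf("g%d", 1:5))
  sim <- simulate_gene_trees(ref, cfg)
  tab <- erc_scan(sim$trees, ref_tree = ref)
  f <- file.path(temp_dir(), "erc.tsv")
  write_erc_table(tab, f)
  back <- read_erc_table(f)
  expect_identical(attr(back, "family_size"), attr(tab, "family_size"))
  expect_equal(back$r, tab$r)
  expect_identical(back$significant, tab$significant)
})

test_that("quartet congruence scores topological agreement", {
  t <- random_tree(7, 11)
  expect_equal(quartet_congruence(t, t), 1.0)

  # 5-taxon caterpillar vs its one-NNI neighbour: exhaustive hand
  # enumeration of the 5 quartets gives 3/5 agreement
  cat5 <- parse_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  nni5 <- parse_newick("((((A:1,C:1):1,B:1):1,D:1):1,E:1);")
  expect_equal(quartet_congruence(cat5, nni5), 0.6)
  expect_equal(quartet_congruence(nni5, cat5), 0.6) # symmetric

  # random 6-taxon pairs match an independent four-point-condition oracle
  for (seed in 1:20) {
    t1 <- random_tree(6, seed)
    t2 <- random_tree(6, seed + 500)
    expect_equal(quartet_congruence(t1, t2), quartet_score_oracle(t1, t2))
  }

  expect_error(quartet_congruence(parse_newick("(A:1,(B:1,C:1):1);"),
                                  parse_newick("(A:1,(B:1,D:1):1);")),
               class = "ratecov_too_few_taxa")
})

test_that("reference-gene selection uses a strict quartet-score cutoff", {
  # swapping B and C in a 6-taxon caterpillar changes exactly the 3
  # quartets containing A, B and C: score 12/15 = 0.8 exactly
  cat6 <- parse_newick("(((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1);")
  swp6 <- parse_newick("(((((A:1,C:1):1,B:1):1,D:1):1,E:1):1,F:1);")
  expect_equal(quartet_congruence(cat6, swp6), 0.8)

  trees <- list(borderline = swp6, identical = cat6)
  sel <- select_reference_genes(trees, cat6, cutoff = 0.8)
  expect_identical(as.character(sel), "identical") # 0.8 is excluded

  expect_identical(select_reference_genes(list(), cat6), character(0))
})
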