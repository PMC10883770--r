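# fixtures and independent oracles built in code

temp_dir <- function() {
  d <- tempfile("ratecov")
  dir.create(d)
  d
}

# quartet tree newicks
nwk_quartet <- "((A:1,B:1):1,(C:1,D:1):1);"

# random binary tree with positive lengths, fixed seed
random_tree <- function(n, seed) {
  ratecov:::with_seed(seed, {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
    tr$tip.label <- sprintf("t%02d", seq_len(n))
    tr
  })
}

# gene tree obtained by multiplying the reference branch lengths, edge by
# edge in the reference edge order, by `factors`
scaled_gene_tree <- function(ref, factors) {
  stopifnot(length(factors) == length(ref$edge.length))
  g <- ref
  g$edge.length <- ref$edge.length * factors
  g
}

# independent Pearson + t-transform oracle (explicit sums, no cor())
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# independent quartet-topology oracle via the four-point condition on
# patristic distances (strict inequality requires a positive internal edge)
quartet_score_oracle <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  top4 <- function(tr) {
    d <- ape::cophenetic.phylo(tr)[shared, shared]
    qs <- utils::combn(length(shared), 4L)
    apply(qs, 2L, function(q) {
      s1 <- d[q[1], q[2]] + d[q[3], q[4]]
      s2 <- d[q[1], q[3]] + d[q[2], q[4]]
      s3 <- d[q[1], q[4]] + d[q[2], q[3]]
      sums <- c(s1, s2, s3)
      lo <- which(sums < min(sums[-which.min(sums)]) - 1e-9)
      if (length(lo) == 1L) which.min(sums) else 0L
    })
  }
  a <- top4(t1)
  b <- top4(t2)
  mean(a == b & a > 0L)
}

# toy labeled graphs for assortativity
two_clique_graph <- function() {
  ed <- rbind(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
              c("b1", "b2"), c("b1", "b3"), c("b2", "b3"))
  labeled_network(as.data.frame(ed),
                  labels = data.frame(gene = c("a1", "a2", "a3",
                                               "b1", "b2", "b3"),
                                      label = rep(c("A", "B"), each = 3)))
}

k22_graph <- function() {
  ed <- rbind(c("u1", "v1"), c("u1", "v2"), c("u2", "v1"), c("u2", "v2"))
  labeled_network(as.data.frame(ed),
                  labels = data.frame(gene = c("u1", "u2", "v1", "v2"),
                                      label = c("U", "U", "V", "V")))
}
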