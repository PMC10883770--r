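# Synthetic data with planted rate covariation.
#
# A Yule reference tree carries "true" branch lengths b_e. Gene i in group
# g (within-group rate correlation rho_g) gets branch lengths
#
#   l_{i,e} = s_i * b_e * max(eps, 1 + sigma * d_{i,e}),
#   d_{i,e} = sqrt(rho_g) * z_{g,e} + sqrt(1 - rho_g) * eta_{i,e},
#
# with z_{g,e} shared within the group and eta_{i,e} independent, both
# standard normal, and s_i a per-gene global rate multiplier. This makes
# corr(d_i, d_j) = rho exactly for same-group genes, so rho is a direct
# recovery target, and keeps normalized branch lengths centered at 1.
# Taxon dropout (independent per gene) emulates gene families present in
# only part of the genome set.

#' Simulation configuration
#'
#' @param n_taxa number of leaves in the reference tree (>= 4).
#' @param n_genes number of gene trees.
#' @param groups list of planted co-evolving groups, each a list with
#'   `members` (gene IDs from `gene_ids`) and `rho` (within-group
#'   deviation correlation in `[0, 1]`). Memberships must be disjoint;
#'   ungrouped genes evolve independently.
#' @param sigma per-branch rate-deviation SD (>= 0).
#' @param dropout per-gene, per-taxon missingness probability in `[0, 0.5]`.
#' @param gene_scale_range range of the per-gene global rate multiplier
#'   (uniform draw).
#' @param mean_branch_length mean of the exponential reference branch
#'   lengths (substitutions/site).
#' @param seed integer seed; all randomness flows from it.
#' @param gene_ids gene identifiers (default `gene001`, `gene002`, ...).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_taxa = 60, n_genes = 40, groups = list(),
                       sigma = 0.5, dropout = 0.1,
                       gene_scale_range = c(0.5, 2),
                       mean_branch_length = 0.1, seed = 1L,
                       gene_ids = sprintf("gene%03d", seq_len(n_genes))) {
  stopifnot(n_taxa >= 4, n_genes >= 1, sigma >= 0,
            dropout >= 0, dropout <= 0.5,
            length(gene_scale_range) == 2L, all(gene_scale_range > 0),
            gene_scale_range[1] <= gene_scale_range[2],
            mean_branch_length > 0, length(gene_ids) == n_genes,
            !anyDuplicated(gene_ids))
  members <- unlist(lapply(groups, `[[`, "members"))
  if (anyDuplicated(members)) {
    stop_ratecov("group memberships must be disjoint",
                 "ratecov_validation_error")
  }
  if (!all(members %in% gene_ids)) {
    stop_ratecov("group members must be gene IDs of the simulation",
                 "ratecov_validation_error")
  }
  for (g in groups) {
    stopifnot(is.numeric(g$rho), g$rho >= 0, g$rho <= 1,
              length(g$members) >= 2)
  }
  structure(list(n_taxa = as.integer(n_taxa), n_genes = as.integer(n_genes),
                 groups = groups, sigma = sigma, dropout = dropout,
                 gene_scale_range = gene_scale_range,
                 mean_branch_length = mean_branch_length,
                 seed = as.integer(seed), gene_ids = gene_ids),
            class = "sim_config")
}

#' Simulate a reference species tree
#'
#' Random Yule (pure-birth) topology with i.i.d. exponential branch
#' lengths (mean `mean_length`), deterministic for a given seed. Leaf
#' labels are `t001`, `t002`, ...
#'
#' @param n_taxa number of leaves (>= 4).
#' @param seed integer seed.
#' @param mean_length mean branch length.
#' @return a rooted `phylo` object.
#' @export
simulate_reference_tree <- function(n_taxa, seed = 1L, mean_length = 0.1) {
  if (n_taxa < 4L) {
    stop_ratecov("need at least 4 taxa", "ratecov_too_few_taxa")
  }
  with_seed(seed, {
    tr <- ape::rphylo(n_taxa, birth = 1, death = 0)
    tr$tip.label <- sprintf("t%03d", seq_len(n_taxa))
    tr$edge.length <- stats::rexp(length(tr$edge.length),
                                  rate = 1 / mean_length)
    tr
  })
}

#' Simulate gene trees with planted rate covariation
#'
#' Every gene tree has the reference topology (pruned after taxon
#' dropout); branch lengths follow the multiplicative rate-deviation model
#' described above. Genes in the same planted group have deviation
#' correlation `rho`; all other pairs are independent.
#'
#' @param ref reference tree from [simulate_reference_tree()].
#' @param config a [sim_config()].
#' @param eps positive floor for the multiplicative deviation factor.
#' @param max_retries dropout redraws allowed before giving up when a gene
#'   would fall below 4 taxa.
#' @return list with `trees` (named list of `phylo`), `truth` (data.frame
#'   `gene_a`, `gene_b`, `coevolving`, with the config echoed as attribute
#'   `config`), and `config`.
#' @export
simulate_gene_trees <- function(ref, config, eps = 1e-6, max_retries = 100L) {
  stopifnot(inherits(config, "sim_config"))
  if (length(ref$tip.label) != config$n_taxa) {
    stop_ratecov("reference tree size does not match the configuration",
                 "ratecov_validation_error")
  }
  n_edges <- length(ref$edge.length)
  ids <- config$gene_ids
  group_of <- stats::setNames(integer(config$n_genes), ids)
  rho_of <- numeric(length(config$groups))
  for (gi in seq_along(config$groups)) {
    group_of[config$groups[[gi]]$members] <- gi
    rho_of[gi] <- config$groups[[gi]]$rho
  }
  trees <- vector("list", config$n_genes)
  names(trees) <- ids
  with_seed(config$seed, {
    z <- if (length(config$groups) > 0L) {
      matrix(stats::rnorm(length(config$groups) * n_edges),
             nrow = length(config$groups))
    } else {
      matrix(numeric(0), nrow = 0L, ncol = n_edges)
    }
    s <- stats::runif(config$n_genes, config$gene_scale_range[1L],
                      config$gene_scale_range[2L])
    for (i in seq_len(config$n_genes)) {
      eta <- stats::rnorm(n_edges)
      g <- group_of[i]
      dev <- if (g > 0L) {
        sqrt(rho_of[g]) * z[g, ] + sqrt(1 - rho_of[g]) * eta
      } else {
        eta
      }
      tr <- ref
      tr$edge.length <- s[i] * ref$edge.length *
        pmax(eps, 1 + config$sigma * dev)
      if (config$dropout > 0) {
        keep <- NULL
        for (try in seq_len(max_retries)) {
          cand <- stats::runif(config$n_taxa) >= config$dropout
          if (sum(cand) >= 4L) { keep <- cand; break }
        }
        if (is.null(keep)) {
          stop_ratecov(sprintf("gene %s fell below 4 taxa after %d dropout redraws",
                               ids[i], max_retries),
                       "ratecov_simulation_error")
        }
        if (!all(keep)) tr <- prune_to_taxa(tr, ref$tip.label[keep])
      }
      trees[[i]] <- tr
    }
  })
  truth <- planted_truth(config)
  list(trees = trees, truth = truth, config = config)
}

#' Planted co-evolution truth table
#'
#' All unordered gene pairs with a flag marking pairs whose members share
#' a planted group.
#'
#' @param config a [sim_config()].
#' @return data.frame `gene_a`, `gene_b`, `coevolving`; the config is
#'   attached as attribute `config`.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pairs <- enumerate_pairs(config$gene_ids)
  group_of <- stats::setNames(integer(config$n_genes), config$gene_ids)
  for (gi in seq_along(config$groups)) {
    group_of[config$groups[[gi]]$members] <- gi
  }
  pairs$coevolving <- group_of[pairs$gene_a] > 0L &
    group_of[pairs$gene_a] == group_of[pairs$gene_b]
  attr(pairs, "config") <- config
  pairs
}

#' Companion interaction network and label table for a planted truth
#'
#' Builds an "interaction" network equal to the planted co-evolution graph
#' with each potential edge flipped independently with probability
#' `noise`, and a label table assigning each gene its planted group ID
#' (`unassigned` for ungrouped genes) — so that, by construction, label
#' assortativity of the planted graph is positive.
#'
#' @param truth truth table from [planted_truth()] /
#'   [simulate_gene_trees()] (config attribute required).
#' @param noise edge flip probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @return list with `network` (labeled `igraph`) and `labels`
#'   (data.frame `gene`, `label`).
#' @export
simulate_companion_networks <- function(truth, noise = 0.05, seed = 1L) {
  stopifnot(noise >= 0, noise < 0.5)
  config <- attr(truth, "config")
  if (is.null(config)) {
    stop_ratecov("truth table lacks its config attribute",
                 "ratecov_validation_error")
  }
  edge <- with_seed(seed, {
    flip <- stats::runif(nrow(truth)) < noise
    xor(truth$coevolving, flip)
  })
  group_of <- stats::setNames(integer(config$n_genes), config$gene_ids)
  for (gi in seq_along(config$groups)) {
    group_of[config$groups[[gi]]$members] <- gi
  }
  labels <- data.frame(
    gene = config$gene_ids,
    label = ifelse(group_of > 0L, sprintf("group%02d", group_of),
                   "unassigned"),
    stringsAsFactors = FALSE
  )
  net <- labeled_network(truth[edge, c("gene_a", "gene_b"), drop = FALSE],
                         nodes = config$gene_ids, labels = labels)
  list(network = net, labels = labels)
}

#' Network of the planted co-evolving pairs
#'
#' @param truth truth table from [planted_truth()].
#' @return an `igraph` over all simulated genes.
#' @export
planted_network <- function(truth) {
  config <- attr(truth, "config")
  nodes <- if (is.null(config)) NULL else config$gene_ids
  labeled_network(truth[truth$coevolving, c("gene_a", "gene_b"),
                        drop = FALSE],
                  nodes = nodes)
}

#' Filter gene trees by taxon prevalence
#'
#' Re-applies the family-presence criterion: keep genes whose tree retains
#' at least `min_presence` of the reference taxa.
#'
#' @param trees named list of gene trees.
#' @param ref reference tree.
#' @param min_presence fraction in `(0, 1]` (default 0.5).
#' @return the filtered named list.
#' @export
filter_by_prevalence <- function(trees, ref, min_presence = 0.5) {
  stopifnot(min_presence > 0, min_presence <= 1)
  n_ref <- length(ref$tip.label)
  keep <- vapply(trees, function(t) {
    length(intersect(t$tip.label, ref$tip.label)) >= min_presence * n_ref
  }, logical(1))
  trees[keep]
}
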