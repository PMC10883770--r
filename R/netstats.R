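# Network construction and comparison.
#
# Networks are undirected igraph objects; nodes are gene IDs (vertex
# names) and categorical labels, when present, live in the vertex
# attribute "label". Before any comparison two networks are restricted to
# their common node set: interaction and co-fitness databases cover only a
# subset of gene families, and edge overlap over mismatched universes is
# meaningless.

#' Build an undirected labeled network
#'
#' @param edges data.frame (or 2-column matrix) whose first two columns are
#'   node IDs; self-loops are rejected, duplicate undirected edges merged.
#' @param nodes optional character vector of nodes (isolated nodes are kept);
#'   defaults to the nodes appearing in `edges`.
#' @param labels optional data.frame with columns `gene`, `label`.
#' @return an `igraph` object.
#' @export
labeled_network <- function(edges = NULL, nodes = NULL, labels = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    ed <- data.frame(a = character(0), b = character(0),
                     stringsAsFactors = FALSE)
  } else {
    ed <- data.frame(a = as.character(edges[[1L]]),
                     b = as.character(edges[[2L]]),
                     stringsAsFactors = FALSE)
  }
  if (any(ed$a == ed$b)) {
    stop_ratecov("self-loops are not allowed", "ratecov_validation_error")
  }
  ed <- ed[!duplicated(pair_key(ed$a, ed$b)), , drop = FALSE]
  nodes <- radix_sort(unique(c(nodes %||% character(0), ed$a, ed$b)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  if (!is.null(labels)) g <- set_network_labels(g, labels)
  g
}

#' Attach categorical labels to network nodes
#'
#' Nodes with no row in `labels`, or with more than one distinct label,
#' get `NA` (treated as unlabeled / ambiguous).
#'
#' @param net an `igraph` object.
#' @param labels data.frame with columns `gene`, `label`.
#' @return the network with vertex attribute `label` set.
#' @export
set_network_labels <- function(net, labels) {
  stopifnot(is.data.frame(labels), all(c("gene", "label") %in% names(labels)))
  per_gene <- tapply(as.character(labels$label), as.character(labels$gene),
                     function(x) {
                       u <- unique(x)
                       if (length(u) == 1L) u else NA_character_
                     })
  lab <- unname(per_gene[match(igraph::V(net)$name, names(per_gene))])
  igraph::set_vertex_attr(net, "label", value = as.character(lab))
}

#' Co-evolution network from a scan table
#'
#' Nodes are all scanned genes; an edge joins a pair iff its rate
#' covariation was called significant. Isolated nodes are retained.
#'
#' @param table an `erc_table` (see [erc_scan()]).
#' @return an `igraph` object.
#' @export
build_network <- function(table) {
  sig <- table[!is.na(table$significant) & table$significant,
               c("gene_a", "gene_b"), drop = FALSE]
  labeled_network(sig, nodes = unique(c(table$gene_a, table$gene_b)))
}

#' Co-fitness network from pairwise co-fitness scores
#'
#' A pair is an edge iff its co-fitness exceeds 0.75, or exceeds 0.60 and
#' the pair is conserved in other species (both inequalities strict).
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`, `cofitness`
#'   (in `[-1, 1]`), `conserved` (logical).
#' @param hi,lo the two cutoffs.
#' @return an `igraph` object over all genes appearing in `pairs`.
#' @export
cofitness_edges <- function(pairs, hi = 0.75, lo = 0.60) {
  stopifnot(all(c("gene_a", "gene_b", "cofitness", "conserved") %in%
                  names(pairs)))
  cf <- pairs$cofitness
  if (any(!is.finite(cf)) || any(cf < -1) || any(cf > 1)) {
    stop_ratecov("co-fitness values must lie in [-1, 1]",
                 "ratecov_validation_error")
  }
  hit <- cf > hi | (cf > lo & as.logical(pairs$conserved))
  labeled_network(pairs[hit, c("gene_a", "gene_b"), drop = FALSE],
                  nodes = unique(c(pairs$gene_a, pairs$gene_b)))
}

#' Subnetwork of unambiguously labeled nodes
#'
#' Induced subgraph on the nodes carrying exactly one label (vertex
#' attribute `label` not `NA`); an edge survives iff both endpoints do.
#'
#' @param net an `igraph` object with a `label` vertex attribute (set it
#'   with `labels` or beforehand via [set_network_labels()]).
#' @param labels optional label data.frame applied first.
#' @return the induced labeled subgraph.
#' @export
labeled_subnetwork <- function(net, labels = NULL) {
  if (!is.null(labels)) net <- set_network_labels(net, labels)
  lab <- igraph::vertex_attr(net, "label")
  if (is.null(lab)) {
    stop_ratecov("network has no label attribute; supply `labels`",
                 "ratecov_validation_error")
  }
  igraph::induced_subgraph(net, which(!is.na(lab)))
}

.edge_keys <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) return(character(0))
  pair_key(el[, 1L], el[, 2L])
}

.restrict_common <- function(a, b) {
  common <- intersect(igraph::V(a)$name, igraph::V(b)$name)
  list(a = igraph::induced_subgraph(a, match(common, igraph::V(a)$name)),
       b = igraph::induced_subgraph(b, match(common, igraph::V(b)$name)),
       nodes = radix_sort(common))
}

#' Edge Jaccard index between two networks
#'
#' Both networks are first restricted to their common node set; the index
#' is the fraction of shared edges, `|Ea n Eb| / |Ea u Eb|`. An empty edge
#' union is undefined and raises an error.
#'
#' @param a,b `igraph` objects.
#' @return a number in `[0, 1]`.
#' @export
jaccard_edges <- function(a, b) {
  r <- .restrict_common(a, b)
  ea <- .edge_keys(r$a)
  eb <- .edge_keys(r$b)
  u <- union(ea, eb)
  if (length(u) == 0L) {
    stop_ratecov("Jaccard index undefined: no edges on the common node set",
                 "ratecov_undefined_index")
  }
  length(intersect(ea, eb)) / length(u)
}

.perm_result <- function(observed, null_values, n_perm, seed, statistic,
                         method = NULL) {
  p <- (1 + sum(null_values >= observed, na.rm = TRUE)) / (1 + n_perm)
  structure(
    list(observed = observed, null_values = null_values,
         p_empirical = p, n_perm = n_perm, seed = seed,
         statistic = statistic, method = method),
    class = "ratecov_perm_test"
  )
}

#' @export
print.ratecov_perm_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s%s): observed = %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, if (is.null(x$method)) "" else paste0(", ", x$method),
              x$observed, x$p_empirical, x$n_perm, x$seed))
  invisible(x)
}

#' Permutation test for edge overlap between two networks
#'
#' The observed statistic is [jaccard_edges()] on the common node set. Each
#' permutation replaces network `a`'s edge set with a random edge set of
#' the same size over the same nodes and recomputes the index against `b`.
#' The default null draws the edge set uniformly among all equal-size sets
#' (`method = "uniform"`); `method = "degree"` instead rewires `a` with
#' degree-preserving double-edge swaps, for sensitivity analysis.
#'
#' The empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)` and therefore never
#' reaches exactly zero.
#'
#' @param a,b `igraph` objects (`a` is the network being shuffled).
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @param method `"uniform"` or `"degree"`.
#' @return a `ratecov_perm_test`: list with `observed`, `null_values`,
#'   `p_empirical`, `n_perm`, `seed`.
#' @export
jaccard_permutation_test <- function(a, b, n_perm = 1000, seed = 1L,
                                     method = c("uniform", "degree")) {
  method <- match.arg(method)
  if (n_perm < 1L) {
    stop_ratecov("n_perm must be >= 1", "ratecov_parameter_error")
  }
  r <- .restrict_common(a, b)
  observed <- jaccard_edges(r$a, r$b)
  eb <- .edge_keys(r$b)
  nb <- length(eb)
  n <- length(r$nodes)
  m <- igraph::ecount(r$a)
  null_values <- numeric(n_perm)
  with_seed(seed, {
    if (method == "uniform") {
      if (n > 3000L) {
        stop_ratecov("uniform edge shuffling supports up to 3000 common nodes",
                     "ratecov_parameter_error")
      }
      allp <- utils::combn(n, 2L)
      allk <- paste(r$nodes[allp[1L, ]], r$nodes[allp[2L, ]], sep = "|")
      npairs <- ncol(allp)
      for (i in seq_len(n_perm)) {
        ek <- allk[sample.int(npairs, m)]
        inter <- sum(ek %in% eb)
        null_values[i] <- inter / (m + nb - inter)
      }
    } else {
      for (i in seq_len(n_perm)) {
        g <- igraph::rewire(r$a, igraph::keeping_degseq(niter = max(100L, 10L * m)))
        ek <- .edge_keys(g)
        inter <- sum(ek %in% eb)
        null_values[i] <- inter / (length(ek) + nb - inter)
      }
    }
  })
  .perm_result(observed, null_values, n_perm, as.integer(seed),
               statistic = "jaccard", method = method)
}

#' Nominal (categorical) assortativity of a labeled network
#'
#' Mixing-matrix form: with `e[i, j]` the fraction of edge ends joining
#' label classes i and j (each undirected edge counted once in each
#' direction) and `a = rowSums(e)`,
#' `r = (sum(diag(e)) - sum(a^2)) / (1 - sum(a^2))`.
#' `r` is +1 when only same-class nodes are connected and negative down to
#' -1 when only different-class nodes are.
#'
#' @param net an `igraph` object whose edge-incident vertices all carry a
#'   non-`NA` `label` attribute (or supply `labels`).
#' @param labels optional label data.frame applied first.
#' @return a number in `[-1, 1]`.
#' @export
nominal_assortativity <- function(net, labels = NULL) {
  if (!is.null(labels)) net <- set_network_labels(net, labels)
  el <- igraph::as_edgelist(net, names = TRUE)
  if (nrow(el) == 0L) {
    stop_ratecov("assortativity needs at least one edge",
                 "ratecov_validation_error")
  }
  lab <- igraph::vertex_attr(net, "label")
  if (is.null(lab)) {
    stop_ratecov("network has no label attribute; supply `labels`",
                 "ratecov_validation_error")
  }
  names(lab) <- igraph::V(net)$name
  lu <- lab[el[, 1L]]
  lv <- lab[el[, 2L]]
  if (anyNA(lu) || anyNA(lv)) {
    stop_ratecov("unlabeled node incident to an edge; extract the labeled subnetwork first",
                 "ratecov_validation_error")
  }
  .assortativity_from_ends(lu, lv)
}

.assortativity_from_ends <- function(lu, lv) {
  classes <- radix_sort(unique(c(lu, lv)))
  if (length(classes) < 2L) {
    stop_ratecov("assortativity undefined with a single label class",
                 "ratecov_validation_error")
  }
  fu <- factor(lu, levels = classes)
  fv <- factor(lv, levels = classes)
  tab <- table(fu, fv)
  e <- (tab + t(tab)) / (2 * length(lu))
  ai <- rowSums(e)
  saa <- sum(ai * ai)
  (sum(diag(e)) - saa) / (1 - saa)
}

#' Permutation test for label assortativity
#'
#' Labels are shuffled uniformly over the labeled nodes (label multiset
#' preserved) and the assortativity recomputed for each permutation.
#' Empirical p-value as in [jaccard_permutation_test()].
#'
#' @inheritParams jaccard_permutation_test
#' @param net an `igraph` object; only nodes with non-`NA` labels take part
#'   (the labeled subnetwork is extracted internally).
#' @param labels optional label data.frame applied first.
#' @return a `ratecov_perm_test`.
#' @export
assortativity_permutation_test <- function(net, labels = NULL, n_perm = 1000,
                                           seed = 1L) {
  if (!is.null(labels)) net <- set_network_labels(net, labels)
  net <- labeled_subnetwork(net)
  if (n_perm < 1L) {
    stop_ratecov("n_perm must be >= 1", "ratecov_parameter_error")
  }
  observed <- nominal_assortativity(net)
  lab <- igraph::vertex_attr(net, "label")
  el <- igraph::as_edgelist(net, names = FALSE)
  null_values <- numeric(n_perm)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      perm <- sample(lab)
      null_values[i] <- tryCatch(
        .assortativity_from_ends(perm[el[, 1L]], perm[el[, 2L]]),
        error = function(e) NA_real_
      )
    }
  })
  .perm_result(observed, null_values, n_perm, as.integer(seed),
               statistic = "assortativity")
}

#' Write / read a network as a TSV edge list
#'
#' Node universe is preserved via a `#`-prefixed header line listing
#' isolated nodes.
#'
#' @param net an `igraph` object.
#' @param file path.
#' @return `file` (write) or an `igraph` object (read).
#' @export
write_network <- function(net, file) {
  el <- igraph::as_edgelist(net, names = TRUE)
  deg <- igraph::degree(net)
  iso <- radix_sort(igraph::V(net)$name[deg == 0])
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# isolated_nodes=", paste(iso, collapse = ",")), con)
  df <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene_a, df$gene_b, method = "radix"), , drop = FALSE]
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_network
#' @export
read_network <- function(file) {
  hdr <- readLines(file, n = 1L)
  iso <- character(0)
  skip <- 0L
  if (startsWith(hdr, "#")) {
    skip <- 1L
    iso_str <- sub("^# isolated_nodes=", "", hdr)
    if (nzchar(iso_str)) iso <- strsplit(iso_str, ",", fixed = TRUE)[[1L]]
  }
  df <- utils::read.delim(file, skip = skip, stringsAsFactors = FALSE)
  labeled_network(df, nodes = iso)
}
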