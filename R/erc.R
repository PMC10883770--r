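# The rate-covariation statistic.
#
# For a pair of gene trees whose topologies are constrained to a reference
# species tree: prune all trees to the pair's shared taxa, divide each gene
# branch by the corresponding reference branch (correspondence by
# bipartition), drop branches whose normalized length exceeds 5 in either
# gene (paired deletion keeps the vectors aligned), Z-transform each vector
# and compute Pearson's correlation with the exact t-transform p-value.
# A pair is called co-evolving when r > 0 and the Bonferroni-adjusted
# p-value (p times the comparison-family size) is at most alpha.

#' Normalize gene-tree branch lengths against a reference tree
#'
#' Both trees are pruned to their shared taxa; each gene branch is divided
#' by the reference branch with the same bipartition. Branch correspondence
#' requires identical bipartition sets (the gene topology must be
#' constrained to the reference). Zero-length reference branches make the
#' ratio undefined: those branches are dropped with a warning.
#'
#' @param gene_tree,ref_tree `phylo` objects sharing at least 4 taxa.
#' @param warn_zero_ref warn when zero-length reference branches are dropped.
#' @return named numeric vector of normalized branch lengths, one entry per
#'   retained bipartition of the shared taxon set (keys as in
#'   [branch_map()]).
#' @export
normalize_branches <- function(gene_tree, ref_tree, warn_zero_ref = TRUE) {
  shared <- intersect(gene_tree$tip.label, ref_tree$tip.label)
  if (length(shared) < 4L) {
    stop_ratecov("fewer than 4 shared taxa between gene tree and reference",
                 "ratecov_too_few_taxa")
  }
  g <- prune_to_taxa(gene_tree, shared)
  r <- prune_to_taxa(ref_tree, shared)
  bg <- branch_map(g)
  br <- branch_map(r)
  if (!setequal(names(bg), names(br))) {
    bad <- c(setdiff(names(bg), names(br)), setdiff(names(br), names(bg)))
    stop_ratecov(
      paste0("gene tree topology conflicts with the reference; first ",
             "unmatched split: {", bad[1L], "}"),
      "ratecov_incongruence_error"
    )
  }
  br <- br[names(bg)]
  zero <- br == 0
  if (any(zero)) {
    if (warn_zero_ref) {
      warning(sprintf("%d zero-length reference branch(es) dropped from normalization",
                      sum(zero)))
    }
    bg <- bg[!zero]
    br <- br[!zero]
  }
  bg / br
}

#' Remove outlier branches from an aligned pair of branch vectors
#'
#' A bipartition is deleted from both vectors when the normalized length in
#' either vector exceeds `threshold` (default 5). Paired deletion keeps the
#' two vectors aligned for correlation.
#'
#' @param a,b named numeric vectors over the same bipartition set.
#' @param threshold normalized-length cutoff.
#' @return list with elements `a` and `b`, filtered and key-aligned.
#' @export
filter_outlier_branches <- function(a, b, threshold = 5) {
  if (!setequal(names(a), names(b))) {
    stop_ratecov("branch vectors are not indexed by the same bipartition set",
                 "ratecov_validation_error")
  }
  b <- b[names(a)]
  keep <- a <= threshold & b <= threshold
  list(a = a[keep], b = b[keep])
}

#' Z-transform a branch-length vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1.
#'
#' @param v numeric vector with at least 2 entries and non-zero variance.
#' @return the transformed vector (names preserved).
#' @export
z_transform <- function(v) {
  if (length(v) < 2L) {
    stop_ratecov("Z-transform needs at least 2 entries", "ratecov_skip")
  }
  s <- stats::sd(v)
  if (.near_constant(v)) {
    stop_ratecov("zero variance: Z-transform undefined", "ratecov_skip")
  }
  (v - mean(v)) / s
}

# zero variance up to floating-point noise: a vector of identical ratios
# computed as (s*b)/b need not be bit-identical across branches
.near_constant <- function(v) {
  s <- stats::sd(v)
  !is.finite(s) || s <= 1e-12 * max(mean(abs(v)), .Machine$double.xmin)
}

.skip_row <- function(gene_a, gene_b, reason) {
  data.frame(gene_a = gene_a, gene_b = gene_b,
             n_branches = NA_integer_, r = NA_real_, p = NA_real_,
             skip_reason = reason, stringsAsFactors = FALSE)
}

# correlation step on two aligned normalized vectors; returns a result row
.erc_from_vectors <- function(va, vb, gene_a, gene_b, min_overlap,
                              outlier_threshold) {
  common <- intersect(names(va), names(vb))
  if (length(common) < min_overlap) {
    return(.skip_row(gene_a, gene_b, "insufficient_branches"))
  }
  flt <- filter_outlier_branches(va[common], vb[common], outlier_threshold)
  n <- length(flt$a)
  if (n < min_overlap) {
    return(.skip_row(gene_a, gene_b, "insufficient_branches"))
  }
  if (.near_constant(flt$a) || .near_constant(flt$b)) {
    return(.skip_row(gene_a, gene_b, "zero_variance"))
  }
  za <- z_transform(flt$a)
  zb <- z_transform(flt$b)
  ct <- stats::cor.test(za, zb, method = "pearson", alternative = "two.sided")
  data.frame(gene_a = gene_a, gene_b = gene_b,
             n_branches = n, r = unname(ct$estimate), p = ct$p.value,
             skip_reason = NA_character_, stringsAsFactors = FALSE)
}

#' Rate covariation between two gene trees
#'
#' Runs the full per-pair procedure (shared-taxon pruning, reference
#' normalization, paired outlier filtering, Z-transform, Pearson
#' correlation). The result is symmetric in the two genes: internally the
#' pair is put in canonical (C-collation) order, so
#' `erc_pair(a, b, ...)` and `erc_pair(b, a, ...)` are identical.
#'
#' Degenerate inputs (too few shared taxa or aligned branches, zero
#' variance) yield a skipped-pair row carrying the reason rather than an
#' error, so that scans over many pairs keep an exact account of every
#' attempted comparison.
#'
#' @param tree_a,tree_b gene trees (`phylo`).
#' @param ref_tree reference species tree (`phylo`).
#' @param gene_a,gene_b gene identifiers used in the output row.
#' @param min_overlap minimum number of aligned branches after filtering
#'   (default 10, keeping >= 8 degrees of freedom for the t-transform).
#' @param outlier_threshold normalized-length cutoff (default 5).
#' @return one-row data.frame: `gene_a`, `gene_b`, `n_branches`, `r`, `p`,
#'   `skip_reason` (`NA` when the pair was computed).
#' @export
erc_pair <- function(tree_a, tree_b, ref_tree, gene_a = "gene_a",
                     gene_b = "gene_b", min_overlap = 10,
                     outlier_threshold = 5) {
  if (order_pair_swap(gene_a, gene_b)) {
    tmp <- tree_a; tree_a <- tree_b; tree_b <- tmp
    tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp
  }
  shared <- intersect(intersect(tree_a$tip.label, tree_b$tip.label),
                      ref_tree$tip.label)
  if (length(shared) < 4L) {
    return(.skip_row(gene_a, gene_b, "too_few_shared_taxa"))
  }
  pref <- prune_to_taxa(ref_tree, shared)
  va <- normalize_branches(prune_to_taxa(tree_a, shared), pref,
                           warn_zero_ref = FALSE)
  vb <- normalize_branches(prune_to_taxa(tree_b, shared), pref,
                           warn_zero_ref = FALSE)
  .erc_from_vectors(va, vb, gene_a, gene_b, min_overlap, outlier_threshold)
}

#' Scan all gene pairs for rate covariation
#'
#' With one tree set, every unordered pair within the set is compared
#' (`n(n-1)/2` comparisons); with two disjoint sets, every cross pair
#' (`|A| x |B|`). The Bonferroni family size `m` is the number of attempted
#' comparisons, including pairs skipped for insufficient data (skips are
#' recorded, never dropped from `m`). A pair is significant when `r > 0`
#' and `p * m <= alpha`.
#'
#' @param genes_a named list of gene trees.
#' @param genes_b optional second named list (cross scan); must be disjoint
#'   from `genes_a` by gene ID.
#' @param ref_tree reference species tree.
#' @param alpha family-wise significance level (default 0.05).
#' @param min_overlap,outlier_threshold see [erc_pair()].
#' @return an `erc_table`: data.frame with columns `gene_a`, `gene_b`,
#'   `n_branches`, `r`, `p`, `p_bonferroni`, `significant`, `skip_reason`,
#'   with attributes `family_size` and `alpha`.
#' @export
erc_scan <- function(genes_a, genes_b = NULL, ref_tree, alpha = 0.05,
                     min_overlap = 10, outlier_threshold = 5) {
  .check_gene_set <- function(g, what) {
    if (length(g) == 0L) {
      stop_ratecov(paste0(what, " is empty"), "ratecov_validation_error")
    }
    if (is.null(names(g)) || any(names(g) == "")) {
      stop_ratecov(paste0(what, " must be a named list of trees"),
                   "ratecov_validation_error")
    }
    if (anyDuplicated(names(g))) {
      stop_ratecov(paste0("duplicate gene IDs in ", what),
                   "ratecov_validation_error")
    }
  }
  .check_gene_set(genes_a, "genes_a")
  if (!is.null(genes_b)) {
    .check_gene_set(genes_b, "genes_b")
    if (length(intersect(names(genes_a), names(genes_b))) > 0L) {
      stop_ratecov("genes_a and genes_b must be disjoint by gene ID",
                   "ratecov_validation_error")
    }
  }
  pairs <- enumerate_pairs(names(genes_a), names(genes_b))
  all_trees <- c(genes_a, genes_b %||% list())

  # cache: per gene, its taxon set and (lazily) its normalized vector
  # against the reference pruned to that taxon set; valid for any pair in
  # which both genes carry the same taxon set.
  taxa <- lapply(all_trees, function(t) radix_sort(t$tip.label))
  vec_cache <- new.env(parent = emptyenv())
  get_vec <- function(id) {
    if (!is.null(vec_cache[[id]])) return(vec_cache[[id]])
    v <- normalize_branches(all_trees[[id]], ref_tree, warn_zero_ref = FALSE)
    vec_cache[[id]] <- v
    v
  }

  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$gene_a[i]
    gb <- pairs$gene_b[i]
    if (identical(taxa[[ga]], taxa[[gb]]) &&
        all(taxa[[ga]] %in% ref_tree$tip.label)) {
      if (length(taxa[[ga]]) < 4L) {
        rows[[i]] <- .skip_row(ga, gb, "too_few_shared_taxa")
      } else {
        rows[[i]] <- .erc_from_vectors(get_vec(ga), get_vec(gb), ga, gb,
                                       min_overlap, outlier_threshold)
      }
    } else {
      rows[[i]] <- erc_pair(all_trees[[ga]], all_trees[[gb]], ref_tree,
                            gene_a = ga, gene_b = gb,
                            min_overlap = min_overlap,
                            outlier_threshold = outlier_threshold)
    }
  }
  tab <- do.call(rbind, rows)
  finalize_erc_table(tab, alpha = alpha)
}

#' Enumerate the comparison family for a scan
#'
#' Within one ID set: all `n(n-1)/2` unordered pairs; across two disjoint
#' sets: all `|A| x |B|` pairs. Pairs are returned in canonical order
#' (`gene_a` before `gene_b` in C collation), rows sorted.
#'
#' @param ids_a character vector of gene IDs.
#' @param ids_b optional second ID set.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
enumerate_pairs <- function(ids_a, ids_b = NULL) {
  ids_a <- as.character(ids_a)
  if (is.null(ids_b)) {
    ids_a <- radix_sort(ids_a)
    n <- length(ids_a)
    if (n < 2L) {
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        stringsAsFactors = FALSE))
    }
    idx <- utils::combn(n, 2L)
    a <- ids_a[idx[1L, ]]
    b <- ids_a[idx[2L, ]]
  } else {
    ids_b <- as.character(ids_b)
    grid <- expand.grid(a = radix_sort(ids_a), b = radix_sort(ids_b),
                        stringsAsFactors = FALSE)
    a <- grid$a
    b <- grid$b
  }
  swap <- order_pair_swap(a, b)
  out <- data.frame(gene_a = ifelse(swap, b, a), gene_b = ifelse(swap, a, b),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Finalize a scan table: Bonferroni adjustment and significance calls
#'
#' @param tab data.frame with at least `gene_a`, `gene_b`, `r`, `p`.
#' @param alpha family-wise level.
#' @param family_size Bonferroni family size; defaults to `nrow(tab)` (all
#'   attempted comparisons, including skips).
#' @return the table with `p_bonferroni` and `significant` columns, classed
#'   `erc_table` with attributes `family_size` and `alpha`.
#' @export
finalize_erc_table <- function(tab, alpha = 0.05, family_size = nrow(tab)) {
  m <- as.integer(family_size)
  tab$p_bonferroni <- pmin(tab$p * m, 1)
  tab$significant <- !is.na(tab$r) & tab$r > 0 & (tab$p * m) <= alpha
  tab <- tab[, c("gene_a", "gene_b", "n_branches", "r", "p",
                 "p_bonferroni", "significant", "skip_reason")]
  rownames(tab) <- NULL
  attr(tab, "family_size") <- m
  attr(tab, "alpha") <- alpha
  class(tab) <- c("erc_table", "data.frame")
  tab
}

#' @export
print.erc_table <- function(x, ...) {
  m <- attr(x, "family_size")
  nsig <- sum(x$significant, na.rm = TRUE)
  nskip <- sum(!is.na(x$skip_reason))
  cat(sprintf("Rate-covariation scan: %d comparisons (family size m = %d)\n",
              nrow(x), m))
  cat(sprintf("  significant (r > 0, Bonferroni p <= %.3g): %d\n",
              attr(x, "alpha"), nsig))
  cat(sprintf("  skipped (insufficient data): %d\n", nskip))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' Write / read a scan table as TSV
#'
#' The first line is a `#`-prefixed header recording the Bonferroni family
#' size and alpha so the table round-trips.
#'
#' @param tab an `erc_table`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_erc_table <- function(tab, file) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# family_size=%d alpha=%.17g",
                     attr(tab, "family_size"), attr(tab, "alpha")), con)
  utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname write_erc_table
#' @export
read_erc_table <- function(file) {
  hdr <- readLines(file, n = 1L)
  m <- as.integer(sub(".*family_size=([0-9]+).*", "\\1", hdr))
  alpha <- as.numeric(sub(".*alpha=([0-9.eE+-]+).*", "\\1", hdr))
  tab <- utils::read.delim(file, skip = 1L, stringsAsFactors = FALSE)
  tab$skip_reason <- as.character(tab$skip_reason)
  tab$skip_reason[tab$skip_reason %in% c("NA", "")] <- NA_character_
  finalize_erc_table(tab[, c("gene_a", "gene_b", "n_branches", "r", "p",
                             "skip_reason")],
                     alpha = alpha, family_size = m)
}

#' Quartet congruence between two trees
#'
#' Fraction of 4-taxon subsets of the shared taxa whose induced unrooted
#' quartet topology agrees between the two trees, over all `C(n, 4)`
#' subsets. A quartet left unresolved by a polytomy in either tree counts
#' as disagreement. Intended for desk-scale taxon counts (the enumeration
#' is explicit).
#'
#' @param gene_tree,ref_tree `phylo` objects with >= 4 shared taxa.
#' @return a number in `[0, 1]`.
#' @export
quartet_congruence <- function(gene_tree, ref_tree) {
  shared <- intersect(gene_tree$tip.label, ref_tree$tip.label)
  if (length(shared) < 4L) {
    stop_ratecov("fewer than 4 shared taxa", "ratecov_too_few_taxa")
  }
  taxa <- radix_sort(shared)
  t1 <- prune_to_taxa(gene_tree, taxa)
  t2 <- prune_to_taxa(ref_tree, taxa)
  q1 <- .quartet_topologies(t1, taxa)
  q2 <- .quartet_topologies(t2, taxa)
  mean(q1 == q2 & q1 > 0L)
}

# topology code per 4-subset (columns of combn(n, 4)):
# 1 = {1,2}|{3,4}, 2 = {1,3}|{2,4}, 3 = {1,4}|{2,3}, 0 = unresolved
.quartet_topologies <- function(tree, taxa_order) {
  n <- length(taxa_order)
  qs <- utils::combn(n, 4L)
  topo <- integer(ncol(qs))
  mem <- split_memberships(tree, taxa_order)
  for (j in seq_len(ncol(mem))) {
    m <- mem[, j]
    inq <- matrix(m[qs], nrow = 4L)
    res <- colSums(inq) == 2L & topo == 0L
    if (!any(res)) next
    sub <- inq[, res, drop = FALSE]
    topo[res] <- ifelse(sub[1L, ] == sub[2L, ], 1L,
                        ifelse(sub[1L, ] == sub[3L, ], 2L, 3L))
  }
  topo
}

#' Select reference genes by quartet congruence with the species tree
#'
#' Keeps genes whose quartet congruence with the reference tree is strictly
#' greater than `cutoff` (default 0.8).
#'
#' @param gene_trees named list of gene trees.
#' @param ref_tree reference species tree.
#' @param cutoff congruence cutoff (strict inequality).
#' @return character vector of selected gene IDs; quartet scores attached
#'   as the `"scores"` attribute.
#' @export
select_reference_genes <- function(gene_trees, ref_tree, cutoff = 0.8) {
  if (length(gene_trees) == 0L) return(character(0))
  scores <- vapply(gene_trees, quartet_congruence, numeric(1),
                   ref_tree = ref_tree)
  out <- radix_sort(names(scores)[scores > cutoff])
  attr(out, "scores") <- scores
  out
}
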