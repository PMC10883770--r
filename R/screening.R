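# Candidate screening against a reference-gene set, the within- vs
# between-module rank comparison, and pathway enrichment.

#' Candidate screening criteria
#'
#' @param min_ref_links minimum number of reference genes a family must
#'   (i) co-evolve with and (ii) rank highly against (default 5).
#' @param percentile rank-percentile cutoff, strict (default 95: a family
#'   must sit above the 95th percentile of families for that reference
#'   gene, by ascending p AND by descending r).
#' @param alpha family-wise level used for the significance tally.
#' @return a `candidate_criteria` list.
#' @export
candidate_criteria <- function(min_ref_links = 5, percentile = 95,
                               alpha = 0.05) {
  stopifnot(min_ref_links >= 1, percentile > 0, percentile < 100,
            alpha > 0, alpha < 1)
  structure(list(min_ref_links = as.integer(min_ref_links),
                 percentile = percentile, alpha = alpha),
            class = "candidate_criteria")
}

#' Screen gene families for co-evolution with a reference-gene set
#'
#' A family passes when (i) it is significantly co-evolving with at least
#' `min_ref_links` reference genes, and (ii) for at least `min_ref_links`
#' reference genes it lies above the `percentile`-th percentile of all
#' families scanned against that reference gene in BOTH rankings: by
#' ascending p-value and by descending Pearson r (the two conditions must
#' hold for the same reference gene to count). Percentile position uses
#' average ranks for ties; skipped families rank below all computed ones.
#'
#' @param table an `erc_table` containing every family x reference-gene
#'   comparison.
#' @param ref_genes character vector of reference gene IDs.
#' @param criteria a [candidate_criteria()] object.
#' @return character vector of passing family IDs (sorted).
#' @export
candidate_screen <- function(table, ref_genes,
                             criteria = candidate_criteria()) {
  stopifnot(inherits(criteria, "candidate_criteria"))
  ref_genes <- unique(as.character(ref_genes))
  in_tab <- unique(c(table$gene_a, table$gene_b))
  absent <- setdiff(ref_genes, in_tab)
  if (length(absent) > 0L) {
    stop_ratecov(paste0("reference gene(s) absent from scan table: ",
                        paste(absent, collapse = ", ")),
                 "ratecov_validation_error")
  }
  a_is_ref <- table$gene_a %in% ref_genes
  b_is_ref <- table$gene_b %in% ref_genes
  cross <- xor(a_is_ref, b_is_ref)
  sub <- table[cross, , drop = FALSE]
  sub$ref <- ifelse(sub$gene_a %in% ref_genes, sub$gene_a, sub$gene_b)
  sub$family <- ifelse(sub$gene_a %in% ref_genes, sub$gene_b, sub$gene_a)

  families <- radix_sort(unique(sub$family))
  sig_count <- stats::setNames(integer(length(families)), families)
  rank_count <- stats::setNames(integer(length(families)), families)
  for (g in ref_genes) {
    rows <- sub[sub$ref == g, , drop = FALSE]
    if (nrow(rows) == 0L) next
    n_fam <- nrow(rows)
    sig <- !is.na(rows$significant) & rows$significant
    sig_count[rows$family[sig]] <- sig_count[rows$family[sig]] + 1L
    # rank among computed pairs, denominator = all scanned families for g;
    # skipped families therefore sit at the bottom of both rankings
    pct_r <- 100 * rank(rows$r, ties.method = "average",
                        na.last = "keep") / n_fam
    pct_p <- 100 * rank(-rows$p, ties.method = "average",
                        na.last = "keep") / n_fam
    hi <- !is.na(pct_r) & !is.na(pct_p) &
      pct_r > criteria$percentile & pct_p > criteria$percentile
    rank_count[rows$family[hi]] <- rank_count[rows$family[hi]] + 1L
  }
  pass <- sig_count >= criteria$min_ref_links &
    rank_count >= criteria$min_ref_links
  radix_sort(families[pass])
}

#' Within- vs between-module rank comparison of covariation strength
#'
#' Splits reference-gene pairs into those joining genes of the same
#' functional module and those joining different modules, and compares the
#' two sets of Pearson r values with a two-sided Wilcoxon rank-sum
#' (Mann-Whitney U) test.
#'
#' @param table an `erc_table` of reference-gene pairs.
#' @param modules named character vector (gene -> module) or data.frame
#'   with columns `gene`, `module`.
#' @return list with `statistic` (U for the within-module sample),
#'   `p.value`, `n_within`, `n_between`, `median_within`, `median_between`.
#' @export
module_rank_test <- function(table, modules) {
  if (is.data.frame(modules)) {
    modules <- stats::setNames(as.character(modules$module),
                               as.character(modules$gene))
  }
  keep <- table$gene_a %in% names(modules) &
    table$gene_b %in% names(modules) & !is.na(table$r)
  tab <- table[keep, , drop = FALSE]
  within <- modules[tab$gene_a] == modules[tab$gene_b]
  if (sum(within) == 0L || sum(!within) == 0L) {
    stop_ratecov("need at least one within-module and one between-module pair",
                 "ratecov_validation_error")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(tab$r[within], tab$r[!within],
                       alternative = "two.sided")
  )
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n_within = sum(within), n_between = sum(!within),
       median_within = stats::median(tab$r[within]),
       median_between = stats::median(tab$r[!within]))
}

#' Hypergeometric pathway enrichment of a candidate gene set
#'
#' For each pathway, the upper-tail hypergeometric probability of drawing
#' at least `k` pathway members in `n = |candidates|` draws from a universe
#' of `N` genes containing `K` pathway members
#' (`P(X >= k) = phyper(k - 1, K, N - K, n, lower.tail = FALSE)`), with
#' Bonferroni correction over the tested pathways.
#'
#' @param candidates character vector, a subset of `universe`.
#' @param pathways named list (pathway -> gene IDs) or data.frame with
#'   columns `pathway`, `gene`. Pathway memberships are intersected with
#'   the universe.
#' @param universe character vector of all scanned genes.
#' @param alpha family-wise level for the `enriched` call.
#' @return data.frame with columns `pathway`, `k`, `K`, `n`, `N`, `p`,
#'   `p_bonferroni`, `enriched`, sorted by `p`.
#' @export
pathway_enrichment <- function(candidates, pathways, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop_ratecov("empty universe", "ratecov_validation_error")
  }
  candidates <- unique(as.character(candidates))
  if (!all(candidates %in% universe)) {
    stop_ratecov("candidates must be a subset of the universe",
                 "ratecov_validation_error")
  }
  if (is.data.frame(pathways)) {
    pathways <- split(as.character(pathways$gene),
                      as.character(pathways$pathway))
  }
  N <- length(universe)
  n <- length(candidates)
  ids <- radix_sort(names(pathways))
  rows <- lapply(ids, function(pw) {
    members <- intersect(unique(pathways[[pw]]), universe)
    K <- length(members)
    k <- length(intersect(members, candidates))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$enriched <- out$p * m <= alpha
  out <- out[order(out$p, out$pathway, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
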