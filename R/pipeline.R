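# End-to-end orchestration: (simulate ->) rate-covariation scan ->
# candidate screen -> network tests -> pathway enrichment, with one global
# seed split deterministically into per-stage seeds so a rerun with the
# same configuration reproduces identical outputs.

.default_run_config <- function() {
  list(seed = 1L, alpha = 0.05, min_overlap = 10, outlier_threshold = 5,
       quartet_cutoff = 0.8, apply_quartet_filter = FALSE,
       min_ref_links = 5, percentile = 95, n_perm = 1000,
       cofitness_hi = 0.75, cofitness_lo = 0.60)
}

#' Load and normalize a run configuration
#'
#' A configuration is a named list (or a YAML file containing one). Keys:
#' `out_dir` (required); either `simulate` (arguments for [sim_config()],
#' plus optional `noise` for the companion network) or input paths
#' `ref_tree` + `genes` (directory or manifest TSV); optional `ref_genes`
#' (file with one gene ID per line, or character vector), `modules`,
#' `pathways`, `ppi`, `cofitness`, `labels` (TSV paths); thresholds
#' `alpha`, `min_overlap`, `outlier_threshold`, `quartet_cutoff`,
#' `apply_quartet_filter`, `min_ref_links`, `percentile`, `n_perm`,
#' `cofitness_hi`, `cofitness_lo`; and the global `seed`.
#'
#' @param config named list or path to a YAML file.
#' @return the completed configuration list.
#' @export
load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_ratecov(paste0("config file not found: ", config),
                   "ratecov_input_error")
    }
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  utils::modifyList(.default_run_config(), config)
}

#' Validate pipeline inputs before any compute
#'
#' Reports missing files, unparsable trees, trees with fewer than 4 taxa,
#' duplicate gene IDs, and label/module/pathway tables referencing unknown
#' genes. An empty return value means the configuration is clean; entries
#' prefixed `error:` abort [run_full()], `warning:` entries do not.
#'
#' @param config run configuration (list or YAML path).
#' @return character vector of issues (empty when clean).
#' @export
validate_inputs <- function(config) {
  cfg <- load_run_config(config)
  issues <- character(0)
  add <- function(...) issues <<- c(issues, sprintf(...))
  if (is.null(cfg$out_dir)) add("error: out_dir is required")
  simulating <- !is.null(cfg$simulate)
  if (!simulating) {
    if (is.null(cfg$ref_tree) || is.null(cfg$genes)) {
      add("error: either `simulate` or both `ref_tree` and `genes` must be given")
      return(issues)
    }
    if (!file.exists(cfg$ref_tree)) {
      add("error: reference tree not found: %s", cfg$ref_tree)
    } else {
      ref <- tryCatch(parse_newick(paste(readLines(cfg$ref_tree, warn = FALSE),
                                         collapse = "")),
                      error = function(e) conditionMessage(e))
      if (is.character(ref)) {
        add("error: reference tree %s: %s", cfg$ref_tree, ref)
        ref <- NULL
      } else if (length(ref$tip.label) < 4L) {
        add("error: reference tree has fewer than 4 taxa")
      }
    }
    if (!file.exists(cfg$genes) && !dir.exists(cfg$genes)) {
      add("error: gene tree input not found: %s", cfg$genes)
    } else {
      trees <- tryCatch(read_gene_trees(cfg$genes),
                        error = function(e) conditionMessage(e))
      if (is.character(trees)) {
        add("error: gene trees: %s", trees)
      } else {
        small <- names(trees)[vapply(trees, function(t)
          length(t$tip.label) < 4L, logical(1))]
        for (s in small) add("warning: gene tree %s has fewer than 4 taxa", s)
        known <- names(trees)
        for (key in c("labels", "modules")) {
          if (is.null(cfg[[key]])) next
          if (!file.exists(cfg[[key]])) {
            add("error: %s table not found: %s", key, cfg[[key]])
            next
          }
          tab <- utils::read.delim(cfg[[key]], stringsAsFactors = FALSE)
          unk <- setdiff(unique(tab$gene), known)
          if (length(unk) > 0L) {
            add("warning: %s table references unknown gene(s): %s",
                key, paste(utils::head(unk, 5L), collapse = ", "))
          }
        }
      }
    }
    for (key in c("ref_genes", "pathways", "ppi", "cofitness")) {
      if (!is.null(cfg[[key]]) && is.character(cfg[[key]]) &&
          length(cfg[[key]]) == 1L && !file.exists(cfg[[key]])) {
        add("error: %s input not found: %s", key, cfg[[key]])
      }
    }
  }
  issues
}

.read_id_file <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    ids <- readLines(x, warn = FALSE)
    ids[nzchar(ids)]
  } else {
    as.character(x)
  }
}

#' Run the full pipeline
#'
#' Stages: input validation; simulation or loading of the reference tree
#' and gene trees; a single all-pairs rate-covariation scan, finalized
#' separately for the three comparison families the method uses
#' (reference-gene pairs, reference x family cross pairs, all pairs);
#' candidate screening against the reference genes; network comparisons
#' (edge Jaccard vs an interaction and/or co-fitness network, label
#' assortativity) with permutation nulls; pathway enrichment of the
#' candidates. Each stage writes its TSV under `out_dir` and the run
#' report is written as `report.json`. Reruns with the same configuration
#' produce byte-identical outputs.
#'
#' @param config run configuration (list or YAML path), see
#'   [load_run_config()].
#' @return the run report (named list of per-stage counts and p-values),
#'   invisibly.
#' @export
run_full <- function(config) {
  cfg <- load_run_config(config)
  issues <- validate_inputs(cfg)
  if (any(startsWith(issues, "error:"))) {
    stop_ratecov(paste0("invalid configuration:\n  ",
                        paste(issues, collapse = "\n  ")),
                 "ratecov_input_error")
  }
  for (w in issues) message(w)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed)
  truth <- NULL
  companion <- NULL

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    noise <- sim_args$noise %||% 0.05
    sim_args$noise <- NULL
    sim_args$seed <- cfg$seed + 1L
    scfg <- do.call(sim_config, sim_args)
    ref <- simulate_reference_tree(scfg$n_taxa, seed = cfg$seed,
                                   mean_length = scfg$mean_branch_length)
    sim <- simulate_gene_trees(ref, scfg)
    trees <- sim$trees
    truth <- sim$truth
    companion <- simulate_companion_networks(truth, noise = noise,
                                             seed = cfg$seed + 2L)
    sim_dir <- file.path(cfg$out_dir, "sim")
    dir.create(file.path(sim_dir, "genes"), showWarnings = FALSE,
               recursive = TRUE)
    write_newick(ref, file.path(sim_dir, "ref.nwk"))
    for (id in names(trees)) {
      write_newick(trees[[id]], file.path(sim_dir, "genes",
                                          paste0(id, ".nwk")))
    }
    utils::write.table(truth, file.path(sim_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_network(companion$network, file.path(sim_dir, "ppi.tsv"))
    utils::write.table(companion$labels, file.path(sim_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(gene_id = names(trees),
                 path = file.path("genes", paste0(names(trees), ".nwk"))),
      file.path(sim_dir, "manifest.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ref_genes <- if (!is.null(cfg$ref_genes)) {
      .read_id_file(cfg$ref_genes)
    } else if (length(scfg$groups) > 0L) {
      scfg$groups[[1L]]$members
    } else {
      character(0)
    }
    report$simulate <- list(n_taxa = scfg$n_taxa, n_genes = scfg$n_genes,
                            n_planted_pairs = sum(truth$coevolving))
  } else {
    ref <- parse_newick(paste(readLines(cfg$ref_tree, warn = FALSE),
                              collapse = ""))
    trees <- read_gene_trees(cfg$genes)
    ref_genes <- if (!is.null(cfg$ref_genes)) {
      .read_id_file(cfg$ref_genes)
    } else {
      character(0)
    }
  }
  if (length(trees) == 0L) {
    stop_ratecov("no gene trees to analyse", "ratecov_input_error")
  }

  if (length(ref_genes) > 0L && isTRUE(cfg$apply_quartet_filter)) {
    kept <- select_reference_genes(trees[ref_genes], ref,
                                   cutoff = cfg$quartet_cutoff)
    report$quartet_filter <- list(candidates = length(ref_genes),
                                  retained = length(kept))
    ref_genes <- as.character(kept)
  }
  families <- setdiff(names(trees), ref_genes)

  # one all-pairs scan; family-specific significance by re-finalizing the
  # relevant sub-tables with their own Bonferroni family sizes
  scan_all <- erc_scan(trees, ref_tree = ref, alpha = cfg$alpha,
                       min_overlap = cfg$min_overlap,
                       outlier_threshold = cfg$outlier_threshold)
  write_erc_table(scan_all, file.path(cfg$out_dir, "erc_all.tsv"))
  report$erc_all <- .scan_counts(scan_all)

  if (length(ref_genes) >= 2L) {
    in_ref <- scan_all$gene_a %in% ref_genes & scan_all$gene_b %in% ref_genes
    scan_refs <- finalize_erc_table(
      as.data.frame(scan_all)[in_ref, c("gene_a", "gene_b", "n_branches",
                                        "r", "p", "skip_reason")],
      alpha = cfg$alpha)
    write_erc_table(scan_refs, file.path(cfg$out_dir, "erc_refs.tsv"))
    report$erc_refs <- .scan_counts(scan_refs)
    if (!is.null(cfg$modules)) {
      modules <- utils::read.delim(cfg$modules, stringsAsFactors = FALSE)
      mrt <- module_rank_test(scan_refs, modules)
      report$module_rank_test <- mrt
    }
  }

  candidates <- character(0)
  if (length(ref_genes) >= 1L && length(families) >= 1L) {
    is_cross <- xor(scan_all$gene_a %in% ref_genes,
                    scan_all$gene_b %in% ref_genes)
    scan_cross <- finalize_erc_table(
      as.data.frame(scan_all)[is_cross, c("gene_a", "gene_b", "n_branches",
                                          "r", "p", "skip_reason")],
      alpha = cfg$alpha)
    write_erc_table(scan_cross, file.path(cfg$out_dir, "erc_cross.tsv"))
    report$erc_cross <- .scan_counts(scan_cross)
    crit <- candidate_criteria(min_ref_links = cfg$min_ref_links,
                               percentile = cfg$percentile,
                               alpha = cfg$alpha)
    candidates <- candidate_screen(scan_cross, ref_genes, crit)
    writeLines(candidates, file.path(cfg$out_dir, "candidates.txt"))
    report$screen <- list(n_candidates = length(candidates))
  }

  coevo <- build_network(scan_all)
  write_network(coevo, file.path(cfg$out_dir, "coevolution_network.tsv"))

  other_nets <- list()
  if (!is.null(companion)) {
    other_nets$ppi <- companion$network
  } else if (!is.null(cfg$ppi)) {
    other_nets$ppi <- read_network(cfg$ppi)
  }
  if (!is.null(cfg$cofitness)) {
    cf <- utils::read.delim(cfg$cofitness, stringsAsFactors = FALSE)
    other_nets$cofitness <- cofitness_edges(cf, hi = cfg$cofitness_hi,
                                            lo = cfg$cofitness_lo)
  }
  pseed <- cfg$seed + 3L
  for (nm in names(other_nets)) {
    jt <- tryCatch(
      jaccard_permutation_test(coevo, other_nets[[nm]], n_perm = cfg$n_perm,
                               seed = pseed),
      error = function(e) NULL
    )
    pseed <- pseed + 1L
    if (!is.null(jt)) {
      report[[paste0("jaccard_", nm)]] <-
        list(observed = jt$observed, p_empirical = jt$p_empirical)
    }
  }
  label_tab <- if (!is.null(companion)) {
    companion$labels
  } else if (!is.null(cfg$labels)) {
    utils::read.delim(cfg$labels, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  if (!is.null(label_tab)) {
    at <- tryCatch(
      assortativity_permutation_test(coevo, labels = label_tab,
                                     n_perm = cfg$n_perm,
                                     seed = cfg$seed + 10L),
      error = function(e) NULL
    )
    if (!is.null(at)) {
      report$assortativity <- list(observed = at$observed,
                                   p_empirical = at$p_empirical)
    }
  }

  if (!is.null(cfg$pathways) && length(candidates) > 0L) {
    pw <- utils::read.delim(cfg$pathways, stringsAsFactors = FALSE)
    enr <- pathway_enrichment(candidates, pw, universe = families,
                              alpha = cfg$alpha)
    utils::write.table(enr, file.path(cfg$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$enrichment <- list(n_tested = nrow(enr),
                              n_enriched = sum(enr$enriched))
  }

  if (!is.null(truth)) {
    sig <- scan_all[!is.na(scan_all$significant) & scan_all$significant, ]
    sig_keys <- pair_key(sig$gene_a, sig$gene_b)
    planted_keys <- pair_key(truth$gene_a[truth$coevolving],
                             truth$gene_b[truth$coevolving])
    report$recovery <- list(
      planted = length(planted_keys),
      detected = sum(planted_keys %in% sig_keys))
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.scan_counts <- function(tab) {
  list(m = attr(tab, "family_size"),
       significant = sum(tab$significant, na.rm = TRUE),
       skipped = sum(!is.na(tab$skip_reason)),
       non_significant = sum(!tab$significant & is.na(tab$skip_reason),
                             na.rm = TRUE))
}
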