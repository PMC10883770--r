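# Tree input/output and bipartition-indexed branch access.
#
# Trees are ape "phylo" objects throughout. Branch identity across trees is
# by bipartition (split) of the current taxon set, canonicalized by the block
# that does NOT contain the pivot taxon (the C-collation-smallest leaf label),
# with the block's labels sorted and joined by "|". All rate computation uses
# the unrooted view of a tree: on rooted input the two root-adjacent edges
# describe the same bipartition and are merged with their lengths summed.

#' Parse a Newick string into a phylogenetic tree
#'
#' Strict reader for the trees used in rate-covariation analysis: every
#' non-root edge must carry a finite, non-negative branch length and leaf
#' labels must be unique. Internal node labels are ignored.
#'
#' @param text a single Newick string (terminating `;` required).
#' @return an object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  .check_newick_syntax(text)
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop_ratecov("malformed Newick string: parser failed", "ratecov_parse_error")
  }
  validate_tree(tr)
  tr
}

# cheap positional syntax check so parse errors can name an offset
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop_ratecov(
          sprintf("malformed Newick string: unbalanced ')' at position %d", i),
          "ratecov_parse_error"
        )
      }
    }
  }
  if (depth != 0L) {
    stop_ratecov(
      sprintf("malformed Newick string: %d unclosed '(' at end of input", depth),
      "ratecov_parse_error"
    )
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop_ratecov(
      sprintf("malformed Newick string: missing ';' terminator (position %d)",
              nchar(text)),
      "ratecov_parse_error"
    )
  }
  invisible(TRUE)
}

#' Validate a tree for rate computation
#'
#' Checks leaf-label uniqueness and that all branch lengths are finite and
#' non-negative. Called by [parse_newick()]; exported for use on trees built
#' in code.
#'
#' @param tree a `phylo` object.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    stop_ratecov(
      paste0("duplicate leaf label(s): ", paste(dup, collapse = ", ")),
      "ratecov_validation_error"
    )
  }
  if (is.null(tree$edge.length)) {
    stop_ratecov("tree has no branch lengths", "ratecov_validation_error")
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop_ratecov("non-finite branch length(s)", "ratecov_validation_error")
  }
  if (any(tree$edge.length < 0)) {
    stop_ratecov("negative branch length(s)", "ratecov_validation_error")
  }
  invisible(tree)
}

#' Write a tree as a Newick string
#'
#' Internal node labels are dropped; branch lengths are written as decimal
#' floats.
#'
#' @param tree a `phylo` object.
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tree$node.label <- NULL
  txt <- ape::write.tree(tree)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a directory (or manifest) of gene trees
#'
#' Accepts either a directory containing `*.nwk` / `*.tree` / `*.newick`
#' files (gene IDs taken from file names without extension) or a manifest
#' TSV with columns `gene_id` and `path` (paths relative to the manifest's
#' directory or absolute).
#'
#' @param path directory or manifest TSV file.
#' @return a named list of `phylo` objects.
#' @export
read_gene_trees <- function(path) {
  if (dir.exists(path)) {
    files <- radix_sort(list.files(path, pattern = "\\.(nwk|tree|newick)$",
                                   full.names = TRUE))
    if (length(files) == 0L) {
      stop_ratecov(paste0("no tree files found in ", path),
                   "ratecov_input_error")
    }
    ids <- sub("\\.(nwk|tree|newick)$", "", basename(files))
  } else if (file.exists(path)) {
    man <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "path") %in% names(man))) {
      stop_ratecov("manifest must have columns gene_id and path",
                   "ratecov_input_error")
    }
    ids <- man$gene_id
    files <- ifelse(grepl("^/", man$path), man$path,
                    file.path(dirname(path), man$path))
  } else {
    stop_ratecov(paste0("no such file or directory: ", path),
                 "ratecov_input_error")
  }
  if (anyDuplicated(ids)) {
    stop_ratecov("duplicate gene IDs in tree input", "ratecov_validation_error")
  }
  trees <- vector("list", length(ids))
  names(trees) <- ids
  for (i in seq_along(files)) {
    txt <- paste(readLines(files[i], warn = FALSE), collapse = "")
    trees[[i]] <- tryCatch(parse_newick(txt), error = function(e) {
      stop_ratecov(paste0("while reading ", files[i], ": ", conditionMessage(e)),
                   "ratecov_parse_error")
    })
  }
  trees
}

#' Prune a tree to a subset of taxa
#'
#' Degree-2 nodes created by pruning are suppressed and their incident
#' branch lengths summed, so the patristic distance between any two retained
#' taxa is unchanged.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of leaf labels to keep (at least 4).
#' @return the pruned `phylo` object.
#' @export
prune_to_taxa <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"))
  taxa <- unique(taxa)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing) > 0L) {
    stop_ratecov(
      paste0("taxa not in tree: ", paste(missing, collapse = ", ")),
      "ratecov_validation_error"
    )
  }
  if (length(taxa) < 4L) {
    stop_ratecov("fewer than 4 taxa requested; rate and quartet computations need >= 4",
                 "ratecov_too_few_taxa")
  }
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Map branches to canonical bipartition keys
#'
#' Returns one branch length per edge of the unrooted view of the tree; on
#' rooted input the two root-adjacent edges induce the same bipartition and
#' are merged with lengths summed. Keys are the canonical split
#' representation: the block not containing the pivot taxon
#' (C-collation-smallest leaf label), sorted and joined by `"|"`.
#'
#' @param tree a `phylo` object with at least 3 leaves.
#' @return a named numeric vector, names = bipartition keys, sorted by key.
#' @export
branch_map <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3L) {
    stop_ratecov("branch_map needs at least 3 leaves (unrooted view)",
                 "ratecov_too_few_taxa")
  }
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  utree <- ape::reorder.phylo(utree, "postorder")
  ntip <- length(utree$tip.label)
  tipsets <- vector("list", ntip + utree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  ed <- utree$edge
  for (k in seq_len(nrow(ed))) {
    par <- ed[k, 1L]
    chl <- ed[k, 2L]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[chl]])
  }
  labs <- utree$tip.label
  pivot <- radix_sort(labs)[1L]
  keys <- character(nrow(ed))
  for (k in seq_len(nrow(ed))) {
    side <- labs[tipsets[[ed[k, 2L]]]]
    if (pivot %in% side) side <- setdiff(labs, side)
    keys[k] <- paste(radix_sort(side), collapse = "|")
  }
  len <- utree$edge.length
  if (anyDuplicated(keys)) {
    # degree-2 remnants: merge identical splits by summing
    len <- tapply(len, keys, sum)
    out <- as.numeric(len)
    names(out) <- names(len)
  } else {
    out <- stats::setNames(len, keys)
  }
  out[radix_sort(names(out))]
}

# membership matrix of internal splits over a fixed taxon ordering;
# rows = taxa (in taxa_order), cols = internal bipartitions
split_memberships <- function(tree, taxa_order) {
  utree <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  utree <- ape::reorder.phylo(utree, "postorder")
  ntip <- length(utree$tip.label)
  tipsets <- vector("list", ntip + utree$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- i
  ed <- utree$edge
  cols <- list()
  for (k in seq_len(nrow(ed))) {
    par <- ed[k, 1L]
    chl <- ed[k, 2L]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[chl]])
    sz <- length(tipsets[[chl]])
    if (sz >= 2L && sz <= ntip - 2L) {
      memb <- logical(ntip)
      memb[match(utree$tip.label[tipsets[[chl]]], taxa_order)] <- TRUE
      cols[[length(cols) + 1L]] <- memb
    }
  }
  if (length(cols) == 0L) {
    matrix(logical(0), nrow = length(taxa_order), ncol = 0L)
  } else {
    do.call(cbind, cols)
  }
}

#' Total branch length of a tree
#' @param tree a `phylo` object.
#' @return sum of all branch lengths.
#' @export
total_tree_length <- function(tree) sum(tree$edge.length)
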