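#' Read a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()].  Accepts the usual
#' Newick dialect (branch lengths after `:`, `[...]` comments stripped,
#' polytomies preserved) and adds the checks the rest of the package relies
#' on: balanced parentheses (reported with character position) and unique
#' leaf labels.
#'
#' @param text a Newick string, or `NULL` to read from `file`.
#' @param file path to a Newick file.
#' @return an [ape::phylo] tree.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- gsub("\\[[^]]*\\]", "", text)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("unbalanced ')' at character ", i, " of Newick string")
      }
    }
  }
  if (depth != 0L) {
    stop("unbalanced '(' in Newick string: ", depth,
         " parenthesis/es left open at end of input")
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  dup <- unique(tr$tip.label[duplicated(tr$tip.label)])
  if (length(dup) > 0) {
    stop("duplicate leaf label(s): ", paste(dup, collapse = ", "))
  }
  tr
}

#' Write a tree as Newick
#'
#' @param tree an [ape::phylo] tree.
#' @param file optional output path; if `NULL` the Newick string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# stop unless every edge has a defined, non-negative length
check_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; simulation and likelihood need them")
  }
  bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)
  if (length(bad) > 0) {
    stop("edge ", bad[1], " (towards node ", tree$edge[bad[1], 2],
         ") has a missing or negative branch length")
  }
  invisible(tree)
}

#' Test monophyly on an unrooted tree
#'
#' A leaf set is monophyletic, in the unrooted sense used for gene-tree
#' curation, when it forms one side of some bipartition of the tree: either
#' the set or its complement is a clade under the stored rooting.  This is
#' the natural reading for unrooted gene trees, where "the paralogues form a
#' monophyletic group" cannot depend on an arbitrary root placement.
#'
#' @param tree an [ape::phylo] tree.
#' @param leaves character vector of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' is_monophyletic(tr, c("A", "B"))
#' is_monophyletic(tr, c("A", "C"))
#' @export
is_monophyletic <- function(tree, leaves) {
  leaves <- unique(as.character(leaves))
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0) {
    stop("label(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  comp <- setdiff(tree$tip.label, leaves)
  if (length(comp) == 0L || length(leaves) <= 1L) return(TRUE)
  ape::is.monophyletic(tree, leaves) || ape::is.monophyletic(tree, comp)
}

#' Prune leaves from a tree
#'
#' Removes the named leaves and suppresses the resulting degree-2 internal
#' nodes, summing branch lengths across suppressed nodes (so total path
#' lengths between remaining leaves are preserved).
#'
#' @param tree an [ape::phylo] tree.
#' @param leaves leaf labels to remove (may be empty).
#' @return the pruned [ape::phylo] tree.
#' @export
prune_leaves <- function(tree, leaves) {
  leaves <- unique(as.character(leaves))
  if (length(leaves) == 0L) return(tree)
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown) > 0) {
    stop("label(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(tree$tip.label) - length(leaves) < 2L) {
    stop("pruning would leave fewer than 2 leaves")
  }
  ape::drop.tip(tree, leaves, collapse.singles = TRUE)
}

# terminal branch length of each leaf, named by label
terminal_branch_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  idx <- match(seq_len(ntip), tree$edge[, 2])
  stats::setNames(tree$edge.length[idx], tree$tip.label)
}
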