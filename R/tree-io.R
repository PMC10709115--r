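#' Parse a Newick string into a phylogeny
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is an
#' `ape::phylo` object, the container used throughout the package. Branch
#' lengths are required on every non-root edge; internal node labels are
#' ignored. Tip labels must be unique and the tree must have at least two tips.
#'
#' @param text A single Newick string (terminating `;` required).
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tree_height(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  check_balanced_parens(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("failed to parse Newick: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("failed to parse Newick: not a valid tree string")
  validate_phylogeny(tree)
  tree
}

# Pre-scan for unbalanced parentheses so the parse error can name a character
# offset (ape's own message does not).
check_balanced_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed Newick: unmatched ')' at character %d", i))
      }
    }
  }
  if (depth > 0L) {
    abort(sprintf(
      "malformed Newick: %d unclosed '(' at character %d (end of string)",
      depth, length(chars)
    ))
  }
  invisible(TRUE)
}

#' Validate a phylogeny
#'
#' Checks the structural invariants assumed by every downstream computation:
#' at least two uniquely labelled tips, branch lengths present on all edges,
#' and all lengths non-negative.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  n_tip <- length(tree$tip.label)
  if (n_tip < 2L) abort("tree must have at least 2 tips")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || length(tree$edge.length) != nrow(tree$edge)) {
    abort("branch lengths are required on all non-root edges")
  }
  if (anyNA(tree$edge.length)) abort("branch lengths contain NA")
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  invisible(tree)
}

#' Write a phylogeny as a Newick string or file
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 15L) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Depth of every node from the root
#'
#' @param tree A `phylo` object.
#' @return Numeric vector over all nodes (tips first, ape node numbering) of
#'   the summed branch length from the root.
#' @export
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Tree height (maximum root-to-tip depth)
#'
#' @param tree A `phylo` object.
#' @return A single number in the tree's time units.
#' @export
tree_height <- function(tree) {
  max(node_depths(tree)[seq_along(tree$tip.label)])
}

#' Prune a phylogeny to a set of tips
#'
#' Returns the induced subtree on `keep`: internal nodes left with a single
#' child are suppressed and their branch lengths summed, so root-to-tip
#' distances (and all patristic distances) among kept tips are unchanged.
#' Species lacking data for a gene are excised this way before model fitting.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `phylo` object.
#' @export
prune_tips <- function(tree, keep) {
  validate_phylogeny(tree)
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0L) {
    abort(paste0("unknown tip labels: ", paste(unknown, collapse = ", ")))
  }
  if (length(keep) < 2L) abort("`keep` must contain at least 2 tip labels")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Test whether a tree is ultrametric
#'
#' A tree is treated as ultrametric when the spread of root-to-tip depths does
#' not exceed `rel_tol` times the tree height. Chronograms carry numeric
#' jitter, hence the relative tolerance; a zero-height tree is ultrametric by
#' convention.
#'
#' @param tree A `phylo` object.
#' @param rel_tol Relative tolerance on the depth spread (default `1e-6`).
#' @return `TRUE` or `FALSE`.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  validate_phylogeny(tree)
  depths <- node_depths(tree)[seq_along(tree$tip.label)]
  h <- max(depths)
  if (h == 0) return(TRUE)
  (h - min(depths)) <= rel_tol * h
}

#' Resolve polytomies into zero-length bifurcations
#'
#' Multifurcations are broken into arbitrary bifurcations joined by zero-length
#' edges, leaving all tip depths (and the phylogenetic variance-covariance
#' matrix) unchanged. The order of resolution is randomised but deterministic
#' given `seed`. Contrasts require a strictly bifurcating tree.
#'
#' @param tree A `phylo` object.
#' @param seed Integer seed controlling the (arbitrary) resolution order.
#' @return A bifurcating `phylo` object.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  validate_phylogeny(tree)
  if (ape::is.binary(tree)) return(tree)
  out <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  # multi2di inserts NA lengths on some ape versions; new edges have length 0
  out$edge.length[is.na(out$edge.length)] <- 0
  out
}
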