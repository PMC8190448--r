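#' Read and validate a dated phylogeny
#'
#' Reads a Newick tree and validates it for downstream community-phylogenetic
#' and macroevolutionary analyses: single root, unique tip labels, branch
#' lengths present and non-negative.  Polytomies are permitted.
#'
#' @param path Path to a Newick file with branch lengths.
#' @return An [ape::phylo] object with two extra attributes: `age` (maximum
#'   root-to-tip distance, in the tree's time units) and `ultrametric`
#'   (logical; `TRUE` iff all root-to-tip distances are equal within a 1e-6
#'   relative tolerance).
#' @seealso [prune_to_samples()], [write_phylogeny()]
#' @export
read_phylogeny <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick: ", conditionMessage(e),
                                          call. = FALSE))
  if (is.null(tr)) stop("malformed Newick in '", path, "'", call. = FALSE)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1L]]
  validate_phylogeny(tr)
}

#' @rdname read_phylogeny
#' @param tree A `phylo` object to validate in place.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0", call. = FALSE)
  attr(tree, "age") <- tree_age(tree)
  attr(tree, "ultrametric") <- is_ultrametric(tree)
  tree
}

#' @rdname read_phylogeny
#' @export
tree_age <- function(tree) {
  max(.node_depths(tree)[seq_len(ape::Ntip(tree))])
}

#' @rdname read_phylogeny
#' @param tol Relative tolerance on root-to-tip distances.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- .node_depths(tree)[seq_len(ape::Ntip(tree))]
  if (max(d) == 0) return(TRUE)
  (max(d) - min(d)) / max(d) <= tol
}

#' @rdname read_phylogeny
#' @param digits Number of digits used for branch lengths on output.
#' @export
write_phylogeny <- function(tree, path, digits = 15) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Prune a phylogeny to the surveyed species
#'
#' Drops all tips not in `species`, collapsing the resulting degree-2 internal
#' nodes and summing their branch lengths, so that root-to-tip distances and
#' patristic distances among retained tips are unchanged.
#'
#' @param tree A validated `phylo` object.
#' @param species Character vector of tip labels to retain (a subset of the
#'   tree's tips).
#' @return The pruned, re-validated tree.
#' @export
prune_to_samples <- function(tree, species) {
  species <- unique(as.character(species))
  missing <- setdiff(species, tree$tip.label)
  if (length(missing))
    stop("species not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  if (length(species) < 2)
    stop("need at least two species to keep a tree", call. = FALSE)
  validate_phylogeny(ape::keep.tip(tree, species))
}

#' Patristic distance matrix
#'
#' All-pairs sum of branch lengths along tip-to-tip paths.
#'
#' @param tree A `phylo` object.
#' @return A symmetric species-by-species matrix in the tree's time units.
#' @export
patristic_distances <- function(tree) {
  stats::cophenetic(tree)
}
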