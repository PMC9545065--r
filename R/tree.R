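#' Parse a Newick string into a validated phylogeny
#'
#' Wraps [ape::read.tree()] and validates the result for downstream
#' comparative analyses: the tree must be rooted, carry branch lengths on
#' every edge (interpreted as time in million years, mya), and have unique
#' tip labels. Zero-length internal branches are collapsed into polytomies
#' to avoid singular phylogenetic covariance matrices; zero-length terminal
#' branches are kept.
#'
#' @param text A Newick string (with trailing semicolon).
#' @return An object of class `"phylo"`.
#' @seealso [write_newick()], [phylo_covariance()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("malformed Newick string: ", substr(text, 1L, 60L))
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param file Path to a Newick file.
#' @export
read_newick <- function(file) {
  tree <- ape::read.tree(file)
  if (is.null(tree)) stop("could not parse Newick file: ", file)
  validate_tree(tree)
}

#' @rdname parse_newick
#' @param tree A `"phylo"` object.
#' @param file Output path, or `""` to return the string.
#' @param digits Significant digits for branch lengths (default 17, so a
#'   write/parse round trip preserves the covariance to machine precision).
#' @export
write_newick <- function(tree, file = "", digits = 17) {
  ape::write.tree(tree, file = file, digits = digits)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree A `"phylo"` object.
#' @return The tree, with zero-length internal branches collapsed.
#' @keywords internal
validate_tree <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; time-calibrated branch lengths are required")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree has missing or negative branch lengths")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  if (!ape::is.rooted(tree))
    stop("tree must be rooted")
  # collapse zero-length *internal* branches into polytomies
  internal0 <- tree$edge[, 2] > ape::Ntip(tree) & tree$edge.length <= 0
  if (any(internal0)) tree <- ape::di2multi(tree, tol = 0)
  tree
}

#' Phylogenetic covariance matrix
#'
#' Shared evolutionary time between species pairs: entry (i, j) is the summed
#' branch length from the root to the most recent common ancestor of tips i
#' and j; the diagonal is the root-to-tip distance. Computed with
#' [ape::vcv.phylo()]. Units follow the branch lengths (mya).
#'
#' @param tree A rooted `"phylo"` object with branch lengths.
#' @return A symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  ape::vcv.phylo(tree)
}

#' Prune a phylogeny to a set of species
#'
#' Drops all tips not in `keep` and suppresses the resulting unifurcations,
#' summing branch lengths so root-to-tip distances of retained tips are
#' preserved. The phylogenetic covariance of the pruned tree equals the
#' corresponding submatrix of the original covariance.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (at least 2).
#' @return The pruned `"phylo"` object.
#' @export
prune_tree <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop("species not in tree: ", paste(unknown, collapse = ", "))
  if (length(keep) < 2L) stop("need at least 2 species to keep")
  if (length(keep) == ape::Ntip(tree)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip distances must agree within `tol` times the maximum tip
#' depth. Contemporaneous tips are assumed by the stationary
#' Ornstein-Uhlenbeck covariance used in trait-model fitting.
#'
#' @param tree A rooted `"phylo"` object.
#' @param tol Relative tolerance (default 1e-8).
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-8) {
  d <- tip_depths(tree)
  (max(d) - min(d)) <= tol * max(d, .Machine$double.eps)
}

#' Root-to-tip distances
#' @param tree A `"phylo"` object.
#' @return Named numeric vector of tip depths (mya).
#' @export
tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  names(d) <- tree$tip.label
  d
}

#' Tree height (maximum root-to-tip distance)
#' @param tree A `"phylo"` object.
#' @return Numeric scalar (mya).
#' @export
tree_height <- function(tree) max(tip_depths(tree))
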