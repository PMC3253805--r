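#' Read a dated tree from newick text or file
#'
#' Parses a newick tree with branch lengths in Ma. Ultrametricity is *not*
#' enforced at read time; it is checked by [extract_ages()], so that
#' non-ultrametric trees can still be inspected.
#'
#' @param x a newick string, or the path of a file containing one.
#' @return an [ape::phylo] object with branch lengths.
#' @examples
#' tr <- read_chronogram("((A:1,B:1):1,C:2);")
#' @seealso [extract_ages()], [write_chronogram()]
#' @export
read_chronogram <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  tr <- withCallingHandlers(
    if (file.exists(x) && !grepl(";", x, fixed = TRUE)) {
      ape::read.tree(file = x)
    } else {
      ape::read.tree(text = x)
    },
    warning = function(w) stop("could not parse newick input: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("could not parse newick input")
  if (is.null(tr$edge.length)) {
    stop("newick input has no branch lengths; a chronogram requires them")
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed in a chronogram")
  }
  tr
}

#' Write a chronogram to newick
#'
#' @param tree an `phylo` object.
#' @param path output file; if `NULL` the newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the path (invisibly) or the newick string.
#' @export
write_chronogram <- function(tree, path = NULL, digits = 12) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

## depth of every node (edge-length distance from the root), ape numbering
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Check a tree for ultrametricity
#'
#' All root-to-tip path lengths must agree within `tol` (relative to tree
#' height). Returns the tip-depth spread; errors if the spread exceeds
#' tolerance, naming the most discordant pair of tips.
#'
#' @param tree a `phylo` object with branch lengths.
#' @param tol relative tolerance (fraction of tree height).
#' @return invisibly, the maximum relative tip-depth spread.
#' @export
assert_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)
  ntip <- length(tree$tip.label)
  tipd <- d[seq_len(ntip)]
  height <- max(d)
  if (height <= 0) stop("tree has zero height")
  spread <- (max(tipd) - min(tipd)) / height
  if (spread > tol) {
    stop(sprintf(
      "tree is not ultrametric (relative tip-depth spread %.3g > tol %.3g); worst pair: '%s' (depth %.6g) vs '%s' (depth %.6g)",
      spread, tol,
      tree$tip.label[which.max(tipd)], max(tipd),
      tree$tip.label[which.min(tipd)], min(tipd)
    ))
  }
  invisible(spread)
}

#' Extract branching-event ages from an ultrametric tree
#'
#' Every internal node of a chronogram is one branching event; its age is its
#' distance in Ma from the present (the tips). The root is included; a
#' polytomy contributes a single event, not one per implied split. Ages are
#' returned as a node-age table sorted by descending age, with the interval
#' columns equal to the mean (point estimates carry no dating uncertainty).
#'
#' @param tree a `phylo` object; must be ultrametric within `tol`.
#' @param tol relative ultrametricity tolerance (fraction of tree height).
#' @return a `node_ages` data frame (columns `label`, `mean`, `low`, `high`).
#' @examples
#' extract_ages(read_chronogram("((A:1,B:1):1,C:2);"))$mean  # 2, 1
#' @export
extract_ages <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  assert_ultrametric(tree, tol = tol)
  d <- node_depths(tree)
  ntip <- length(tree$tip.label)
  height <- max(d[seq_len(ntip)])
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  age <- height - d[internal]
  labels <- if (!is.null(tree$node.label) && length(tree$node.label) == tree$Nnode) {
    tree$node.label
  } else {
    paste0("n", internal)
  }
  empty <- !nzchar(labels)
  labels[empty] <- paste0("n", internal[empty])
  ord <- order(age, decreasing = TRUE)
  node_ages(label = labels[ord], mean = age[ord])
}
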