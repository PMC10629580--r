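#' Time-calibrated phylogeny with sampling fraction
#'
#' A `time_tree` is an [ape::read.tree()]-style `phylo` object that has been
#' validated as a rooted, binary, ultrametric tree with positive branch
#' lengths, and that carries the sampling fraction `f` (the probability that
#' an extant species appears among the tips). Ages are measured in million
#' years (My) before present, with tips at age 0 and the crown node at
#' `crown_age`.
#'
#' @param phy a `phylo` object (rooted, binary, with branch lengths).
#' @param sampling_fraction global sampling fraction `f` in (0, 1].
#' @param tol relative ultrametricity tolerance: the maximum spread of
#'   root-to-tip path lengths, as a fraction of the crown age. Trees beyond
#'   the tolerance are rejected rather than silently stretched, because
#'   silent repair biases the branching times entering the likelihood.
#'
#' @return an object of class `c("time_tree", "phylo")` with attributes
#'   `sampling_fraction` and `crown_age`.
#' @export
time_tree <- function(phy, sampling_fraction = 1, tol = 1e-6) {
  if (!inherits(phy, "phylo")) stop("`phy` must be a 'phylo' object")
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  n <- length(phy$tip.label)
  if (n < 2L) stop("tree must have at least 2 tips")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  if (!is.numeric(sampling_fraction) || length(sampling_fraction) != 1L ||
      is.na(sampling_fraction) || sampling_fraction <= 0 || sampling_fraction > 1)
    stop("`sampling_fraction` must be a single value in (0, 1]")
  if (phy$Nnode != n - 1L) {
    deg <- tabulate(phy$edge[, 1L], nbins = n + phy$Nnode)
    poly <- which(deg > 2L)
    stop("tree is not binary: polytomy at node(s) ", paste(poly, collapse = ", "))
  }
  if (!ape::is.rooted(phy)) stop("tree must be rooted")
  if (any(is.na(phy$edge.length))) stop("missing branch length")
  if (any(phy$edge.length <= 0)) stop("all branch lengths must be > 0")
  depths <- node_depths(phy)
  tip_depths <- depths[seq_len(n)]
  crown <- max(tip_depths)
  if (diff(range(tip_depths)) > tol * crown)
    stop(sprintf("tree is not ultrametric: root-to-tip spread %.3g exceeds %.3g x crown age",
                 diff(range(tip_depths)), tol))
  structure(phy,
            class = c("time_tree", "phylo"),
            sampling_fraction = sampling_fraction,
            crown_age = crown)
}

# Root-to-tip path length of every node (tips first, ape numbering).
node_depths <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  depth <- numeric(nn)
  root <- n + 1L
  # edges in ape cladewise order: parents appear before their children
  ord <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    depth[ch] <- depth[p] + ord$edge.length[i]
  }
  depth
}

#' Read a Newick tree file as a validated time tree
#'
#' @param file path to a file containing a single Newick tree.
#' @param text alternatively, a Newick string.
#' @inheritParams time_tree
#' @return a [time_tree()].
#' @export
read_time_tree <- function(file = NULL, text = NULL, sampling_fraction = 1,
                           tol = 1e-6) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse Newick input")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree")
    phy <- phy[[1L]]
  }
  time_tree(phy, sampling_fraction = sampling_fraction, tol = tol)
}

#' Write a time tree to Newick
#'
#' @param tree a [time_tree()] (any `phylo` is accepted).
#' @param file output path; if `NULL` the Newick string is returned.
#' @export
write_time_tree <- function(tree, file = NULL) {
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("Time-calibrated tree: %d tips, crown age %.4g My, sampling fraction f = %.3g\n",
              length(x$tip.label), attr(x, "crown_age"), attr(x, "sampling_fraction")))
  invisible(x)
}

#' Sampling fraction of a time tree
#' @param tree a [time_tree()].
#' @export
sampling_fraction <- function(tree) attr(tree, "sampling_fraction")

#' Crown age of a time tree
#' @param tree a [time_tree()].
#' @export
crown_age <- function(tree) attr(tree, "crown_age")

#' Branching times (internal node ages), descending
#'
#' Ages of the n−1 internal nodes in My before present, sorted from the
#' crown age down. These are the \eqn{t_i} entering the birth-death
#' likelihood.
#'
#' @param tree a [time_tree()].
#' @return numeric vector of length `n_tips - 1`, descending; the first
#'   element equals the crown age.
#' @export
branching_times <- function(tree) {
  bt <- unname(sort(ape::branching.times(tree), decreasing = TRUE))
  as.numeric(bt)
}

#' Lineage-through-time counts on an age grid
#'
#' Number of reconstructed lineages extant at each query age: at age `a`
#' there are `1 + #{branching times > a}` lineages, so the curve runs from 2
#' at the crown age to `n_tips` at the present.
#'
#' @param tree a [time_tree()].
#' @param grid ages (My) within `[0, crown_age]`.
#' @return integer vector of lineage counts, one per grid age.
#' @export
ltt_counts <- function(tree, grid) {
  ca <- crown_age(tree)
  if (any(grid < 0 | grid > ca + 1e-9 * ca))
    stop("grid ages must lie within [0, crown_age]")
  bt <- branching_times(tree)
  # splits at exactly age a count as having happened, so the curve is 2 at
  # the crown age and n_tips at the present
  eps <- 1e-9 * max(ca, 1)
  vapply(grid, function(a) 1L + sum(bt >= a - eps), integer(1L))
}
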