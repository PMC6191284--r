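# Time-calibrated phylogenies.  A time_tree wraps an ape "phylo" whose
# branch lengths are in Myr, adds per-node point dates (Mya, tips of extant
# species at 0) and per-node (older, younger) divergence-date bounds from a
# calibration table.  Branches are identified throughout the package by the
# label of their child node.

#' Construct a time tree
#'
#' @param phy An `ape::phylo` with branch lengths in Myr.  Internal nodes
#'   without labels are auto-labelled `node<k>`.
#' @param calibrations Optional data.frame with columns `label`,
#'   `older_bound`, `younger_bound` (Mya) giving divergence-date bounds for
#'   labelled nodes.  Unlisted nodes get point bounds at their date.
#' @param root_age Age of the root (Mya); default places the most distant
#'   tip at 0 Mya.
#' @return An object of class `time_tree`.
#' @export
time_tree <- function(phy, calibrations = NULL, root_age = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("time_tree: tree has no branch lengths")
  if (is.null(phy$node.label) || any(phy$node.label == "")) {
    lab <- phy$node.label
    if (is.null(lab)) lab <- rep("", phy$Nnode)
    need <- lab == ""
    lab[need] <- paste0("node", which(need))
    phy$node.label <- lab
  }
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels)) {
    stop("time_tree: duplicate node/tip labels")
  }
  depth <- ape::node.depth.edgelength(phy)
  if (is.null(root_age)) root_age <- max(depth)
  dates <- root_age - depth
  names(dates) <- labels
  older <- younger <- dates
  if (!is.null(calibrations)) {
    calibrations <- as.data.frame(calibrations)
    bad <- setdiff(calibrations$label, labels)
    if (length(bad)) {
      stop("time_tree: calibration labels not in tree: ",
           paste(bad, collapse = ", "))
    }
    if (any(calibrations$older_bound < calibrations$younger_bound)) {
      stop("time_tree: calibration error: older_bound < younger_bound")
    }
    older[calibrations$label] <- calibrations$older_bound
    younger[calibrations$label] <- calibrations$younger_bound
  }
  # child node dates must not exceed parent node dates, at both bounds
  parent_lab <- labels[phy$edge[, 1]]
  child_lab <- labels[phy$edge[, 2]]
  if (any(older[child_lab] > older[parent_lab] + 1e-9) ||
      any(younger[child_lab] > younger[parent_lab] + 1e-9)) {
    stop("time_tree: calibration error: a child node is dated older than ",
         "its parent")
  }
  structure(list(phy = phy, node_dates = dates, older = older,
                 younger = younger, root_age = root_age),
            class = "time_tree")
}

#' Read a newick time tree with calibration bounds
#'
#' @param path Newick file with branch lengths in Myr.
#' @param calibrations Optional calibration table or path to a TSV with
#'   columns `label`, `older_bound`, `younger_bound`.
#' @param root_age Optional root age (Mya).
#' @return A [time_tree()].
#' @export
read_time_tree <- function(path, calibrations = NULL, root_age = NULL) {
  phy <- ape::read.tree(path)
  if (is.character(calibrations) && length(calibrations) == 1) {
    calibrations <- utils::read.table(calibrations, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
  }
  time_tree(phy, calibrations = calibrations, root_age = root_age)
}

tt_labels <- function(tree) {
  c(tree$phy$tip.label, tree$phy$node.label)
}

tt_node_id <- function(tree, label) {
  id <- match(label, tt_labels(tree))
  if (any(is.na(id))) {
    stop("time_tree: unknown node label(s): ",
         paste(label[is.na(id)], collapse = ", "))
  }
  id
}

#' Point date of a node
#'
#' @param tree A [time_tree()].
#' @param label Tip or internal node label.
#' @param bound `"point"`, `"older"` or `"younger"`.
#' @return Date in Mya.
#' @export
node_date <- function(tree, label, bound = c("point", "older", "younger")) {
  bound <- match.arg(bound)
  v <- switch(bound, point = tree$node_dates, older = tree$older,
              younger = tree$younger)
  unname(v[label])
}

#' Duration of the branch above a node
#'
#' @param tree A [time_tree()].
#' @param child_label Label of the branch's child node.
#' @return Branch length in Myr (0 for the root).
#' @export
branch_duration <- function(tree, child_label) {
  id <- tt_node_id(tree, child_label)
  e <- match(id, tree$phy$edge[, 2])
  if (is.na(e)) return(0)
  tree$phy$edge.length[e]
}

# label of the parent node of `label` (NA for the root)
parent_label <- function(tree, label) {
  id <- tt_node_id(tree, label)
  e <- match(id, tree$phy$edge[, 2])
  if (is.na(e)) return(NA_character_)
  tt_labels(tree)[tree$phy$edge[, 1][e]]
}

# tip labels descending from (and including) the node `label`
descendant_tips <- function(tree, label) {
  phy <- tree$phy
  id <- tt_node_id(tree, label)
  ntip <- length(phy$tip.label)
  if (id <= ntip) return(phy$tip.label[id])
  stack <- id
  tips <- integer(0)
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == nd, 2]
    tips <- c(tips, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  phy$tip.label[tips]
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d tips, root at %.1f Mya\n",
              length(x$phy$tip.label), x$root_age))
  invisible(x)
}
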