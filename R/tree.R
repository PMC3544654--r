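#' Species trees for miRNA age inference
#'
#' A `species_tree` is a rooted, dated phylogeny (an [ape::read.tree()] `phylo`
#' object with branch lengths in Myr) together with a designated focal tip
#' (human, by default). The internal nodes on the root-to-focal-tip path define
#' the age intervals into which miRNA family origins are binned: with K
#' internal nodes on that path there are K+1 intervals, labelled `t0` (focal
#' tip only, youngest) through `tK` (origin at or before the root, oldest).
#'
#' @name species_tree
NULL

new_species_tree <- function(phy, focal) {
  path <- focal_path_table(phy, focal)
  structure(
    list(phylo = phy, focal = focal, path = path),
    class = "species_tree"
  )
}

#' Build a species tree from a phylo object
#'
#' Validates the tree (unique tip labels, non-negative branch lengths, focal
#' tip present) and computes the root-to-focal-tip path that defines the age
#' intervals.
#'
#' @param phy a rooted `phylo` object with branch lengths (Myr).
#' @param focal name of the focal tip (the species whose miRNAs are dated).
#' @return a `species_tree` object.
#' @export
species_tree <- function(phy, focal) {
  if (!inherits(phy, "phylo")) abort("`phy` must be a `phylo` object")
  if (is.null(phy$edge.length)) abort("tree has no branch lengths")
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    abort(paste0("duplicate tip label(s): ", paste(dup, collapse = ", ")))
  }
  if (any(phy$edge.length < 0)) {
    abort("negative branch length(s) in tree")
  }
  if (!focal %in% phy$tip.label) {
    abort(paste0("focal tip absent from tree: '", focal, "'"))
  }
  if (!ape::is.rooted(phy)) abort("tree must be rooted")
  new_species_tree(phy, focal)
}

#' Read a species tree from a Newick file
#'
#' @param path path to a Newick file with branch lengths in Myr.
#' @param focal name of the focal tip.
#' @return a `species_tree` object.
#' @export
read_species_tree <- function(path, focal = "human") {
  if (!file.exists(path)) abort(paste0("tree file not found: ", path))
  phy <- ape::read.tree(path)
  if (is.null(phy)) abort(paste0("could not parse Newick in ", path))
  species_tree(phy, focal)
}

#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree$phylo, file = path)
  invisible(path)
}

# Table of nodes on the root-to-focal path, youngest first.
# age_index r corresponds to the r-th internal node above the focal tip
# (r = 1 .. K); time_myr is the node's age (depth below it to any tip on an
# ultrametric tree; computed as height above the focal tip).
focal_path_table <- function(phy, focal) {
  tip <- match(focal, phy$tip.label)
  parent <- integer(0)
  node <- tip
  edge <- phy$edge
  len <- phy$edge.length
  times <- numeric(0)
  acc <- 0
  repeat {
    row <- which(edge[, 2] == node)
    if (length(row) == 0) break  # reached root
    acc <- acc + len[row]
    node <- edge[row, 1]
    parent <- c(parent, node)
    times <- c(times, acc)
  }
  tibble(
    age_index = seq_along(parent),
    node = parent,
    time_myr = times
  )
}

#' Age intervals implied by a species tree
#'
#' @param tree a `species_tree`.
#' @return a tibble with one row per age group `t0..tK`: the group label, its
#'   index, and the time interval `(younger_myr, older_myr]` (Myr before
#'   present) in which a family origin falls into that group. The oldest group
#'   is open-ended (`older_myr = Inf`).
#' @export
age_intervals <- function(tree) {
  k <- nrow(tree$path)
  bounds <- c(0, tree$path$time_myr, Inf)
  tibble(
    age_index = 0:k,
    age_label = paste0("t", 0:k),
    younger_myr = bounds[1:(k + 1)],
    older_myr = bounds[2:(k + 2)]
  )
}

#' @export
n_age_groups <- function(tree) nrow(tree$path) + 1L

#' @export
print.species_tree <- function(x, ...) {
  k <- nrow(x$path)
  cat("Species tree: ", length(x$phylo$tip.label), " tips, focal = '",
      x$focal, "'\n", sep = "")
  cat(k, " internal nodes on the root-to-focal path -> ", k + 1,
      " age intervals (t0..t", k, ")\n", sep = "")
  invisible(x)
}

#' The packaged 11-taxon vertebrate tree
#'
#' Human, chimp, orangutan, rhesus, mouse, rat, dog, horse, cow, chicken and
#' zebrafish, with standard literature divergence times (6, 16, 29, 90, 97,
#' 310, 450 Myr on the human path). The seven internal nodes on the human path
#' yield the eight age intervals t0 (human-specific) .. t7 (pre-vertebrate).
#'
#' @param focal the focal tip; default `"human"`.
#' @return a `species_tree`.
#' @export
default_species_tree <- function(focal = "human") {
  path <- system.file("extdata", "vertebrate_tree.nwk", package = "mirage")
  read_species_tree(path, focal)
}

# Tips descending from an internal node (indices into tip.label)
descendant_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ch <- phy$edge[phy$edge[, 1] == v, 2]
    out <- c(out, ch[ch <= ntip])
    stack <- c(stack, ch[ch > ntip])
  }
  out
}

# Divergence time (Myr) between two tips: time of their MRCA, via the focal
# path when possible; general case uses node depths.
node_times_all <- function(phy) {
  # height of each node above the tips, assuming ultrametric; computed as
  # max root-to-node path subtracted from tree height
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  h <- max(depth[1:ntip])
  h - depth
}

#' Pairwise divergence times between tips
#'
#' @param tree a `species_tree`.
#' @return a symmetric matrix of divergence times (Myr), dimnames = tip labels.
#' @export
divergence_times <- function(tree) {
  phy <- tree$phylo
  d <- ape::cophenetic.phylo(phy) / 2
  d[tree$phylo$tip.label, tree$phylo$tip.label]
}
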