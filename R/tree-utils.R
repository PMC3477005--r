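# Internal helpers around ape's "phylo" representation. Branches are
# identified throughout the package by the label of the node *below* them
# (tip label for terminal branches, internal node label otherwise).

#' Ensure a tree carries unique internal node labels
#'
#' Internal nodes are labelled `N<number>` (ape node numbering) when labels are
#' missing or empty. Tip labels are left untouched.
#'
#' @param tree an object of class `phylo`.
#' @return the tree with a complete `node.label` vector.
#' @export
ensure_node_labels <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  lab <- tree$node.label
  auto <- paste0("N", seq_len(tree$Nnode) + n)
  if (is.null(lab)) {
    tree$node.label <- auto
  } else {
    bad <- is.na(lab) | lab == ""
    lab[bad] <- auto[bad]
    tree$node.label <- lab
  }
  tree
}

# label of any node number (tip or internal); vectorised
node_label <- function(tree, node) {
  n <- ape::Ntip(tree)
  out <- character(length(node))
  tip <- node <= n
  out[tip] <- tree$tip.label[node[tip]]
  out[!tip] <- tree$node.label[node[!tip] - n]
  out
}

# node number for a label; NA if absent
node_id <- function(tree, label) {
  n <- ape::Ntip(tree)
  i <- match(label, tree$tip.label)
  j <- match(label, tree$node.label)
  ifelse(!is.na(i), i, ifelse(!is.na(j), j + n, NA_integer_))
}

# list: children[[node]] = integer vector of child node numbers
tree_children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[k, 2])
  }
  ch
}

tree_root <- function(tree) ape::Ntip(tree) + 1L

# tip numbers contained in the clade below `node`
tips_under <- function(tree, node) {
  n <- ape::Ntip(tree)
  if (node <= n) return(node)
  ch <- tree_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) out <- c(out, v) else stack <- c(stack, ch[[v]])
  }
  sort(out)
}

# LCA of a set of tip numbers (a single tip is its own LCA)
lca_node <- function(tree, tips) {
  if (length(tips) == 1) return(tips)
  ape::getMRCA(tree, tips)
}

#' Branch table of a tree
#'
#' One row per edge, identified by the child-node label: the currency used by
#' the simulator's event log and by Dollo reconstructions.
#'
#' @param tree a `phylo` with node labels (see [ensure_node_labels()]).
#' @return data.frame with columns `parent`, `child` (node numbers),
#'   `branch` (child label) and `length`.
#' @export
branch_table <- function(tree) {
  tree <- ensure_node_labels(tree)
  data.frame(
    parent = tree$edge[, 1],
    child = tree$edge[, 2],
    branch = node_label(tree, tree$edge[, 2]),
    length = if (is.null(tree$edge.length)) NA_real_ else tree$edge.length,
    stringsAsFactors = FALSE
  )
}

#' Simulate a rooted binary species tree
#'
#' Random rooted binary topology with independent uniform(0, 1) branch lengths
#' (expected substitutions per site), tips labelled `sp01`, `sp02`, ... and
#' internal nodes `N<k>`. Deterministic for a fixed seed.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a rooted `phylo` object.
#' @examples
#' tr <- simulate_species_tree(8, seed = 7)
#' @export
simulate_species_tree <- function(n_species, seed = NULL) {
  if (!is.numeric(n_species) || length(n_species) != 1 || n_species < 2)
    stop("n_species must be a single integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(as.integer(n_species), rooted = TRUE)
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  ensure_node_labels(tr)
}
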