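# Tree building and tree/locus concordance. Neighbor joining (through ape's
# agglomerator) stands in for Bayesian inference, whose inputs are exported
# as NEXUS instead; midpoint rooting and concordance scoring are computed
# here.

#' Neighbor-joining tree from a distance matrix
#'
#' Validates the matrix (symmetric, non-negative, >= 3 taxa) and runs the
#' standard agglomeration; tiny negative branch lengths arising from noisy
#' distances are clamped to zero. On an additive matrix the generating
#' topology and branch lengths are recovered exactly.
#'
#' @param d symmetric numeric matrix with taxon dimnames.
#' @return an unrooted `phylo`.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' The root is placed halfway along the tree diameter, so the two extreme
#' leaves are equidistant from it (within 1e-9). Ties between equally long
#' paths are broken deterministically by the lexicographically smallest
#' (sorted) leaf-label pair. A tree with zero total length is rooted
#' arbitrarily at its first internal node and flagged with attribute
#' `"zero_length"`.
#'
#' @param tree a `phylo` with branch lengths.
#' @return rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  n <- ape::Ntip(tree)
  if (n < 2) stop("need at least 2 tips")
  if (sum(tree$edge.length) == 0) {
    out <- if (ape::is.rooted(tree)) tree else
      ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    attr(out, "zero_length") <- TRUE
    return(out)
  }
  D <- ape::dist.nodes(tree)
  DL <- D[seq_len(n), seq_len(n), drop = FALSE]
  dmax <- max(DL)
  cand <- which(DL == dmax, arr.ind = TRUE)
  cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
  pairs <- apply(cand, 1, function(r)
    paste(sort(tree$tip.label[r]), collapse = "\r"))
  pick <- cand[order(pairs)[1], ]
  a <- pick[[1]]; b <- pick[[2]]
  half <- dmax / 2

  path <- ape::nodepath(tree, a, b)
  elen <- function(u, v) {
    k <- which((tree$edge[, 1] == u & tree$edge[, 2] == v) |
                 (tree$edge[, 1] == v & tree$edge[, 2] == u))
    tree$edge.length[k]
  }
  walked <- 0
  for (i in seq_len(length(path) - 1)) {
    u <- path[i]; v <- path[i + 1]
    len <- elen(u, v)
    if (walked + len >= half - 1e-12) {
      x_from_u <- half - walked      # distance from u along this edge
      # identify the child side of the edge in the tree's own orientation
      k <- which(tree$edge[, 1] == u & tree$edge[, 2] == v)
      if (length(k)) { child <- v; from_child <- len - x_from_u }
      else { child <- u; from_child <- x_from_u }
      return(reroot_along_edge(tree, child, from_child))
    }
    walked <- walked + len
  }
  stop("internal error: midpoint not located")  # nocov
}

# subdivide the edge above `child` at `pos` from the child and root there
reroot_along_edge <- function(tree, child, pos) {
  k <- which(tree$edge[, 2] == child)
  len <- tree$edge.length[k]
  eps <- 1e-12
  pos <- min(max(pos, 0), len)
  tmp <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                        tip.label = "..midpoint..",
                        edge.length = 0, Nnode = 1L), class = "phylo")
  t2 <- ape::bind.tree(tree, tmp, where = child, position = max(pos, eps))
  mid_tip <- which(t2$tip.label == "..midpoint..")
  mid_node <- t2$edge[t2$edge[, 2] == mid_tip, 1]
  t3 <- ape::root(t2, node = mid_node)
  out <- ape::drop.tip(t3, "..midpoint..")
  out$node.label <- NULL
  ensure_node_labels(out)
}

#' Leaf depths of a rooted tree
#'
#' @param tree rooted `phylo`.
#' @return named numeric vector of root-to-tip path lengths.
#' @export
leaf_depths <- function(tree) {
  n <- ape::Ntip(tree)
  D <- ape::dist.nodes(tree)
  stats::setNames(D[n + 1, seq_len(n)], tree$tip.label)
}

#' Concordance between tree clades and locus assignments
#'
#' A locus with two or more member leaves is concordant when its leaf set is
#' exactly the leaf set of some node of the (rooted) tree. The overall score
#' is the fraction of multi-member loci that are monophyletic; `NA` when no
#' locus has two members. Leaves assigned `NOVEL`, `AMBIGUOUS` or `NA` are
#' outside every locus but still count against monophyly when nested inside a
#' locus clade.
#'
#' @param tree `phylo`; midpoint-rooted first if unrooted.
#' @param loci named character vector: locus per leaf label.
#' @return list: `per_locus` (locus, n, monophyletic), `score`.
#' @export
clade_locus_concordance <- function(tree, loci) {
  if (!all(tree$tip.label %in% names(loci)))
    stop("every leaf needs a locus assignment (or NOVEL/NA)")
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  loci <- loci[tree$tip.label]
  real <- !(is.na(loci) | loci %in% c("NOVEL", "AMBIGUOUS"))
  tab <- table(loci[real])
  multi <- names(tab)[tab >= 2]
  if (!length(multi))
    return(list(per_locus = data.frame(locus = character(), n = integer(),
                                       monophyletic = logical()),
                score = NA_real_))
  per <- do.call(rbind, lapply(multi, function(lc) {
    members <- which(loci == lc & real)
    node <- lca_node(tree, members)
    mono <- setequal(tips_under(tree, node), members)
    data.frame(locus = lc, n = length(members), monophyletic = mono,
               stringsAsFactors = FALSE)
  }))
  list(per_locus = per, score = mean(per$monophyletic))
}

#' Mean patristic distance between families
#'
#' Path-length distance averaged over all cross-family leaf pairs; the
#' diagonal holds the within-family mean (NA for singleton families).
#'
#' @param tree `phylo` with branch lengths.
#' @param families named character vector: family label per leaf.
#' @return symmetric numeric matrix, families x families.
#' @export
family_patristic_distance <- function(tree, families) {
  if (!all(tree$tip.label %in% names(families)))
    stop("unlabeled leaf(s): ",
         paste(setdiff(tree$tip.label, names(families)), collapse = ", "))
  families <- families[tree$tip.label]
  D <- ape::cophenetic.phylo(tree)
  fams <- sort(unique(families))
  out <- matrix(NA_real_, length(fams), length(fams),
                dimnames = list(fams, fams))
  for (i in seq_along(fams)) for (j in i:length(fams)) {
    ti <- tree$tip.label[families == fams[i]]
    tj <- tree$tip.label[families == fams[j]]
    block <- D[ti, tj, drop = FALSE]
    v <- if (i == j) {
      if (length(ti) < 2) NA_real_ else mean(block[upper.tri(block)])
    } else mean(block)
    out[i, j] <- out[j, i] <- v
  }
  out
}
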