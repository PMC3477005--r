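# Dollo parsimony on a rooted species tree: a binary character (locus or
# intron site present/absent/unknown) is explained by exactly one gain —
# placed at the last common ancestor of the present taxa — plus the minimal
# set of loss branches. Unknown (?) taxa are completed so as to minimise the
# loss count, ties resolved towards absence.

# states of all leaves after completion -> all-zero flag per node, postorder
all_zero_flags <- function(tree, leaf_state) {
  n <- ape::Ntip(tree)
  n_all <- n + tree$Nnode
  ch <- tree_children(tree)
  az <- logical(n_all)
  az[seq_len(n)] <- leaf_state[tree$tip.label] == 0
  visit <- function(v) {
    if (v <= n) return(az[v])
    res <- TRUE
    for (w in ch[[v]]) res <- visit(w) && res
    az[v] <<- res
    res
  }
  visit(tree_root(tree))
  az
}

# minimal loss edges for a fixed gain node: edges (u -> w) inside the gain
# subtree whose child subtree is entirely 0 but whose parent subtree is not
loss_edges_for_gain <- function(tree, az, gain) {
  keep <- integer(0)
  n <- ape::Ntip(tree)
  ch <- tree_children(tree)
  stack <- gain
  sub <- logical(n + tree$Nnode)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    sub[v] <- TRUE
    if (v > n) stack <- c(stack, ch[[v]])
  }
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1]; w <- tree$edge[k, 2]
    if (sub[u] && az[w] && !az[u]) keep <- c(keep, w)
  }
  keep
}

#' Dollo reconstruction of a binary character on a rooted tree
#'
#' @param states named vector over (a subset of) the tree's tips; values 1
#'   (present), 0 (absent) or `NA` (unknown). Tips not named are treated as
#'   absent.
#' @param tree rooted `phylo`.
#' @param max_unknown cap on the number of `NA` taxa enumerated exhaustively.
#' @return list of class `dollo_fit`: `gain` (node label, or `NA` when no
#'   taxon is present), `gain_node`, `losses` (child labels of loss edges),
#'   `n_losses`, `completion` (chosen 0/1 values for the `NA` taxa) and
#'   `node_present` (named presence over all nodes).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' dollo_reconstruct(c(A = 1, C = 1, B = 0, D = 0), tr)$n_losses  # 2
#' @export
dollo_reconstruct <- function(states, tree, max_unknown = 16) {
  tree <- ensure_node_labels(tree)
  tips <- tree$tip.label
  if (!all(names(states) %in% tips))
    stop("character names outside the tree: ",
         paste(setdiff(names(states), tips), collapse = ", "))
  full <- stats::setNames(rep(0, length(tips)), tips)
  full[names(states)] <- states
  unk <- names(full)[is.na(full)]
  if (length(unk) > max_unknown)
    stop("too many unknown taxa for exhaustive completion (",
         length(unk), " > ", max_unknown, ")")

  n <- ape::Ntip(tree)
  evaluate <- function(completed) {
    ones <- which(tree$tip.label %in% names(completed)[completed == 1])
    if (!length(ones))
      return(list(gain = NA_integer_, losses = integer(0), n = 0))
    gain <- lca_node(tree, ones)
    az <- all_zero_flags(tree, completed)
    le <- loss_edges_for_gain(tree, az, gain)
    list(gain = gain, losses = le, n = length(le))
  }

  # enumerate completions in order of increasing number of 1s so that the
  # first minimum found realises the tie-break towards absence
  best <- NULL; best_completion <- NULL
  n_unk <- length(unk)
  combos <- if (n_unk)
    expand.grid(rep(list(c(0, 1)), n_unk), KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  ord <- order(if (n_unk) rowSums(combos) else 0)
  for (i in ord) {
    completed <- full
    if (n_unk) completed[unk] <- as.numeric(combos[i, ])
    ev <- evaluate(completed)
    if (is.null(best) || ev$n < best$n) {
      best <- ev
      best_completion <- completed
    }
  }

  node_present <- stats::setNames(rep(0, n + tree$Nnode),
                                  c(tips, tree$node.label))
  if (!is.na(best$gain)) {
    # presence: everything under the gain minus subtrees cut by a loss edge
    ch <- tree_children(tree)
    present <- rep(FALSE, n + tree$Nnode)
    mark <- function(v) {
      if (v %in% best$losses) return(invisible())
      present[v] <<- TRUE
      if (v > n) for (w in ch[[v]]) mark(w)
    }
    mark(best$gain)
    node_present[] <- as.numeric(present)
  }

  structure(list(
    gain = if (is.na(best$gain)) NA_character_ else node_label(tree, best$gain),
    gain_node = best$gain,
    losses = if (length(best$losses)) node_label(tree, best$losses) else character(0),
    n_losses = best$n,
    completion = best_completion[unk],
    node_present = node_present), class = "dollo_fit")
}

#' Exhaustive single-gain minimum for a binary character
#'
#' Enumerates every candidate gain node (all tree nodes whose clade contains
#' all present taxa) and every completion of unknown taxa, computing the
#' minimal loss count for each by an independent recursive argument. Serves as
#' the brute-force yardstick for [dollo_reconstruct()].
#'
#' @inheritParams dollo_reconstruct
#' @return list: `n_losses` (the global minimum; 0 with `gain = NA` when no
#'   completion has a present taxon), `gain_node` (a node attaining it).
#' @export
dollo_min_events <- function(states, tree, max_unknown = 16) {
  tree <- ensure_node_labels(tree)
  tips <- tree$tip.label
  full <- stats::setNames(rep(0, length(tips)), tips)
  full[names(states)] <- states
  unk <- names(full)[is.na(full)]
  if (length(unk) > max_unknown) stop("too many unknown taxa")
  n <- ape::Ntip(tree)
  ch <- tree_children(tree)

  # recursive: minimal losses inside subtree v so every 0-leaf is severed;
  # returns c(losses, all_zero)
  count <- function(v, st) {
    if (v <= n) return(c(0, unname(st[tree$tip.label[v]] == 0)))
    tot <- 0; zero <- TRUE
    kids <- lapply(ch[[v]], count, st = st)
    for (k in kids) { tot <- tot + k[1]; zero <- zero && k[2] }
    if (!zero) {
      # severing a fully-zero child costs one loss each
      for (j in seq_along(kids)) if (kids[[j]][2]) tot <- tot + 1
    }
    c(tot, zero)
  }

  n_unk <- length(unk)
  combos <- if (n_unk)
    expand.grid(rep(list(c(0, 1)), n_unk), KEEP.OUT.ATTRS = FALSE)
  else data.frame(row.names = 1)
  best_n <- Inf; best_gain <- NA_integer_
  for (i in seq_len(nrow(combos))) {
    st <- full
    if (n_unk) st[unk] <- as.numeric(combos[i, ])
    ones <- which(tree$tip.label %in% names(st)[st == 1])
    if (!length(ones)) {
      if (0 < best_n) { best_n <- 0; best_gain <- NA_integer_ }
      next
    }
    for (g in seq_len(n + tree$Nnode)) {
      under <- tips_under(tree, g)
      if (!all(ones %in% under)) next
      r <- count(g, st)
      if (r[1] < best_n) { best_n <- r[1]; best_gain <- g }
    }
  }
  list(n_losses = if (is.finite(best_n)) unname(best_n) else 0,
       gain_node = best_gain)
}
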