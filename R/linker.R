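# Clone-end contig linking: build the link graph, infer relative contig
# orientations from end-strand parity, then order contigs by least-squares
# offset estimation — the procedure used to join disconnected assembly contigs
# from BAC/fosmid end-sequence hits.

#' Build a contig link graph from clone-end hits
#'
#' Clones whose two ends land on distinct contigs become linking edges; clones
#' with both ends on one contig are kept as spanning records (useful for
#' validating insert sizes, never as links); single-ended clones are set aside.
#'
#' @param contigs data.frame with columns `contig`, `length`.
#' @param ends data.frame with columns `clone`, `end`, `contig`, `pos`
#'   (0-based), `strand`; at most two rows per clone.
#' @return list of class `contig_link_graph`: `contigs`, `edges` (clone,
#'   contig1, pos1, strand1, contig2, pos2, strand2), `spanning`, `unpaired`.
#' @export
build_link_graph <- function(contigs, ends) {
  stopifnot(all(c("contig", "length") %in% names(contigs)),
            all(c("clone", "contig", "pos", "strand") %in% names(ends)))
  bad <- ends$contig[!ends$contig %in% contigs$contig]
  if (length(bad)) stop("clone ends reference unknown contigs: ",
                        paste(unique(bad), collapse = ", "))
  len <- structure(contigs$length, names = contigs$contig)
  if (any(ends$pos < 0 | ends$pos >= len[ends$contig]))
    stop("clone end positions outside contig bounds")

  counts <- table(ends$clone)
  if (any(counts > 2))
    stop("malformed input: clone(s) with more than two end records: ",
         paste(names(counts)[counts > 2], collapse = ", "))

  split_ends <- split(ends, ends$clone)
  edges <- list(); spanning <- list(); unpaired <- list()
  for (e in split_ends) {
    if (nrow(e) == 1) { unpaired[[length(unpaired) + 1L]] <- e; next }
    e <- e[order(e$end), , drop = FALSE]
    row <- data.frame(clone = e$clone[1],
                      contig1 = e$contig[1], pos1 = e$pos[1], strand1 = e$strand[1],
                      contig2 = e$contig[2], pos2 = e$pos[2], strand2 = e$strand[2],
                      stringsAsFactors = FALSE)
    if (e$contig[1] == e$contig[2]) spanning[[length(spanning) + 1L]] <- row
    else edges[[length(edges) + 1L]] <- row
  }
  empty_edge <- data.frame(clone = character(), contig1 = character(),
                           pos1 = numeric(), strand1 = character(),
                           contig2 = character(), pos2 = numeric(),
                           strand2 = character(), stringsAsFactors = FALSE)
  out <- list(
    contigs = contigs,
    edges = if (length(edges)) do.call(rbind, edges) else empty_edge,
    spanning = if (length(spanning)) do.call(rbind, spanning) else empty_edge,
    unpaired = if (length(unpaired)) do.call(rbind, unpaired) else
      ends[0, , drop = FALSE])
  class(out) <- "contig_link_graph"
  out
}

#' Infer contig orientations from end-strand parity
#'
#' Each inward-facing clone imposes the parity constraint
#' `flip(A) XOR flip(B) = (strand_A == strand_B)`: in a consistent
#' super-scaffold frame the two ends must sit on opposite strands. Constraints
#' are propagated per connected component from the lexicographically smallest
#' contig (left unflipped); edges contradicting the propagated assignment are
#' returned as conflicts, not resolved.
#'
#' @param graph a `contig_link_graph`.
#' @param geometry `"inward"` (BAC/fosmid libraries) or `"outward"`; flips the
#'   parity truth table.
#' @return list: `flips` (named logical over all contigs), `conflicts`
#'   (conflicting edge rows), `components` (named integer membership).
#' @export
infer_orientations <- function(graph, geometry = c("inward", "outward")) {
  stopifnot(inherits(graph, "contig_link_graph"))
  geometry <- match.arg(geometry)
  ed <- graph$edges
  need_flip_diff <- function(s1, s2) {
    same <- s1 == s2
    if (geometry == "inward") same else !same
  }
  g <- igraph::graph_from_data_frame(
    if (nrow(ed)) ed[, c("contig1", "contig2")] else
      data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = graph$contigs$contig))
  comp <- igraph::components(g)$membership
  flips <- stats::setNames(rep(NA, nrow(graph$contigs)), graph$contigs$contig)

  adj <- vector("list", nrow(graph$contigs))
  names(adj) <- graph$contigs$contig
  for (i in seq_len(nrow(ed))) {
    a <- ed$contig1[i]; b <- ed$contig2[i]
    req <- need_flip_diff(ed$strand1[i], ed$strand2[i])
    adj[[a]] <- rbind(adj[[a]], data.frame(to = b, req = req, edge = i))
    adj[[b]] <- rbind(adj[[b]], data.frame(to = a, req = req, edge = i))
  }

  for (cm in unique(comp)) {
    members <- sort(names(comp)[comp == cm])
    seed <- members[1]
    flips[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (j in seq_len(nrow(nb))) {
        w <- nb$to[j]
        want <- xor(flips[[v]], nb$req[j])
        if (is.na(flips[[w]])) {
          flips[w] <- want
          queue <- c(queue, w)
        }
      }
    }
  }
  flips[is.na(flips)] <- FALSE

  conflict_idx <- integer(0)
  for (i in seq_len(nrow(ed))) {
    req <- need_flip_diff(ed$strand1[i], ed$strand2[i])
    if (xor(flips[[ed$contig1[i]]], flips[[ed$contig2[i]]]) != req)
      conflict_idx <- c(conflict_idx, i)
  }
  list(flips = flips,
       conflicts = ed[conflict_idx, , drop = FALSE],
       components = comp)
}

#' Order oriented contigs into super-scaffolds
#'
#' With orientations fixed, every linking clone yields one linear constraint
#' on the contig offsets in super-scaffold coordinates: the minus-strand end
#' must lie one (estimated) insert length downstream of the plus-strand end.
#' Offsets are solved per component by least squares (first contig pinned at
#' 0) using the midpoint of `insert_range` as the insert estimate; contigs are
#' then sorted by offset. Gaps more negative than half the insert-range width
#' are reported as ordering conflicts.
#'
#' @param graph a `contig_link_graph`.
#' @param orientations result of [infer_orientations()].
#' @param insert_range numeric c(min, max) insert size, bp.
#' @return list of class `super_scaffolds`: `scaffolds` (super, rank, contig,
#'   orientation, offset, gap_to_next) and `conflicts` (overlapping
#'   neighbours).
#' @export
order_contigs <- function(graph, orientations, insert_range) {
  stopifnot(inherits(graph, "contig_link_graph"), length(insert_range) == 2)
  flips <- orientations$flips
  comp <- orientations$components
  ins_mid <- mean(insert_range)
  tol <- diff(range(insert_range)) / 2
  len <- structure(graph$contigs$length, names = graph$contigs$contig)
  ed <- graph$edges
  drop_edges <- if (nrow(orientations$conflicts))
    orientations$conflicts$clone else character(0)

  scaffolds <- list(); conflicts <- list()
  super_i <- 0
  for (cm in unique(comp)) {
    members <- sort(names(comp)[comp == cm])
    super_i <- super_i + 1
    offs <- stats::setNames(rep(0, length(members)), members)
    ce <- ed[ed$contig1 %in% members & !(ed$clone %in% drop_edges), ,
             drop = FALSE]
    if (nrow(ce) && length(members) > 1) {
      # oriented end positions/strands
      o_pos <- function(ctg, pos) if (flips[[ctg]]) len[[ctg]] - 1 - pos else pos
      o_str <- function(ctg, s) if (flips[[ctg]]) (if (s == "+") "-" else "+") else s
      rows <- list()
      for (i in seq_len(nrow(ce))) {
        c1 <- ce$contig1[i]; c2 <- ce$contig2[i]
        p1 <- o_pos(c1, ce$pos1[i]); p2 <- o_pos(c2, ce$pos2[i])
        s1 <- o_str(c1, ce$strand1[i]); s2 <- o_str(c2, ce$strand2[i])
        if (s1 == s2) next  # parity conflict; handled upstream
        if (s1 == "+") { up <- c1; pu <- p1; dn <- c2; pd <- p2 }
        else { up <- c2; pu <- p2; dn <- c1; pd <- p1 }
        rows[[length(rows) + 1L]] <-
          list(up = up, dn = dn, d = ins_mid - 1 + pu - pd)
      }
      if (length(rows)) {
        # least squares on offset differences: o[dn] - o[up] = d
        A <- matrix(0, length(rows), length(members),
                    dimnames = list(NULL, members))
        rhs <- numeric(length(rows))
        for (i in seq_along(rows)) {
          A[i, rows[[i]]$up] <- -1
          A[i, rows[[i]]$dn] <- 1
          rhs[i] <- rows[[i]]$d
        }
        pin <- members[1]
        keep <- setdiff(members, pin)
        fit <- stats::lsfit(A[, keep, drop = FALSE], rhs, intercept = FALSE)
        offs[keep] <- fit$coefficients
        offs[pin] <- 0
      }
    }
    ord <- order(offs, members)
    members <- members[ord]
    offs <- offs[ord]
    offs <- offs - offs[1]
    gaps <- c(offs[-1] - (offs[-length(offs)] + len[members[-length(members)]]),
              NA)
    df <- data.frame(super = sprintf("super%02d", super_i),
                     rank = seq_along(members),
                     contig = members,
                     orientation = ifelse(unlist(flips[members]), "-", "+"),
                     offset = round(offs, 1),
                     gap_to_next = round(gaps, 1),
                     stringsAsFactors = FALSE)
    scaffolds[[super_i]] <- df
    ov <- which(!is.na(gaps) & gaps < -tol)
    if (length(ov))
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        super = df$super[1], contig_a = members[ov], contig_b = members[ov + 1],
        overlap = -gaps[ov], stringsAsFactors = FALSE)
  }
  out <- list(
    scaffolds = do.call(rbind, scaffolds),
    conflicts = if (length(conflicts)) do.call(rbind, conflicts) else
      data.frame(super = character(), contig_a = character(),
                 contig_b = character(), overlap = numeric(),
                 stringsAsFactors = FALSE))
  class(out) <- "super_scaffolds"
  out
}

#' Link contigs end to end
#'
#' Convenience wrapper: graph construction, orientation inference and ordering
#' in one call.
#'
#' @inheritParams build_link_graph
#' @inheritParams order_contigs
#' @param geometry clone library geometry, see [infer_orientations()].
#' @return list with `graph`, `orientations` and the `super_scaffolds` result.
#' @export
link_contigs <- function(contigs, ends, insert_range,
                         geometry = "inward") {
  graph <- build_link_graph(contigs, ends)
  ori <- infer_orientations(graph, geometry)
  res <- order_contigs(graph, ori, insert_range)
  list(graph = graph, orientations = ori, scaffolds = res$scaffolds,
       conflicts = res$conflicts, parity_conflicts = ori$conflicts)
}

#' Compare two contig layouts up to global flip
#'
#' Two single-component layouts are equivalent when their (contig,
#' orientation) sequences are identical, or identical after reversing the
#' order and flipping every orientation — the inherent symmetry of mate-pair
#' scaffolding.
#'
#' @param layout data.frame with columns `contig`, `orientation`, ordered.
#' @param truth data.frame with columns `contig`, `flipped` (logical), in true
#'   order.
#' @return TRUE/FALSE.
#' @export
layout_matches_truth <- function(layout, truth) {
  want <- data.frame(contig = truth$contig,
                     orientation = ifelse(truth$flipped, "-", "+"),
                     stringsAsFactors = FALSE)
  got <- layout[, c("contig", "orientation")]
  same <- function(a, b) nrow(a) == nrow(b) &&
    all(a$contig == b$contig) && all(a$orientation == b$orientation)
  rev_got <- data.frame(contig = rev(got$contig),
                        orientation = ifelse(rev(got$orientation) == "+", "-", "+"),
                        stringsAsFactors = FALSE)
  same(got, want) || same(rev_got, want)
}
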