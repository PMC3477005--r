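# Synteny locus tracking: identify a family member's locus from its flanking
# anchor genes, tabulate locus presence/absence across species, and hand the
# rows to the Dollo engine to reconstruct the ancestral locus roadmap.

# collapse an exon-level annotation to one row per gene
gene_spans <- function(annotation) {
  sp <- split(annotation, annotation$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    gene_id = g$gene_id[1], species = g$species[1], scaffold = g$scaffold[1],
    strand = g$strand[1], start = min(g$start), end = max(g$end),
    symbol = g$symbol[1], family = g$family[1],
    premature_stop = any(g$premature_stop), frameshift = any(g$frameshift),
    low_coverage = any(g$low_coverage), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Extract the gene neighbourhood of a focal gene
#'
#' Up to `window` genes on each side of the focal gene on its scaffold,
#' re-expressed in the focal gene's frame: the focal gene is normalised to the
#' plus orientation, so on a minus-strand gene the genomic downstream side
#' becomes the upstream flank and relative orientations flip accordingly.
#' Flanks are truncated silently at scaffold ends.
#'
#' @param annotation exon-level annotation data.frame (columns `gene_id`,
#'   `scaffold`, `strand`, `start`, `end`, `symbol`, `family`, ...).
#' @param focal_gene gene id present in the annotation.
#' @param window maximum flank size, genes per side.
#' @return list of class `locus_profile`: `focal` (one-row gene span) and
#'   `flanks` (symbol, side `"up"`/`"down"`, rel_orientation
#'   `"same"`/`"opposite"`, dist_genes, dist_bp).
#' @export
extract_neighborhood <- function(annotation, focal_gene, window = 10) {
  genes <- gene_spans(annotation)
  fi <- which(genes$gene_id == focal_gene)
  if (!length(fi)) stop("focal gene not found: ", focal_gene)
  focal <- genes[fi, , drop = FALSE]
  nb <- genes[genes$scaffold == focal$scaffold, , drop = FALSE]
  nb <- nb[order(nb$start), , drop = FALSE]
  pos <- which(nb$gene_id == focal_gene)
  idx <- seq_len(nrow(nb))
  sel <- idx[idx != pos & abs(idx - pos) <= window]
  if (!length(sel)) {
    flanks <- data.frame(symbol = character(), side = character(),
                         rel_orientation = character(), dist_genes = integer(),
                         dist_bp = numeric(), stringsAsFactors = FALSE)
  } else {
    genomic_side <- ifelse(sel < pos, "up", "down")
    side <- if (focal$strand == "+") genomic_side else
      ifelse(genomic_side == "up", "down", "up")
    flanks <- data.frame(
      symbol = nb$symbol[sel],
      side = side,
      rel_orientation = ifelse(nb$strand[sel] == focal$strand,
                               "same", "opposite"),
      dist_genes = abs(sel - pos),
      dist_bp = ifelse(sel < pos, focal$start - nb$end[sel],
                       nb$start[sel] - focal$end),
      stringsAsFactors = FALSE)
    # flanks sorted outward from the focal gene, upstream first
    flanks <- flanks[order(flanks$side != "up", flanks$dist_genes), ,
                     drop = FALSE]
    rownames(flanks) <- NULL
  }
  structure(list(focal = focal, flanks = flanks), class = "locus_profile")
}

#' Assign a neighbourhood profile to a named locus
#'
#' Each anchor set is scored by how many of its anchor symbols occur among the
#' profile's flanks; the unique set meeting its minimum `k` with the highest
#' count wins. No set meeting its `k` gives `"NOVEL"` (a gene alone on a small
#' scaffold); a tie between best sets gives `"AMBIGUOUS"`.
#'
#' @param profile a `locus_profile`.
#' @param anchor_sets list of lists with fields `name`, `anchors` (character),
#'   `k` (minimum anchors to call).
#' @return locus name, `"NOVEL"` or `"AMBIGUOUS"`.
#' @export
assign_locus <- function(profile, anchor_sets) {
  stopifnot(inherits(profile, "locus_profile"))
  nms <- vapply(anchor_sets, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("anchor set names must be distinct")
  counts <- vapply(anchor_sets, function(s)
    sum(s$anchors %in% profile$flanks$symbol), 0L)
  ks <- vapply(anchor_sets, function(s) as.integer(s$k), 0L)
  if (any(ks < 1)) stop("every anchor set needs k >= 1")
  meets <- counts >= ks
  if (!any(meets)) return("NOVEL")
  top <- max(counts[meets])
  winners <- nms[meets & counts == top]
  if (length(winners) > 1) "AMBIGUOUS" else winners
}

#' Build a locus presence/absence matrix across species
#'
#' @param assignments data.frame with columns `species`, `locus` (one row per
#'   assigned gene; `NOVEL`/`AMBIGUOUS` rows are ignored).
#' @param taxa character vector of all species (matrix columns).
#' @param loci optional row universe; defaults to the loci observed.
#' @param low_coverage species whose absences are recorded as unknown (`NA`)
#'   rather than 0 — a genome too shallow to conclude absence.
#' @return integer matrix loci x taxa with values 1, 0 or `NA` (unknown).
#' @export
build_presence_matrix <- function(assignments, taxa, loci = NULL,
                                  low_coverage = character()) {
  keep <- !(assignments$locus %in% c("NOVEL", "AMBIGUOUS"))
  assignments <- assignments[keep, , drop = FALSE]
  if (is.null(loci)) loci <- sort(unique(assignments$locus))
  m <- matrix(0L, nrow = length(loci), ncol = length(taxa),
              dimnames = list(loci, taxa))
  m[, taxa %in% low_coverage] <- NA_integer_
  for (i in seq_len(nrow(assignments))) {
    m[assignments$locus[i], assignments$species[i]] <- 1L
  }
  m
}

#' Reconstruct every locus row of a presence matrix
#'
#' @param presence matrix from [build_presence_matrix()].
#' @param tree rooted species tree covering the matrix columns.
#' @return data.frame `locus`, `gain` (branch label), `losses`
#'   (comma-joined branch labels), `n_losses`.
#' @export
locus_dollo_report <- function(presence, tree) {
  rows <- lapply(rownames(presence), function(lc) {
    fit <- dollo_reconstruct(presence[lc, ], tree)
    data.frame(locus = lc, gain = fit$gain,
               losses = paste(fit$losses, collapse = ","),
               n_losses = fit$n_losses, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Find adjacent gene pairs from two families
#'
#' Scans each scaffold for pairs (one gene from each family) separated by at
#' most `max_intervening` genes, reporting whether they are transcribed in the
#' same orientation — the test used to establish that two related families
#' are neighbours at some locus.
#'
#' @param annotation exon-level annotation.
#' @param family_a,family_b family labels as annotated on the genes.
#' @param max_intervening maximum number of genes between the pair.
#' @return data.frame `gene_a`, `gene_b`, `scaffold`, `intervening`,
#'   `same_orientation`.
#' @export
detect_adjacent_family_pair <- function(annotation, family_a, family_b,
                                        max_intervening = 0) {
  genes <- gene_spans(annotation)
  out <- list()
  for (scf in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == scf, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    ia <- which(g$family == family_a)
    ib <- which(g$family == family_b)
    for (i in ia) for (j in ib) {
      between <- abs(i - j) - 1L
      if (between <= max_intervening)
        out[[length(out) + 1L]] <- data.frame(
          gene_a = g$gene_id[i], gene_b = g$gene_id[j], scaffold = scf,
          intervening = between,
          same_orientation = g$strand[i] == g$strand[j],
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      scaffold = character(), intervening = integer(),
                      same_orientation = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Render a text roadmap of locus evolution
#'
#' Indented depiction of the species tree; each branch lists the locus gains
#' and losses reconstructed on it, each leaf its extant locus content.
#'
#' @param presence presence matrix.
#' @param tree rooted species tree.
#' @return character vector of text lines (one per tree node), invisibly
#'   printable with `cat(..., sep = "\n")`.
#' @export
render_roadmap <- function(presence, tree) {
  tree <- ensure_node_labels(tree)
  fits <- lapply(rownames(presence), function(lc)
    dollo_reconstruct(presence[lc, ], tree))
  names(fits) <- rownames(presence)
  ch <- tree_children(tree)
  n <- ape::Ntip(tree)
  lines <- character(0)
  visit <- function(v, depth) {
    lab <- node_label(tree, v)
    gains <- names(fits)[vapply(fits, function(f) identical(f$gain, lab), TRUE)]
    losses <- names(fits)[vapply(fits, function(f) lab %in% f$losses, TRUE)]
    here <- names(fits)[vapply(fits, function(f)
      f$node_present[[lab]] == 1, TRUE)]
    ann <- c(if (length(gains)) paste0("+", gains),
             if (length(losses)) paste0("-", losses))
    lines <<- c(lines, paste0(
      strrep("  ", depth), lab,
      if (v <= n) paste0(" [", paste(here, collapse = ","), "]") else "",
      if (length(ann)) paste0("  (", paste(ann, collapse = " "), ")") else ""))
    if (v > n) for (w in ch[[v]]) visit(w, depth + 1)
  }
  visit(tree_root(tree), 0)
  lines
}
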