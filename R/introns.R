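# CDS intron position/phase analysis: extract intron sites from gene models,
# project them through a protein alignment, cluster homologous sites
# (identical column and phase) and reconstruct intron gain/loss on a tree.
# Only CDS introns are considered; untranslated-region introns need
# transcript evidence and are outside this analysis.

#' CDS intron sites of one gene model
#'
#' One site per junction between consecutive CDS exons, located at the
#' cumulative upstream CDS length. `codon_index = floor(cds_offset / 3)`
#' (0-based codon) and `phase = cds_offset mod 3`. Exons are taken in
#' transcript orientation (reverse genomic order on the minus strand).
#'
#' @param annotation exon-level annotation (possibly many genes).
#' @param gene_id gene to extract.
#' @return data.frame `gene_id`, `cds_offset`, `codon_index`, `phase`,
#'   `cds_len`; zero rows for a single-exon gene.
#' @examples
#' ann <- data.frame(gene_id = "g", species = "s", scaffold = "c",
#'                   strand = "+", start = c(0, 955), end = c(155, 1883),
#'                   exon = 1:2, symbol = "g", family = "focal",
#'                   premature_stop = FALSE, frameshift = FALSE,
#'                   low_coverage = FALSE)
#' cds_intron_sites(ann, "g")  # one site: offset 155, codon 51, phase 2
#' @export
cds_intron_sites <- function(annotation, gene_id) {
  ex <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) stop("gene not found: ", gene_id)
  ex <- ex[order(ex$exon), , drop = FALSE]
  strand <- ex$strand[1]
  genomic <- if (strand == "+") ex[order(ex$start), ] else ex[order(-ex$start), ]
  if (!identical(genomic$exon, ex$exon))
    stop("malformed gene model (exon ranks not in transcript order): ", gene_id)
  if (any(ex$end <= ex$start)) stop("malformed exon interval in ", gene_id)
  spans <- ex[order(ex$start), , drop = FALSE]
  if (nrow(spans) > 1 && any(spans$start[-1] < spans$end[-nrow(spans)]))
    stop("overlapping exons in ", gene_id)
  lens <- ex$end - ex$start
  cds_len <- sum(lens)
  if (nrow(ex) == 1)
    return(data.frame(gene_id = character(), cds_offset = integer(),
                      codon_index = integer(), phase = integer(),
                      cds_len = integer(), stringsAsFactors = FALSE))
  off <- cumsum(lens)[-nrow(ex)]
  data.frame(gene_id = gene_id, cds_offset = as.integer(off),
             codon_index = as.integer(off %/% 3), phase = as.integer(off %% 3),
             cds_len = as.integer(cds_len), stringsAsFactors = FALSE)
}

#' Intron sites for every gene of a family
#'
#' @param annotation exon-level annotation.
#' @param family restrict to this family label (`NULL` = all genes).
#' @return row-bound [cds_intron_sites()] output (may include zero-intron
#'   genes only implicitly, as absent rows).
#' @export
intron_site_table <- function(annotation, family = "focal") {
  ids <- unique(annotation$gene_id[
    if (is.null(family)) TRUE else annotation$family == family])
  do.call(rbind, lapply(ids, function(id) cds_intron_sites(annotation, id)))
}

#' Project intron sites onto a protein alignment
#'
#' A site in codon `i` (0-based) maps to the alignment column (0-based)
#' holding that row's `i`-th residue; the phase travels unchanged. Sites in
#' codons beyond the aligned row are flagged unmappable. Each gene's ungapped
#' row must have `cds_len / 3 - 1` residues (the stop codon carries no
#' residue).
#'
#' @param sites data.frame from [cds_intron_sites()]/[intron_site_table()].
#' @param msa named character vector of equal-length gapped rows; names are
#'   gene ids.
#' @return `sites` with added `column` (0-based alignment column) and
#'   `unmappable` (logical).
#' @export
project_to_alignment <- function(sites, msa) {
  if (!nrow(sites)) {
    sites$column <- integer(0); sites$unmappable <- logical(0)
    return(sites)
  }
  missing <- setdiff(unique(sites$gene_id), names(msa))
  if (length(missing))
    stop("genes absent from the alignment: ", paste(missing, collapse = ", "))
  cols <- rep(NA_integer_, nrow(sites))
  unmap <- rep(FALSE, nrow(sites))
  for (g in unique(sites$gene_id)) {
    row <- strsplit(msa[[g]], "")[[1]]
    res_cols <- which(row != "-")            # 1-based columns of residues
    i <- which(sites$gene_id == g)
    expected <- sites$cds_len[i][1] / 3 - 1
    if (length(res_cols) != expected)
      stop("alignment row / CDS length mismatch for gene ", g,
           " (", length(res_cols), " residues, expected ", expected, ")")
    ci <- sites$codon_index[i]
    ok <- ci + 1 <= length(res_cols)
    cols[i[ok]] <- res_cols[ci[ok] + 1] - 1L # 0-based
    unmap[i[!ok]] <- TRUE
  }
  sites$column <- cols
  sites$unmappable <- unmap
  sites
}

#' Cluster homologous introns
#'
#' Projected sites are homologous when they share the intron phase and their
#' alignment columns differ by at most `column_tolerance` (0 by default: the
#' strict reading, identical column and phase). With a positive tolerance,
#' clusters are single-linkage chains.
#'
#' @param projected output of [project_to_alignment()]; unmappable sites are
#'   dropped with a warning.
#' @param column_tolerance maximum column difference within a cluster link.
#' @return data.frame: `cluster` (label `ph<phase>_col<column>` of the
#'   smallest member column), `phase`, `column`, `gene_id`, `cds_offset`.
#' @export
cluster_homologous_introns <- function(projected, column_tolerance = 0) {
  if (any(projected$unmappable)) {
    warning(sum(projected$unmappable), " unmappable site(s) dropped")
    projected <- projected[!projected$unmappable, , drop = FALSE]
  }
  if (!nrow(projected))
    return(data.frame(cluster = character(), phase = integer(),
                      column = integer(), gene_id = character(),
                      cds_offset = integer(), stringsAsFactors = FALSE))
  out <- list()
  for (ph in sort(unique(projected$phase))) {
    s <- projected[projected$phase == ph, , drop = FALSE]
    s <- s[order(s$column, s$gene_id), , drop = FALSE]
    brk <- c(0, cumsum(diff(s$column) > column_tolerance))
    for (b in unique(brk)) {
      m <- s[brk == b, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        cluster = sprintf("ph%d_col%d", ph, min(m$column)),
        phase = ph, column = m$column, gene_id = m$gene_id,
        cds_offset = m$cds_offset, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Presence matrix of intron clusters over taxa
#'
#' @param clusters output of [cluster_homologous_introns()].
#' @param gene_species named character: species of each analysed gene
#'   (including zero-intron genes, which count as absences).
#' @param low_coverage species scored unknown when a cluster is absent.
#' @return integer matrix clusters x species (1/0/NA).
#' @export
intron_presence_matrix <- function(clusters, gene_species,
                                   low_coverage = character()) {
  taxa <- sort(unique(gene_species))
  cl <- unique(clusters$cluster)
  m <- matrix(0L, length(cl), length(taxa), dimnames = list(cl, taxa))
  m[, taxa %in% low_coverage] <- NA_integer_
  for (i in seq_len(nrow(clusters))) {
    sp <- gene_species[[clusters$gene_id[i]]]
    m[clusters$cluster[i], sp] <- 1L
  }
  m
}

#' Intron gain/loss reconstruction per cluster
#'
#' Runs the Dollo engine on every cluster's species presence vector and
#' reports pairs of clusters whose gain order cannot be read off the tree:
#' gains on the same branch, or on branches neither of which is ancestral to
#' the other.
#'
#' @param clusters output of [cluster_homologous_introns()].
#' @param tree rooted species tree.
#' @param gene_species named character mapping gene id to species.
#' @param low_coverage species scored unknown on absence.
#' @return list: `events` (data.frame cluster, gain, losses, n_losses),
#'   `order_ambiguous` (data.frame cluster_a, cluster_b, reason).
#' @export
intron_gain_loss <- function(clusters, tree, gene_species,
                             low_coverage = character()) {
  tree <- ensure_node_labels(tree)
  taxa <- sort(unique(gene_species))
  if (!all(taxa %in% tree$tip.label))
    stop("species absent from the tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  m <- intron_presence_matrix(clusters, gene_species, low_coverage)
  fits <- lapply(rownames(m), function(cl) dollo_reconstruct(m[cl, ], tree))
  names(fits) <- rownames(m)
  events <- do.call(rbind, lapply(rownames(m), function(cl) data.frame(
    cluster = cl, gain = fits[[cl]]$gain,
    losses = paste(fits[[cl]]$losses, collapse = ","),
    n_losses = fits[[cl]]$n_losses, stringsAsFactors = FALSE)))

  amb <- list()
  cls <- rownames(m)
  if (length(cls) > 1) {
    anc <- function(a, b) {          # is node a an ancestor of node b?
      ta <- tips_under(tree, a); tb <- tips_under(tree, b)
      length(setdiff(tb, ta)) == 0 && length(ta) > length(tb)
    }
    for (i in seq_along(cls)) for (j in seq_along(cls)) {
      if (j <= i) next
      ga <- fits[[cls[i]]]$gain_node; gb <- fits[[cls[j]]]$gain_node
      if (is.na(ga) || is.na(gb)) next
      if (ga == gb)
        amb[[length(amb) + 1L]] <- data.frame(
          cluster_a = cls[i], cluster_b = cls[j], reason = "same branch",
          stringsAsFactors = FALSE)
      else if (!anc(ga, gb) && !anc(gb, ga))
        amb[[length(amb) + 1L]] <- data.frame(
          cluster_a = cls[i], cluster_b = cls[j],
          reason = "incomparable branches", stringsAsFactors = FALSE)
    }
  }
  list(events = events,
       order_ambiguous = if (length(amb)) do.call(rbind, amb) else
         data.frame(cluster_a = character(), cluster_b = character(),
                    reason = character(), stringsAsFactors = FALSE))
}

#' Text rendering of intron maps
#'
#' One line per gene: the CDS as a scaled bar with each intron marked by its
#' phase digit at its proportional position.
#'
#' @param sites intron site table (needs `gene_id`, `cds_offset`, `phase`,
#'   `cds_len`).
#' @param gene_ids genes to draw (defaults to those in `sites`).
#' @param width bar width in characters.
#' @return character vector of lines.
#' @export
render_intron_map <- function(sites, gene_ids = NULL, width = 60) {
  if (is.null(gene_ids)) gene_ids <- unique(sites$gene_id)
  vapply(gene_ids, function(g) {
    s <- sites[sites$gene_id == g, , drop = FALSE]
    bar <- rep("-", width)
    if (nrow(s)) {
      at <- pmax(1, pmin(width, ceiling(s$cds_offset / s$cds_len * width)))
      bar[at] <- as.character(s$phase)
    }
    sprintf("%-14s |%s| %d nt", g, paste(bar, collapse = ""),
            if (nrow(s)) s$cds_len[1] else NA_integer_)
  }, "")
}
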