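# On-disk fixture format. Internal coordinates are 0-based half-open; GFF3 is
# written 1-based inclusive per the standard, with CDS phase columns derived
# from cumulative coding length. Proteins and alignments travel as FASTA,
# trees as newick, tabular evidence as TSV, anchor sets as YAML.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# GFF3 phase of each CDS exon: bases to skip to reach the next codon start
gff_phase <- function(exon_lengths) {
  up <- c(0L, cumsum(exon_lengths)[-length(exon_lengths)])
  as.integer((3L - (up %% 3L)) %% 3L)
}

#' Write one genome's annotation as GFF3
#'
#' Emits a `gene` feature per gene and a `CDS` feature per exon, phase
#' included, with `gene_id`, `symbol`, `family` and integrity flags in the
#' attribute column.
#'
#' @param genome a `fam_genome`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genome_gff3 <- function(genome, path) {
  ann <- genome$annotation
  per_gene <- split(ann, ann$gene_id)
  feats <- list()
  for (g in per_gene) {
    g <- g[order(g$exon), , drop = FALSE]
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = g$scaffold[1], start = min(g$start) + 1L, end = max(g$end),
      strand = g$strand[1], type = "gene", phase = NA_integer_,
      ID = g$gene_id[1], gene_id = g$gene_id[1], symbol = g$symbol[1],
      family = g$family[1],
      premature_stop = tolower(as.character(any(g$premature_stop))),
      frameshift = tolower(as.character(any(g$frameshift))),
      low_coverage = tolower(as.character(any(g$low_coverage))),
      exon = NA_integer_, stringsAsFactors = FALSE)
    ph <- gff_phase(g$end - g$start)
    feats[[length(feats) + 1L]] <- data.frame(
      seqnames = g$scaffold, start = g$start + 1L, end = g$end,
      strand = g$strand, type = "CDS", phase = ph,
      ID = paste0(g$gene_id, ".cds", g$exon), gene_id = g$gene_id,
      symbol = g$symbol, family = g$family,
      premature_stop = tolower(as.character(g$premature_stop)),
      frameshift = tolower(as.character(g$frameshift)),
      low_coverage = tolower(as.character(g$low_coverage)),
      exon = g$exon, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr) <- df[, setdiff(names(df),
                                       c("seqnames", "start", "end", "strand"))]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 annotation back into the exon-level table
#'
#' @param path GFF3 file written by [write_genome_gff3()] (or any GFF3 whose
#'   CDS features carry `gene_id` attributes; `symbol` defaults to the gene
#'   id and `family` to `"unknown"` when absent).
#' @param species species label to stamp on the rows.
#' @return exon-level annotation data.frame (0-based half-open coordinates).
#' @export
read_genome_gff3 <- function(path, species = NA_character_) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  mc <- S4Vectors::mcols(gr)
  get <- function(field, default) {
    if (field %in% names(mc)) {
      v <- as.character(mc[[field]])
      v[is.na(v)] <- default
      v
    } else rep(default, length(gr))
  }
  ex <- suppressWarnings(as.integer(get("exon", NA)))
  df <- data.frame(
    gene_id = get("gene_id", NA_character_),
    species = species,
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    exon = ex,
    symbol = get("symbol", NA_character_),
    family = get("family", "unknown"),
    premature_stop = get("premature_stop", "false") == "true",
    frameshift = get("frameshift", "false") == "true",
    low_coverage = get("low_coverage", "false") == "true",
    stringsAsFactors = FALSE)
  df$symbol[is.na(df$symbol)] <- df$gene_id[is.na(df$symbol)]
  # derive missing exon ranks from transcript orientation
  miss <- is.na(df$exon)
  if (any(miss)) {
    for (g in unique(df$gene_id[miss])) {
      i <- which(df$gene_id == g)
      o <- order(df$start[i], decreasing = df$strand[i[1]] == "-")
      df$exon[i[o]] <- seq_along(i)
    }
  }
  rownames(df) <- NULL
  df
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a complete simulation fixture to a directory
#'
#' Produces, per species, `genes_<species>.gff3`; plus `species_tree.nwk`,
#' `proteins.faa`, `true_msa.faa`, `scaffolds.tsv`, `event_log.tsv`,
#' `hits.tsv`, `domains.tsv`, `candidates.tsv`, `anchor_sets.yaml`, and —
#' when a linker scenario is attached (see [run_simulate()]) — `contigs.tsv`,
#' `clone_ends.tsv` and `fragmentation_truth.tsv`.
#'
#' @param sim a `fam_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "fam_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(sim$tree, file.path(dir, "species_tree.nwk"))
  if (length(sim$alignment)) {
    write_fasta(sim$alignment, file.path(dir, "proteins.faa"))
    write_fasta(sim$alignment, file.path(dir, "true_msa.faa"))
  } else {
    file.create(file.path(dir, "proteins.faa"))
    file.create(file.path(dir, "true_msa.faa"))
  }
  scf <- do.call(rbind, lapply(sim$genomes, function(g)
    cbind(species = g$species, g$scaffolds)))
  write_tsv(scf, file.path(dir, "scaffolds.tsv"))
  for (g in sim$genomes)
    write_genome_gff3(g, file.path(dir, paste0("genes_", g$species, ".gff3")))
  write_tsv(sim$event_log, file.path(dir, "event_log.tsv"))

  cls <- sim_classifier_inputs(sim)
  write_tsv(cls$meta, file.path(dir, "candidates.tsv"))
  write_tsv(cls$domains, file.path(dir, "domains.tsv"))
  write_tsv(cls$hits, file.path(dir, "hits.tsv"))
  write_tsv(sim$references[, c("subject", "family")],
            file.path(dir, "reference_families.tsv"))

  yaml::write_yaml(lapply(sim$anchors, function(s)
    list(name = s$name, anchors = as.list(s$anchors), k = s$k)),
    file.path(dir, "anchor_sets.yaml"))

  if (!is.null(sim$linker)) {
    write_tsv(sim$linker$fragmentation$contigs, file.path(dir, "contigs.tsv"))
    write_tsv(sim$linker$ends, file.path(dir, "clone_ends.tsv"))
    write_tsv(sim$linker$fragmentation$truth,
              file.path(dir, "fragmentation_truth.tsv"))
  }
  invisible(dir)
}

#' Read a fixture directory back
#'
#' Inverse of [emit_fixture()]: rebuilds the species tree, per-species
#' annotations, protein alignment and evidence tables.
#'
#' @param dir fixture directory.
#' @return list with `tree`, `annotations` (named list of exon tables),
#'   `scaffolds`, `alignment`, `event_log`, `meta`, `domains`, `hits`,
#'   `anchors`, and (when present) `contigs`, `clone_ends`,
#'   `fragmentation_truth`.
#' @export
read_fixture <- function(dir) {
  tree <- ape::read.tree(file.path(dir, "species_tree.nwk"))
  scf <- read_tsv(file.path(dir, "scaffolds.tsv"))
  gffs <- list.files(dir, pattern = "^genes_.*\\.gff3$", full.names = TRUE)
  species <- sub("^genes_(.*)\\.gff3$", "\\1", basename(gffs))
  annotations <- stats::setNames(
    lapply(seq_along(gffs), function(i) read_genome_gff3(gffs[i], species[i])),
    species)
  msa_path <- file.path(dir, "true_msa.faa")
  alignment <- if (file.size(msa_path) > 0) read_fasta(msa_path) else character(0)
  anchors <- lapply(yaml::read_yaml(file.path(dir, "anchor_sets.yaml")),
                    function(s) list(name = s$name,
                                     anchors = unlist(s$anchors),
                                     k = s$k))
  out <- list(tree = if (!is.null(tree)) ensure_node_labels(tree) else NULL,
              annotations = annotations,
              scaffolds = scf,
              alignment = alignment,
              event_log = read_tsv(file.path(dir, "event_log.tsv")),
              meta = read_tsv(file.path(dir, "candidates.tsv")),
              domains = read_tsv(file.path(dir, "domains.tsv")),
              hits = read_tsv(file.path(dir, "hits.tsv")),
              anchors = anchors)
  for (f in c("contigs", "clone_ends", "fragmentation_truth")) {
    p <- file.path(dir, paste0(f, ".tsv"))
    if (file.exists(p)) out[[f]] <- read_tsv(p)
  }
  out
}
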