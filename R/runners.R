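# File-level pipeline steps: each run_* function reads the declared input
# files, calls the module functions and writes the declared outputs. The
# command-line dispatcher (inst/cli/famtrace.R) is a thin veneer over these.

#' Simulate a fixture and write it to disk
#'
#' Builds a species tree, evolves the gene family, attaches a contig-linking
#' scenario (one independent assembly scaffold fragmented into contigs with
#' clone-end pairs re-expressed in contig frame) and emits the full fixture
#' directory.
#'
#' @param out output directory.
#' @param n_species number of species.
#' @param seed master seed for the run.
#' @param config optional YAML file with [sim_params()] overrides.
#' @param linker_scaffold_len,linker_breaks,linker_min_contig geometry of the
#'   linker scenario (defaults mirror the ten-contig case: a 1 Mb region in
#'   10 contigs, none shorter than 60 kb so every contig can anchor clone
#'   ends of 30-45 kb inserts).
#' @return the `fam_sim` object, invisibly.
#' @export
run_simulate <- function(out, n_species = 8, seed = 1, config = NULL,
                         linker_scaffold_len = 1e6, linker_breaks = 9,
                         linker_min_contig = 60000) {
  overrides <- if (!is.null(config)) yaml::read_yaml(config) else list()
  overrides$seed <- as.integer(seed)
  params <- do.call(sim_params, overrides)
  tree <- simulate_species_tree(n_species, seed = seed)
  sim <- evolve_gene_family(tree, params)
  frag <- fragment_scaffold(linker_scaffold_len, linker_breaks,
                            seed = seed + 1, scaffold = "asm",
                            min_contig_len = linker_min_contig)
  ends0 <- generate_clone_pairs(linker_scaffold_len, params, seed = seed + 2,
                                scaffold = "asm")
  sim$linker <- list(fragmentation = frag,
                     ends = map_clone_ends(ends0, frag))
  emit_fixture(sim, out)
  invisible(sim)
}

#' Catalogue candidates from evidence tables
#'
#' @param domains,hits,meta paths to the domain, similarity-hit and candidate
#'   metadata TSVs.
#' @param family focal family label.
#' @param required_domains domains every full-length member must carry.
#' @param out output directory (`classifications.tsv`, `summary.tsv`).
#' @return list with `classifications` and `summary` data.frames, invisibly.
#' @export
run_catalog <- function(domains, hits, meta, out, family = "focal",
                        required_domains = c("MACPF", "C2")) {
  dom <- read_tsv(domains); ht <- read_tsv(hits); mt <- read_tsv(meta)
  cls <- classify_table(mt, dom, ht, required_domains, family)
  tal <- tally_species(cls)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv(cls, file.path(out, "classifications.tsv"))
  write_tsv(tal, file.path(out, "summary.tsv"))
  invisible(list(classifications = cls, summary = tal))
}

#' Link contigs from clone-end evidence files
#'
#' @param contigs,ends paths to the contig-length and clone-end TSVs.
#' @param insert_min,insert_max clone insert size bounds, bp.
#' @param out output directory (`superscaffolds.tsv`, `link_conflicts.tsv`).
#' @return the [link_contigs()] result, invisibly.
#' @export
run_link <- function(contigs, ends, out, insert_min = 30000,
                     insert_max = 45000) {
  res <- link_contigs(read_tsv(contigs), read_tsv(ends),
                      c(insert_min, insert_max))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv(res$scaffolds, file.path(out, "superscaffolds.tsv"))
  conf <- res$conflicts
  write_tsv(conf, file.path(out, "link_conflicts.tsv"))
  write_tsv(res$parity_conflicts, file.path(out, "parity_conflicts.tsv"))
  invisible(res)
}

#' Locus assignment, presence matrix and ancestral roadmap
#'
#' @param gff directory of `genes_<species>.gff3` files.
#' @param tree species tree newick file.
#' @param anchors anchor-set YAML (list of name/anchors/k).
#' @param out output directory.
#' @param window neighbourhood window, genes per side.
#' @param family focal family label in the annotations.
#' @param low_coverage species whose absences are unknown.
#' @return list with `assignments`, `presence`, `dollo`, invisibly.
#' @export
run_synteny <- function(gff, tree, anchors, out, window = 10,
                        family = "focal", low_coverage = character()) {
  tr <- ensure_node_labels(ape::read.tree(tree))
  anc <- lapply(yaml::read_yaml(anchors), function(s)
    list(name = s$name, anchors = unlist(s$anchors), k = s$k))
  gffs <- list.files(gff, pattern = "^genes_.*\\.gff3$", full.names = TRUE)
  species <- sub("^genes_(.*)\\.gff3$", "\\1", basename(gffs))
  rows <- list()
  for (i in seq_along(gffs)) {
    ann <- read_genome_gff3(gffs[i], species[i])
    for (gid in unique(ann$gene_id[ann$family == family])) {
      prof <- extract_neighborhood(ann, gid, window)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, species = species[i],
        locus = assign_locus(prof, anc), stringsAsFactors = FALSE)
    }
  }
  assignments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), species = character(),
               locus = character(), stringsAsFactors = FALSE)
  presence <- build_presence_matrix(assignments, tr$tip.label,
                                    low_coverage = low_coverage)
  dollo <- locus_dollo_report(presence, tr)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv(assignments, file.path(out, "locus_assignments.tsv"))
  pm <- data.frame(locus = rownames(presence), presence,
                   check.names = FALSE, stringsAsFactors = FALSE)
  pm[is.na(pm)] <- "?"
  write_tsv(pm, file.path(out, "presence_matrix.tsv"))
  write_tsv(dollo, file.path(out, "dollo_report.tsv"))
  writeLines(render_roadmap(presence, tr), file.path(out, "roadmap.txt"))
  invisible(list(assignments = assignments, presence = presence,
                 dollo = dollo))
}

#' Intron site extraction, clustering and gain/loss inference
#'
#' @param gff directory of `genes_<species>.gff3` files.
#' @param msa aligned FASTA of the family proteins.
#' @param tree species tree newick file.
#' @param out output directory.
#' @param tolerance column tolerance for intron homology.
#' @param family focal family label.
#' @param low_coverage species scored unknown on absence.
#' @return list with `sites`, `clusters`, `events`, invisibly.
#' @export
run_introns <- function(gff, msa, tree, out, tolerance = 0,
                        family = "focal", low_coverage = character()) {
  tr <- ensure_node_labels(ape::read.tree(tree))
  aln <- read_fasta(msa)
  gffs <- list.files(gff, pattern = "^genes_.*\\.gff3$", full.names = TRUE)
  species <- sub("^genes_(.*)\\.gff3$", "\\1", basename(gffs))
  anns <- lapply(seq_along(gffs), function(i)
    read_genome_gff3(gffs[i], species[i]))
  ann <- do.call(rbind, anns)
  sites <- intron_site_table(ann, family = family)
  if (is.null(sites)) sites <- data.frame(
    gene_id = character(), cds_offset = integer(), codon_index = integer(),
    phase = integer(), cds_len = integer(), stringsAsFactors = FALSE)
  proj <- project_to_alignment(sites, aln)
  clusters <- cluster_homologous_introns(proj, tolerance)
  fam_genes <- unique(ann$gene_id[ann$family == family])
  gene_species <- stats::setNames(
    ann$species[match(fam_genes, ann$gene_id)], fam_genes)
  gl <- intron_gain_loss(clusters, tr, gene_species, low_coverage)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_tsv(proj, file.path(out, "intron_sites.tsv"))
  write_tsv(clusters, file.path(out, "intron_clusters.tsv"))
  write_tsv(gl$events, file.path(out, "intron_events.tsv"))
  write_tsv(gl$order_ambiguous, file.path(out, "intron_order_ambiguous.tsv"))
  writeLines(render_intron_map(sites, gene_ids = fam_genes),
             file.path(out, "intron_map.txt"))
  invisible(list(sites = proj, clusters = clusters, events = gl$events,
                 order_ambiguous = gl$order_ambiguous))
}

#' Distance tree, midpoint rooting, NEXUS export, concordance
#'
#' @param msa aligned FASTA.
#' @param out output directory (`gene_tree.nwk`, `alignment.nex`, and
#'   `concordance.tsv` when locus assignments are supplied).
#' @param correction distance correction, `"p"` or `"poisson"`.
#' @param loci optional `locus_assignments.tsv` (from [run_synteny()]) to
#'   score clade/locus concordance on the rooted tree.
#' @return list with `tree` and optional `concordance`, invisibly.
#' @export
run_tree <- function(msa, out, correction = "poisson", loci = NULL) {
  aln <- read_fasta(msa)
  stripped <- strip_gap_columns(aln)$alignment
  d <- distance_matrix(stripped, correction)
  tr <- midpoint_root(nj_tree(d))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(tr, file.path(out, "gene_tree.nwk"))
  export_nexus(aln, file.path(out, "alignment.nex"))
  res <- list(tree = tr)
  if (!is.null(loci)) {
    asg <- read_tsv(loci)
    lv <- stats::setNames(asg$locus[match(tr$tip.label, asg$gene_id)],
                          tr$tip.label)
    cc <- clade_locus_concordance(tr, lv)
    names(cc$per_locus) <- c("locus", "n", "monophyletic")
    write_tsv(cc$per_locus, file.path(out, "concordance.tsv"))
    res$concordance <- cc
  }
  invisible(res)
}
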