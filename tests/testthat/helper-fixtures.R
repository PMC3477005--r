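# Shared fixtures, built once per test run.

.fx <- new.env(parent = emptyenv())

# mid-sized simulation reused by several test files
shared_sim <- function() {
  if (is.null(.fx$sim)) {
    tr <- simulate_species_tree(6, seed = 4)
    .fx$sim <- evolve_gene_family(tr, sim_params(
      seed = 4, rate_dup_local = 0.4, rate_dup_distal = 0.3,
      rate_loss = 0.1, rate_pseudogenize = 0.2))
  }
  .fx$sim
}

# full fixture directory written by run_simulate
shared_fixture_dir <- function() {
  if (is.null(.fx$dir)) {
    .fx$dir <- file.path(tempdir(), "famtrace-fixture")
    run_simulate(.fx$dir, n_species = 6, seed = 4)
  }
  .fx$dir
}

# hand-built exon-level annotation row(s)
ann_rows <- function(gene_id, scaffold, strand, starts, ends,
                     symbol = gene_id, family = "focal", species = "sp",
                     premature_stop = FALSE) {
  data.frame(gene_id = gene_id, species = species, scaffold = scaffold,
             strand = strand, start = starts, end = ends,
             exon = seq_along(starts), symbol = symbol, family = family,
             premature_stop = premature_stop, frameshift = FALSE,
             low_coverage = FALSE, stringsAsFactors = FALSE)
}

# random multi-exon plus-or-minus strand gene model with known intron offsets
random_gene_model <- function(id = "g", n_exons = sample(1:8, 1),
                              strand = sample(c("+", "-"), 1)) {
  lens <- sample(30:300, n_exons, replace = TRUE)
  cds <- sum(lens)
  intron <- 100
  if (strand == "+") {
    starts <- integer(n_exons); ends <- integer(n_exons)
    cur <- 0
    for (k in seq_len(n_exons)) {
      starts[k] <- cur; ends[k] <- cur + lens[k]; cur <- ends[k] + intron
    }
  } else {
    starts <- integer(n_exons); ends <- integer(n_exons)
    cur <- sum(lens) + intron * n_exons
    for (k in seq_len(n_exons)) {
      ends[k] <- cur; starts[k] <- cur - lens[k]; cur <- starts[k] - intron
    }
  }
  list(ann = ann_rows(id, "scf", strand, starts, ends),
       exon_lens = lens,
       true_offsets = if (n_exons > 1) cumsum(lens)[-n_exons] else integer(0))
}

# random binary presence pattern as named vector from an integer bitmask
bit_pattern <- function(i, tips) {
  stats::setNames(as.numeric(intToBits(i)[seq_along(tips)]), tips)
}
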