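# Gene-family evolution simulator.
#
# A single focal gene family evolves along a species tree inside a set of
# conserved anchor-gene neighbourhoods ("loci"). Events are drawn per branch
# as independent Poisson processes; every applied event is recorded in an
# event log keyed by branch (child-node label), the ground-truth channel for
# all recovery tests downstream.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation parameters
#'
#' Rates are events per unit branch length (expected substitutions per site,
#' matching the species-tree branch lengths). Protein sites substitute at rate
#' 1 per unit branch length under a flat replacement model with no indels, so
#' the true protein alignment of the family is the ungapped stack of leaf
#' sequences and intron positions remain directly comparable across genes.
#'
#' Intron gains follow an infinite-sites rule: each gain draws its CDS offset
#' from the family-wide pool of never-used offsets, so identical position and
#' phase always means common descent (the assumption under which conserved
#' introns are linked across genes).
#'
#' @param rate_dup_local,rate_dup_distal,rate_loss,rate_pseudogenize
#'   gene-level event rates; a local duplication inserts the copy next to its
#'   template, a distal duplication inserts it into a different anchor
#'   neighbourhood, pseudogenization plants one premature stop codon at a
#'   uniform position.
#' @param rate_intron_gain,rate_intron_loss intron event rates.
#' @param anchor_genes_per_locus conserved flanking genes per locus.
#' @param n_loci number of anchor neighbourhoods available.
#' @param insert_size_range clone insert length interval in bp (BAC/fosmid
#'   scale by default).
#' @param clone_coverage mean number of clone inserts covering a scaffold
#'   position.
#' @param seed integer RNG seed.
#' @param protein_length focal protein length in residues.
#' @param intron_length genomic length of every simulated intron, bp.
#' @param root_introns CDS offsets (nt) of the ancestral introns carried by the
#'   root gene; the default single offset 155 is the canonical configuration
#'   (one intron after 155 coding nucleotides: codon 51, phase 2).
#' @param init_loci number of family copies present at the root, one per locus
#'   `L1..L<init_loci>` (an ancestrally multi-copy family).
#' @param init_divergence branch length separating the root copies before the
#'   species root (0 = identical root copies).
#' @param dup_scope `"all"` draws duplications on every branch; `"terminal"`
#'   restricts them to terminal branches, emulating purely species-specific
#'   duplication scenarios.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(rate_dup_local = 0.3,
                       rate_dup_distal = 0.15,
                       rate_loss = 0.1,
                       rate_pseudogenize = 0.1,
                       rate_intron_gain = 0.5,
                       rate_intron_loss = 0.1,
                       anchor_genes_per_locus = 4,
                       n_loci = 6,
                       insert_size_range = c(30000, 45000),
                       clone_coverage = 5,
                       seed = 1L,
                       protein_length = 360,
                       intron_length = 750,
                       root_introns = 155L,
                       init_loci = 1,
                       init_divergence = 0,
                       dup_scope = c("all", "terminal")) {
  p <- list(
    rate_dup_local = rate_dup_local, rate_dup_distal = rate_dup_distal,
    rate_loss = rate_loss, rate_pseudogenize = rate_pseudogenize,
    rate_intron_gain = rate_intron_gain, rate_intron_loss = rate_intron_loss,
    anchor_genes_per_locus = as.integer(anchor_genes_per_locus),
    n_loci = as.integer(n_loci),
    insert_size_range = as.numeric(insert_size_range),
    clone_coverage = clone_coverage,
    seed = as.integer(seed),
    protein_length = as.integer(protein_length),
    intron_length = as.integer(intron_length),
    root_introns = sort(as.integer(root_introns)),
    init_loci = as.integer(init_loci),
    init_divergence = init_divergence,
    dup_scope = match.arg(dup_scope)
  )
  rates <- unlist(p[grep("^rate_", names(p))])
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (length(p$insert_size_range) != 2 ||
      p$insert_size_range[1] >= p$insert_size_range[2])
    stop("insert_size_range must be c(min, max) with min < max")
  if (p$n_loci < p$init_loci) stop("n_loci must be >= init_loci")
  if (p$anchor_genes_per_locus < 1) stop("anchor_genes_per_locus must be >= 1")
  cds_len <- 3L * (p$protein_length + 1L)
  if (length(p$root_introns) &&
      (min(p$root_introns) <= 0 || max(p$root_introns) >= cds_len))
    stop("root_introns must lie strictly inside the CDS")
  class(p) <- "sim_params"
  p
}

# point substitutions on a residue vector: Poisson(dt * L) events, each picks
# a site and replaces it with a uniformly random different residue
mutate_protein <- function(prot, dt) {
  if (dt <= 0) return(prot)
  k <- stats::rpois(1, dt * length(prot))
  if (k == 0) return(prot)
  pos <- sample.int(length(prot), k, replace = TRUE)
  for (i in pos) {
    prot[i] <- sample(AA_ALPHABET[AA_ALPHABET != prot[i]], 1)
  }
  prot
}

new_gene <- function(id, locus, pos, ori, introns, prot) {
  list(id = id, locus = locus, pos = pos, ori = ori,
       introns = introns, prot = prot, pseudo = FALSE, stop_at = NA_integer_)
}

#' Evolve a gene family along a species tree
#'
#' Starts from `init_loci` root copies (each carrying the ancestral introns)
#' and applies, on every branch, substitutions plus Poisson-distributed
#' duplication, loss, pseudogenization and intron gain/loss events in
#' time order. Leaf states are materialised into coordinate genomes: one
#' scaffold per locus per species holding the shared anchor genes and the
#' surviving family members.
#'
#' @param tree rooted `phylo` species tree (see [simulate_species_tree()]).
#' @param params a [sim_params()] object; `params$seed` seeds the run.
#' @return an object of class `fam_sim`: list with elements `tree`, `params`,
#'   `genomes` (per-species `fam_genome`), `event_log` (one row per applied
#'   event: `event`, `branch`, `gene`, `src_gene`, `locus`, `cds_offset`,
#'   `phase`), `alignment` (true ungapped protein MSA, named character),
#'   `references` (similarity-search reference proteins) and `anchors`
#'   (per-locus anchor symbol sets).
#' @export
evolve_gene_family <- function(tree, params = sim_params()) {
  stopifnot(inherits(tree, "phylo"), inherits(params, "sim_params"))
  tree <- ensure_node_labels(tree)
  set.seed(params$seed)
  L <- params$protein_length
  cds_len <- 3L * (L + 1L)

  root_prot <- sample(AA_ALPHABET, L, replace = TRUE)
  decoy <- root_prot
  flip <- sample.int(L, round(L / 2))
  for (i in flip) decoy[i] <- sample(AA_ALPHABET[AA_ALPHABET != decoy[i]], 1)

  env <- new.env(parent = emptyenv())
  env$counter <- params$init_loci
  env$events <- list()
  env$used_offsets <- params$root_introns
  env$genomes <- list()

  record <- function(event, branch, gene, src_gene = NA_character_,
                     locus = NA_character_, cds_offset = NA_integer_,
                     phase = NA_integer_) {
    env$events[[length(env$events) + 1L]] <- data.frame(
      event = event, branch = branch, gene = gene, src_gene = src_gene,
      locus = locus, cds_offset = cds_offset, phase = phase,
      stringsAsFactors = FALSE)
  }

  next_id <- function() {
    env$counter <- env$counter + 1L
    sprintf("g%04d", env$counter)
  }

  init_genes <- lapply(seq_len(params$init_loci), function(i) {
    prot <- root_prot
    if (params$init_divergence > 0)
      prot <- mutate_protein(prot, params$init_divergence)
    new_gene(sprintf("g%04d", i), i, 0, 1L, params$root_introns, prot)
  })

  apply_event <- function(genes, type, branch) {
    n <- length(genes)
    if (type %in% c("dup_local", "dup_distal", "loss")) {
      if (n == 0) return(genes)
      gi <- sample.int(n, 1)
      g <- genes[[gi]]
      if (type == "loss") {
        record("loss", branch, g$id)
        return(genes[-gi])
      }
      cp <- g
      cp$id <- next_id()
      if (type == "dup_local") {
        # insert the copy between its template and the next family member
        pos_here <- sort(vapply(genes, function(x)
          if (x$locus == g$locus) x$pos else NA_real_, 0), na.last = NA)
        nxt <- pos_here[pos_here > g$pos]
        cp$pos <- if (length(nxt)) (g$pos + min(nxt)) / 2 else g$pos + 1
      } else {
        others <- setdiff(seq_len(params$n_loci), g$locus)
        if (!length(others)) return(genes)  # nowhere to jump
        cp$locus <- if (length(others) == 1) others else sample(others, 1)
        cp$pos <- stats::runif(1)
      }
      record(type, branch, cp$id, src_gene = g$id,
             locus = paste0("L", cp$locus))
      return(c(genes, list(cp)))
    }
    if (type == "pseudogenize") {
      ok <- which(!vapply(genes, `[[`, TRUE, "pseudo"))
      if (!length(ok)) return(genes)
      gi <- if (length(ok) == 1) ok else sample(ok, 1)
      genes[[gi]]$pseudo <- TRUE
      genes[[gi]]$stop_at <- sample.int(L - 1L, 1)
      record("pseudogenize", branch, genes[[gi]]$id)
      return(genes)
    }
    if (type == "intron_gain") {
      if (n == 0) return(genes)
      gi <- sample.int(n, 1)
      # infinite-sites: never reuse an offset anywhere in the family, and stay
      # inside the translated codons (offsets 1 .. 3L-1)
      cand <- setdiff(seq_len(3L * L - 1L), env$used_offsets)
      if (!length(cand)) return(genes)
      off <- if (length(cand) == 1) cand else sample(cand, 1)
      genes[[gi]]$introns <- sort(c(genes[[gi]]$introns, off))
      env$used_offsets <- c(env$used_offsets, off)
      record("intron_gain", branch, genes[[gi]]$id,
             cds_offset = off, phase = off %% 3L)
      return(genes)
    }
    if (type == "intron_loss") {
      carriers <- which(vapply(genes, function(x) length(x$introns) > 0, TRUE))
      if (!length(carriers)) return(genes)
      gi <- if (length(carriers) == 1) carriers else sample(carriers, 1)
      ii <- sample.int(length(genes[[gi]]$introns), 1)
      off <- genes[[gi]]$introns[ii]
      genes[[gi]]$introns <- genes[[gi]]$introns[-ii]
      record("intron_loss", branch, genes[[gi]]$id,
             cds_offset = off, phase = off %% 3L)
      return(genes)
    }
    genes
  }

  evolve_branch <- function(genes, t, branch, is_tip) {
    if (t <= 0) return(genes)
    dup_ok <- params$dup_scope == "all" || is_tip
    rates <- c(
      dup_local = if (dup_ok) params$rate_dup_local else 0,
      dup_distal = if (dup_ok) params$rate_dup_distal else 0,
      loss = params$rate_loss,
      pseudogenize = params$rate_pseudogenize,
      intron_gain = params$rate_intron_gain,
      intron_loss = params$rate_intron_loss)
    counts <- stats::rpois(length(rates), rates * t)
    types <- rep(names(rates), counts)
    n_ev <- length(types)
    if (n_ev == 0) {
      genes <- lapply(genes, function(g) { g$prot <- mutate_protein(g$prot, t); g })
      return(genes)
    }
    times <- sort(stats::runif(n_ev, 0, t))
    types <- sample(types)          # random interleaving of event kinds
    prev <- 0
    for (i in seq_len(n_ev)) {
      dt <- times[i] - prev
      genes <- lapply(genes, function(g) { g$prot <- mutate_protein(g$prot, dt); g })
      genes <- apply_event(genes, types[i], branch)
      prev <- times[i]
    }
    lapply(genes, function(g) { g$prot <- mutate_protein(g$prot, t - prev); g })
  }

  children <- tree_children(tree)
  ntip <- ape::Ntip(tree)
  blen <- structure(tree$edge.length, names = tree$edge[, 2])

  recurse <- function(node, genes) {
    if (node <= ntip) {
      env$genomes[[tree$tip.label[node]]] <-
        build_genome(tree$tip.label[node], genes, params)
      return(invisible())
    }
    for (ch in children[[node]]) {
      gch <- evolve_branch(genes, blen[[as.character(ch)]],
                           node_label(tree, ch), ch <= ntip)
      recurse(ch, gch)
    }
  }
  recurse(tree_root(tree), init_genes)

  log_df <- if (length(env$events)) {
    do.call(rbind, env$events)
  } else {
    data.frame(event = character(), branch = character(), gene = character(),
               src_gene = character(), locus = character(),
               cds_offset = integer(), phase = integer(),
               stringsAsFactors = FALSE)
  }

  genomes <- env$genomes[tree$tip.label]
  alignment <- unlist(lapply(genomes, function(g) g$proteins))
  names(alignment) <- unlist(lapply(genomes, function(g) names(g$proteins)))

  out <- list(
    tree = tree, params = params, genomes = genomes, event_log = log_df,
    alignment = alignment,
    references = data.frame(
      subject = c("REF_FOCAL", "REF_OUT"),
      family = c("focal", "other"),
      seq = c(paste(root_prot, collapse = ""), paste(decoy, collapse = "")),
      stringsAsFactors = FALSE),
    anchors = anchor_sets(params)
  )
  class(out) <- "fam_sim"
  out
}

# shared anchor symbol sets, identical in every species
anchor_sets <- function(params) {
  sets <- lapply(seq_len(params$n_loci), function(i)
    list(name = paste0("L", i),
         anchors = paste0("ANC", i, "_", seq_len(params$anchor_genes_per_locus)),
         k = 1L))
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

# Materialise one species' gene list into genomic coordinates.
# Coordinates are 0-based half-open; one scaffold per locus; anchors flank the
# family members (half upstream, half downstream) with fixed alternating
# orientations shared across species.
build_genome <- function(species, genes, params) {
  a <- params$anchor_genes_per_locus
  gap <- 2000L
  anchor_len <- 900L
  cds_len <- 3L * (params$protein_length + 1L)

  scaffolds <- character(0)
  sc_len <- integer(0)
  rows <- list()
  prots <- character(0)

  add_exon <- function(gene_id, scaffold, strand, start, end, exon, symbol,
                       family, pseudo = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, species = species, scaffold = scaffold,
      strand = strand, start = start, end = end, exon = exon,
      symbol = symbol, family = family, premature_stop = pseudo,
      frameshift = FALSE, low_coverage = FALSE, stringsAsFactors = FALSE)
  }

  for (loc in seq_len(params$n_loci)) {
    scf <- paste0(species, "_L", loc)
    n_up <- ceiling(a / 2)
    focal_here <- Filter(function(g) g$locus == loc, genes)
    ord <- order(vapply(focal_here, `[[`, 0, "pos"),
                 vapply(focal_here, `[[`, "", "id"))
    focal_here <- focal_here[ord]

    cursor <- gap
    place_anchor <- function(k) {
      sym <- paste0("ANC", loc, "_", k)
      strand <- if (k %% 2 == 1) "+" else "-"
      add_exon(paste0(species, "_", sym), scf, strand,
               cursor, cursor + anchor_len, 1L, sym, "anchor")
      cursor <<- cursor + anchor_len + gap
    }
    for (k in seq_len(n_up)) place_anchor(k)
    for (g in focal_here) {
      strand <- if (g$ori > 0) "+" else "-"
      offs <- sort(g$introns)
      segs <- diff(c(0L, offs, cds_len))
      glen <- cds_len + params$intron_length * length(offs)
      gid <- paste0(species, "_", g$id)
      for (k in seq_along(segs)) {
        up_cds <- if (k == 1) 0L else sum(segs[seq_len(k - 1)])
        up_genomic <- up_cds + (k - 1L) * params$intron_length
        if (strand == "+") {
          s <- cursor + up_genomic
          e <- s + segs[k]
        } else {
          e <- cursor + glen - up_genomic
          s <- e - segs[k]
        }
        add_exon(gid, scf, strand, s, e, k, g$id, "focal", g$pseudo)
      }
      prots[gid] <- paste(g$prot, collapse = "")
      cursor <- cursor + glen + gap
    }
    for (k in seq(n_up + 1, length.out = a - n_up)) place_anchor(k)
    scaffolds <- c(scaffolds, scf)
    sc_len <- c(sc_len, cursor + gap)
  }

  ann <- do.call(rbind, rows)
  out <- list(species = species,
              scaffolds = data.frame(scaffold = scaffolds, length = sc_len,
                                     stringsAsFactors = FALSE),
              annotation = ann, proteins = prots)
  class(out) <- "fam_genome"
  out
}

#' Replay an event log into per-species gene states
#'
#' Independent reconstruction of each leaf's family content (gene identities,
#' locus, pseudogene state, intron offsets) from the event log alone. Used as
#' the truth channel when testing that simulated genomes, classifications and
#' intron maps agree with the recorded events.
#'
#' @param sim a `fam_sim` object.
#' @return named list (per species) of data.frames with columns `gene`,
#'   `locus`, `pseudo`, `introns` (comma-joined CDS offsets).
#' @export
replay_event_log <- function(sim) {
  stopifnot(inherits(sim, "fam_sim"))
  tree <- sim$tree
  log <- sim$event_log
  log$ord <- seq_len(nrow(log))
  params <- sim$params
  init <- lapply(seq_len(params$init_loci), function(i)
    list(id = sprintf("g%04d", i), locus = paste0("L", i), pseudo = FALSE,
         introns = params$root_introns))

  apply_log_row <- function(genes, r) {
    idx <- match(TRUE, vapply(genes, function(g) g$id == r$gene, TRUE))
    if (r$event %in% c("dup_local", "dup_distal")) {
      src <- match(TRUE, vapply(genes, function(g) g$id == r$src_gene, TRUE))
      cp <- genes[[src]]
      cp$id <- r$gene
      if (r$event == "dup_distal") cp$locus <- r$locus
      return(c(genes, list(cp)))
    }
    if (r$event == "loss") return(genes[-idx])
    if (r$event == "pseudogenize") { genes[[idx]]$pseudo <- TRUE; return(genes) }
    if (r$event == "intron_gain") {
      genes[[idx]]$introns <- sort(c(genes[[idx]]$introns, r$cds_offset))
      return(genes)
    }
    if (r$event == "intron_loss") {
      genes[[idx]]$introns <- setdiff(genes[[idx]]$introns, r$cds_offset)
      return(genes)
    }
    genes
  }

  children <- tree_children(tree)
  ntip <- ape::Ntip(tree)
  out <- list()
  recurse <- function(node, genes) {
    if (node <= ntip) {
      sp <- tree$tip.label[node]
      out[[sp]] <<- if (length(genes)) data.frame(
        gene = vapply(genes, `[[`, "", "id"),
        locus = vapply(genes, `[[`, "", "locus"),
        pseudo = vapply(genes, `[[`, TRUE, "pseudo"),
        introns = vapply(genes, function(g)
          paste(sort(g$introns), collapse = ","), ""),
        stringsAsFactors = FALSE)
      else data.frame(gene = character(), locus = character(),
                      pseudo = logical(), introns = character(),
                      stringsAsFactors = FALSE)
      return(invisible())
    }
    for (ch in children[[node]]) {
      lab <- node_label(tree, ch)
      gch <- genes
      br <- log[log$branch == lab, , drop = FALSE]
      if (nrow(br)) {
        br <- br[order(br$ord), , drop = FALSE]
        for (i in seq_len(nrow(br))) gch <- apply_log_row(gch, br[i, ])
      }
      recurse(ch, gch)
    }
  }
  # locus labels in replay are "L<j>"; initial genes already use them
  init <- lapply(init, function(g) g)
  recurse(tree_root(tree), init)
  out[tree$tip.label]
}

#' @export
print.fam_sim <- function(x, ...) {
  cat("Gene family simulation\n")
  cat("  species:", length(x$genomes), " loci:", x$params$n_loci, "\n")
  cat("  events recorded:", nrow(x$event_log), "\n")
  ng <- vapply(x$genomes, function(g) length(g$proteins), 0L)
  cat("  family genes per species:",
      paste(sprintf("%s=%d", names(ng), ng), collapse = " "), "\n")
  invisible(x)
}
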