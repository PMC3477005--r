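three_gene_scaffold <- function(strand_focal = "+", strand_nb = "-") {
  rbind(
    ann_rows("up1", "scf", "+", 0, 900, symbol = "ANC1_1", family = "anchor"),
    ann_rows("focal", "scf", strand_focal, 3000, 4000),
    ann_rows("down1", "scf", strand_nb, 6000, 6900, symbol = "ANC1_2",
             family = "anchor"))
}

test_that("neighbourhoods are re-expressed in the focal gene's frame", {
  prof <- extract_neighborhood(three_gene_scaffold("+", "-"), "focal")
  up <- prof$flanks[prof$flanks$side == "up", ]
  dn <- prof$flanks[prof$flanks$side == "down", ]
  expect_equal(up$symbol, "ANC1_1")
  expect_equal(dn$symbol, "ANC1_2")
  expect_equal(dn$rel_orientation, "opposite")
  expect_equal(dn$dist_bp, 2000)

  # minus-strand focal gene: genomic downstream becomes the upstream flank,
  # and a minus-strand neighbour is now same-orientation
  prof2 <- extract_neighborhood(three_gene_scaffold("-", "-"), "focal")
  up2 <- prof2$flanks[prof2$flanks$side == "up", ]
  expect_equal(up2$symbol, "ANC1_2")
  expect_equal(up2$rel_orientation, "same")
})

test_that("flanks truncate at scaffold ends and respect the window", {
  ann <- do.call(rbind, lapply(1:7, function(i)
    ann_rows(paste0("g", i), "scf", "+", i * 2000, i * 2000 + 900,
             symbol = paste0("S", i),
             family = if (i == 1) "focal" else "anchor")))
  prof <- extract_neighborhood(ann, "g1", window = 10)
  expect_equal(nrow(prof$flanks[prof$flanks$side == "up", ]), 0)
  profw <- extract_neighborhood(
    within(ann, family[4] <- "focal"), "g4", window = 2)
  expect_lte(nrow(profw$flanks), 4)
  expect_error(extract_neighborhood(ann, "nope"), "not found")
})

test_that("locus assignment scores anchor sets and reports NOVEL/AMBIGUOUS", {
  sets <- list(
    list(name = "PRF", anchors = c("ADAMTS14", "c10orf27", "KIAA1274"), k = 1),
    list(name = "STX1b", anchors = c("STX1b", "STX4"), k = 1))
  ann <- rbind(
    ann_rows("a", "s", "+", 0, 900, symbol = "ADAMTS14", family = "anchor"),
    ann_rows("f", "s", "+", 2000, 3000),
    ann_rows("b", "s", "+", 5000, 5900, symbol = "c10orf27",
             family = "anchor"))
  expect_equal(assign_locus(extract_neighborhood(ann, "f"), sets), "PRF")

  lone <- ann_rows("f", "s", "+", 0, 1000)
  expect_equal(assign_locus(extract_neighborhood(lone, "f"), sets), "NOVEL")

  tied <- rbind(
    ann_rows("a", "s", "+", 0, 900, symbol = "ADAMTS14", family = "anchor"),
    ann_rows("f", "s", "+", 2000, 3000),
    ann_rows("b", "s", "+", 5000, 5900, symbol = "STX4", family = "anchor"))
  expect_equal(assign_locus(extract_neighborhood(tied, "f"), sets),
               "AMBIGUOUS")
})

test_that("locus assignment is invariant under scaffold reverse-complement", {
  sim <- shared_sim()
  sets <- sim$anchors
  sp <- names(sim$genomes)[1]
  ann <- sim$genomes[[sp]]$annotation
  focal <- unique(ann$gene_id[ann$family == "focal"])
  # reverse-complement every scaffold: mirror coordinates, flip strands
  rc <- ann
  for (scf in unique(ann$scaffold)) {
    i <- ann$scaffold == scf
    L <- max(ann$end[i]) + 1000
    rc$start[i] <- L - ann$end[i]
    rc$end[i] <- L - ann$start[i]
    rc$strand[i] <- ifelse(ann$strand[i] == "+", "-", "+")
  }
  for (g in focal) {
    a1 <- assign_locus(extract_neighborhood(ann, g), sets)
    a2 <- assign_locus(extract_neighborhood(rc, g), sets)
    expect_identical(a1, a2, label = g)
  }
})

test_that("presence matrices encode 1, 0 and unknown states", {
  asg <- data.frame(species = c("a", "c", "c"),
                    locus = c("L1", "L1", "L2"))
  m <- build_presence_matrix(asg, taxa = c("a", "b", "c", "d"),
                             low_coverage = "d")
  expect_equal(dim(m), c(2, 4))
  expect_equal(m["L1", "a"], 1L)
  expect_equal(m["L1", "b"], 0L)
  expect_equal(unname(m[, "c"]), c(1L, 1L))
  expect_true(all(is.na(m[, "d"])))

  one <- build_presence_matrix(data.frame(species = "a", locus = "L1"), "a")
  expect_equal(dim(one), c(1, 1))
  expect_equal(one[1, 1], 1L)
})

test_that("adjacent family pairs report intervening count and orientation", {
  ann <- rbind(
    ann_rows("mpeg", "s", "+", 0, 900, family = "partner"),
    ann_rows("prf", "s", "+", 2000, 3000),
    ann_rows("far", "s2", "+", 0, 900, family = "partner"))
  rec <- detect_adjacent_family_pair(ann, "partner", "focal",
                                     max_intervening = 0)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$intervening, 0)
  expect_true(rec$same_orientation)

  opp <- within(ann, strand[2] <- "-")
  rec2 <- detect_adjacent_family_pair(opp, "partner", "focal", 0)
  expect_false(rec2$same_orientation)
})

test_that("distal duplication branches are recovered from synteny + Dollo", {
  tr <- simulate_species_tree(8, seed = 14)
  sim <- evolve_gene_family(tr, sim_params(
    seed = 14, rate_dup_distal = 0.8, rate_dup_local = 0, rate_loss = 0,
    rate_pseudogenize = 0, rate_intron_gain = 0))
  dups <- sim$event_log[sim$event_log$event == "dup_distal", ]
  expect_gt(nrow(dups), 0)
  rows <- list()
  for (sp in names(sim$genomes)) {
    ann <- sim$genomes[[sp]]$annotation
    for (g in unique(ann$gene_id[ann$family == "focal"]))
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, locus = assign_locus(
          extract_neighborhood(ann, g), sim$anchors))
  }
  asg <- do.call(rbind, rows)
  m <- build_presence_matrix(asg, tr$tip.label)
  rep <- locus_dollo_report(m, tr)
  # each derived locus with no subsequent erasure should gain on the branch
  # where the event log placed the duplication
  ancestral <- paste0("L", seq_len(sim$params$init_loci))
  for (i in seq_len(nrow(dups))) {
    lc <- dups$locus[i]
    if (!lc %in% rownames(m) || lc %in% ancestral) next
    # only check loci created exactly once and never lost
    if (sum(dups$locus == lc) != 1) next
    if (any(sim$event_log$event == "loss")) next
    expect_equal(rep$gain[rep$locus == lc], dups$branch[i], label = lc)
  }
})
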