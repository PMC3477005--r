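test_that("intron sites sit at exon junctions with offset-consistent phase", {
  one <- ann_rows("g1", "s", "+", 0, 1083)
  expect_equal(nrow(cds_intron_sites(one, "g1")), 0)

  # canonical configuration: first exon 155 nt -> codon 51, phase 2
  two <- ann_rows("g2", "s", "+", c(0, 955), c(155, 1883))
  s <- cds_intron_sites(two, "g2")
  expect_equal(s$cds_offset, 155)
  expect_equal(s$codon_index, 51)
  expect_equal(s$phase, 2)

  ten <- random_gene_model("g3", n_exons = 10, strand = "+")
  s10 <- cds_intron_sites(ten$ann, "g3")
  expect_equal(nrow(s10), 9)
  expect_equal(s10$cds_offset, ten$true_offsets)
})

test_that("phase equals cds_offset mod 3 for random gene models on both strands", {
  set.seed(11)
  for (i in 1:40) {
    gm <- random_gene_model(paste0("r", i))
    s <- cds_intron_sites(gm$ann, paste0("r", i))
    expect_equal(s$cds_offset, gm$true_offsets)
    expect_equal(s$phase, s$cds_offset %% 3)
    expect_equal(s$codon_index, s$cds_offset %/% 3)
    expect_true(all(s$cds_offset > 0 & s$cds_offset < s$cds_len))
  }
})

test_that("malformed exon sets are rejected", {
  overlap <- ann_rows("g", "s", "+", c(0, 100), c(155, 300))
  expect_error(cds_intron_sites(overlap, "g"), "overlap")
  disordered <- ann_rows("g", "s", "+", c(500, 0), c(650, 155))
  expect_error(cds_intron_sites(disordered, "g"), "transcript order")
})

test_that("projection maps codons through gaps and flags unmappable sites", {
  sites <- data.frame(gene_id = "g", cds_offset = c(3, 5), codon_index = c(1, 1),
                      phase = c(0, 2), cds_len = 12)
  sites$codon_index <- c(1L, 1L)
  # ungapped row must have cds_len/3 - 1 = 3 residues
  expect_equal(project_to_alignment(sites, c(g = "MKV"))$column, c(1, 1))
  # gap shifts the column: row M-KV, codon 1 -> column 2
  expect_equal(project_to_alignment(sites, c(g = "M-KV"))$column, c(2, 2))
  expect_error(project_to_alignment(sites, c(g = "MKVAA")), "mismatch")
})

test_that("projection is invariant to all-gap column insertion", {
  sim <- shared_sim()
  ann <- do.call(rbind, lapply(sim$genomes, `[[`, "annotation"))
  sites <- intron_site_table(ann)
  proj <- project_to_alignment(sites, sim$alignment)
  # splice an all-gap column block into the middle of the alignment
  w <- nchar(sim$alignment[1])
  cut <- floor(w / 2)
  shifted <- vapply(sim$alignment, function(s)
    paste0(substr(s, 1, cut), "---", substr(s, cut + 1, w)), "")
  proj2 <- project_to_alignment(sites, shifted)
  d <- proj2$column - proj$column
  expect_true(all(d %in% c(0, 3)))
  cl1 <- cluster_homologous_introns(proj)
  cl2 <- cluster_homologous_introns(proj2)
  memberships <- function(cl) sort(vapply(
    split(paste(cl$gene_id, cl$cds_offset), cl$cluster),
    function(x) paste(sort(x), collapse = "|"), ""))
  expect_equal(unname(memberships(cl1)), unname(memberships(cl2)))
  expect_equal(nrow(cl1), nrow(cl2))
})

test_that("clustering requires identical phase and respects tolerance", {
  base <- data.frame(gene_id = c("a", "b"), cds_offset = c(6, 6),
                     codon_index = 2, phase = 0, cds_len = 30,
                     column = 2, unmappable = FALSE)
  cl <- cluster_homologous_introns(base)
  expect_equal(length(unique(cl$cluster)), 1)

  mixed <- base; mixed$phase <- c(1, 2)
  expect_equal(length(unique(cluster_homologous_introns(mixed)$cluster)), 2)

  near <- base; near$column <- c(2, 3)
  expect_equal(length(unique(cluster_homologous_introns(near, 0)$cluster)), 2)
  expect_equal(length(unique(cluster_homologous_introns(near, 1)$cluster)), 1)
})

test_that("gain/loss reconstruction recovers root and terminal gains", {
  tr <- ensure_node_labels(ape::read.tree(
    text = "((A:1,B:1):1,(C:1,D:1):1);"))
  clusters <- data.frame(
    cluster = c(rep("ph2_col51", 4), "ph0_col10"),
    phase = c(rep(2, 4), 0), column = c(rep(51, 4), 10),
    gene_id = c("gA", "gB", "gC", "gD", "gD"),
    cds_offset = c(rep(155, 4), 30))
  gs <- c(gA = "A", gB = "B", gC = "C", gD = "D")
  gl <- intron_gain_loss(clusters, tr, gs)
  ev <- gl$events
  expect_equal(ev$gain[ev$cluster == "ph2_col51"], "N5")
  expect_equal(ev$n_losses[ev$cluster == "ph2_col51"], 0)
  expect_equal(ev$gain[ev$cluster == "ph0_col10"], "D")
})

test_that("overlapping cluster pairs with undecidable gain order are flagged", {
  tr <- ensure_node_labels(ape::read.tree(
    text = "((A:1,B:1):1,(C:1,D:1):1);"))
  # two introns on sibling terminal branches: incomparable
  clusters <- data.frame(
    cluster = c("ph0_col5", "ph1_col9"), phase = c(0, 1), column = c(5, 9),
    gene_id = c("gA", "gB"), cds_offset = c(15, 28))
  gl <- intron_gain_loss(clusters, tr, c(gA = "A", gB = "B", gC = "C",
                                         gD = "D"))
  expect_equal(nrow(gl$order_ambiguous), 1)
  expect_equal(gl$order_ambiguous$reason, "incomparable branches")

  # nested gains are ordered: no ambiguity
  nested <- data.frame(
    cluster = c("ph0_col5", "ph1_col9"), phase = c(0, 1), column = c(5, 9),
    gene_id = c("gA", "gB"), cds_offset = c(15, 28))
  nested$gene_id <- c("gA", "gA")
  gl2 <- intron_gain_loss(
    rbind(nested,
          data.frame(cluster = "ph0_col5", phase = 0, column = 5,
                     gene_id = "gB", cds_offset = 15)),
    tr, c(gA = "A", gB = "B", gC = "C", gD = "D"))
  expect_equal(nrow(gl2$order_ambiguous), 0)
})

test_that("intron maps render one phase-marked bar per gene", {
  sites <- data.frame(gene_id = "g", cds_offset = c(155, 800),
                      codon_index = c(51, 266), phase = c(2, 2),
                      cds_len = 1083)
  txt <- render_intron_map(sites)
  expect_match(txt, "^g")
  expect_equal(length(gregexpr("2", txt)[[1]]), 2)
})
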