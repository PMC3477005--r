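test_that("neighbor joining recovers additive trees exactly", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  for (i in 1:25) {
    tr <- ape::rtree(sample(4:12, 1))
    d <- ape::cophenetic.phylo(tr)
    njt <- nj_tree(d)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), njt), 0)
    # branch lengths reproduced
    expect_equal(max(abs(ape::cophenetic.phylo(njt)[rownames(d), colnames(d)]
                         - d)), 0, tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "3 taxa")
  m <- matrix(c(0, 1, 2, 1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(m), "symmetric")
})

test_that("three equidistant taxa give the unique star resolution", {
  m <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(m) <- 0
  tr <- nj_tree(m)
  expect_equal(ape::Ntip(tr), 3)
  expect_true(all(tr$edge.length >= 0))
})

test_that("midpoint rooting balances the diameter pair", {
  t2 <- ape::read.tree(text = "(A:3,B:1);")
  expect_equal(unname(leaf_depths(midpoint_root(t2))), c(2, 2))

  set.seed(6)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(sample(4:10, 1)))
    m <- midpoint_root(tr)
    d <- leaf_depths(m)
    D <- ape::cophenetic.phylo(tr)
    idx <- which(D == max(D), arr.ind = TRUE)[1, ]
    pair <- rownames(D)[idx]
    expect_lt(abs(d[pair[1]] - d[pair[2]]), 1e-9)
    expect_equal(sum(m$edge.length), sum(tr$edge.length), tolerance = 1e-9)
  }
})

test_that("midpoint ties resolve to the lexicographically smallest pair", {
  # two diameters of equal length: (A,C) and (B,C) both length 4
  tie <- ape::read.tree(text = "((A:2,B:2):1,C:1):0;")
  m1 <- midpoint_root(tie)
  m2 <- midpoint_root(tie)
  expect_identical(ape::write.tree(m1), ape::write.tree(m2))
  d <- leaf_depths(m1)
  expect_lt(abs(d["A"] - d["B"]), 1e-9)  # the (A,B) pair sorts first
})

test_that("zero-length trees root arbitrarily but are flagged", {
  z <- ape::read.tree(text = "((A:0,B:0):0,C:0);")
  z <- ape::unroot(z)
  m <- midpoint_root(z)
  expect_true(ape::is.rooted(m))
  expect_true(isTRUE(attr(m, "zero_length")))
})

test_that("clade/locus concordance scores monophyly of multi-member loci", {
  good <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  loci <- c(a1 = "L1", a2 = "L1", b1 = "L2", b2 = "L2")
  cc <- clade_locus_concordance(good, loci)
  expect_equal(cc$score, 1.0)

  bad <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  cc2 <- clade_locus_concordance(bad, loci)
  expect_equal(cc2$score, 0.0)

  single <- clade_locus_concordance(
    good, c(a1 = "L1", a2 = "L2", b1 = "L3", b2 = "L4"))
  expect_true(is.na(single$score))
})

test_that("family patristic distances average cross-family path lengths", {
  star <- ape::read.tree(text = "(a:2,b:2,c:2);")
  fp <- family_patristic_distance(star, c(a = "F1", b = "F2", c = "F3"))
  expect_equal(unname(fp["F1", "F2"]), 4)
  expect_equal(unname(fp["F2", "F3"]), 4)

  # caterpillar with hand-computed means
  cat4 <- ape::read.tree(text = "(((a:1,b:1):1,c:1):1,d:4);")
  fam <- c(a = "X", b = "X", c = "Y", d = "Z")
  fp2 <- family_patristic_distance(cat4, fam)
  expect_equal(unname(fp2["X", "Y"]), mean(c(1 + 1 + 1, 1 + 1 + 1)))
  expect_equal(unname(fp2["X", "Z"]), mean(c(1 + 1 + 1 + 4, 1 + 1 + 1 + 4)))
  expect_equal(unname(fp2["X", "X"]), 2)
  expect_true(is.na(fp2["Z", "Z"]))
  expect_error(family_patristic_distance(star, c(a = "F1", b = "F2")),
               "unlabeled")
})

test_that("families that split later are closer in patristic distance", {
  tr <- simulate_species_tree(6, seed = 33)
  sim <- evolve_gene_family(tr, sim_params(
    seed = 33, init_loci = 3, init_divergence = 1.2,
    rate_dup_local = 0, rate_dup_distal = 0, rate_loss = 0,
    rate_pseudogenize = 0, rate_intron_gain = 0))
  d <- distance_matrix(strip_gap_columns(sim$alignment)$alignment, "poisson")
  gt <- midpoint_root(nj_tree(d))
  rp <- replay_event_log(sim)
  fam <- unlist(lapply(names(rp), function(sp)
    stats::setNames(rp[[sp]]$locus, paste0(sp, "_", rp[[sp]]$gene))))
  fp <- family_patristic_distance(gt, fam)
  # paralog families separated by the deep stems are farther apart than
  # members of the same family are from each other
  expect_gt(min(fp["L1", "L2"], fp["L1", "L3"], fp["L2", "L3"]),
            max(fp["L1", "L1"], fp["L2", "L2"], fp["L3", "L3"]))
})
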