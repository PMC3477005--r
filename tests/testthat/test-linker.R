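mk_contigs <- function(...) {
  x <- c(...)
  data.frame(contig = names(x), length = unname(x), stringsAsFactors = FALSE)
}

end_row <- function(clone, end, contig, pos, strand) {
  data.frame(clone = clone, end = end, contig = contig, pos = pos,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("link graph separates linking, spanning and unpaired clones", {
  contigs <- mk_contigs(A = 1e4, B = 1e4)
  ends <- rbind(
    end_row("c1", 1, "A", 9500, "+"), end_row("c1", 2, "B", 500, "-"),
    end_row("c2", 1, "A", 100, "+"), end_row("c2", 2, "A", 5000, "-"),
    end_row("c3", 1, "B", 50, "+"))
  g <- build_link_graph(contigs, ends)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$clone, "c1")
  expect_equal(nrow(g$spanning), 1)
  expect_equal(nrow(g$unpaired), 1)

  bad <- rbind(ends, end_row("c1", 1, "A", 1, "+"))
  expect_error(build_link_graph(contigs, bad), "malformed")
})

test_that("orientation parity propagates along chains and flags conflicts", {
  contigs <- mk_contigs(A = 100, B = 100, C = 100)
  # A+ -> B-  and  B+ -> C-: all "opposite" constraints, no flips needed
  ends <- rbind(
    end_row("c1", 1, "A", 90, "+"), end_row("c1", 2, "B", 10, "-"),
    end_row("c2", 1, "B", 90, "+"), end_row("c2", 2, "C", 10, "-"))
  g <- build_link_graph(contigs, ends)
  o <- infer_orientations(g)
  expect_false(any(o$flips))
  expect_equal(nrow(o$conflicts), 0)

  # frustrated triangle: opposite, opposite, same — any assignment leaves
  # exactly one violated edge (verified by enumerating all 8 flip vectors)
  tri <- rbind(
    end_row("t1", 1, "A", 90, "+"), end_row("t1", 2, "B", 10, "-"),
    end_row("t2", 1, "B", 90, "+"), end_row("t2", 2, "C", 10, "-"),
    end_row("t3", 1, "A", 10, "+"), end_row("t3", 2, "C", 90, "+"))
  gt <- build_link_graph(contigs, tri)
  req <- c(FALSE, FALSE, TRUE)  # required flip-parity per edge
  best <- min(vapply(0:7, function(m) {
    f <- as.logical(intToBits(m)[1:3])
    sum(xor(f[c(1, 2, 1)], f[c(2, 3, 3)]) != req)
  }, 0))
  expect_equal(best, 1)
  ot <- infer_orientations(gt)
  expect_equal(nrow(ot$conflicts), 1)

  single <- build_link_graph(mk_contigs(Z = 10), end_row("q", 1, "Z", 1, "+"))
  os <- infer_orientations(single)
  expect_equal(nrow(os$conflicts), 0)
  expect_false(os$flips[["Z"]])
})

test_that("two-contig ordering reproduces the insert arithmetic", {
  contigs <- mk_contigs(A = 1e4, B = 1e4)
  ends <- rbind(end_row("c1", 1, "A", 9500, "+"),
                end_row("c1", 2, "B", 500, "-"))
  res <- link_contigs(contigs, ends, c(40000, 40000))
  sc <- res$scaffolds
  expect_equal(sc$contig, c("A", "B"))
  expect_equal(sc$orientation, c("+", "+"))
  expect_equal(sc$gap_to_next[1], 39000, tolerance = 2e-4)  # 40 kb - 500 - 500
})

test_that("exact insert lengths give exact least-squares offsets", {
  # three contigs in a row, clones with known exact inserts
  contigs <- mk_contigs(A = 1000, B = 1000, C = 1000)
  ins <- 1500
  # true layout: A at 0, B at 2000, C at 4000
  # clone u: + end at A:800 (global 800), - end at B:2299 (local 299)
  # clone v: + end at B:2700 (local 700), - end at C:4199 (local 199)
  ends <- rbind(
    end_row("u", 1, "A", 800, "+"), end_row("u", 2, "B", 299, "-"),
    end_row("v", 1, "B", 700, "+"), end_row("v", 2, "C", 199, "-"))
  res <- link_contigs(contigs, ends, c(ins, ins))
  sc <- res$scaffolds
  expect_equal(sc$contig, c("A", "B", "C"))
  expect_equal(sc$offset, c(0, 2000, 4000))
  expect_equal(nrow(res$conflicts), 0)
})

test_that("an edgeless contig forms a singleton super-scaffold", {
  contigs <- mk_contigs(A = 100, B = 100, Lone = 50)
  ends <- rbind(end_row("c1", 1, "A", 90, "+"),
                end_row("c1", 2, "B", 10, "-"))
  res <- link_contigs(contigs, ends, c(150, 150))
  sc <- res$scaffolds
  expect_equal(sum(sc$contig == "Lone"), 1)
  expect_equal(length(unique(sc$super)), 2)
})

test_that("ten fragmented contigs are recovered up to global flip", {
  p <- sim_params(seed = 1, insert_size_range = c(30000, 45000),
                  clone_coverage = 5)
  fr <- fragment_scaffold(1e6, n_breaks = 9, seed = 31, scaffold = "asm",
                          min_contig_len = 6e4)
  ends <- map_clone_ends(generate_clone_pairs(1e6, p, seed = 32,
                                              scaffold = "asm"), fr)
  res <- link_contigs(fr$contigs, ends, c(30000, 45000))
  expect_equal(nrow(res$parity_conflicts), 0)
  expect_true(layout_matches_truth(res$scaffolds, fr$truth))
  # offsets track the true coordinates to within the insert half-width
  tr <- fr$truth[order(fr$truth$order), ]
  sc <- res$scaffolds
  if (sc$contig[1] == tr$contig[1]) {
    m <- match(tr$contig, sc$contig)
    expect_lt(max(abs(sc$offset[m] - tr$start)), 7500)
  }
})

test_that("recovery rate does not degrade when coverage rises", {
  recover <- function(cov, seed) {
    p <- sim_params(seed = 1, insert_size_range = c(30000, 45000),
                    clone_coverage = cov)
    fr <- fragment_scaffold(5e5, n_breaks = 4, seed = seed,
                            scaffold = "s", min_contig_len = 6e4)
    ends <- map_clone_ends(generate_clone_pairs(5e5, p, seed = seed + 100,
                                                scaffold = "s"), fr)
    layout_matches_truth(link_contigs(fr$contigs, ends,
                                      c(30000, 45000))$scaffolds, fr$truth)
  }
  lo <- mean(vapply(1:8, function(s) recover(2, s), TRUE))
  hi <- mean(vapply(1:8, function(s) recover(8, s), TRUE))
  expect_gte(hi, lo)
  expect_equal(hi, 1)
})
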