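req <- c("MACPF", "C2")

cand <- function(completeness, domains, stop = FALSE, shift = FALSE,
                 hits = data.frame()) {
  list(id = "x", completeness = completeness, domains = domains,
       premature_stop = stop, frameshift = shift, hits = hits)
}

hit <- function(subject, family, bitscore, evalue = 1e-50) {
  data.frame(subject = subject, family = family, bitscore = bitscore,
             evalue = evalue, stringsAsFactors = FALSE)
}

test_that("the two-rule decision table behaves on its canonical cases", {
  expect_equal(classify_candidate(
    cand("full_length", c("MACPF", "EGF", "C2")), req, "perforin")$verdict,
    "full")
  expect_equal(classify_candidate(
    cand("full_length", c("MACPF", "EGF")), req, "perforin")$verdict,
    "reject")
  expect_equal(classify_candidate(
    cand("full_length", c("MACPF", "EGF", "C2"), stop = TRUE),
    req, "perforin")$verdict, "pseudogene")
  expect_equal(classify_candidate(
    cand("partial", character(),
         hits = hit("q", "perforin", 100)), req, "perforin")$verdict,
    "partial")
  expect_equal(classify_candidate(
    cand("partial", character(),
         hits = hit("q", "complement", 100)), req, "perforin")$verdict,
    "reject")
  no_ev <- classify_candidate(cand("partial", character()), req, "perforin")
  expect_equal(no_ev$verdict, "reject")
  expect_equal(no_ev$rule_fired, "no evidence")
})

test_that("every decision-table combination maps to exactly one verdict", {
  domain_sets <- list(character(), "MACPF", "C2", c("MACPF", "C2"),
                      c("MACPF", "EGF", "C2"))
  hit_sets <- list(
    none = data.frame(),
    focal = hit("a", "perforin", 90),
    other = hit("b", "complement", 90),
    tie_same = rbind(hit("a", "perforin", 90), hit("b", "perforin", 90)),
    tie_diff = rbind(hit("a", "perforin", 90), hit("b", "complement", 90)))
  for (comp in c("full_length", "partial"))
    for (doms in domain_sets)
      for (stop in c(FALSE, TRUE)) for (shift in c(FALSE, TRUE))
        for (h in hit_sets) {
          v <- classify_candidate(cand(comp, doms, stop, shift, h),
                                  req, "perforin")
          expect_true(v$verdict %in% c("full", "partial", "pseudogene",
                                       "reject"))
          expect_true(nchar(v$rule_fired) > 0)
          if (comp == "full_length") {
            if (!all(req %in% doms)) expect_equal(v$verdict, "reject")
            else if (stop || shift) expect_equal(v$verdict, "pseudogene")
            else expect_equal(v$verdict, "full")
          } else {
            got_focal <- nrow(h) > 0 && !is.null(h$family) &&
              length(unique(h$family[h$bitscore == max(h$bitscore)])) == 1 &&
              unique(h$family[h$bitscore == max(h$bitscore)])[1] == "perforin"
            expect_equal(v$verdict, if (got_focal) "partial" else "reject")
          }
        }
})

test_that("top-hit ranking breaks ties by score fields only", {
  expect_equal(top_hit_family(hit("a", "perforin", 100)), "perforin")
  expect_equal(top_hit_family(
    rbind(hit("a", "perforin", 100), hit("b", "perforin", 100))), "perforin")
  expect_equal(top_hit_family(
    rbind(hit("a", "perforin", 100), hit("b", "complement", 100))),
    "AMBIGUOUS")
  # equal bitscore, distinct e-value: the better e-value decides
  expect_equal(top_hit_family(
    rbind(hit("a", "perforin", 100, 1e-80),
          hit("b", "complement", 100, 1e-10))), "perforin")
  expect_equal(top_hit_family(
    rbind(hit("a", "complement", 120), hit("b", "perforin", 90))),
    "complement")
})

test_that("species tallies render the (full, partial, pseudo) total format", {
  cls <- data.frame(
    species = c("a", "a", "a", "b", "b"),
    verdict = c("full", "partial", "pseudogene", "reject", "full"))
  tal <- tally_species(cls)
  expect_equal(tal$summary[tal$species == "a"], "(1, 1, 1) 3")
  expect_equal(tal$total[tal$species == "b"], 1)  # reject excluded
  allrej <- tally_species(data.frame(species = "c", verdict = "reject"))
  expect_equal(allrej$summary, "(0, 0, 0) 0")
  # order invariance
  tal2 <- tally_species(cls[sample(nrow(cls)), ])
  expect_equal(tal, tal2)
})

test_that("completeness calling uses the domain-span threshold", {
  expect_equal(completeness_from_span(500), "full_length")
  expect_equal(completeness_from_span(200), "partial")
  expect_equal(completeness_from_span(200, min_span = 150), "full_length")
})

test_that("classification recovers simulator truth through the hit tables", {
  sim <- shared_sim()
  inp <- sim_classifier_inputs(sim)
  cls <- classify_table(inp$meta, inp$domains, inp$hits, req, "focal")
  rp <- replay_event_log(sim)
  truth <- do.call(rbind, lapply(names(rp), function(sp)
    if (nrow(rp[[sp]])) data.frame(
      id = paste0(sp, "_", rp[[sp]]$gene),
      want = ifelse(rp[[sp]]$pseudo, "pseudogene", "full"))))
  m <- merge(cls, truth, by = "id")
  expect_equal(nrow(m), nrow(cls))
  expect_true(all(m$verdict == m$want))
})
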