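---
title: "Tracing gene-family evolution with famtrace: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing gene-family evolution with famtrace: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famtrace)
```

## The inference chain

famtrace packages the chain of comparative-genomics arguments used to trace a
gene family — such as the pore-forming immune effector perforin — back through
vertebrate genomes:

1. **Homolog cataloguing** — candidate genes are classified as full-length
   members, partial genes, pseudogenes or rejects from domain composition and
   similarity-hit evidence.
2. **Contig linking** — where a family member sits on disconnected assembly
   contigs, paired BAC/fosmid clone-end hits orient and order the contigs into
   a super-scaffold.
3. **Synteny locus tracking** — each family member is assigned to a named
   locus through its flanking anchor genes; presence/absence of loci across
   species is reconstructed ancestrally by Dollo parsimony, yielding a
   "roadmap" of locus gains and losses.
4. **Intron evolution** — CDS intron positions and phases are projected onto
   the protein alignment, clustered into homologous sites, and their gains and
   losses reconstructed on the tree.
5. **Tree/locus concordance** — a distance tree of the family is midpoint
   rooted and compared against locus assignments: clades that exactly contain
   the genes of one locus corroborate the synteny history.

Every stage is exercised end to end against a bundled genome-evolution
simulator that emits a complete event log, so each inference can be scored
against known truth.

## The synthetic-data model

`simulate_species_tree()` draws a random rooted binary topology with uniform
(0, 1) branch lengths in expected substitutions per site.
`evolve_gene_family()` then evolves the family along the tree:

* The root lineage starts with `init_loci` copies (default 1), each sitting in
  its own anchor-gene neighbourhood and carrying the ancestral introns —
  by default a single intron after 155 coding nucleotides (codon 51,
  phase 2), the canonical configuration for this family.
* On each branch of length $t$, six Poisson processes draw events at the
  configured per-branch rates: local duplication (copy inserted beside its
  template), distal duplication (copy jumps into a different anchor
  neighbourhood), gene loss, pseudogenization (one premature stop at a
  uniform CDS position), intron gain and intron loss. Events are applied in
  drawn time order, with protein substitutions accumulated piecewise between
  them.
* Proteins evolve by per-site substitution at rate 1 per unit branch length
  under a flat 20-letter replacement model with **no indels**. The true
  alignment of the family is therefore the ungapped stack of leaf sequences,
  which keeps the projection of intron sites onto alignment columns exact —
  the property the intron-oracle tests rely on.
* **Infinite-sites intron gains:** each gain draws its CDS offset from the
  family-wide pool of offsets never used before. Over a kilobase-scale CDS the
  probability of two independent gains striking the same nucleotide is
  negligible in reality; excluding it by construction mirrors the analytical
  assumption that identical position *and* phase imply homology, and makes
  "cluster = event" exact for recovery tests.

Leaf states are materialised as coordinate genomes: one scaffold per locus,
anchor genes (shared symbols, fixed orientations) flanking the family members,
exon structures derived from each gene's intron set. Coordinates are 0-based
half-open internally and 1-based inclusive in emitted GFF3, with CDS phase
columns computed from cumulative coding length. Genomes carry no nucleotide
sequence — the analyses operate on gene models, protein sequences and
coordinates — so fragmentation round-trips are asserted on exact coordinate
maps rather than on strings.

Similarity-hit tables for the classifier are derived from the true alignment:
percent identity of each candidate against a focal-family reference (the root
protein) and a decoy reference (the root protein mutated at half its sites),
with bitscore proportional to identity and e-value a fixed monotone transform.
The classifier consumes hit tables; it never runs a search itself.

### Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `rate_dup_local` / `rate_dup_distal` | 0.3 / 0.15 | duplications per branch-length unit |
| `rate_loss`, `rate_pseudogenize` | 0.1, 0.1 | gene decay per branch-length unit |
| `rate_intron_gain` / `rate_intron_loss` | 0.5 / 0.1 | intron events per branch-length unit |
| `n_loci`, `anchor_genes_per_locus` | 6, 4 | anchor neighbourhoods available |
| `insert_size_range` | 30–45 kb | BAC/fosmid clone insert length (uniform) |
| `clone_coverage` | 5 | mean clone inserts covering a position |
| `protein_length` | 360 aa | focal protein length |
| `root_introns` | 155 | ancestral intron CDS offset(s), nt |

No published rates exist for these events; the defaults were chosen once for
testability — large enough that a handful of events occur on a typical
8-species tree, small enough that recoveries remain interpretable — and are
not revisited per analysis.

## Classifier decision table

A full-length candidate is a member (`full`) iff it carries every required
domain (for a perforin-style filter, the pore-forming MACPF domain *and* the
C2 membrane-binding domain) with an intact ORF; with the domains present but a
premature stop or frameshift it is a `pseudogene`; missing a required domain
it is rejected. A partial candidate stands or falls by its best similarity
hit: ranked by bitscore then e-value, a unique top family equal to the focal
family gives `partial`; anything else — a different family, a cross-family
tie, or no hits at all — is a reject with the failed rule named. Ambiguous
top hits are rejected explicitly rather than silently dropped, keeping the
catalogue auditable. When completeness is not annotated,
`completeness_from_span()` calls a candidate partial when its span cannot
plausibly contain the required domains (default threshold 400 aa, roughly the
summed minimal domain lengths; the boundary between "truncated mid-domain"
and "partial" is genuinely underdetermined and the threshold is exposed).

Tallies render per species as `"(full, partial, pseudogenes) total"`, with
rejects excluded from the total.

## Contig linking

Clone ends are point positions with strands; libraries are inward-facing
(BAC/fosmid convention; the parity function is configurable for outward
libraries). A clone with ends on two contigs imposes the parity constraint
`flip(A) XOR flip(B) = [strand_A == strand_B]`. Constraints are propagated
per connected component from the lexicographically smallest contig; edges
contradicting the propagated assignment are *reported* as conflicts, never
auto-resolved — the analyst inspects them, as one would by eye.

With orientations fixed, each clone gives one linear equation on contig
offsets (the minus end lies one insert length downstream of the plus end).
The per-clone insert is unknown, so the midpoint of the configured insert
range is used — unbiased under the uniform insert model — and offsets are
solved per component by least squares with the first contig pinned at zero.
Contigs are sorted by offset; neighbours overlapping by more than half the
insert-range width are flagged as ordering conflicts. In the zero-noise limit
(exact insert lengths) the least-squares solution reproduces exact positions.

Mate-pair evidence cannot distinguish a layout from its mirror image, so
recovered layouts are compared to truth up to a global flip
(`layout_matches_truth()`).

**Known limitation.** At 5x clone coverage a given contig junction is crossed
by a Poisson(5) number of clones and is therefore unlinked with probability
e^-5 ≈ 0.7%. A ten-contig region has nine junctions, so roughly 6% of
simulated regions contain a junction that *no* method could bridge; recovery
rates slightly below 100% at this coverage reflect evidence gaps, not linking
errors, and recovery is monotone non-decreasing in coverage.

## Synteny and Dollo reconstruction

A family member's neighbourhood (default 10 genes per side) is re-expressed
with the focal gene normalised to the plus strand, which makes locus calls
invariant under scaffold reverse-complement. Each configured anchor set scores
the number of its anchors found among the flanks; the unique set meeting its
minimum `k` (default 1 — loci are routinely recognised from a single shared
neighbour) with the highest count wins. No qualifying set yields `NOVEL` (a
gene alone on a small scaffold); tied sets yield `AMBIGUOUS`.

Locus presence/absence across species forms a matrix with a third state,
unknown (`?`), for species whose assemblies are too shallow to conclude
absence. Ancestral states are reconstructed under **Dollo parsimony**: a
character arises exactly once — the reasoning "present in the ancestor,
subsequently lost" presumes unique gains — at the last common ancestor of the
present taxa, and the minimal set of loss branches severs all absent leaves.
Unknown taxa are completed to whichever state minimises the loss count, with
ties resolved to absence (the conservative reading: shallow coverage is never
promoted to presence without need). Completions are enumerated exhaustively
(capped at 16 unknown taxa). For binary trees the LCA placement is provably
optimal among single-gain scenarios; the package nevertheless ships an
independent brute-force enumerator over all gain nodes and completions
(`dollo_min_events()`) used by the tests and acceptance script as a yardstick.

## Intron evolution

Intron sites live at junctions between consecutive CDS exons, located by
cumulative coding length; `phase = offset mod 3` by construction, and the
invariant is property-tested over random gene models on both strands.
Untranslated-region introns are excluded: they require transcript evidence
and cannot be traced consistently from gene models. A site in codon *i* maps
to the alignment column of that row's *i*-th residue (the stop codon carries
no residue; a row/CDS length mismatch is an error naming the gene). Sites are
homologous when they share the phase and the column exactly (tolerance 0;
a column tolerance is exposed for sloppier alignments, where clusters become
single-linkage chains). Per-cluster presence over species feeds the same
Dollo engine; pairs of clusters whose gain branches are identical or
incomparable in the tree are reported as order-ambiguous — the situation
where one cannot deduce which intron was gained first.

## Tree building and concordance

Bayesian tree inference is deliberately out of scope: `export_nexus()` writes
the alignment with a sampler block (WAG, invariant+gamma rates, 100,000
generations, sampling every 100, 25% burnin) for an external run, and
neighbor joining over p- or Poisson-corrected distances serves as the in-repo
stand-in. Distances are computed only on gap-free alignments;
`strip_gap_columns()` removes every column containing a gap (returning a
column map so projected intron columns survive the stripping). On additive
matrices NJ provably recovers the generating topology; the tests verify this
on random trees up to 12 taxa against an independent split comparison.

Midpoint rooting places the root halfway along the tree diameter. The
implementation is deterministic under ties (lexicographically smallest leaf
pair), subdivides the midpoint edge exactly, and guarantees the diameter pair
is equidistant from the root to within 1e-9; zero-length trees are rooted
arbitrarily and flagged. Monophyly of a locus is then assessed on the rooted
tree: a locus with two or more member genes is concordant iff its member set
is exactly some node's leaf set, and the overall score is the fraction of
multi-member loci that are monophyletic (NA when no locus has two members).

## What passing tests do and do not show

The simulator's proteins evolve without indels, alignments are exact, domain
annotations are uncorrupted and hit tables are deterministic transforms of
true identity. Passing recovery tests therefore demonstrates that the
*inference chain* is correct under clean evidence — classification equals the
event log, intron clusters equal gain events, Dollo equals the brute-force
minimum, locus clades equal gene-tree clades when duplications are
species-specific. They do not demonstrate robustness to misalignment,
mis-annotated domains, assembly artefacts or rate heterogeneity, none of
which the generator emulates; real-data use should treat borderline calls
(AMBIGUOUS assignments, order-ambiguous clusters, link conflicts) as prompts
for inspection, which is why every such state is reported rather than
resolved silently.

## Numerical and design choices

* Coordinates: 0-based half-open everywhere internally; GFF3 written 1-based
  inclusive with standard phase semantics; alignment columns 0-based.
* Clone-end arithmetic uses inclusive end positions, so a clone of insert
  $I$ spans from its plus end at $a$ to its minus end at $a + I - 1$; gap
  estimates inherit the corresponding $-1$.
* Breakpoints under a minimum contig length are drawn by the shrunken-interval
  construction (uniform conditional on all spacings meeting the minimum),
  not by rejection.
* NJ branch lengths are clamped at zero from below, the common convention for
  noisy distances.
* Dollo's unknown-state completion is exhaustive with a documented cap;
  beyond 16 unknowns the function refuses rather than silently approximating.
* The problem sizes used by the test-suite and the acceptance script — 200
  trees of up to 8 leaves with exhaustive presence patterns for the Dollo
  yardstick, fifty 1 Mb ten-contig linking replicates at 5x coverage, twenty
  8-species intron replicates per regime, one ~200-gene 16-species
  classification fixture, 100 NJ/midpoint replicates up to 12 taxa — were
  chosen as the smallest scales at which each property is exercised across
  its combinatorial range.
* The linker acceptance fixture keeps every contig at least 60 kb: a contig
  shorter than one clone insert (30–45 kb) cannot reliably anchor both ends
  of the clones that cross it, and the motivating use case (gene-bearing
  contigs joined by BAC/fosmid ends) concerns contigs of at least that scale.
* The classification fixture disables whole-gene loss: a sufficiently unlucky
  early loss can extinguish the family outright, leaving nothing to classify;
  loss inference is exercised by the Dollo and synteny tests instead.

## A worked micro-example

```{r example}
tr <- simulate_species_tree(6, seed = 4)
sim <- evolve_gene_family(tr, sim_params(seed = 4, rate_dup_distal = 0.3))
sim
head(sim$event_log)

# locus assignment for every family member of one species
ann <- sim$genomes$sp05$annotation
fam <- unique(ann$gene_id[ann$family == "focal"])
sapply(fam, function(g) assign_locus(extract_neighborhood(ann, g),
                                     sim$anchors))
```
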