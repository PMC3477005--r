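# Scaffold fragmentation and clone-end (mate-pair) simulation.
#
# Genomes are coordinate models, so fragmentation is an exact partition of the
# scaffold interval [0, L): the truth table records, per contig, its original
# interval, rank and flip state, and position maps between the two frames are
# exact inverses.

#' Fragment a scaffold into contigs
#'
#' Cuts a scaffold of length `length` into `n_breaks + 1` contigs at uniform
#' breakpoints, then flips each contig independently with probability 0.5.
#'
#' @param length scaffold length in bp.
#' @param n_breaks number of breakpoints (>= 0; must be < `length`).
#' @param seed optional RNG seed.
#' @param scaffold scaffold name used to derive contig names.
#' @param genes optional data.frame with 0-based half-open `start`, `end`
#'   columns; with `avoid_genes = TRUE` breakpoints are rejected while they
#'   fall inside a gene.
#' @param avoid_genes keep breakpoints out of the `genes` intervals.
#' @param min_contig_len minimum contig length enforced by rejection sampling
#'   (0 = pure uniform breakpoints).
#' @return list of class `fam_fragmentation`: `contigs` (contig, length) and
#'   `truth` (contig, scaffold, order, start, end, length, flipped).
#' @examples
#' fr <- fragment_scaffold(1e6, n_breaks = 9, seed = 1)
#' nrow(fr$contigs)  # 10
#' @export
fragment_scaffold <- function(length, n_breaks, seed = NULL, scaffold = "scf",
                              genes = NULL, avoid_genes = TRUE,
                              min_contig_len = 0) {
  length <- as.numeric(length)
  if (n_breaks < 0) stop("n_breaks must be >= 0")
  if (n_breaks >= length) stop("n_breaks must be smaller than the scaffold length")
  if ((n_breaks + 1) * min_contig_len > length)
    stop("min_contig_len too large for the requested number of contigs")
  if (!is.null(seed)) set.seed(seed)

  ok_break <- function(b) {
    if (!avoid_genes || is.null(genes) || !nrow(genes)) return(rep(TRUE, length(b)))
    !vapply(b, function(x) any(genes$start < x & x < genes$end), TRUE)
  }

  breaks <- numeric(0)
  if (n_breaks > 0) {
    # uniform breakpoints conditional on every contig >= min_contig_len:
    # draw in the shrunken interval, then pad the minimum spacing back in
    m <- max(min_contig_len, 1)
    slack <- length - (n_breaks + 1) * m
    for (attempt in seq_len(10000)) {
      u <- sort(stats::runif(n_breaks, 0, slack))
      cand <- floor(u) + seq_len(n_breaks) * m
      if (all(ok_break(cand))) {
        breaks <- cand
        break
      }
    }
    if (!base::length(breaks)) stop("could not place breakpoints under the constraints")
  }

  bounds <- c(0, breaks, length)
  n <- n_breaks + 1
  flipped <- sample(c(TRUE, FALSE), n, replace = TRUE)
  truth <- data.frame(
    contig = sprintf("%s_c%02d", scaffold, seq_len(n)),
    scaffold = scaffold,
    order = seq_len(n),
    start = bounds[-(n + 1)],
    end = bounds[-1],
    length = diff(bounds),
    flipped = flipped,
    stringsAsFactors = FALSE)
  out <- list(contigs = truth[, c("contig", "length")], truth = truth)
  class(out) <- "fam_fragmentation"
  out
}

#' Fragment every scaffold of a simulated genome
#'
#' @param genome a `fam_genome`.
#' @param n_breaks breakpoints per scaffold.
#' @param seed optional RNG seed.
#' @inheritParams fragment_scaffold
#' @return a `fam_fragmentation` covering all scaffolds.
#' @export
fragment_assembly <- function(genome, n_breaks, seed = NULL,
                              avoid_genes = TRUE, min_contig_len = 0) {
  stopifnot(inherits(genome, "fam_genome"))
  if (!is.null(seed)) set.seed(seed)
  parts <- lapply(seq_len(nrow(genome$scaffolds)), function(i) {
    scf <- genome$scaffolds$scaffold[i]
    g <- genome$annotation[genome$annotation$scaffold == scf, , drop = FALSE]
    fragment_scaffold(genome$scaffolds$length[i], n_breaks, seed = NULL,
                      scaffold = scf, genes = g, avoid_genes = avoid_genes,
                      min_contig_len = min_contig_len)
  })
  out <- list(contigs = do.call(rbind, lapply(parts, `[[`, "contigs")),
              truth = do.call(rbind, lapply(parts, `[[`, "truth")))
  class(out) <- "fam_fragmentation"
  out
}

# map a 0-based base position on the original scaffold into contig frame
# (and the inverse); strand is "+"/"-" in the original frame
map_to_contig <- function(truth, pos, strand = "+") {
  i <- findInterval(pos, truth$start[order(truth$start)])
  tr <- truth[order(truth$start), , drop = FALSE]
  row <- tr[i, , drop = FALSE]
  local <- pos - row$start
  if (row$flipped) {
    local <- row$length - 1 - local
    strand <- if (strand == "+") "-" else "+"
  }
  list(contig = row$contig, pos = local, strand = strand)
}

#' Simulate clone-end pairs over a scaffold
#'
#' Clones are placed uniformly; counts follow a Poisson law with mean
#' `clone_coverage * length / mean(insert_size_range)`, so the expected number
#' of inserts covering a position equals `clone_coverage`. Each clone reports
#' two point end-reads facing inward: end 1 at the left insert boundary on the
#' plus strand, end 2 at the right boundary on the minus strand.
#'
#' @param length scaffold length, bp; must exceed the maximum insert size.
#' @param params a [sim_params()] (uses `insert_size_range`, `clone_coverage`).
#' @param seed optional RNG seed.
#' @param scaffold scaffold name for the output table.
#' @return data.frame `clone`, `end` (1/2), `contig` (= scaffold here), `pos`
#'   (0-based), `strand`.
#' @export
generate_clone_pairs <- function(length, params, seed = NULL,
                                 scaffold = "scf") {
  stopifnot(inherits(params, "sim_params"))
  rng <- params$insert_size_range
  if (rng[2] >= length) stop("max insert size must be smaller than the scaffold")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, params$clone_coverage * length / mean(rng))
  if (n == 0)
    return(data.frame(clone = character(), end = integer(),
                      contig = character(), pos = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  ins <- round(stats::runif(n, rng[1], rng[2]))
  a <- floor(stats::runif(n, 0, length - ins + 1))
  b <- a + ins - 1
  id <- sprintf("clone%05d", seq_len(n))
  data.frame(
    clone = rep(id, each = 2),
    end = rep(1:2, n),
    contig = scaffold,
    pos = as.vector(rbind(a, b)),
    strand = rep(c("+", "-"), n),
    stringsAsFactors = FALSE)
}

#' Re-express clone ends in fragmented-contig frame
#'
#' @param ends table from [generate_clone_pairs()] (positions on the original
#'   scaffold).
#' @param fragmentation a `fam_fragmentation` truth for that scaffold.
#' @return the table with `contig`, `pos`, `strand` rewritten into each
#'   contig's possibly-flipped frame.
#' @export
map_clone_ends <- function(ends, fragmentation) {
  truth <- fragmentation$truth
  out <- ends
  for (i in seq_len(nrow(ends))) {
    tr <- truth[truth$scaffold == ends$contig[i], , drop = FALSE]
    if (!nrow(tr)) stop("no fragmentation truth for scaffold ", ends$contig[i])
    m <- map_to_contig(tr, ends$pos[i], ends$strand[i])
    out$contig[i] <- m$contig
    out$pos[i] <- m$pos
    out$strand[i] <- m$strand
  }
  out
}
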