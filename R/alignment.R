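# Alignment preprocessing for tree building: gap-column stripping, domain
# truncation, distance matrices and NEXUS export towards external Bayesian
# samplers.

aln_matrix <- function(aln) {
  stopifnot(length(aln) >= 1)
  rows <- strsplit(aln, "")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1) stop("alignment rows differ in length")
  if (anyDuplicated(names(aln))) stop("duplicated sequence ids")
  do.call(rbind, stats::setNames(rows, names(aln)))
}

#' Remove every alignment column containing a gap
#'
#' @param aln named character vector of equal-length gapped rows.
#' @return list: `alignment` (stripped rows, order preserved) and
#'   `column_map` (data.frame `old`, `new`; 0-based columns) for carrying
#'   projected intron columns across the stripping.
#' @examples
#' strip_gap_columns(c(a = "MK-V", b = "ML-V"))$alignment
#' @export
strip_gap_columns <- function(aln) {
  m <- aln_matrix(aln)
  keep <- which(colSums(m == "-") == 0)
  if (!length(keep))
    warning("all columns contained gaps; the stripped alignment is empty")
  out <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  if (!length(keep)) out <- stats::setNames(rep("", nrow(m)), rownames(m))
  list(alignment = out,
       column_map = data.frame(old = keep - 1L,
                               new = seq_along(keep) - 1L))
}

#' Truncate sequences to per-sequence domain boundaries
#'
#' @param seqs named character vector of (ungapped) sequences.
#' @param boundaries data.frame `id`, `start`, `end` — 0-based half-open
#'   residue intervals, one row per sequence to cut.
#' @return the sequences with listed ids truncated to `[start, end)`.
#' @export
truncate_to_domain <- function(seqs, boundaries) {
  for (i in seq_len(nrow(boundaries))) {
    id <- boundaries$id[i]
    if (!id %in% names(seqs)) stop("unknown sequence id: ", id)
    s <- boundaries$start[i]; e <- boundaries$end[i]
    if (s < 0 || s >= e) stop("invalid boundaries for ", id)
    if (e > nchar(seqs[[id]]))
      stop("boundaries exceed sequence length for ", id)
    seqs[id] <- substr(seqs[[id]], s + 1, e)
  }
  seqs
}

#' Pairwise distance matrix from a gap-free alignment
#'
#' `p` is the mismatch fraction; `poisson` applies the correction
#' `-ln(1 - p)` (infinite, and flagged, at saturation `p = 1`).
#'
#' @param aln named character vector; must contain no gap characters
#'   (strip first).
#' @param correction `"p"` or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal; saturated pairs (if
#'   any) are listed in the `"saturated"` attribute.
#' @export
distance_matrix <- function(aln, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  if (nrow(m) < 2) stop("need at least two sequences")
  if (any(m == "-")) stop("alignment contains gaps; run strip_gap_columns() first")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- mean(m[i, ] != m[j, ])
    v <- if (correction == "p") p else -log(1 - p)
    d[i, j] <- d[j, i] <- v
  }
  sat <- which(is.infinite(d), arr.ind = TRUE)
  if (nrow(sat)) {
    warning("saturated pair(s): Poisson distance infinite")
    attr(d, "saturated") <- data.frame(
      a = rownames(m)[sat[, 1]], b = rownames(m)[sat[, 2]])
  }
  d
}

#' Export an alignment as NEXUS with an MCMC command block
#'
#' Writes the protein DATA matrix plus a `mrbayes` block carrying the default
#' settings used for the family trees: WAG substitution model,
#' invariant-sites-plus-gamma rates, 100,000 generations sampled every 100,
#' first 25% discarded as burnin. The DATA portion round-trips through
#' standard NEXUS readers.
#'
#' @param aln named character vector (gaps allowed).
#' @param file optional path to write to.
#' @param ngen,samplefreq,burninfrac,model,rates MCMC block settings.
#' @return the NEXUS text as a character vector of lines (invisibly when
#'   `file` is given).
#' @export
export_nexus <- function(aln, file = NULL, ngen = 100000, samplefreq = 100,
                         burninfrac = 0.25, model = "wag",
                         rates = "invgamma") {
  m <- aln_matrix(aln)
  tmp <- tempfile(fileext = ".nex")
  on.exit(unlink(tmp), add = TRUE)
  ape::write.nexus.data(stats::setNames(split(m, row(m)), rownames(m)),
                        tmp, format = "protein", interleaved = FALSE)
  lines <- readLines(tmp)
  block <- c(
    "BEGIN mrbayes;",
    sprintf("  prset aamodelpr = fixed(%s);", model),
    sprintf("  lset rates = %s;", rates),
    sprintf("  mcmc ngen=%d samplefreq=%d;", as.integer(ngen),
            as.integer(samplefreq)),
    sprintf("  sumt burninfrac=%.2f;", burninfrac),
    "END;")
  out <- c(lines, block)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
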