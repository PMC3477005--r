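# Homolog cataloguing: the two-rule classifier. Full-length candidates are
# judged on domain composition (all required domains present) plus ORF
# integrity; partial candidates on whether their unique top similarity hit
# falls in the focal family. Verdicts: full / partial / pseudogene / reject.

#' Family of the top-scoring similarity hit
#'
#' Hits are ranked by bitscore (descending), then e-value (ascending), then
#' subject id (lexicographic, for reporting only). If after comparing the
#' score fields the top rank is still shared by hits from two or more distinct
#' families, the result is `"AMBIGUOUS"`.
#'
#' @param hits data.frame with columns `subject`, `family`, `bitscore`,
#'   `evalue`.
#' @return a family label, or `"AMBIGUOUS"`.
#' @export
top_hit_family <- function(hits) {
  stopifnot(nrow(hits) >= 1)
  top <- hits[hits$bitscore == max(hits$bitscore), , drop = FALSE]
  top <- top[top$evalue == min(top$evalue), , drop = FALSE]
  fams <- unique(top$family)
  if (length(fams) > 1) "AMBIGUOUS" else fams
}

#' Classify one candidate gene
#'
#' Decision table:
#' * full-length, all required domains, intact ORF -> `full`
#' * full-length, all required domains, premature stop or frameshift ->
#'   `pseudogene`
#' * full-length, missing a required domain -> `reject`
#' * partial, unique top hit in the focal family -> `partial`
#' * partial, top hit elsewhere or ambiguous or no hits -> `reject`
#'
#' @param candidate list (or one-row data.frame) with fields `id`,
#'   `completeness` (`"full_length"`/`"partial"`), `domains` (character vector
#'   of domain labels), `premature_stop`, `frameshift` (logicals) and `hits`
#'   (data.frame as in [top_hit_family()], may have zero rows).
#' @param required_domains non-empty character vector of domain labels every
#'   true family member must carry.
#' @param focal_family family label of the gene family being catalogued.
#' @return list with `verdict` and `rule_fired`.
#' @examples
#' classify_candidate(
#'   list(id = "x", completeness = "full_length",
#'        domains = c("MACPF", "EGF", "C2"),
#'        premature_stop = FALSE, frameshift = FALSE,
#'        hits = data.frame()),
#'   required_domains = c("MACPF", "C2"), focal_family = "perforin")
#' @export
classify_candidate <- function(candidate, required_domains, focal_family) {
  if (!length(required_domains)) stop("required_domains must be non-empty")
  comp <- candidate$completeness
  if (!comp %in% c("full_length", "partial"))
    stop("completeness must be 'full_length' or 'partial'")

  if (comp == "full_length") {
    missing <- setdiff(required_domains, candidate$domains)
    if (length(missing))
      return(list(verdict = "reject",
                  rule_fired = paste0("missing required domain(s): ",
                                      paste(missing, collapse = ", "))))
    if (isTRUE(candidate$premature_stop) || isTRUE(candidate$frameshift))
      return(list(verdict = "pseudogene",
                  rule_fired = "required domains present, disrupted ORF"))
    return(list(verdict = "full",
                rule_fired = "required domains present, intact ORF"))
  }

  hits <- candidate$hits
  if (is.null(hits) || nrow(hits) == 0)
    return(list(verdict = "reject", rule_fired = "no evidence"))
  fam <- top_hit_family(hits)
  if (fam == "AMBIGUOUS")
    return(list(verdict = "reject", rule_fired = "ambiguous top hit"))
  if (fam == focal_family)
    return(list(verdict = "partial", rule_fired = "top hit in focal family"))
  list(verdict = "reject", rule_fired = "top hit outside focal family")
}

#' Call completeness from sequence span
#'
#' A candidate too short to contain all required domains is treated as
#' partial. The threshold defaults to 400 residues, roughly the summed minimal
#' lengths of a pore-forming (MACPF) plus membrane-binding (C2) domain.
#'
#' @param span candidate sequence length, residues.
#' @param min_span minimum span regarded as potentially full length.
#' @return `"full_length"` or `"partial"`.
#' @export
completeness_from_span <- function(span, min_span = 400) {
  ifelse(span >= min_span, "full_length", "partial")
}

#' Classify a table of candidates
#'
#' @param meta data.frame: `id`, `species`, `completeness`, `premature_stop`,
#'   `frameshift`.
#' @param domains data.frame: `id`, `domain`, `start`, `end`.
#' @param hits data.frame: `query`, `subject`, `family`, `bitscore`, `evalue`.
#' @inheritParams classify_candidate
#' @return data.frame `id`, `species`, `verdict`, `rule_fired`.
#' @export
classify_table <- function(meta, domains, hits, required_domains,
                           focal_family) {
  res <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$id[i]
    cand <- list(
      id = id,
      completeness = meta$completeness[i],
      domains = domains$domain[domains$id == id],
      premature_stop = as.logical(meta$premature_stop[i]),
      frameshift = as.logical(meta$frameshift[i]),
      hits = hits[hits$query == id, , drop = FALSE])
    cl <- classify_candidate(cand, required_domains, focal_family)
    data.frame(id = id, species = meta$species[i], verdict = cl$verdict,
               rule_fired = cl$rule_fired, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Tally classifications per species
#'
#' Counts full, partial and pseudogene calls (rejects are excluded from the
#' total) and renders the conventional summary string
#' `"(# full, # partial, # pseudogenes) # total"`.
#'
#' @param classifications data.frame with columns `species`, `verdict`.
#' @return data.frame `species`, `full`, `partial`, `pseudogene`, `total`,
#'   `summary`.
#' @examples
#' tally_species(data.frame(species = "hsa", verdict = "full"))
#' @export
tally_species <- function(classifications) {
  sp <- sort(unique(classifications$species))
  out <- do.call(rbind, lapply(sp, function(s) {
    v <- classifications$verdict[classifications$species == s]
    f <- sum(v == "full"); p <- sum(v == "partial"); q <- sum(v == "pseudogene")
    data.frame(species = s, full = f, partial = p, pseudogene = q,
               total = f + p + q,
               summary = sprintf("(%d, %d, %d) %d", f, p, q, f + p + q),
               stringsAsFactors = FALSE)
  }))
  out
}

#' Derive classifier inputs from a simulation
#'
#' Builds the candidate metadata, domain-annotation and similarity-hit tables
#' a search pipeline would produce, using the simulation's reference proteins:
#' percent identity against each reference from the true alignment, bitscore
#' proportional to identity and e-value a monotone transform of it. Domain
#' coordinates follow a fixed fractional layout over the protein.
#'
#' @param sim a `fam_sim`.
#' @return list with `meta`, `domains`, `hits` data.frames.
#' @export
sim_classifier_inputs <- function(sim) {
  stopifnot(inherits(sim, "fam_sim"))
  L <- sim$params$protein_length
  ids <- names(sim$alignment)
  if (!length(ids)) {
    return(list(
      meta = data.frame(id = character(), species = character(),
                        completeness = character(), premature_stop = logical(),
                        frameshift = logical(), stringsAsFactors = FALSE),
      domains = data.frame(id = character(), domain = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE),
      hits = data.frame(query = character(), subject = character(),
                        family = character(), bitscore = numeric(),
                        evalue = numeric(), stringsAsFactors = FALSE)))
  }
  species <- sub("_g[0-9]+$", "", ids)
  pseudo <- vapply(ids, function(id) {
    g <- sim$genomes[[sub("_g[0-9]+$", "", id)]]
    any(g$annotation$premature_stop[g$annotation$gene_id == id])
  }, TRUE)

  meta <- data.frame(id = ids, species = species,
                     completeness = "full_length",
                     premature_stop = pseudo, frameshift = FALSE,
                     stringsAsFactors = FALSE)

  layout <- data.frame(
    domain = c("MACPF", "EGF", "C2"),
    start = pmax(1L, round(L * c(0.10, 0.71, 0.83))),
    end = round(L * c(0.70, 0.80, 1.00)))
  domains <- do.call(rbind, lapply(ids, function(id)
    cbind(data.frame(id = id, stringsAsFactors = FALSE), layout)))

  refs <- sim$references
  hits <- do.call(rbind, lapply(ids, function(id) {
    q <- strsplit(sim$alignment[[id]], "")[[1]]
    do.call(rbind, lapply(seq_len(nrow(refs)), function(j) {
      s <- strsplit(refs$seq[j], "")[[1]]
      ident <- mean(q == s)
      bits <- round(2 * ident * L, 1)
      data.frame(query = id, subject = refs$subject[j], family = refs$family[j],
                 bitscore = bits, evalue = max(10^(-bits / 3), 1e-300),
                 stringsAsFactors = FALSE)
    }))
  }))
  list(meta = meta, domains = domains, hits = hits)
}
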