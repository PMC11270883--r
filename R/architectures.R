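DOMAIN_HIT_COLS <- c("protein_id", "profile_acc", "ali_start", "ali_end",
                     "bitscore", "profile_coverage")

#' Read a domain-hit table from TSV
#'
#' Expected columns: protein_id (namespaced), profile_acc, ali_start,
#' ali_end (1-based inclusive aa coordinates), bitscore,
#' profile_coverage (fraction of the profile covered, in \[0, 1\]).
#'
#' @param path TSV file with a header row.
#' @return data.frame of raw domain hits.
#' @export
readDomainHits <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  missing <- setdiff(DOMAIN_HIT_COLS, names(d))
  if (length(missing))
    stop("domain-hit table lacks columns: ", paste(missing, collapse = ", "))
  d
}

#' Filter raw profile-search hits
#'
#' Keeps a hit iff its bitscore is at least 30 and its profile coverage
#' at least 75% (both boundaries inclusive).
#'
#' @param raw data.frame of domain hits (see [readDomainHits()]).
#' @param minBitscore,minProfileCoverage the two thresholds.
#' @return the filtered data.frame.
#' @export
filterDomainHits <- function(raw, minBitscore = 30,
                             minProfileCoverage = 0.75) {
  raw[raw$bitscore >= minBitscore &
        raw$profile_coverage >= minProfileCoverage, , drop = FALSE]
}

#' Build the domain architecture of one protein
#'
#' Overlapping hits are resolved greedily by descending bitscore (the
#' lower-scoring hit is discarded). The surviving domains are ordered by
#' start coordinate and uncovered runs longer than four amino acids —
#' including the termini — become gap tokens carrying their length.
#' Coverage is the fraction of residues under domain tokens.
#'
#' @param hitsDf filtered hits for a single protein.
#' @param proteinLength protein length in aa.
#' @param proteinId protein id (defaults to the one in `hitsDf`).
#' @return a [DomainArchitecture-class].
#' @export
buildArchitecture <- function(hitsDf, proteinLength, proteinId = NULL) {
  proteinId <- proteinId %||%
    (if (nrow(hitsDf)) hitsDf$protein_id[1L] else NA_character_)
  if (nrow(hitsDf) && length(unique(hitsDf$protein_id)) > 1L)
    stop("hits for more than one protein passed to buildArchitecture")
  if (nrow(hitsDf) && any(hitsDf$ali_start < 1L |
                          hitsDf$ali_start > hitsDf$ali_end |
                          hitsDf$ali_end > proteinLength))
    stop("domain coordinates outside 1..", proteinLength, " for ",
         proteinId)

  # greedy non-overlap resolution by descending bitscore
  o <- order(-hitsDf$bitscore, hitsDf$ali_start, hitsDf$profile_acc)
  kept <- hitsDf[integer(), , drop = FALSE]
  for (i in o) {
    h <- hitsDf[i, ]
    if (nrow(kept) == 0L ||
        all(h$ali_end < kept$ali_start | h$ali_start > kept$ali_end)) {
      kept <- rbind(kept, h)
    }
  }
  kept <- kept[order(kept$ali_start), , drop = FALSE]

  tokens <- data.frame(kind = character(), value = character())
  cursor <- 0L  # last covered position
  addGap <- function(tokens, from, to) {
    len <- to - from + 1L
    if (len > 4L)
      tokens <- rbind(tokens, data.frame(kind = "gap",
                                         value = as.character(len)))
    tokens
  }
  for (i in seq_len(nrow(kept))) {
    if (kept$ali_start[i] > cursor + 1L)
      tokens <- addGap(tokens, cursor + 1L, kept$ali_start[i] - 1L)
    tokens <- rbind(tokens, data.frame(kind = "domain",
                                       value = kept$profile_acc[i]))
    cursor <- kept$ali_end[i]
  }
  if (cursor < proteinLength)
    tokens <- addGap(tokens, cursor + 1L, as.integer(proteinLength))

  covered <- if (nrow(kept)) sum(kept$ali_end - kept$ali_start + 1L) else 0L
  new("DomainArchitecture",
      proteinId = proteinId,
      proteinLength = as.integer(proteinLength),
      tokens = tokens,
      coverage = covered / proteinLength,
      domainCount = nrow(kept))
}

#' Build architectures for all annotated proteins
#'
#' @param hitsDf filtered domain hits for any number of proteins.
#' @param proteinLengths named vector (namespaced protein id -> length).
#' @return named list of [DomainArchitecture-class], one per protein with
#'   at least one surviving hit.
#' @export
buildArchitectures <- function(hitsDf, proteinLengths) {
  if (nrow(hitsDf) == 0L) return(list())
  unknown <- setdiff(unique(hitsDf$protein_id), names(proteinLengths))
  if (length(unknown))
    stop("no length known for protein: ", unknown[1L])
  by_prot <- split(hitsDf, hitsDf$protein_id)
  lapply(by_prot, function(h)
    buildArchitecture(h, proteinLengths[[h$protein_id[1L]]]))
}

#' @describeIn DomainArchitecture-class architecture coverage
#' @param x a `DomainArchitecture`.
#' @export
archCoverage <- function(x) x@coverage

#' @describeIn DomainArchitecture-class number of annotated domains
#' @export
domainCount <- function(x) x@domainCount

#' @describeIn DomainArchitecture-class the domain accessions, in order
#' @export
domainAccessions <- function(x) x@tokens$value[x@tokens$kind == "domain"]

#' Render an architecture as a document (word sequence)
#'
#' Domains are rendered as their accession, uncovered runs as their
#' length in amino acids (a decimal integer). An optional bin width
#' coarsens gap lengths (`floor(len / binWidth) * binWidth`) to limit
#' vocabulary fragmentation; the default of 1 leaves lengths raw.
#'
#' @param arch a [DomainArchitecture-class].
#' @param gapBinWidth bin width for gap lengths (default 1 = off).
#' @return character vector of words.
#' @export
architectureDocument <- function(arch, gapBinWidth = 1L) {
  w <- arch@tokens$value
  if (gapBinWidth > 1L) {
    g <- arch@tokens$kind == "gap"
    w[g] <- as.character(pmax(1L, (as.integer(w[g]) %/% gapBinWidth) *
                                gapBinWidth))
  }
  w
}

setMethod("show", "DomainArchitecture", function(object) {
  cat("DomainArchitecture ", object@proteinId, " (", object@proteinLength,
      " aa): [", paste(architectureDocument(object), collapse = " "),
      "], coverage ", round(object@coverage, 3), "\n", sep = "")
})

#' Build the embedding training corpus from architectures
#'
#' A document (the rendered word sequence) enters the corpus iff its
#' architecture covers at least 70% of the protein; duplicated documents
#' are collapsed to a single training entity. Proteins below the
#' coverage cutoff retain no embedding and are excluded from
#' domain-based orthology.
#'
#' @param architectures named list of [DomainArchitecture-class].
#' @param minCoverage corpus admission cutoff (default 0.70, inclusive).
#' @param gapBinWidth passed to [architectureDocument()].
#' @return list with `corpus` (named list of unique word vectors, keyed
#'   by the space-joined document) and `docIndex` (named character
#'   vector: protein id -> document key).
#' @export
buildCorpus <- function(architectures, minCoverage = 0.70,
                        gapBinWidth = 1L) {
  keep <- vapply(architectures, function(a) a@coverage >= minCoverage,
                 logical(1))
  archs <- architectures[keep]
  docs <- lapply(archs, architectureDocument, gapBinWidth = gapBinWidth)
  keys <- vapply(docs, paste, character(1), collapse = " ")
  uniq <- !duplicated(keys)
  corpus <- setNames(docs[uniq], keys[uniq])
  docIndex <- setNames(keys, vapply(archs, function(a) a@proteinId,
                                    character(1)))
  list(corpus = corpus, docIndex = docIndex)
}
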