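#' Prefilter an architecture pair before cosine scoring
#'
#' A pair is rejected (FALSE) iff any of the four rules applies:
#' one protein is more than 3 times the length of the other; their
#' coverages differ by more than 0.25 (absolute difference of the
#' fractions); one has more than double the annotated domains of the
#' other; or they share no domain accession. All rules are symmetric
#' under argument swap.
#'
#' @param archA,archB [DomainArchitecture-class] objects.
#' @return TRUE (accept) or FALSE (reject).
#' @export
prefilterPair <- function(archA, archB) {
  lenA <- archA@proteinLength; lenB <- archB@proteinLength
  if (max(lenA, lenB) > 3 * min(lenA, lenB)) return(FALSE)
  if (abs(archA@coverage - archB@coverage) > 0.25) return(FALSE)
  dA <- archA@domainCount; dB <- archB@domainCount
  if (max(dA, dB) > 2 * min(dA, dB)) return(FALSE)
  if (length(intersect(domainAccessions(archA),
                       domainAccessions(archB))) == 0L) return(FALSE)
  TRUE
}

#' Cosine-score the surviving architecture pairs of a proteome pair
#'
#' For every pair accepted by [prefilterPair()], the cosine similarity
#' of the two document vectors is computed and stored iff it is at
#' least the threshold ("at least 0.5" by default). Rejected and
#' sub-threshold pairs are absent from the matrix.
#'
#' @param archsA,archsB named lists of [DomainArchitecture-class] for the
#'   two proteomes; only proteins with an embedding are considered.
#' @param emb a [DocEmbeddings-class] covering both proteomes.
#' @param proteomeA,proteomeB species pair labels.
#' @param threshold minimum cosine to store (default 0.5, inclusive).
#' @return an [ArchSimilarity-class].
#' @export
scoreArchitecturePairs <- function(archsA, archsB, emb,
                                   proteomeA, proteomeB,
                                   threshold = 0.5) {
  withEmb <- function(archs) {
    archs[vapply(archs, function(a) a@proteinId %in% names(emb@docIndex),
                 logical(1))]
  }
  archsA <- withEmb(archsA)
  archsB <- withEmb(archsB)
  rows <- list()
  for (a in archsA) {
    va <- docVector(emb, a@proteinId)
    for (b in archsB) {
      if (!prefilterPair(a, b)) next
      cs <- cosineSimilarity(va, docVector(emb, b@proteinId))
      if (cs >= threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          a = a@proteinId, b = b@proteinId, cosine = cs)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), cosine = numeric())
  entries <- entries[order(entries$a, entries$b), , drop = FALSE]
  rownames(entries) <- NULL
  new("ArchSimilarity", proteomeA = proteomeA, proteomeB = proteomeB,
      entries = entries, threshold = threshold)
}

#' @describeIn ArchSimilarity-class stored entries as a data.frame
#' @param x an `ArchSimilarity`.
#' @export
similarityEntries <- function(x) x@entries

setMethod("show", "ArchSimilarity", function(object) {
  cat("ArchSimilarity ", object@proteomeA, "-", object@proteomeB, ": ",
      nrow(object@entries), " pairs >= ", object@threshold, "\n", sep = "")
})

#' Extract domain-based ortholog clusters from a similarity matrix
#'
#' Selects, for every non-empty row (architecture of A), the
#' maximum-cosine partner in B, and for every non-empty column the
#' maximum-cosine partner in A; ties on a maximum are broken by
#' lexicographically smallest partner id. The union of selected pairs is
#' grouped into clusters by shared proteins (connected components of the
#' selected-pair graph).
#'
#' @param M an [ArchSimilarity-class].
#' @return a [PairwiseOrthologs-class] with provenance "domain"; each
#'   cluster carries the attested pairs with their cosines.
#' @export
extractDomainClusters <- function(M) {
  e <- M@entries
  po <- new("PairwiseOrthologs", proteomeA = M@proteomeA,
            proteomeB = M@proteomeB, clusters = list())
  if (nrow(e) == 0L) return(po)

  pickMax <- function(d, by, partner) {
    sel <- lapply(split(d, d[[by]]), function(g) {
      g <- g[g$cosine == max(g$cosine), , drop = FALSE]
      g[order(g[[partner]]), , drop = FALSE][1L, ]
    })
    do.call(rbind, sel)
  }
  sel <- unique(rbind(pickMax(e, "a", "b"), pickMax(e, "b", "a")))

  g <- igraph::graph_from_data_frame(sel[, c("a", "b")], directed = FALSE)
  comp <- igraph::components(g)$membership
  clist <- lapply(sort(unique(comp)), function(ci) {
    nodes <- names(comp)[comp == ci]
    pairs <- sel[sel$a %in% nodes | sel$b %in% nodes, , drop = FALSE]
    pairs <- pairs[order(pairs$a, pairs$b), , drop = FALSE]
    rownames(pairs) <- NULL
    list(seedA = NA_character_, seedB = NA_character_,
         seedScore = NA_real_, membersA = NULL, membersB = NULL,
         pairs = pairs, provenance = "domain")
  })
  # deterministic cluster order: by smallest member id
  ord <- order(vapply(clist, function(cl) min(cl$pairs$a, cl$pairs$b),
                      character(1)))
  po@clusters <- clist[ord]
  po
}
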