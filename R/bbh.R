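#' Threshold a hit table and flag per-query best hits
#'
#' Hits scoring below `t` bits are removed. For each query the
#' maximal-bitscore hit is flagged as best; exact ties are all flagged.
#' All surviving hits (not just the flagged ones) are retained, since
#' inparalog detection needs them.
#'
#' @param table a [HitTable-class].
#' @param t bitscore threshold in bits (default 40).
#' @return a `HitTable` with `isBest` set.
#' @export
reduceToBestHits <- function(table, t = 40) {
  h <- table@hits[table@hits$bitscore >= t, , drop = FALSE]
  if (nrow(h)) {
    best <- tapply(h$bitscore, h$query, max)
    h$isBest <- as.vector(h$bitscore == best[h$query])
  }
  HitTable(table@queryProteome, table@targetProteome, h)
}

#' Build the essential subsets of a proteome pair
#'
#' From the full first-direction alignment A-B: ess(A) is every query
#' with at least one hit scoring >= t, and ess(B) every target appearing
#' in at least one such hit. Proteins outside these subsets cannot be
#' part of a bidirectional best hit, so the reverse alignment only needs
#' ess(B) queried against ess(A).
#'
#' @param tableAB the full A-B [HitTable-class] (raw or reduced).
#' @param t bitscore threshold in bits.
#' @return list with elements `essA` and `essB`, both
#'   [EssentialSubset-class] objects (namespaced member ids).
#' @export
buildEssentialSubsets <- function(tableAB, t = 40) {
  h <- tableAB@hits[tableAB@hits$bitscore >= t, , drop = FALSE]
  list(
    essA = new("EssentialSubset", proteomeId = tableAB@queryProteome,
               memberIds = sort(unique(h$query)), threshold = t),
    essB = new("EssentialSubset", proteomeId = tableAB@targetProteome,
               memberIds = sort(unique(h$target)), threshold = t)
  )
}

#' @describeIn EssentialSubset-class member ids
#' @param x an `EssentialSubset`.
#' @export
memberIds <- function(x) x@memberIds

setMethod("show", "EssentialSubset", function(object) {
  cat("EssentialSubset of '", object@proteomeId, "': ",
      length(object@memberIds), " proteins (t=", object@threshold,
      ")\n", sep = "")
})

bestPairs <- function(table) {
  h <- table@hits[table@hits$isBest, c("query", "target", "bitscore")]
  rownames(h) <- NULL
  h
}

# intersect best-hit pairs of the two directions on (query a, target b)
reciprocalPairs <- function(tabAB, tabRev) {
  ab <- bestPairs(tabAB)
  ba <- bestPairs(tabRev)
  key_ab <- paste(ab$query, ab$target)
  key_ba <- paste(ba$target, ba$query)
  m <- match(key_ab, key_ba)
  keep <- !is.na(m)
  out <- data.frame(a = ab$query[keep], b = ab$target[keep],
                    scoreAB = ab$bitscore[keep],
                    scoreBA = ba$bitscore[m[keep]])
  out[order(out$a, out$b), , drop = FALSE]
}

#' Infer bidirectional best hits from two full-direction alignments
#'
#' A pair (a, b) is returned iff b is the best hit for query a in A-B and
#' a is the best hit for query b in B-A. Both tables must already be
#' reduced with [reduceToBestHits()] at the same threshold, which also
#' enforces that seed scores are >= t. Bitscore ties produce multiple
#' flagged best hits, so a tie can yield more than one reciprocal pair.
#'
#' @param tableAB,tableBA reduced [HitTable-class] objects for the two
#'   directions.
#' @return data.frame with columns `a`, `b`, `scoreAB`, `scoreBA`.
#' @export
inferBBHFull <- function(tableAB, tableBA) {
  stopifnot(tableAB@queryProteome == tableBA@targetProteome,
            tableAB@targetProteome == tableBA@queryProteome)
  reciprocalPairs(tableAB, tableBA)
}

#' Infer bidirectional best hits using the essential alignment
#'
#' Same as [inferBBHFull()], but the second condition is evaluated on the
#' reduced alignment of ess(B) queried against ess(A): (a, b) is returned
#' iff b is best for a in the full A-B alignment and a is best for b in
#' ess(B)-ess(A).
#'
#' @param tableAB the reduced full A-B [HitTable-class].
#' @param tableEssBA the reduced [HitTable-class] of ess(B) vs ess(A).
#' @return data.frame with columns `a`, `b`, `scoreAB`, `scoreBA`.
#' @export
inferBBHEssential <- function(tableAB, tableEssBA) {
  stopifnot(tableAB@queryProteome == tableEssBA@targetProteome,
            tableAB@targetProteome == tableEssBA@queryProteome)
  reciprocalPairs(tableAB, tableEssBA)
}

# symmetric intra-proteome score lookup: max over both stored directions
intraScore <- function(intra, x, y) {
  h <- intra@hits
  s <- c(h$bitscore[h$query == x & h$target == y],
         h$bitscore[h$query == y & h$target == x])
  if (length(s)) max(s) else NA_real_
}

#' Cluster inparalogs around seed ortholog pairs
#'
#' InParanoid-style clustering: for each seed pair (a, b), a protein x of
#' species A joins the cluster as an inparalog iff its intra-proteome
#' score against the seed, score(x, a), is at least the seed score.
#' Confidence is (score(x, a) - seedScore) / (selfScore(a) - seedScore),
#' clipped to \[0, 1\]; seeds themselves carry confidence 1. A protein
#' qualifying for several clusters is assigned to the one where its
#' confidence is highest (ties: lexicographically smallest seed);
#' proteins that are seeds of any cluster never join another cluster as
#' inparalogs.
#'
#' @param seeds data.frame from [inferBBHFull()]/[inferBBHEssential()].
#' @param intraAA,intraBB intra-proteome [HitTable-class]s, reduced at the
#'   same threshold as the seeds.
#' @param proteomeA,proteomeB species pair labels.
#' @return a [PairwiseOrthologs-class] with provenance "graph".
#' @export
clusterInparalogs <- function(seeds, intraAA, intraBB,
                              proteomeA, proteomeB) {
  seedScore <- (seeds$scoreAB + seeds$scoreBA) / 2
  seedIds <- unique(c(seeds$a, seeds$b))

  side <- function(intra, seedCol) {
    # candidate inparalogs per seed from one species' intra table
    cand <- list()
    if (nrow(seeds) == 0L) return(cand)
    h <- intra@hits
    for (i in seq_len(nrow(seeds))) {
      sd <- seeds[[seedCol]][i]
      sc <- h[(h$query == sd | h$target == sd), , drop = FALSE]
      if (nrow(sc) == 0L) next
      other <- ifelse(sc$query == sd, sc$target, sc$query)
      score <- tapply(sc$bitscore, other, max)
      other <- names(score)
      keep <- !(other %in% seedIds) & score >= seedScore[i]
      if (!any(keep)) next
      self <- intraScore(intra, sd, sd)
      denom <- if (is.na(self) || self <= seedScore[i]) NA_real_
               else self - seedScore[i]
      conf <- if (is.na(denom)) rep(1, sum(keep))
              else pmin(1, pmax(0, (score[keep] - seedScore[i]) / denom))
      cand[[i]] <- data.frame(id = other[keep], confidence = unname(conf),
                              cluster = i)
    }
    cand
  }

  resolve <- function(cand) {
    # each inparalog keeps only its highest-confidence cluster
    d <- do.call(rbind, cand)
    if (is.null(d) || nrow(d) == 0L) return(d)
    d <- d[order(d$id, -d$confidence, d$cluster), , drop = FALSE]
    d[!duplicated(d$id), , drop = FALSE]
  }

  inA <- resolve(side(intraAA, "a"))
  inB <- resolve(side(intraBB, "b"))

  clusters <- lapply(seq_len(nrow(seeds)), function(i) {
    mA <- data.frame(id = seeds$a[i], confidence = 1)
    mB <- data.frame(id = seeds$b[i], confidence = 1)
    if (!is.null(inA)) {
      e <- inA[inA$cluster == i, c("id", "confidence")]
      mA <- rbind(mA, e)
    }
    if (!is.null(inB)) {
      e <- inB[inB$cluster == i, c("id", "confidence")]
      mB <- rbind(mB, e)
    }
    rownames(mA) <- rownames(mB) <- NULL
    list(seedA = seeds$a[i], seedB = seeds$b[i],
         seedScore = seedScore[i], membersA = mA, membersB = mB,
         pairs = NULL, provenance = "graph")
  })

  new("PairwiseOrthologs", proteomeA = proteomeA, proteomeB = proteomeB,
      clusters = clusters)
}

#' @describeIn PairwiseOrthologs-class the cluster list
#' @param x a `PairwiseOrthologs`.
#' @export
clusters <- function(x) x@clusters

#' @describeIn PairwiseOrthologs-class all member ids of one cluster
#' @param cl a single cluster (element of `clusters(x)`).
#' @export
clusterMembers <- function(cl) {
  if (!is.null(cl$pairs) && is.null(cl$membersA)) {
    unique(c(cl$pairs$a, cl$pairs$b))
  } else {
    unique(c(cl$membersA$id, cl$membersB$id))
  }
}

setMethod("show", "PairwiseOrthologs", function(object) {
  prov <- table(vapply(object@clusters, `[[`, "", "provenance"))
  cat("PairwiseOrthologs ", object@proteomeA, "-", object@proteomeB,
      ": ", length(object@clusters), " clusters",
      if (length(prov)) paste0(" (", paste(names(prov), prov, sep = ":",
                                           collapse = ", "), ")"),
      "\n", sep = "")
})

#' Compare full-alignment BBH with essential-alignment BBH for a pair
#'
#' Runs the toy symmetric scorer in both full directions and along the
#' essential-subset path, infers both BBH sets and reports how the
#' reduction behaved: with a symmetric scorer the full-alignment BBH set
#' is always contained in the essential-alignment set, and the two are
#' equal whenever every best hit of the full tables scores at least t.
#'
#' @param A,B [Proteome-class] objects.
#' @param t bitscore threshold in bits.
#' @param ... passed to [toyAlignment()].
#' @return list with `fullPairs`, `essentialPairs` (data.frames),
#'   `subsetHolds`, `allBestAboveT`, `equal` (logicals) and
#'   `excludedFraction` (fraction of the pair's proteins absent from the
#'   essential subsets, i.e. skipped by the second alignment).
#' @export
compareBBHDefinitions <- function(A, B, t = 40, ...) {
  rawAB <- toyAlignment(A, B, ...)
  rawBA <- toyAlignment(B, A, ...)
  redAB <- reduceToBestHits(rawAB, t)
  redBA <- reduceToBestHits(rawBA, t)
  full <- inferBBHFull(redAB, redBA)

  ess <- buildEssentialSubsets(rawAB, t)
  nEssA <- length(memberIds(ess$essA))
  nEssB <- length(memberIds(ess$essB))
  if (nEssA && nEssB) {
    essBA <- reduceToBestHits(
      toyAlignment(subsetProteome(B, memberIds(ess$essB)),
                   subsetProteome(A, memberIds(ess$essA)), ...), t)
  } else {
    essBA <- HitTable(proteomeId(B), proteomeId(A), emptyHits())
  }
  essential <- inferBBHEssential(redAB, essBA)

  key <- function(d) sort(paste(d$a, d$b))
  bestAbove <- function(raw) {
    h <- raw@hits
    if (nrow(h) == 0L) return(TRUE)
    all(tapply(h$bitscore, h$query, max) >= t)
  }
  list(fullPairs = full, essentialPairs = essential,
       subsetHolds = all(key(full) %in% key(essential)),
       allBestAboveT = bestAbove(rawAB) && bestAbove(rawBA),
       equal = identical(key(full), key(essential)),
       excludedFraction = 1 - (nEssA + nEssB) /
         (nProteins(A) + nProteins(B)))
}
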