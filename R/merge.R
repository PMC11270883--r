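#' Merge graph- and domain-based clusters for one species pair
#'
#' Graph-based predictions are regarded as the more accurate and are
#' never modified or removed; domain-based clusters are integrated into
#' them by three rules:
#' \describe{
#'   \item{Case 1}{a domain cluster sharing no protein with any graph
#'     cluster is accepted as a new cluster only if every member has
#'     architecture coverage >= 75% and every attested pair has an equal
#'     number of annotated domains; otherwise it is rejected entirely.}
#'   \item{Case 2}{a domain cluster whose proteins are all already in
#'     graph clusters is dropped; the graph clusters are kept without
#'     modification.}
#'   \item{Case 3}{partial overlap: each novel protein with coverage
#'     >= 75% is inserted into the graph cluster containing its
#'     highest-cosine partner (ties: lexicographically smallest
#'     partner); the remaining novel proteins are dropped.}
#' }
#'
#' @param G [PairwiseOrthologs-class] from the graph pipeline.
#' @param D [PairwiseOrthologs-class] from the domain pipeline (may have
#'   zero clusters).
#' @param coverage named numeric: namespaced protein id -> architecture
#'   coverage fraction.
#' @param domainCounts named integer: namespaced protein id -> number of
#'   annotated domains.
#' @param minCoverage insertion/acceptance coverage cutoff (default
#'   0.75, inclusive).
#' @return a merged [PairwiseOrthologs-class]; clusters that received
#'   domain-based members carry provenance "graph+domain" and list them
#'   in `domainAdded`.
#' @export
mergePairwise <- function(G, D, coverage, domainCounts,
                          minCoverage = 0.75) {
  merged <- G@clusters
  gMembers <- lapply(merged, clusterMembers)
  allG <- unique(unlist(gMembers, use.names = FALSE))
  cov <- function(id) if (id %in% names(coverage)) coverage[[id]] else 0
  dcount <- function(id)
    if (id %in% names(domainCounts)) domainCounts[[id]] else NA_integer_

  for (d in D@clusters) {
    dProts <- unique(c(d$pairs$a, d$pairs$b))
    inG <- dProts %in% allG
    if (all(inG)) next                      # case 2: keep G as is
    if (!any(inG)) {                        # case 1: all-novel cluster
      covOk <- all(vapply(dProts, cov, numeric(1)) >= minCoverage)
      cntEq <- all(vapply(seq_len(nrow(d$pairs)), function(i) {
        ca <- dcount(d$pairs$a[i]); cb <- dcount(d$pairs$b[i])
        !is.na(ca) && !is.na(cb) && ca == cb
      }, logical(1)))
      if (covOk && cntEq) {
        merged[[length(merged) + 1L]] <- d
        allG <- c(allG, dProts)
        gMembers[[length(gMembers) + 1L]] <- dProts
      }
      next
    }
    # case 3: insert qualifying novel proteins into overlapping clusters
    for (p in dProts[!inG]) {
      if (cov(p) < minCoverage) next
      prs <- d$pairs
      partnerOf <- ifelse(prs$a == p, prs$b,
                          ifelse(prs$b == p, prs$a, NA_character_))
      cand <- which(!is.na(partnerOf) & partnerOf %in% allG)
      if (length(cand) == 0L) next
      cand <- cand[order(-prs$cosine[cand], partnerOf[cand])]
      partner <- partnerOf[cand[1L]]
      cs <- prs$cosine[cand[1L]]
      ci <- which(vapply(gMembers, function(m) partner %in% m,
                         logical(1)))[1L]
      cl <- merged[[ci]]
      if (is.null(cl$membersA)) next  # only graph clusters are extended
      sideA <- splitNsId(p)$proteome == G@proteomeA
      row <- data.frame(id = p, confidence = cs)
      if (sideA) cl$membersA <- rbind(cl$membersA, row)
      else cl$membersB <- rbind(cl$membersB, row)
      cl$provenance <- "graph+domain"
      cl$domainAdded <- c(cl$domainAdded, p)
      merged[[ci]] <- cl
      gMembers[[ci]] <- c(gMembers[[ci]], p)
      allG <- c(allG, p)
    }
  }
  new("PairwiseOrthologs", proteomeA = G@proteomeA,
      proteomeB = G@proteomeB, clusters = merged)
}
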