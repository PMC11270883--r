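# Independent oracles and fixture builders shared across tests. These
# deliberately use naive base-R computations (nested loops, dense
# matrices) so they exercise none of the package's code paths.

# hit tables (both directions, reduced) from an explicit score matrix;
# scores[i, j] = score between protein i of A and protein j of B
tablesFromMatrix <- function(scores, spA = "A", spB = "B", t = 40) {
  idsA <- nsId(spA, rownames(scores))
  idsB <- nsId(spB, colnames(scores))
  rows_ab <- list(); rows_ba <- list()
  for (i in seq_len(nrow(scores))) for (j in seq_len(ncol(scores))) {
    s <- scores[i, j]
    if (s > 0) {
      rows_ab[[length(rows_ab) + 1L]] <-
        data.frame(query = idsA[i], target = idsB[j], bitscore = s)
      rows_ba[[length(rows_ba) + 1L]] <-
        data.frame(query = idsB[j], target = idsA[i], bitscore = s)
    }
  }
  mk <- function(rows, q, tg) {
    h <- if (length(rows)) do.call(rbind, rows) else
      data.frame(query = character(), target = character(),
                 bitscore = numeric())
    h$isBest <- FALSE
    HitTable(q, tg, h)
  }
  list(ab = reduceToBestHits(mk(rows_ab, spA, spB), t),
       ba = reduceToBestHits(mk(rows_ba, spB, spA), t))
}

# brute-force BBH: checks both conditions over every (i, j) of the score
# matrix directly
bruteForceBBH <- function(scores, spA = "A", spB = "B", t = 40) {
  out <- list()
  for (i in seq_len(nrow(scores))) for (j in seq_len(ncol(scores))) {
    s <- scores[i, j]
    if (s < t) next
    if (s == max(scores[i, ]) && s == max(scores[, j]))
      out[[length(out) + 1L]] <-
        data.frame(a = nsId(spA, rownames(scores)[i]),
                   b = nsId(spB, colnames(scores)[j]))
  }
  d <- if (length(out)) do.call(rbind, out) else
    data.frame(a = character(), b = character())
  d[order(d$a, d$b), , drop = FALSE]
}

pairKey <- function(df) sort(paste(df$a, df$b))

# independent dense-matrix MCL; same declared algorithm, naive coding
referenceMCL <- function(adj, inflation = 1.5, pruning = 1e-5,
                         tol = 1e-6, maxIter = 100L) {
  n <- nrow(adj)
  M <- adj
  diag(M) <- diag(M) + 1
  colnorm <- function(M) {
    for (j in seq_len(n)) {
      s <- sum(M[, j])
      if (s == 0) { M[j, j] <- 1; s <- 1 }
      M[, j] <- M[, j] / s
    }
    M
  }
  M <- colnorm(M)
  for (it in seq_len(maxIter)) {
    M2 <- (M %*% M)^inflation
    M2[M2 < pruning] <- 0
    M2 <- colnorm(M2)
    d <- max(abs(M2 - M))
    M <- M2
    if (d < tol) break
  }
  supp <- (M + t(M)) > 0
  comp <- integer(n); seen <- logical(n); k <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (seen[v]) next
      seen[v] <- TRUE; comp[v] <- k
      queue <- c(queue, which(supp[v, ] & !seen))
    }
  }
  comp
}

# canonical form of a partition for label-free comparison
canonicalPartition <- function(groups) {
  gs <- lapply(groups, sort)
  paste(sort(vapply(gs, paste, character(1), collapse = ",")),
        collapse = ";")
}

# random DomainArchitecture for property tests
randomArchitecture <- function(id = "A!p1", accPool = sprintf("PF%05d", 1:6)) {
  len <- sample(60:400, 1L)
  nd <- sample(1:4, 1L)
  bounds <- sort(sample.int(len, 2L * nd))
  starts <- bounds[seq(1L, 2L * nd, by = 2L)]
  ends <- bounds[seq(2L, 2L * nd, by = 2L)]
  hits <- data.frame(protein_id = id,
                     profile_acc = sample(accPool, nd, replace = TRUE),
                     ali_start = starts, ali_end = ends,
                     bitscore = runif(nd, 30, 120),
                     profile_coverage = runif(nd, 0.75, 1))
  buildArchitecture(hits, len)
}

# two-species planted-fusion fixture used in several tests
fusionFixture <- function(seed = 11L) {
  spec <- syntheticProteomeSpec(
    nSpecies = 2L, proteinsPerSpecies = 8L, meanLen = 150L,
    duplicationRate = 0, divergenceLevels = c(0.02, 0.05),
    fusionEvents = list(list(species = 2L, families = c(1L, 2L))),
    seed = seed)
  g <- generateProteomes(spec)
  g$domainHits <- synthDomainHits(g$proteomes, g$truth)
  g
}
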