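test_that("domain-hit filtering uses inclusive 30-bit / 75% boundaries", {
  raw <- data.frame(
    protein_id = "A!p", profile_acc = "PF1",
    ali_start = 1L, ali_end = 50L,
    bitscore = c(29, 50, 30, 100),
    profile_coverage = c(0.9, 0.74, 0.75, 0.80))
  kept <- filterDomainHits(raw)
  expect_equal(kept$bitscore, c(30, 100))
})

test_that("architecture construction: ordering, gap rule, greedy overlap
           resolution and coverage", {
  h <- data.frame(protein_id = "A!p", profile_acc = c("PF00001", "PF00002"),
                  ali_start = c(1L, 150L), ali_end = c(100L, 300L),
                  bitscore = c(80, 70), profile_coverage = 0.9)
  a <- buildArchitecture(h, 300L)
  expect_equal(architectureDocument(a), c("PF00001", "49", "PF00002"))
  expect_equal(archCoverage(a), (100 + 151) / 300)
  expect_equal(domainCount(a), 2L)

  # a 4-aa gap emits no token ("longer than four" is strict)
  h2 <- data.frame(protein_id = "A!p", profile_acc = c("PF1", "PF2"),
                   ali_start = c(1L, 55L), ali_end = c(50L, 100L),
                   bitscore = c(50, 50), profile_coverage = 0.9)
  expect_equal(architectureDocument(buildArchitecture(h2, 100L)),
               c("PF1", "PF2"))
  # 5-aa gap does, and so do termini
  h3 <- data.frame(protein_id = "A!p", profile_acc = "PF1",
                   ali_start = 6L, ali_end = 50L,
                   bitscore = 50, profile_coverage = 0.9)
  expect_equal(architectureDocument(buildArchitecture(h3, 60L)),
               c("5", "PF1", "10"))

  # overlapping hits: greedy keeps the higher bitscore only, which on a
  # 2-hit case equals exhaustive non-overlap maximization by score
  h4 <- data.frame(protein_id = "A!p", profile_acc = c("PFLOW", "PFHIGH"),
                   ali_start = c(10L, 40L), ali_end = c(60L, 90L),
                   bitscore = c(60, 80), profile_coverage = 0.9)
  a4 <- buildArchitecture(h4, 100L)
  expect_equal(domainAccessions(a4), "PFHIGH")
  expect_error(buildArchitecture(
    data.frame(protein_id = "A!p", profile_acc = "PF1", ali_start = 0L,
               ali_end = 10L, bitscore = 50, profile_coverage = 0.9), 100L))
})

test_that("corpus admission: 70% coverage inclusive, duplicates collapse", {
  arch <- function(id, cov, acc = "PF1") {
    len <- 100L
    end <- as.integer(round(cov * len))
    buildArchitecture(data.frame(protein_id = id, profile_acc = acc,
                                 ali_start = 1L, ali_end = end,
                                 bitscore = 50, profile_coverage = 0.9),
                      len)
  }
  archs <- list(arch("A!p1", 0.69), arch("A!p2", 0.70),
                arch("A!p3", 0.80), arch("B!q1", 0.80))
  names(archs) <- vapply(archs, function(a) a@proteinId, "")
  cc <- buildCorpus(archs)
  expect_false("A!p1" %in% names(cc$docIndex))
  expect_true("A!p2" %in% names(cc$docIndex))
  # p3 and q1 have identical documents -> one corpus entry, both mapped
  expect_equal(cc$docIndex[["A!p3"]], cc$docIndex[["B!q1"]])
  expect_equal(length(cc$corpus),
               length(unique(unname(cc$docIndex))))
})

test_that("DBOW embeddings: dimension, determinism, and identity of
           identical documents", {
  docs <- list(d1 = c("PF1"), d2 = c("PF2"), d3 = c("PF1", "12", "PF2"),
               d4 = c("PF3"), d5 = c("PF3", "8"))
  emb <- trainEmbeddings(docs, seed = 3L, epochs = 60L)
  expect_equal(dim(emb@vectors), c(5L, 100L))
  emb2 <- trainEmbeddings(docs, seed = 3L, epochs = 60L)
  expect_identical(emb@vectors, emb2@vectors)
  embOther <- trainEmbeddings(docs, seed = 4L, epochs = 60L)
  expect_false(identical(emb@vectors, embOther@vectors))
  expect_error(trainEmbeddings(list()), "empty")
  # two proteins sharing one document share one vector exactly
  cc <- list(corpus = docs,
             docIndex = c("A!x" = "d1", "B!y" = "d1"))
  emb3 <- trainEmbeddings(cc$corpus, seed = 1L, epochs = 30L,
                          docIndex = cc$docIndex)
  expect_identical(docVector(emb3, "A!x"), docVector(emb3, "B!y"))
  expect_equal(cosineSimilarity(docVector(emb3, "A!x"),
                                docVector(emb3, "B!y")), 1)
})

test_that("all four prefilter rules fire and are symmetric over random
           architecture pairs", {
  mk <- function(len, cov, nd, accs) {
    # direct construction bypassing buildArchitecture for exact control
    new("DomainArchitecture", proteinId = "x", proteinLength = as.integer(len),
        tokens = data.frame(kind = rep("domain", nd),
                            value = rep_len(accs, nd)),
        coverage = cov, domainCount = as.integer(nd))
  }
  base <- mk(100L, 0.9, 2L, c("PF1", "PF2"))
  expect_true(prefilterPair(base, base))
  expect_false(prefilterPair(base, mk(350L, 0.9, 2L, c("PF1", "PF2"))))   # length
  expect_false(prefilterPair(base, mk(100L, 0.64, 2L, c("PF1", "PF2"))))  # coverage
  expect_false(prefilterPair(base, mk(100L, 0.9, 5L, c("PF1", "PF2"))))   # count
  expect_false(prefilterPair(base, mk(100L, 0.9, 2L, c("PF8", "PF9"))))   # mutual
  # boundary: exactly 3x length and exactly double domains are accepted
  expect_true(prefilterPair(base, mk(300L, 0.9, 2L, c("PF1", "PF2"))))
  expect_true(prefilterPair(base, mk(100L, 0.9, 4L, c("PF1", "PF2"))))

  set.seed(99)
  for (i in 1:300) {
    a <- randomArchitecture("A!p")
    b <- randomArchitecture("B!q")
    expect_identical(prefilterPair(a, b), prefilterPair(b, a))
  }
})

test_that("cosine scoring stores only pairs at or above threshold and
           matches direct recomputation", {
  g <- fusionFixture(seed = 13L)
  archs <- buildArchitectures(filterDomainHits(g$domainHits),
                              do.call(c, unname(lapply(g$proteomes,
                                function(p) setNames(proteinLengths(p),
                                  nsId(proteomeId(p),
                                       names(proteinLengths(p))))))))
  cc <- buildCorpus(archs)
  emb <- trainEmbeddings(cc$corpus, seed = 2L, docIndex = cc$docIndex)
  sp <- vapply(archs, function(a) splitNsId(a@proteinId)$proteome, "")
  M <- scoreArchitecturePairs(archs[sp == "sp01"], archs[sp == "sp02"],
                              emb, "sp01", "sp02")
  e <- similarityEntries(M)
  expect_gt(nrow(e), 0L)
  expect_true(all(e$cosine >= 0.5))
  for (k in seq_len(nrow(e))) {
    expect_equal(e$cosine[k],
                 cosineSimilarity(docVector(emb, e$a[k]),
                                  docVector(emb, e$b[k])))
  }
  # monotonicity: a higher threshold never stores more pairs
  M8 <- scoreArchitecturePairs(archs[sp == "sp01"], archs[sp == "sp02"],
                               emb, "sp01", "sp02", threshold = 0.8)
  expect_lte(nrow(similarityEntries(M8)), nrow(e))
  expect_true(all(paste(similarityEntries(M8)$a, similarityEntries(M8)$b)
                  %in% paste(e$a, e$b)))
})

test_that("domain cluster extraction equals brute-force row/column argmax
           selection", {
  mkM <- function(entries) new("ArchSimilarity", proteomeA = "A",
                               proteomeB = "B", entries = entries,
                               threshold = 0.5)
  one <- mkM(data.frame(a = "A!a1", b = "B!b1", cosine = 0.9))
  cl <- clusters(extractDomainClusters(one))
  expect_length(cl, 1L)
  expect_equal(cl[[1L]]$pairs$cosine, 0.9)
  expect_equal(cl[[1L]]$provenance, "domain")

  diag2 <- mkM(data.frame(a = c("A!a1", "A!a2", "A!a1"),
                          b = c("B!b1", "B!b2", "B!b2"),
                          cosine = c(0.9, 0.8, 0.55)))
  cl2 <- clusters(extractDomainClusters(diag2))
  expect_length(cl2, 2L)

  set.seed(41)
  for (rep in 1:20) {
    n <- sample(2:6, 1L); m <- sample(2:6, 1L)
    dens <- matrix(round(runif(n * m), 3), n, m)
    dens[dens < 0.5] <- 0
    ent <- which(dens > 0, arr.ind = TRUE)
    if (nrow(ent) == 0L) next
    e <- data.frame(a = nsId("A", sprintf("a%d", ent[, 1L])),
                    b = nsId("B", sprintf("b%d", ent[, 2L])),
                    cosine = dens[ent])
    got <- clusters(extractDomainClusters(mkM(e)))
    gotPairs <- sort(unlist(lapply(got, function(cl)
      paste(cl$pairs$a, cl$pairs$b))))
    # brute force: row and column maxima with lexicographic ties
    want <- character()
    for (i in seq_len(n)) if (any(dens[i, ] > 0)) {
      j <- which(dens[i, ] == max(dens[i, ]))[1L]
      want <- c(want, paste(nsId("A", sprintf("a%d", i)),
                            nsId("B", sprintf("b%d", j))))
    }
    for (j in seq_len(m)) if (any(dens[, j] > 0)) {
      i <- which(dens[, j] == max(dens[, j]))[1L]
      want <- c(want, paste(nsId("A", sprintf("a%d", i)),
                            nsId("B", sprintf("b%d", j))))
    }
    expect_equal(gotPairs, sort(unique(want)))
  }
})
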