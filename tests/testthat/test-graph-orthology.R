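test_that("toy scorer is symmetric and maximal on self-alignment", {
  g <- generateProteomes(syntheticProteomeSpec(nSpecies = 2L,
                                               proteinsPerSpecies = 10L,
                                               divergenceLevels = 0.1,
                                               seed = 21L))
  A <- g$proteomes[[1L]]; B <- g$proteomes[[2L]]
  ab <- toyAlignment(A, B); ba <- toyAlignment(B, A)
  key_ab <- paste(hits(ab)$query, hits(ab)$target)
  key_ba <- paste(hits(ba)$target, hits(ba)$query)
  expect_setequal(key_ab, key_ba)
  expect_equal(hits(ab)$bitscore[order(key_ab)],
               hits(ba)$bitscore[order(key_ba)])
  # self-alignment: each protein's top hit is itself
  aa <- reduceToBestHits(toyAlignment(A, A), t = 0)
  h <- hits(aa)
  best_self <- h[h$query == h$target, ]
  for (q in unique(h$query))
    expect_true(max(h$bitscore[h$query == q]) ==
                  best_self$bitscore[best_self$query == q])
  # disjoint k-mer spaces give an empty table
  p1 <- Proteome("x", c(a = strrep("MK", 30)))
  p2 <- Proteome("y", c(b = strrep("WC", 30)))
  expect_equal(nHits(toyAlignment(p1, p2)), 0L)
})

test_that("BLAST-tab parsing consumes columns 1, 2 and 12", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\tt1\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t185.2",
    "q1\tt2\t40.0\t80\t40\t2\t5\t84\t3\t82\t1e-10\t52.0",
    "q2\tt1\t88.0\t90\t10\t1\t1\t90\t1\t90\t1e-40\t150.0"), tmp)
  ht <- parseBlastTab(tmp, "A", "B")
  expect_equal(nHits(ht), 3L)
  expect_equal(hits(ht)$query, nsId("A", c("q1", "q1", "q2")))
  expect_equal(hits(ht)$bitscore, c(185.2, 52.0, 150.0))
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nHits(parseBlastTab(empty, "A", "B")), 0L)
})

test_that("best-hit reduction matches a brute-force per-query argmax", {
  set.seed(8)
  h <- data.frame(
    query = nsId("A", sample(sprintf("q%02d", 1:10), 60, replace = TRUE)),
    target = nsId("B", sample(sprintf("t%02d", 1:12), 60, replace = TRUE)),
    bitscore = round(runif(60, 10, 100)))
  h <- h[!duplicated(h[, 1:2]), ]
  ht <- HitTable("A", "B", h)
  red <- reduceToBestHits(ht, t = 40)
  expect_true(all(hits(red)$bitscore >= 40))
  # brute force per query
  kept <- h[h$bitscore >= 40, ]
  for (q in unique(kept$query)) {
    sub <- hits(red)[hits(red)$query == q, ]
    expect_setequal(sub$target[sub$isBest],
                    kept$target[kept$query == q &
                                  kept$bitscore == max(kept$bitscore[
                                    kept$query == q])])
  }
  # simple cases: both hits kept, top flagged; all below t -> empty
  ht2 <- HitTable("A", "B", data.frame(
    query = nsId("A", c("q", "q")), target = nsId("B", c("x", "y")),
    bitscore = c(50, 40)))
  r2 <- hits(reduceToBestHits(ht2, 40))
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$isBest, c(TRUE, FALSE))
  expect_equal(nHits(reduceToBestHits(ht2, 60)), 0L)
})

test_that("essential subsets apply the threshold on both sides", {
  ht <- HitTable("A", "B", data.frame(
    query = nsId("A", c("a1", "a2")), target = nsId("B", c("b1", "b2")),
    bitscore = c(50, 30)))
  ess <- buildEssentialSubsets(ht, t = 40)
  expect_equal(memberIds(ess$essA), nsId("A", "a1"))
  expect_equal(memberIds(ess$essB), nsId("B", "b1"))
  ess0 <- buildEssentialSubsets(HitTable("A", "B", data.frame(
    query = character(), target = character(), bitscore = numeric())), 40)
  expect_length(memberIds(ess0$essA), 0L)
  expect_length(memberIds(ess0$essB), 0L)
})

test_that("full BBH equals the exhaustive double-argmax oracle", {
  # hand cases
  sc <- matrix(0, 2, 2, dimnames = list(c("a1", "a2"), c("b1", "b2")))
  sc["a1", "b1"] <- 90
  tt <- tablesFromMatrix(sc)
  expect_equal(inferBBHFull(tt$ab, tt$ba)[, c("a", "b")],
               data.frame(a = "A!a1", b = "B!b1"))
  # reciprocity failure: a1 -> b1 best, but b1 -> a2 best, so (a1, b1)
  # is not returned
  sc2 <- matrix(c(50, 60, 0, 0), 2, 2,
                dimnames = list(c("a1", "a2"), c("b1", "b2")))
  tt2 <- tablesFromMatrix(sc2)
  got2 <- inferBBHFull(tt2$ab, tt2$ba)
  expect_false("A!a1 B!b1" %in% pairKey(got2))
  expect_equal(pairKey(got2), pairKey(bruteForceBBH(sc2)))
  # randomized: equality with brute force over 25 draws
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(3:8, 1L); m <- sample(3:8, 1L)
    sc <- matrix(sample(c(0, 0, 30, 45, 60, 80), n * m, replace = TRUE),
                 n, m, dimnames = list(sprintf("a%d", 1:n),
                                       sprintf("b%d", 1:m)))
    tt <- tablesFromMatrix(sc)
    got <- inferBBHFull(tt$ab, tt$ba)
    expect_equal(pairKey(got), pairKey(bruteForceBBH(sc)))
  }
})

test_that("essential BBH is a superset of full BBH and equals it when
           every best hit clears the threshold (symmetric scorer)", {
  essTables <- function(sc, t = 40) {
    tt <- tablesFromMatrix(sc, t = t)
    raw_ab <- HitTable("A", "B", within(hits(tablesFromMatrix(sc, t = 0)$ab),
                                        isBest <- FALSE))
    ess <- buildEssentialSubsets(raw_ab, t)
    scE <- sc[rownames(sc) %in% splitNsId(memberIds(ess$essA))$protein,
              colnames(sc) %in% splitNsId(memberIds(ess$essB))$protein,
              drop = FALSE]
    # essential reverse table: ess(B) queried against ess(A)
    rows <- list()
    for (j in seq_len(ncol(scE))) for (i in seq_len(nrow(scE))) {
      if (scE[i, j] > 0)
        rows[[length(rows) + 1L]] <- data.frame(
          query = nsId("B", colnames(scE)[j]),
          target = nsId("A", rownames(scE)[i]),
          bitscore = scE[i, j])
    }
    h <- if (length(rows)) do.call(rbind, rows) else
      data.frame(query = character(), target = character(),
                 bitscore = numeric())
    h$isBest <- FALSE
    list(ab = tt$ab, ba = tt$ba,
         essba = reduceToBestHits(HitTable("B", "A", h), t))
  }
  set.seed(123)
  for (rep in 1:25) {
    n <- sample(4:10, 1L); m <- sample(4:10, 1L)
    sc <- matrix(sample(c(0, 20, 35, 45, 60, 90), n * m, replace = TRUE),
                 n, m, dimnames = list(sprintf("a%02d", 1:n),
                                       sprintf("b%02d", 1:m)))
    et <- essTables(sc)
    full <- inferBBHFull(et$ab, et$ba)
    essn <- inferBBHEssential(et$ab, et$essba)
    expect_true(all(pairKey(full) %in% pairKey(essn)))
    bestOk <- all(apply(sc, 1, function(r) !any(r > 0) || max(r) >= 40)) &&
      all(apply(sc, 2, function(c) !any(c > 0) || max(c) >= 40))
    if (bestOk) expect_equal(pairKey(essn), pairKey(full))
  }
  # no reduction at all: essential equals full by construction
  sc <- matrix(c(80, 41, 42, 90), 2, 2,
               dimnames = list(c("a1", "a2"), c("b1", "b2")))
  et <- essTables(sc)
  expect_equal(pairKey(inferBBHEssential(et$ab, et$essba)),
               pairKey(inferBBHFull(et$ab, et$ba)))
})

test_that("raising t never adds a BBH pair", {
  set.seed(5)
  sc <- matrix(sample(c(0, 30, 45, 60, 90), 49, replace = TRUE), 7, 7,
               dimnames = list(sprintf("a%d", 1:7), sprintf("b%d", 1:7)))
  prev <- NULL
  for (t in c(20, 40, 60, 80)) {
    tt <- tablesFromMatrix(sc, t = t)
    cur <- pairKey(inferBBHFull(tt$ab, tt$ba))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("inparalog clustering follows the confidence formula and
           assigns each protein to one cluster", {
  # 3-protein fixture evaluated by hand: seed pair (a1, b1) with seed
  # score 60; duplicate a2 has intra score 80 vs a1, self score 100
  seeds <- data.frame(a = "A!a1", b = "B!b1", scoreAB = 60, scoreBA = 60)
  intraAA <- reduceToBestHits(HitTable("A", "A", data.frame(
    query = nsId("A", c("a1", "a1", "a2")),
    target = nsId("A", c("a1", "a2", "a2")),
    bitscore = c(100, 80, 95))), 40)
  intraBB <- reduceToBestHits(HitTable("B", "B", data.frame(
    query = nsId("B", "b1"), target = nsId("B", "b1"), bitscore = 90)), 40)
  po <- clusterInparalogs(seeds, intraAA, intraBB, "A", "B")
  cl <- clusters(po)[[1L]]
  expect_equal(cl$membersA$id, nsId("A", c("a1", "a2")))
  expect_equal(cl$membersA$confidence, c(1, (80 - 60) / (100 - 60)))
  expect_equal(cl$membersB$id, "B!b1")
  expect_equal(cl$membersB$confidence, 1)

  # no intra hit reaches the seed score -> seed-only cluster
  seeds2 <- data.frame(a = "A!a1", b = "B!b1", scoreAB = 95, scoreBA = 95)
  po2 <- clusterInparalogs(seeds2, intraAA, intraBB, "A", "B")
  expect_equal(clusterMembers(clusters(po2)[[1L]]), c("A!a1", "B!b1"))

  # shared candidate between two seeds lands in exactly one cluster
  seeds3 <- data.frame(a = nsId("A", c("a1", "a3")),
                       b = nsId("B", c("b1", "b2")),
                       scoreAB = c(60, 50), scoreBA = c(60, 50))
  intraAA3 <- reduceToBestHits(HitTable("A", "A", data.frame(
    query = nsId("A", c("a1", "a3", "a1", "a3", "a2")),
    target = nsId("A", c("a2", "a2", "a1", "a3", "a2")),
    bitscore = c(70, 65, 100, 100, 100))), 40)
  po3 <- clusterInparalogs(seeds3, intraAA3, intraBB, "A", "B")
  where <- vapply(clusters(po3),
                  function(cl) "A!a2" %in% cl$membersA$id, logical(1))
  expect_equal(sum(where), 1L)
  # higher confidence wins: (70-60)/(100-60)=0.25 vs (65-50)/(100-50)=0.3
  expect_true(where[2L])
})
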