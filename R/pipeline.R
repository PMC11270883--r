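#' Run the full dual-pipeline orthology inference
#'
#' Orchestrates, for N >= 2 proteomes: per-proteome statistics,
#' alignment-direction decisions, full first-direction alignments,
#' essential subsets, essential reverse alignments, BBH seed orthologs
#' and InParanoid-style inparalog clustering (the graph pipeline);
#' unless `graphOnly`, also domain-hit filtering, architecture building,
#' corpus construction, on-the-fly DBOW embedding training, prefiltered
#' cosine scoring and domain cluster extraction (the domain pipeline);
#' then the rule-based merge, the ortholog graph and Markov clustering
#' into multi-species ortholog groups.
#'
#' @param proteomes named list of [Proteome-class], or NULL to read from
#'   `inputDir`.
#' @param inputDir directory of proteome FASTA files (used when
#'   `proteomes` is NULL).
#' @param outputDir if non-NULL, outputs and a run manifest are written
#'   there via [writeOutputs()].
#' @param engine alignment engine (see [runAlignment()]); the default
#'   "toy" built-in scorer needs no external binary.
#' @param mode engine sensitivity: "fast", "default" or "sensitive".
#' @param graphOnly skip the domain pipeline entirely.
#' @param domainHits domain-hit table (data.frame or TSV path with
#'   namespaced protein ids); required unless `graphOnly`.
#' @param directionModel optional [DirectionModel-class]; without it the
#'   proteome-size heuristic picks the first alignment direction.
#' @param bitscoreThreshold BBH bitscore threshold t in bits (default 40).
#' @param cosineThreshold architecture cosine threshold (default 0.5).
#' @param inflation MCL inflation (default 1.5).
#' @param seed integer seed for every stochastic stage (embedding
#'   initialisation); identical configuration and seed reproduce the
#'   outputs byte for byte with the toy engine.
#' @return invisibly, a list with `tables` (merged
#'   [PairwiseOrthologs-class] per species pair), `graph`, `groups`
#'   (an [OrthologGroupSet-class]), `decisions`, `stats`, and
#'   `embeddings` (NULL when `graphOnly`).
#' @export
runPipeline <- function(proteomes = NULL, inputDir = NULL,
                        outputDir = NULL,
                        engine = "toy", mode = "default",
                        graphOnly = FALSE, domainHits = NULL,
                        directionModel = NULL,
                        bitscoreThreshold = 40, cosineThreshold = 0.5,
                        inflation = 1.5, seed = 1L) {
  if (is.null(proteomes)) {
    if (is.null(inputDir)) stop("provide proteomes or inputDir")
    proteomes <- readProteomeDir(inputDir)
  }
  if (length(proteomes) < 2L)
    stop("orthology inference needs at least 2 proteomes")
  proteomes <- proteomes[order(names(proteomes))]
  if (!graphOnly && is.null(domainHits))
    stop("no domain hits available: pass domainHits = <table or TSV>, ",
         "or set graphOnly = TRUE to run without the domain pipeline")
  t <- bitscoreThreshold
  sp <- names(proteomes)
  stats <- lapply(proteomes, proteomeStats)

  align <- function(q, tg) runAlignment(q, tg, engine = engine,
                                        sensitivity = mode)
  intra <- lapply(proteomes, function(p) reduceToBestHits(align(p, p), t))

  # domain pipeline: architectures, corpus and embeddings are global
  archs <- list(); emb <- NULL
  coverage <- numeric(); domCounts <- integer()
  if (!graphOnly) {
    hitsDf <- if (is.character(domainHits)) readDomainHits(domainHits)
              else domainHits
    hitsDf <- filterDomainHits(hitsDf)
    lens <- do.call(c, unname(lapply(proteomes, function(p) {
      w <- proteinLengths(p)
      setNames(w, nsId(proteomeId(p), names(w)))
    })))
    archs <- buildArchitectures(hitsDf, lens)
    coverage <- vapply(archs, archCoverage, numeric(1))
    domCounts <- vapply(archs, domainCount, integer(1))
    corp <- buildCorpus(archs)
    if (length(corp$corpus))
      emb <- trainEmbeddings(corp$corpus, seed = seed,
                             docIndex = corp$docIndex)
  }
  archsBySpecies <- split(archs,
                          vapply(archs, function(a)
                            splitNsId(a@proteinId)$proteome, character(1)))

  decisions <- list()
  tables <- list()
  for (i in seq_len(length(sp) - 1L)) {
    for (j in seq(i + 1L, length(sp))) {
      A <- sp[i]; B <- sp[j]
      fe <- buildPairFeatures(stats[[A]], stats[[B]])
      dec <- predictDirection(fe, directionModel)
      decisions[[paste0(A, "-", B)]] <- dec
      qId <- dec$first[1L]; tId <- dec$first[2L]
      tabFirst <- reduceToBestHits(align(proteomes[[qId]],
                                         proteomes[[tId]]), t)
      ess <- buildEssentialSubsets(tabFirst, t)
      if (length(memberIds(ess$essA)) && length(memberIds(ess$essB))) {
        qSub <- subsetProteome(proteomes[[tId]], memberIds(ess$essB))
        tSub <- subsetProteome(proteomes[[qId]], memberIds(ess$essA))
        tabSecond <- reduceToBestHits(align(qSub, tSub), t)
      } else {
        tabSecond <- HitTable(tId, qId, emptyHits())
      }
      seeds <- inferBBHEssential(tabFirst, tabSecond)
      if (qId != A) {  # orient seeds so column a belongs to species A
        seeds <- data.frame(a = seeds$b, b = seeds$a,
                            scoreAB = seeds$scoreBA,
                            scoreBA = seeds$scoreAB)
        seeds <- seeds[order(seeds$a, seeds$b), , drop = FALSE]
      }
      G <- clusterInparalogs(seeds, intra[[A]], intra[[B]], A, B)
      if (!graphOnly && !is.null(emb)) {
        M <- scoreArchitecturePairs(archsBySpecies[[A]] %||% list(),
                                    archsBySpecies[[B]] %||% list(),
                                    emb, A, B,
                                    threshold = cosineThreshold)
        D <- extractDomainClusters(M)
        tab <- mergePairwise(G, D, coverage, domCounts)
      } else {
        tab <- G
      }
      tables[[paste0(A, "-", B)]] <- tab
    }
  }

  graph <- buildOrthologGraph(tables)
  ogs <- mclCluster(graph, inflation = inflation)

  if (!is.null(outputDir)) {
    writeOutputs(tables, ogs, graph, outputDir, config = list(
      seed = seed, bitscore_threshold = t,
      cosine_threshold = cosineThreshold, inflation = inflation,
      engine = engine, mode = mode, graph_only = graphOnly,
      proteomes = sp,
      direction_sources = vapply(decisions, `[[`, "", "source")))
  }

  invisible(list(tables = tables, graph = graph, groups = ogs,
                 decisions = decisions, stats = stats,
                 embeddings = emb))
}
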