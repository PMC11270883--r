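AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
FUSION_LINKER <- "GGSGGSGGSG"  # 10-aa flexible linker joining fused parts

#' Specification for a synthetic multi-species proteome set
#'
#' Families of ancestral proteins are mutated independently into each
#' species; within-species duplications plant inparalogs and fusion
#' events plant the fused-protein scenario (the fused species carries a
#' single protein concatenating two families via a 10-aa linker, in
#' place of its copies of those families). Substitution uses uniform
#' random replacement at the stated fraction of sites, which is enough
#' to modulate shared-k-mer bitscores monotonically with divergence.
#' All randomness is fixed by the seed.
#'
#' @param nSpecies number of species.
#' @param proteinsPerSpecies number of ancestral families.
#' @param meanLen mean ancestral protein length in aa (lengths drawn
#'   uniformly in \[0.6, 1.4\] x meanLen).
#' @param duplicationRate per-gene probability of a within-species
#'   duplicate (an inparalog), in \[0, 1\].
#' @param divergenceLevels per-species substitution fraction from the
#'   ancestor (recycled to nSpecies), each in \[0, 1\].
#' @param duplicateDivergence extra substitution applied to duplicates.
#' @param fusionEvents list of `list(species=, families=c(i, j))`.
#' @param seed integer seed fixing all randomness.
#' @return a `SyntheticSpec` (classed list).
#' @export
syntheticProteomeSpec <- function(nSpecies = 2L, proteinsPerSpecies = 20L,
                                  meanLen = 150L, duplicationRate = 0,
                                  divergenceLevels = 0.05,
                                  duplicateDivergence = 0.05,
                                  fusionEvents = list(), seed = 1L) {
  stopifnot(nSpecies >= 1L, proteinsPerSpecies >= 1L,
            all(divergenceLevels >= 0 & divergenceLevels <= 1),
            duplicationRate >= 0, duplicationRate <= 1)
  structure(list(nSpecies = as.integer(nSpecies),
                 proteinsPerSpecies = as.integer(proteinsPerSpecies),
                 meanLen = as.integer(meanLen),
                 duplicationRate = duplicationRate,
                 divergenceLevels = rep_len(divergenceLevels, nSpecies),
                 duplicateDivergence = duplicateDivergence,
                 fusionEvents = fusionEvents,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

randomSeq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                 collapse = "")

mutateSeq <- function(seq, fraction) {
  if (fraction <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  n <- length(chars)
  k <- round(fraction * n)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  repl <- sample(AA20, k, replace = TRUE)
  bad <- repl == chars[pos]
  while (any(bad)) {  # substitutions must change the residue
    repl[bad] <- sample(AA20, sum(bad), replace = TRUE)
    bad <- repl == chars[pos]
  }
  chars[pos] <- repl
  paste(chars, collapse = "")
}

#' Generate synthetic proteomes with planted ground truth
#'
#' @param spec a [syntheticProteomeSpec()].
#' @return list with `proteomes` (named list of [Proteome-class],
#'   species "sp01", "sp02", ...) and `truth`, a list holding
#'   `orthologs` (data.frame a, b of namespaced planted ortholog pairs
#'   over all species pairs), `inparalogs` (named list: namespaced
#'   original -> namespaced duplicate ids), `fusions` (data.frame
#'   species, fusedId, family1, family2, component ids) and `familyOf`
#'   (named integer: namespaced id -> family).
#' @export
generateProteomes <- function(spec) {
  set.seed(deriveSeed(spec$seed, "proteomes"))
  nf <- spec$proteinsPerSpecies
  lens <- round(runif(nf, 0.6 * spec$meanLen, 1.4 * spec$meanLen))
  ancestors <- vapply(lens, randomSeq, character(1))
  famIds <- sprintf("f%03d", seq_len(nf))
  spIds <- sprintf("sp%02d", seq_len(spec$nSpecies))

  seqs <- list()      # per species: named character vectors
  familyOf <- integer()
  inparalogs <- list()
  for (s in seq_len(spec$nSpecies)) {
    d <- spec$divergenceLevels[s]
    ss <- character()
    for (f in seq_len(nf)) {
      id <- famIds[f]
      ss[id] <- mutateSeq(ancestors[f], d)
      familyOf[nsId(spIds[s], id)] <- f
      if (spec$duplicationRate > 0 &&
          runif(1L) < spec$duplicationRate) {
        did <- paste0(id, "_d1")
        ss[did] <- mutateSeq(ss[id], spec$duplicateDivergence)
        familyOf[nsId(spIds[s], did)] <- f
        inparalogs[[nsId(spIds[s], id)]] <-
          c(inparalogs[[nsId(spIds[s], id)]], nsId(spIds[s], did))
      }
    }
    seqs[[spIds[s]]] <- ss
  }

  fusions <- data.frame(species = character(), fusedId = character(),
                        family1 = integer(), family2 = integer(),
                        component1 = character(), component2 = character())
  for (ev in spec$fusionEvents) {
    s <- spIds[ev$species]
    f1 <- ev$families[1L]; f2 <- ev$families[2L]
    fid <- paste0("fus_", famIds[f1], "_", famIds[f2])
    fused <- paste0(seqs[[s]][[famIds[f1]]], FUSION_LINKER,
                    seqs[[s]][[famIds[f2]]])
    # the fused gene replaces the species' own copies of both families
    drop <- names(seqs[[s]]) %in%
      c(famIds[c(f1, f2)], paste0(famIds[c(f1, f2)], "_d1"))
    familyOf <- familyOf[!names(familyOf) %in% nsId(s, names(seqs[[s]])[drop])]
    inparalogs[nsId(s, famIds[c(f1, f2)])] <- NULL
    seqs[[s]] <- seqs[[s]][!drop]
    seqs[[s]][fid] <- fused
    fusions <- rbind(fusions, data.frame(
      species = s, fusedId = nsId(s, fid), family1 = f1, family2 = f2,
      component1 = famIds[f1], component2 = famIds[f2]))
  }

  proteomes <- lapply(spIds, function(s) Proteome(s, seqs[[s]]))
  names(proteomes) <- spIds

  orth <- list()
  for (i in seq_len(spec$nSpecies - 1L)) {
    for (j in seq(i + 1L, spec$nSpecies)) {
      for (f in seq_len(nf)) {
        a <- nsId(spIds[i], famIds[f]); b <- nsId(spIds[j], famIds[f])
        if (a %in% names(familyOf) && b %in% names(familyOf))
          orth[[length(orth) + 1L]] <- data.frame(a = a, b = b)
      }
    }
  }
  orthologs <- if (length(orth)) do.call(rbind, orth) else
    data.frame(a = character(), b = character())

  list(proteomes = proteomes,
       truth = list(orthologs = orthologs, inparalogs = inparalogs,
                    fusions = fusions, familyOf = familyOf,
                    ancestorLengths = setNames(lens, famIds)))
}

#' All directed toy hit tables for a proteome set
#'
#' Runs the deterministic, symmetric shared-k-mer scorer for every
#' directed inter-proteome pair and every intra-proteome alignment.
#'
#' @param proteomes named list of [Proteome-class].
#' @param ... passed to [toyAlignment()].
#' @return named list of [HitTable-class], keys "A-B" (directed) and
#'   "A-A" (intra).
#' @export
toyHitTables <- function(proteomes, ...) {
  ids <- names(proteomes)
  out <- list()
  for (q in ids) for (t in ids) {
    out[[paste0(q, "-", t)]] <- toyAlignment(proteomes[[q]],
                                             proteomes[[t]], ...)
  }
  out
}

#' Synthetic domain-hit table matching the planted proteomes
#'
#' Every family protein (and its duplicates) receives one domain
#' ("PFxxxxx" derived from its family) covering all but two residues at
#' each terminus; fused proteins receive the two component domains
#' separated by the linker-induced gap. Coverages are above 75% by
#' construction, and the profile coverage is set to 0.9.
#'
#' @param proteomes named list of [Proteome-class].
#' @param truth the `truth` element from [generateProteomes()].
#' @return data.frame in the domain-hit TSV dialect (namespaced
#'   protein_id, profile_acc, ali_start, ali_end, bitscore,
#'   profile_coverage).
#' @export
synthDomainHits <- function(proteomes, truth) {
  accOf <- function(f) sprintf("PF%05d", f)
  rows <- list()
  fusedIds <- truth$fusions$fusedId
  for (sp in names(proteomes)) {
    lens <- proteinLengths(proteomes[[sp]])
    for (pid in names(lens)) {
      id <- nsId(sp, pid)
      L <- lens[[pid]]
      if (id %in% fusedIds) {
        fu <- truth$fusions[truth$fusions$fusedId == id, ]
        L1 <- truth$ancestorLengths[[fu$component1]]
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = id, profile_acc = accOf(fu$family1),
          ali_start = 3L, ali_end = L1 - 2L,
          bitscore = 100, profile_coverage = 0.9)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = id, profile_acc = accOf(fu$family2),
          ali_start = L1 + nchar(FUSION_LINKER) + 3L, ali_end = L - 2L,
          bitscore = 100, profile_coverage = 0.9)
      } else if (id %in% names(truth$familyOf)) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = id, profile_acc = accOf(truth$familyOf[[id]]),
          ali_start = 3L, ali_end = L - 2L,
          bitscore = 100, profile_coverage = 0.9)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate labeled alignment-timing samples
#'
#' Stands in for wall-clock-timed training data: for each proteome pair
#' the two directed execution times are drawn as
#' `rule(queryStats, targetStats) * (1 + e)` with `e` uniform in
#' \[-noise, noise\], and the canonical-orientation sample is labeled
#' with [labelFromTimes()]. The default rule makes time proportional to
#' query protein count times target residue count.
#'
#' @param statsPairs list of `list(statsA=, statsB=)` with
#'   [ProteomeStats-class] entries.
#' @param rule function(queryStats, targetStats) -> seconds.
#' @param noise multiplicative noise half-width (default 0.2).
#' @param seed integer seed.
#' @return data.frame with the eight feature columns, `label`, and the
#'   drawn times `time_first`, `time_second` (canonical orientation
#'   first).
#' @export
simulateAlignmentTimes <- function(statsPairs,
                                   rule = function(q, t)
                                     1e-9 * q@proteinCount * t@residueCount,
                                   noise = 0.2, seed = 1L) {
  set.seed(deriveSeed(seed, "timings"))
  rows <- lapply(statsPairs, function(pr) {
    fe <- buildPairFeatures(pr$statsA, pr$statsB)
    # orient raw stats to the canonical order found by buildPairFeatures
    q <- if (pr$statsA@proteomeId == fe$queryId) pr$statsA else pr$statsB
    t <- if (pr$statsA@proteomeId == fe$queryId) pr$statsB else pr$statsA
    t1 <- rule(q, t) * (1 + runif(1L, -noise, noise))
    t2 <- rule(t, q) * (1 + runif(1L, -noise, noise))
    c(fe$features, label = labelFromTimes(t1, t2),
      time_first = t1, time_second = t2)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Draw random proteome summaries for timing simulations
#'
#' @param n number of proteomes.
#' @param countRange protein-count range (uniform).
#' @param meanLenRange mean-protein-length range (uniform).
#' @param seed integer seed.
#' @return list of [ProteomeStats-class].
#' @export
sampleProteomeStats <- function(n, countRange = c(500L, 5000L),
                                meanLenRange = c(250, 450), seed = 1L) {
  set.seed(deriveSeed(seed, "proteomes"))
  lapply(seq_len(n), function(i) {
    pc <- as.integer(round(runif(1L, countRange[1L], countRange[2L])))
    ml <- runif(1L, meanLenRange[1L], meanLenRange[2L])
    rc <- round(pc * ml)
    new("ProteomeStats", proteomeId = sprintf("P%04d", i),
        proteinCount = pc, residueCount = rc,
        meanProteinLength = rc / pc)
  })
}
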