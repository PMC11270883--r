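#' @import methods
NULL

AA_OK <- "ACDEFGHIKLMNPQRSTVWYXBZUO*"

#' Proteome: a set of amino-acid sequences for one species
#'
#' Thin wrapper around [Biostrings::AAStringSet] carrying the proteome label.
#' Sequences use the 20-letter amino-acid alphabet plus the ambiguity codes
#' X, B, Z, U and O, which are accepted and counted as ordinary residues.
#'
#' @slot proteomeId single character label (usually the FASTA file stem).
#' @slot sequences [Biostrings::AAStringSet] named by protein id.
#' @exportClass Proteome
setClass("Proteome", representation(
  proteomeId = "character",
  sequences = "AAStringSet"
))

setValidity("Proteome", function(object) {
  msg <- character()
  if (length(object@proteomeId) != 1L || !nzchar(object@proteomeId))
    msg <- c(msg, "proteomeId must be a single non-empty string")
  if (length(object@sequences) == 0L)
    msg <- c(msg, "proteome must contain at least one protein")
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    msg <- c(msg, "every protein needs an id")
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate protein id: ",
                         ids[duplicated(ids)][1L]))
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "all sequences must be non-empty")
  if (length(msg)) msg else TRUE
})

#' ProteomeStats: per-proteome summary features
#'
#' The three summaries consumed by the alignment-direction classifier:
#' protein count, proteome size in residues, and mean protein length.
#'
#' @slot proteinCount integer number of proteins.
#' @slot residueCount integer total amino acids.
#' @slot meanProteinLength residueCount / proteinCount.
#' @slot proteomeId label of the summarised proteome.
#' @exportClass ProteomeStats
setClass("ProteomeStats", representation(
  proteomeId = "character",
  proteinCount = "integer",
  residueCount = "numeric",
  meanProteinLength = "numeric"
))

setValidity("ProteomeStats", function(object) {
  msg <- character()
  if (object@proteinCount <= 0L) msg <- c(msg, "proteinCount must be > 0")
  if (object@residueCount <= 0) msg <- c(msg, "residueCount must be > 0")
  if (!isTRUE(all.equal(object@meanProteinLength,
                        object@residueCount / object@proteinCount)))
    msg <- c(msg, "meanProteinLength must equal residueCount / proteinCount")
  if (length(msg)) msg else TRUE
})

#' HitTable: directed alignment results between two proteomes
#'
#' @slot queryProteome,targetProteome proteome ids of the alignment
#'   direction (all proteins of `queryProteome` searched against
#'   `targetProteome`).
#' @slot hits data.frame with columns `query`, `target` (namespaced protein
#'   ids), `bitscore` (numeric, bits) and `isBest` (logical; set by
#'   [reduceToBestHits()], ties all flagged).
#' @exportClass HitTable
setClass("HitTable", representation(
  queryProteome = "character",
  targetProteome = "character",
  hits = "data.frame"
))

setValidity("HitTable", function(object) {
  h <- object@hits
  need <- c("query", "target", "bitscore", "isBest")
  if (!all(need %in% names(h)))
    return(paste("hits needs columns:", paste(need, collapse = ", ")))
  if (nrow(h) && any(h$bitscore < 0)) return("bitscores must be >= 0")
  TRUE
})

#' EssentialSubset: proteins that can still take part in a BBH
#'
#' After the first alignment direction A-B is run, only queries with at
#' least one hit scoring >= t (ess(A)) and the targets of such hits
#' (ess(B)) can satisfy the bidirectional-best-hit conditions; the reverse
#' alignment is restricted to these subsets.
#'
#' @slot proteomeId proteome the subset was taken from.
#' @slot memberIds namespaced protein ids in the subset.
#' @slot threshold bitscore threshold t used to build it.
#' @exportClass EssentialSubset
setClass("EssentialSubset", representation(
  proteomeId = "character",
  memberIds = "character",
  threshold = "numeric"
))

#' DirectionModel: boosted-stump classifier for the faster alignment direction
#'
#' @slot booster fitted xgboost booster (depth-1 trees).
#' @slot featureNames column order expected by the booster.
#' @slot cvAccuracy mean 10-fold cross-validation accuracy of the selected
#'   hyper-parameters.
#' @slot params selected hyper-parameters (nrounds, eta).
#' @slot nSamples number of training samples.
#' @slot seed training seed.
#' @exportClass DirectionModel
setClass("DirectionModel", representation(
  booster = "ANY",
  featureNames = "character",
  cvAccuracy = "numeric",
  params = "list",
  nSamples = "integer",
  seed = "integer"
))

#' DomainArchitecture: ordered domain + inter-region tokens of one protein
#'
#' @slot proteinId namespaced protein id.
#' @slot proteinLength protein length in amino acids.
#' @slot tokens data.frame with columns `kind` ("domain" or "gap") and
#'   `value` (Pfam-style accession, or gap length in aa rendered as a
#'   decimal integer string). Gap tokens are only emitted for uncovered
#'   runs longer than four residues, including the termini.
#' @slot coverage fraction of residues under domain tokens, in \[0, 1\].
#' @slot domainCount number of domain tokens.
#' @exportClass DomainArchitecture
setClass("DomainArchitecture", representation(
  proteinId = "character",
  proteinLength = "integer",
  tokens = "data.frame",
  coverage = "numeric",
  domainCount = "integer"
))

setValidity("DomainArchitecture", function(object) {
  msg <- character()
  if (object@coverage < 0 || object@coverage > 1)
    msg <- c(msg, "coverage must be in [0, 1]")
  if (!all(object@tokens$kind %in% c("domain", "gap")))
    msg <- c(msg, "token kinds must be 'domain' or 'gap'")
  if (length(msg)) msg else TRUE
})

#' DocEmbeddings: paragraph vectors for a corpus of architecture documents
#'
#' One 100-dimensional vector per unique document, trained fresh for each
#' run with the distributed bag-of-words (DBOW) objective.
#'
#' @slot vectors numeric matrix, one row per unique document; rownames are
#'   document keys (space-joined words).
#' @slot docIndex named character vector mapping namespaced protein id to
#'   its document key.
#' @slot params training parameters (dim, epochs, window, minCount, seed).
#' @exportClass DocEmbeddings
setClass("DocEmbeddings", representation(
  vectors = "matrix",
  docIndex = "character",
  params = "list"
))

setValidity("DocEmbeddings", function(object) {
  if (!all(object@docIndex %in% rownames(object@vectors)))
    return("every indexed document must have a vector")
  TRUE
})

#' ArchSimilarity: sparse cosine-similarity matrix for a proteome pair
#'
#' Holds only the architecture pairs that survived prefiltering and have
#' cosine similarity >= the threshold (default 0.5).
#'
#' @slot proteomeA,proteomeB the species pair (A indexes rows, B columns).
#' @slot entries data.frame with columns `a`, `b` (namespaced ids) and
#'   `cosine`.
#' @slot threshold the cosine threshold applied.
#' @exportClass ArchSimilarity
setClass("ArchSimilarity", representation(
  proteomeA = "character",
  proteomeB = "character",
  entries = "data.frame",
  threshold = "numeric"
))

setValidity("ArchSimilarity", function(object) {
  e <- object@entries
  if (nrow(e) && any(e$cosine < object@threshold - 1e-12))
    return("all stored cosines must be >= threshold")
  TRUE
})

#' PairwiseOrthologs: ortholog clusters for one species pair
#'
#' Each cluster is a list with elements:
#' \describe{
#'   \item{seedA, seedB}{seed ortholog pair (namespaced ids), or NA for
#'     clusters of purely domain provenance.}
#'   \item{seedScore}{seed alignment bitscore (NA for domain clusters).}
#'   \item{membersA, membersB}{data.frames `id`, `confidence` per species
#'     side; seeds carry confidence 1, inparalogs confidences in \[0, 1\],
#'     domain-inserted members the cosine that attested them.}
#'   \item{pairs}{for domain provenance, data.frame `a`, `b`, `cosine` of
#'     the attested architecture pairs.}
#'   \item{provenance}{"graph", "domain" or "graph+domain".}
#' }
#'
#' @slot proteomeA,proteomeB species pair labels.
#' @slot clusters list of clusters as described above.
#' @exportClass PairwiseOrthologs
setClass("PairwiseOrthologs", representation(
  proteomeA = "character",
  proteomeB = "character",
  clusters = "list"
))

#' OrthologGroupSet: multi-species ortholog groups
#'
#' @slot groups named list (og id -> character vector of namespaced
#'   member ids); the groups partition the ortholog graph's node set.
#' @slot inflation MCL inflation used.
#' @exportClass OrthologGroupSet
setClass("OrthologGroupSet", representation(
  groups = "list",
  inflation = "numeric"
))

setValidity("OrthologGroupSet", function(object) {
  all_ids <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(all_ids))
    return("a protein may belong to only one ortholog group")
  TRUE
})
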