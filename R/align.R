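#' Construct a HitTable
#'
#' @param queryProteome,targetProteome proteome ids of the direction.
#' @param hits data.frame with columns `query`, `target`, `bitscore`
#'   (namespaced ids); an `isBest` column is added if absent.
#' @return a [HitTable-class].
#' @export
HitTable <- function(queryProteome, targetProteome, hits) {
  if (is.null(hits$isBest)) hits$isBest <- rep(FALSE, nrow(hits))
  rownames(hits) <- NULL
  new("HitTable", queryProteome = queryProteome,
      targetProteome = targetProteome,
      hits = hits[, c("query", "target", "bitscore", "isBest")])
}

emptyHits <- function() {
  data.frame(query = character(), target = character(),
             bitscore = numeric(), isBest = logical())
}

#' @describeIn HitTable-class the hits as a data.frame
#' @param x a `HitTable`.
#' @export
hits <- function(x) x@hits

#' @describeIn HitTable-class number of hits
#' @export
nHits <- function(x) nrow(x@hits)

setMethod("show", "HitTable", function(object) {
  cat("HitTable ", object@queryProteome, "-", object@targetProteome, ": ",
      nrow(object@hits), " hits", sep = "")
  if (any(object@hits$isBest)) cat(" (best hits flagged)")
  cat("\n")
})

# distinct k-mers of each sequence as a sparse incidence matrix over a
# shared k-mer vocabulary
kmerIncidence <- function(seqs, k, vocab) {
  ij <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    n <- nchar(s)
    if (n < k) return(NULL)
    km <- unique(substring(s, 1:(n - k + 1L), k:n))
    cbind(match(km, vocab), i)
  })
  ij <- do.call(rbind, ij)
  if (is.null(ij)) ij <- matrix(integer(), ncol = 2L)
  Matrix::sparseMatrix(i = ij[, 1L], j = ij[, 2L], x = 1,
                       dims = c(length(vocab), length(seqs)))
}

seqKmers <- function(seqs, k) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) character() else unique(substring(s, 1:(n - k + 1L), k:n))
  }), use.names = FALSE)
}

#' Built-in deterministic toy alignment scorer
#'
#' Scores every query/target protein pair by the number of distinct shared
#' k-mers, scaled to pseudo-bits (`bitsPerKmer` per shared k-mer). The
#' score is symmetric by construction, which makes the toy engine an exact
#' substrate for checking the essential-subset BBH equations against the
#' full BBH definition. Pairs sharing no k-mer produce no hit.
#'
#' @param query,target [Proteome-class] objects.
#' @param k k-mer length (default 3).
#' @param bitsPerKmer pseudo-bits per shared distinct k-mer (default 2).
#' @return a [HitTable-class] with namespaced ids.
#' @export
toyAlignment <- function(query, target, k = 3L, bitsPerKmer = 2) {
  qs <- proteinSequences(query)
  ts <- proteinSequences(target)
  vocab <- unique(c(seqKmers(qs, k), seqKmers(ts, k)))
  if (length(vocab) == 0L)
    return(HitTable(proteomeId(query), proteomeId(target), emptyHits()))
  Mq <- kmerIncidence(qs, k, vocab)
  Mt <- kmerIncidence(ts, k, vocab)
  shared <- Matrix::crossprod(Mq, Mt)   # n_query x n_target shared counts
  idx <- Matrix::which(shared > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(HitTable(proteomeId(query), proteomeId(target), emptyHits()))
  h <- data.frame(
    query = nsId(proteomeId(query), names(qs)[idx[, 1L]]),
    target = nsId(proteomeId(target), names(ts)[idx[, 2L]]),
    bitscore = bitsPerKmer * shared[idx],
    isBest = FALSE
  )
  h <- h[order(h$query, h$target), ]
  HitTable(proteomeId(query), proteomeId(target), h)
}

#' Parse a BLAST-tab (outfmt 6) hit file
#'
#' Reads the standard 12-column tabular dialect (qseqid, sseqid, pident,
#' length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore); only columns 1, 2 and 12 are consumed. Ids are namespaced
#' with the stated proteome pair.
#'
#' @param path path to the tabular file.
#' @param queryProteome,targetProteome proteome ids of the direction.
#' @param namespaced set TRUE if ids in the file are already namespaced.
#' @return a [HitTable-class].
#' @export
parseBlastTab <- function(path, queryProteome, targetProteome,
                          namespaced = FALSE) {
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
               comment.char = "#", quote = ""),
    error = function(e) NULL)
  if (is.null(raw) || nrow(raw) == 0L)
    return(HitTable(queryProteome, targetProteome, emptyHits()))
  if (ncol(raw) < 12L)
    stop("expected >= 12 tab-separated columns in ", path)
  h <- data.frame(query = as.character(raw[[1L]]),
                  target = as.character(raw[[2L]]),
                  bitscore = as.numeric(raw[[12L]]),
                  isBest = FALSE)
  if (!namespaced) {
    h$query <- nsId(queryProteome, h$query)
    h$target <- nsId(targetProteome, h$target)
  }
  HitTable(queryProteome, targetProteome, h)
}

#' Run a directed all-vs-all protein alignment
#'
#' Dispatches to the built-in toy scorer or to an external aligner
#' adapter. The `blast` engine shells out to `makeblastdb`/`blastp` and
#' parses their tabular output; `mmseqs` and `diamond` adapters are
#' invoked the same way when the binaries are available on the PATH.
#'
#' @param query,target [Proteome-class] objects.
#' @param engine one of "toy", "blast", "mmseqs", "diamond".
#' @param sensitivity engine sensitivity mode: "fast", "default" or
#'   "sensitive" (ignored by the toy engine).
#' @param ... further arguments to [toyAlignment()].
#' @return a [HitTable-class].
#' @export
runAlignment <- function(query, target,
                         engine = c("toy", "blast", "mmseqs", "diamond"),
                         sensitivity = "default", ...) {
  engine <- match.arg(engine)
  if (engine == "toy") return(toyAlignment(query, target, ...))
  runExternalAlignment(query, target, engine, sensitivity)
}

# sensitivity knobs per engine; values are this package's defaults for the
# three modes, applied to the external binaries when used
ENGINE_SENSITIVITY <- list(
  blast = list(fast = c("-word_size", "6"), default = character(),
               sensitive = c("-word_size", "2")),
  mmseqs = list(fast = c("-s", "2.5"), default = c("-s", "5.7"),
                sensitive = c("-s", "7.5")),
  diamond = list(fast = c("--fast"), default = c("--sensitive"),
                 sensitive = c("--ultra-sensitive"))
)

writeProteomeFasta <- function(p, path) {
  s <- proteinSequences(p)
  writeLines(paste0(">", names(s), "\n", s), path)
  path
}

runExternalAlignment <- function(query, target, engine, sensitivity) {
  bin <- c(blast = "blastp", mmseqs = "mmseqs", diamond = "diamond")[[engine]]
  if (Sys.which(bin) == "")
    stop("aligner binary not found on PATH: ", bin)
  extra <- ENGINE_SENSITIVITY[[engine]][[sensitivity]] %||% character()
  td <- tempfile("aln")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- writeProteomeFasta(query, file.path(td, "q.faa"))
  tf <- writeProteomeFasta(target, file.path(td, "t.faa"))
  out <- file.path(td, "hits.tsv")
  if (engine == "blast") {
    st <- system2("makeblastdb",
                  c("-in", tf, "-dbtype", "prot"),
                  stdout = FALSE, stderr = file.path(td, "err1"))
    if (st != 0L)
      stop("makeblastdb failed: ",
           paste(readLines(file.path(td, "err1")), collapse = "\n"))
    st <- system2("blastp",
                  c("-query", qf, "-db", tf, "-outfmt", "6",
                    "-out", out, extra),
                  stdout = FALSE, stderr = file.path(td, "err2"))
    if (st != 0L)
      stop("blastp failed: ",
           paste(readLines(file.path(td, "err2")), collapse = "\n"))
  } else if (engine == "diamond") {
    st <- system2("diamond", c("makedb", "--in", tf, "-d",
                               file.path(td, "db")),
                  stdout = FALSE, stderr = file.path(td, "err1"))
    if (st != 0L) stop("diamond makedb failed")
    st <- system2("diamond", c("blastp", "-q", qf, "-d",
                               file.path(td, "db"), "-o", out, extra),
                  stdout = FALSE, stderr = file.path(td, "err2"))
    if (st != 0L)
      stop("diamond failed: ",
           paste(readLines(file.path(td, "err2")), collapse = "\n"))
  } else {
    st <- system2("mmseqs",
                  c("easy-search", qf, tf, out, file.path(td, "tmp"),
                    extra),
                  stdout = FALSE, stderr = file.path(td, "err2"))
    if (st != 0L)
      stop("mmseqs failed: ",
           paste(readLines(file.path(td, "err2")), collapse = "\n"))
  }
  parseBlastTab(out, proteomeId(query), proteomeId(target))
}
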