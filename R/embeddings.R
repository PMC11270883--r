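#' Train paragraph-vector (DBOW) embeddings for a document corpus
#'
#' Distributed bag-of-words training: each document vector is optimised
#' by stochastic gradient descent to predict the words it contains,
#' ignoring word order within the prediction step (the order still
#' matters because distinct orders give distinct documents). Defaults
#' follow common small-corpus practice for paragraph vectors: dimension
#' 100, 200 epochs, minimum word frequency 1, a single worker and a
#' fixed seed, so training is deterministic and every corpus document
#' receives exactly one vector.
#'
#' The output layer uses the exact softmax over the vocabulary rather
#' than negative sampling: architecture vocabularies are orders of
#' magnitude smaller than natural-language ones, so the exact gradient
#' is affordable and removes sampling noise from the embeddings.
#'
#' @param corpus named list of word vectors as produced by
#'   [buildCorpus()], or a bare list of character vectors.
#' @param seed integer seed for the vector initialisation.
#' @param dim embedding dimension (default 100).
#' @param epochs training epochs (default 200).
#' @param window context window recorded for provenance; the DBOW
#'   objective itself predicts all words of the document (default 2).
#' @param minCount minimum corpus frequency for a word to be trained
#'   (default 1: every word is used).
#' @param alpha,minAlpha initial and final learning rate of the linear
#'   decay schedule.
#' @param docIndex optional protein id -> document key map, stored for
#'   lookup via [docVector()].
#' @return a [DocEmbeddings-class].
#' @export
trainEmbeddings <- function(corpus, seed = 1L, dim = 100L, epochs = 200L,
                            window = 2L, minCount = 1L, alpha = 0.025,
                            minAlpha = 1e-4, docIndex = NULL) {
  if (length(corpus) == 0L) stop("cannot train embeddings on an empty corpus")
  keys <- names(corpus) %||%
    vapply(corpus, paste, character(1), collapse = " ")
  if (is.null(names(corpus))) names(corpus) <- keys

  counts <- table(unlist(corpus, use.names = FALSE))
  vocab <- sort(names(counts)[counts >= minCount])
  docs <- lapply(corpus, function(w) match(w[w %in% vocab], vocab))
  V <- length(vocab)
  if (V == 0L) stop("no word reaches the minimum frequency")
  ndoc <- length(docs)

  set.seed(deriveSeed(seed, "embeddings"))
  D <- matrix((runif(ndoc * dim) - 0.5) / dim, nrow = ndoc)
  W <- matrix(0, nrow = V, ncol = dim)

  totalSteps <- epochs * sum(lengths(docs))
  step <- 0L
  for (ep in seq_len(epochs)) {
    for (d in seq_len(ndoc)) {
      for (w in docs[[d]]) {
        step <- step + 1L
        lr <- max(minAlpha, alpha * (1 - step / totalSteps))
        dv <- D[d, ]
        z <- as.numeric(W %*% dv)
        p <- exp(z - max(z)); p <- p / sum(p)
        g <- -p; g[w] <- g[w] + 1
        D[d, ] <- dv + lr * as.numeric(crossprod(W, g))
        W <- W + lr * tcrossprod(g, dv)
      }
    }
  }
  rownames(D) <- keys
  new("DocEmbeddings",
      vectors = D,
      docIndex = if (is.null(docIndex)) character() else docIndex,
      params = list(dim = dim, epochs = epochs, window = window,
                    minCount = minCount, alpha = alpha,
                    minAlpha = minAlpha, seed = as.integer(seed),
                    objective = "dbow-softmax"))
}

#' Look up the embedding of a document or protein
#'
#' @param emb a [DocEmbeddings-class].
#' @param id a document key, or a protein id present in the stored
#'   docIndex.
#' @return numeric embedding vector.
#' @export
docVector <- function(emb, id) {
  key <- if (id %in% rownames(emb@vectors)) id else emb@docIndex[[id]]
  emb@vectors[key, ]
}

#' @describeIn DocEmbeddings-class protein ids with an embedding
#' @param x a `DocEmbeddings`.
#' @export
embeddedProteins <- function(x) names(x@docIndex)

setMethod("show", "DocEmbeddings", function(object) {
  cat("DocEmbeddings: ", nrow(object@vectors), " documents x ",
      ncol(object@vectors), " dims (epochs=", object@params$epochs,
      ", seed=", object@params$seed, ")\n", sep = "")
})

#' Dump document vectors as TSV for inspection
#'
#' @param emb a [DocEmbeddings-class].
#' @param path output TSV (document key + one column per dimension).
#' @export
writeEmbeddings <- function(emb, path) {
  d <- data.frame(document = rownames(emb@vectors), emb@vectors,
                  check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
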