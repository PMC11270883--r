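#' @importFrom stats runif setNames predict
#' @importFrom utils read.table write.table head
NULL

# Protein ids are namespaced as "<proteome_id>!<protein_id>" everywhere hits,
# clusters and graphs mix species, so ids stay globally unique.
NS_SEP <- "!"

#' Namespace protein ids with their proteome id
#'
#' @param proteomeId single proteome label.
#' @param proteinIds character vector of within-proteome protein ids.
#' @return character vector of globally unique ids.
#' @export
nsId <- function(proteomeId, proteinIds) {
  paste0(proteomeId, NS_SEP, proteinIds)
}

#' Split namespaced protein ids
#'
#' @param ids namespaced ids as produced by [nsId()].
#' @return data.frame with columns `proteome` and `protein`.
#' @export
splitNsId <- function(ids) {
  pos <- regexpr(NS_SEP, ids, fixed = TRUE)
  bad <- pos < 0L
  if (any(bad)) {
    stop("ids not namespaced: ", paste(head(ids[bad], 3L), collapse = ", "))
  }
  data.frame(
    proteome = substr(ids, 1L, pos - 1L),
    protein = substr(ids, pos + 1L, nchar(ids)),
    stringsAsFactors = FALSE
  )
}

#' Cosine similarity of two numeric vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return cosine similarity in \[-1, 1\]; 0 if either vector is all-zero.
#' @export
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# Derive a stream-specific 32-bit seed from the user seed, so independent
# pipeline stages do not consume each other's random numbers.
deriveSeed <- function(seed, stream) {
  offsets <- c(proteomes = 11L, timings = 101L, embeddings = 211L,
               model = 307L, cv = 401L)
  off <- offsets[[stream]]
  as.integer((as.numeric(seed) + off * 9973) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
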