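#' Build the ortholog graph from merged pairwise tables
#'
#' Nodes are the namespaced proteins of all clusters; an undirected
#' weighted edge connects every within-cluster protein pair. Weights:
#' for graph-provenance members the product of the two members'
#' inparalog confidences (seed-seed edges get 1); members inserted from
#' the domain pipeline carry their attesting cosine as confidence, so
#' their edges are cosine-weighted; for pure domain clusters, attested
#' pairs get their cosine and unattested within-cluster pairs the
#' cluster's minimum attested cosine. When several tables attest the
#' same edge, the maximum weight wins.
#'
#' @param tables list of merged [PairwiseOrthologs-class] objects.
#' @return an [igraph::igraph] with a `weight` edge attribute, no
#'   self-loops.
#' @export
buildOrthologGraph <- function(tables) {
  rows <- list()
  addEdges <- function(ids, w) {
    # ids, w aligned vectors of members and per-member confidence
    n <- length(ids)
    if (n < 2L) return(NULL)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
               weight = w[idx[, 1L]] * w[idx[, 2L]])
  }
  for (tab in tables) {
    for (cl in tab@clusters) {
      if (!is.null(cl$membersA)) {
        m <- rbind(cl$membersA, cl$membersB)
        rows[[length(rows) + 1L]] <- addEdges(m$id, m$confidence)
      } else {
        ids <- sort(unique(c(cl$pairs$a, cl$pairs$b)))
        wmin <- min(cl$pairs$cosine)
        n <- length(ids)
        idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
        e <- data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
                        weight = wmin)
        key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
        pkey <- paste(pmin(cl$pairs$a, cl$pairs$b),
                      pmax(cl$pairs$a, cl$pairs$b))
        m <- match(key, pkey)
        e$weight[!is.na(m)] <- cl$pairs$cosine[m[!is.na(m)]]
        rows[[length(rows) + 1L]] <- e
      }
    }
  }
  e <- do.call(rbind, rows)
  if (is.null(e) || nrow(e) == 0L)
    return(igraph::make_empty_graph(directed = FALSE))
  e <- e[e$from != e$to, , drop = FALSE]
  a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
  key <- paste(a, b)
  w <- tapply(e$weight, key, max)
  uniq <- !duplicated(key)
  e2 <- data.frame(from = a[uniq], to = b[uniq],
                   weight = unname(w[key[uniq]]))
  e2 <- e2[order(e2$from, e2$to), ]
  igraph::graph_from_data_frame(e2, directed = FALSE)
}

#' Markov clustering of the ortholog graph
#'
#' Native MCL: the weighted adjacency matrix with self-loops added is
#' column-normalised, then expansion (matrix squaring) and inflation
#' (entry-wise power followed by column renormalisation) alternate,
#' pruning entries below `pruning`, until the largest entry change drops
#' below `tol` or `maxIter` iterations. Clusters are the connected
#' components of the limit matrix's support; every node is assigned to
#' exactly one group. Groups are ordered (and their ids assigned) by
#' their lexicographically smallest member.
#'
#' @param graph an [igraph::igraph] with a `weight` edge attribute (as
#'   from [buildOrthologGraph()]), or a symmetric adjacency matrix.
#' @param inflation inflation exponent, must be > 1 (default 1.5).
#' @param pruning entries below this are dropped each iteration.
#' @param tol convergence tolerance on the max entry change.
#' @param maxIter iteration cap.
#' @return an [OrthologGroupSet-class].
#' @export
mclCluster <- function(graph, inflation = 1.5, pruning = 1e-5,
                       tol = 1e-6, maxIter = 100L) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (inherits(graph, "igraph")) {
    if (igraph::vcount(graph) == 0L)
      return(new("OrthologGroupSet", groups = list(),
                 inflation = inflation))
    A <- igraph::as_adjacency_matrix(graph, attr =
      if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
      sparse = TRUE)
  } else {
    A <- methods::as(graph, "CsparseMatrix")
  }
  n <- nrow(A)
  ids <- rownames(A) %||% as.character(seq_len(n))
  M <- A + Matrix::Diagonal(n)
  normalize <- function(M) {
    cs <- Matrix::colSums(M)
    zero <- cs == 0
    if (any(zero)) {
      M <- M + Matrix::sparseMatrix(i = which(zero), j = which(zero),
                                    x = 1, dims = c(n, n))
      cs <- Matrix::colSums(M)
    }
    M %*% Matrix::Diagonal(n, 1 / cs)
  }
  M <- normalize(M)
  for (it in seq_len(maxIter)) {
    M2 <- M %*% M                       # expansion
    M2 <- methods::as(M2, "CsparseMatrix")
    M2@x <- M2@x^inflation              # inflation
    M2@x[M2@x < pruning] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalize(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  supp <- (M + Matrix::t(M)) > 0
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  groups <- split(ids, comp)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  names(groups) <- sprintf("OG%06d", seq_along(groups))
  new("OrthologGroupSet", groups = groups, inflation = inflation)
}

#' @describeIn OrthologGroupSet-class the groups as a named list
#' @param x an `OrthologGroupSet`.
#' @export
groups <- function(x) x@groups

#' @describeIn OrthologGroupSet-class number of groups
#' @export
nGroups <- function(x) length(x@groups)

setMethod("show", "OrthologGroupSet", function(object) {
  sizes <- lengths(object@groups)
  cat("OrthologGroupSet: ", length(sizes), " groups, ",
      sum(sizes), " proteins (inflation=", object@inflation, ")\n",
      sep = "")
})
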