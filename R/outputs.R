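fmtMembers <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return("")
  paste(sprintf("%s:%s", m$id, formatC(m$confidence, format = "g",
                                       digits = 6)), collapse = ",")
}

parseMembers <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(id = character(), confidence = numeric()))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, "", 1L),
             confidence = as.numeric(vapply(parts, `[`, "", 2L)))
}

fmtPairs <- function(p) {
  if (is.null(p) || nrow(p) == 0L) return("")
  paste(sprintf("%s|%s|%s", p$a, p$b,
                formatC(p$cosine, format = "g", digits = 6)),
        collapse = ",")
}

parsePairs <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(a = character(), b = character(),
                      cosine = numeric()))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1L]], "|", fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1L),
             b = vapply(parts, `[`, "", 2L),
             cosine = as.numeric(vapply(parts, `[`, "", 3L)))
}

#' Write a species-pair ortholog table as TSV
#'
#' One row per cluster: cluster id, provenance, seed pair and score,
#' per-side members with confidences (`id:confidence`, comma-joined) and
#' the attested domain pairs (`a|b|cosine`) where applicable.
#'
#' @param po a [PairwiseOrthologs-class].
#' @param path output TSV path.
#' @export
writePairwiseTable <- function(po, path) {
  cls <- po@clusters
  d <- data.frame(
    cluster_id = if (length(cls)) sprintf("%s-%s_%04d", po@proteomeA,
                                          po@proteomeB,
                                          seq_along(cls)) else character(),
    provenance = vapply(cls, `[[`, "", "provenance"),
    seed_a = vapply(cls, function(x) x$seedA %||% NA_character_, ""),
    seed_b = vapply(cls, function(x) x$seedB %||% NA_character_, ""),
    seed_score = vapply(cls, function(x) x$seedScore %||% NA_real_, 0),
    members_a = vapply(cls, function(x) fmtMembers(x$membersA), ""),
    members_b = vapply(cls, function(x) fmtMembers(x$membersB), ""),
    domain_pairs = vapply(cls, function(x) fmtPairs(x$pairs), "")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pair\t", po@proteomeA, "\t", po@proteomeB), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Re-read a species-pair ortholog table written by [writePairwiseTable()]
#'
#' @param path TSV path.
#' @return a [PairwiseOrthologs-class] equal to the one written.
#' @export
readPairwiseTable <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  d <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = "NA")
  cls <- lapply(seq_len(nrow(d)), function(i) {
    domain <- d$provenance[i] == "domain"
    cl <- list(
      seedA = if (is.na(d$seed_a[i])) NA_character_ else d$seed_a[i],
      seedB = if (is.na(d$seed_b[i])) NA_character_ else d$seed_b[i],
      seedScore = d$seed_score[i],
      membersA = if (domain) NULL else parseMembers(d$members_a[i]),
      membersB = if (domain) NULL else parseMembers(d$members_b[i]),
      pairs = if (nzchar(d$domain_pairs[i] %||% "") &&
                  !is.na(d$domain_pairs[i]))
        parsePairs(d$domain_pairs[i]) else NULL,
      provenance = d$provenance[i])
    if (cl$provenance == "graph") cl$pairs <- NULL
    cl
  })
  new("PairwiseOrthologs", proteomeA = hdr[2L], proteomeB = hdr[3L],
      clusters = cls)
}

#' Write ortholog groups as a TSV table
#'
#' One row per group: og id, group size, then one column per species
#' with the comma-joined member protein ids of that species.
#'
#' @param ogs an [OrthologGroupSet-class].
#' @param path output TSV path.
#' @param species optional character vector fixing the species columns;
#'   defaults to the species present in the groups.
#' @export
writeGroupTable <- function(ogs, path, species = NULL) {
  gl <- ogs@groups
  allIds <- unlist(gl, use.names = FALSE)
  sp <- species %||%
    (if (length(allIds)) sort(unique(splitNsId(allIds)$proteome))
     else character())
  rows <- lapply(names(gl), function(og) {
    ns <- splitNsId(gl[[og]])
    cells <- vapply(sp, function(s)
      paste(sort(ns$protein[ns$proteome == s]), collapse = ","), "")
    c(og_id = og, size = as.character(length(gl[[og]])), cells)
  })
  d <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (nrow(d) == 0L)
    d <- setNames(data.frame(matrix(character(), ncol = 2 + length(sp))),
                  c("og_id", "size", sp))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump an ortholog graph in MCL "abc" format
#'
#' @param graph an [igraph::igraph] with a `weight` attribute.
#' @param path output path (`node <TAB> node <TAB> weight`).
#' @export
writeGraphAbc <- function(graph, path) {
  e <- igraph::as_data_frame(graph, what = "edges")
  lines <- sprintf("%s\t%s\t%s", e$from, e$to,
                   formatC(e$weight, format = "g", digits = 6))
  writeLines(lines, path)
  invisible(path)
}

#' Write all pipeline outputs
#'
#' Per-pair ortholog tables, the ortholog-group table, the MCL input
#' graph in "abc" format and a JSON run manifest recording the seeds and
#' thresholds, so a run can be replayed from its manifest.
#'
#' @param tables list of merged [PairwiseOrthologs-class] objects.
#' @param ogs an [OrthologGroupSet-class].
#' @param graph the ortholog [igraph::igraph].
#' @param outDir output directory (created if needed).
#' @param config named list of run parameters stored in the manifest.
#' @return invisibly, the manifest path.
#' @export
writeOutputs <- function(tables, ogs, graph, outDir, config = list()) {
  ok <- dir.exists(outDir) || dir.create(outDir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outDir, 2L) != 0L)
    stop("output directory is not writable: ", outDir)
  pairDir <- file.path(outDir, "pairwise")
  dir.create(pairDir, showWarnings = FALSE)
  files <- character()
  for (tab in tables) {
    f <- file.path(pairDir, paste0(tab@proteomeA, "-", tab@proteomeB,
                                   ".tsv"))
    writePairwiseTable(tab, f)
    files <- c(files, f)
  }
  ogFile <- file.path(outDir, "ortholog_groups.tsv")
  writeGroupTable(ogs, ogFile)
  abcFile <- file.path(outDir, "graph.abc")
  writeGraphAbc(graph, abcFile)
  manifest <- c(list(package = "OrthoDuet",
                     version = as.character(
                       utils::packageVersion("OrthoDuet"))),
                config,
                list(n_pairwise_tables = length(tables),
                     n_groups = length(ogs@groups)))
  manifestFile <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestFile, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifestFile)
}
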