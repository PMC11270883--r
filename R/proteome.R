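#' Read one proteome from a FASTA file
#'
#' One protein per record. The record id up to the first whitespace becomes
#' the protein id, sequences are uppercased and trailing stop characters
#' (`*`) are stripped. Ambiguity codes (X, B, Z, U, O) are accepted and
#' counted as residues; any other character is an error.
#'
#' @param path path to an amino-acid FASTA file.
#' @param proteomeId proteome label; defaults to the file name stem.
#' @return a [Proteome-class] object.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 desc", "MKV", ">p2", "MAACDE"), fa)
#' p <- readProteome(fa)
#' nProteins(p)
#' @export
readProteome <- function(path, proteomeId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  proteomeId <- proteomeId %||% tools::file_path_sans_ext(basename(path))
  # read without an alphabet first so validation errors can name the record
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate protein id in ", path, ": ", ids[duplicated(ids)][1L])
  chr <- toupper(as.character(seqs))
  chr <- sub("\\*+$", "", chr)
  if (any(!nzchar(chr))) stop("empty sequence for record: ",
                              ids[!nzchar(chr)][1L])
  bad <- grepl(paste0("[^", AA_OK, "]"), chr)
  if (any(bad))
    stop("non-amino-acid characters in record: ", ids[bad][1L])
  Proteome(proteomeId, setNames(chr, ids))
}

#' Construct a Proteome from named character sequences
#'
#' @param proteomeId proteome label.
#' @param sequences named character vector of amino-acid sequences.
#' @return a [Proteome-class] object.
#' @export
Proteome <- function(proteomeId, sequences) {
  new("Proteome", proteomeId = proteomeId,
      sequences = Biostrings::AAStringSet(sequences))
}

#' Read a directory of proteome FASTA files
#'
#' Files are scanned in lexicographic order; each file name stem becomes
#' the proteome id.
#'
#' @param dir directory containing one FASTA file per proteome
#'   (extensions fa/faa/fasta, optionally anything readable as FASTA).
#' @param pattern file-name filter passed to [list.files()].
#' @return named list of [Proteome-class] objects.
#' @export
readProteomeDir <- function(dir, pattern = "\\.(fa|faa|fasta)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files found in ", dir)
  ps <- lapply(files, readProteome)
  setNames(ps, vapply(ps, proteomeId, character(1)))
}

#' @describeIn Proteome-class number of proteins
#' @param p a `Proteome`.
#' @export
nProteins <- function(p) length(p@sequences)

#' @describeIn Proteome-class the proteome label
#' @export
proteomeId <- function(p) p@proteomeId

#' @describeIn Proteome-class named vector of sequence lengths (aa)
#' @export
proteinLengths <- function(p) {
  setNames(Biostrings::width(p@sequences), names(p@sequences))
}

#' @describeIn Proteome-class sequences as a named character vector
#' @export
proteinSequences <- function(p) {
  setNames(as.character(p@sequences), names(p@sequences))
}

#' Restrict a proteome to a subset of its proteins
#'
#' @param p a [Proteome-class].
#' @param ids protein ids to keep (raw or namespaced).
#' @return a `Proteome` with only the requested proteins, in their
#'   original order.
#' @export
subsetProteome <- function(p, ids) {
  ids <- sub(paste0("^", p@proteomeId, NS_SEP), "", ids)
  keep <- names(p@sequences) %in% ids
  if (!any(keep)) stop("subset would be empty")
  new("Proteome", proteomeId = p@proteomeId, sequences = p@sequences[keep])
}

#' Compute per-proteome summary statistics
#'
#' Protein count, total residue count and mean protein length: the
#' features consumed by the alignment-direction classifier. Invariant
#' under protein reordering.
#'
#' @param p a [Proteome-class].
#' @return a [ProteomeStats-class] object.
#' @export
proteomeStats <- function(p) {
  stopifnot(is(p, "Proteome"))
  w <- Biostrings::width(p@sequences)
  new("ProteomeStats",
      proteomeId = p@proteomeId,
      proteinCount = length(w),
      residueCount = as.numeric(sum(w)),
      meanProteinLength = sum(w) / length(w))
}

#' @describeIn ProteomeStats-class accessors
#' @param x a `ProteomeStats`.
#' @export
proteinCount <- function(x) x@proteinCount

#' @describeIn ProteomeStats-class total residues
#' @export
residueCount <- function(x) x@residueCount

#' @describeIn ProteomeStats-class mean protein length (aa)
#' @export
meanProteinLength <- function(x) x@meanProteinLength

setMethod("show", "Proteome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat("Proteome '", object@proteomeId, "': ", length(w), " proteins, ",
      sum(w), " aa (mean ", round(mean(w), 1), ")\n", sep = "")
})

setMethod("show", "ProteomeStats", function(object) {
  cat("ProteomeStats '", object@proteomeId, "': n=", object@proteinCount,
      ", residues=", object@residueCount, ", mean length=",
      round(object@meanProteinLength, 2), "\n", sep = "")
})
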