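#' Protein records
#'
#' Proteins are represented as [Biostrings::AAStringSet] objects whose names
#' are the record identifiers and whose element metadata (`mcols`) carry a
#' free-text `name` and a provenance `source` note. Only the 20 canonical
#' one-letter residue codes are accepted; sequences are uppercased on entry.
#'
#' @param id Short identifier, unique within a collection.
#' @param sequence Amino-acid sequence (one-letter codes; case-insensitive).
#' @param name Free-text protein name.
#' @param source Provenance note.
#' @return An `AAStringSet` of length one.
#' @examples
#' proteinRecord("toy", "MKIIF")
#' @export
proteinRecord <- function(id, sequence, name = id, source = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- checkResidues(sequence)
  x <- Biostrings::AAStringSet(stats::setNames(sequence, id))
  S4Vectors::mcols(x) <- S4Vectors::DataFrame(name = name, source = source)
  x
}

#' Read protein sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] with validation: sequences are
#' uppercased, and any character outside the 20 canonical residue codes is
#' rejected with its record and position named.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped, multi-record).
#' @return An [Biostrings::AAStringSet] with unique names; `mcols()` carries
#'   `name` (the full FASTA header) and `source` (the file path).
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- Biostrings::readAAStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- vapply(seq_along(x), function(i) {
    checkResidues(as.character(x[[i]]), what = paste0("record '", ids[i], "'"))
  }, character(1L))
  out <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(name = headers, source = path)
  out
}

#' Write protein records to a FASTA file
#'
#' Round-trips with [readFasta()] on (id, sequence). Lines are wrapped at 80
#' columns.
#'
#' @param records A non-empty named [Biostrings::AAStringSet] (or a named
#'   character vector of sequences).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path) {
  if (is.character(records)) {
    records <- Biostrings::AAStringSet(records)
  }
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("all records must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(records, filepath = path, width = 80L)
  invisible(path)
}

#' Reconstruct a protein from an ordered fragment list
#'
#' Concatenates digestion fragments, in order, back into the parent protein.
#' This is how the two rice storage proteins shipped with the package are
#' rebuilt from their published hydrolysis fragment lists.
#'
#' @param fragmentList Character vector of non-empty fragment sequences, in
#'   N-to-C order.
#' @param id Identifier for the reconstructed record.
#' @param name,source Passed to [proteinRecord()].
#' @return An `AAStringSet` of length one whose sequence is the in-order
#'   concatenation (length = sum of fragment lengths).
#' @examples
#' reconstructFromFragments(c("M", "K", "IIF"), id = "toy")
#' @export
reconstructFromFragments <- function(fragmentList, id, name = id,
                                     source = "reconstructed from fragments") {
  if (length(fragmentList) == 0L) {
    stop("fragment list must be non-empty", call. = FALSE)
  }
  fragmentList <- checkResiduesVec(fragmentList, what = "fragment")
  proteinRecord(id, paste(fragmentList, collapse = ""), name = name,
                source = source)
}

# Read a one-fragment-per-line fixture file.
readFragmentList <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(trimws(x)) & !startsWith(trimws(x), "#")]
  trimws(x)
}

#' Packaged rice storage proteins
#'
#' The two digestion substrates studied by the package: the rice prolamin
#' and glutelin storage-protein fractions, reconstructed by concatenating
#' their published proteolysis fragment lists (shipped as plain-text
#' fixtures under `extdata/`). Digesting either record with
#' [defaultRules()] regenerates its fragment list exactly.
#'
#' @return An `AAStringSet` of length one (prolamin 149 aa, glutelin 499 aa).
#' @examples
#' riceProlamin()
#' @export
riceProlamin <- function() {
  path <- system.file("extdata", "prolamin_fragments.txt",
                      package = "PepScreen", mustWork = TRUE)
  reconstructFromFragments(readFragmentList(path), id = "prolamin",
                           name = "rice prolamin fraction",
                           source = "reconstructed from published hydrolysis fragments")
}

#' @rdname riceProlamin
#' @export
riceGlutelin <- function() {
  path <- system.file("extdata", "glutelin_fragments.txt",
                      package = "PepScreen", mustWork = TRUE)
  reconstructFromFragments(readFragmentList(path), id = "glutelin",
                           name = "rice glutelin fraction",
                           source = "reconstructed from published hydrolysis fragments")
}
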