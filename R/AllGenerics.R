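#' @include AllClasses.R
NULL

#' Accessors for PepScreen result objects
#'
#' @param object A [DigestResult-class], [ScreenReport-class] or
#'   [ContactReport-class] object.
#' @return `fragments()` the fragment `data.frame`; `cutSites()` the integer
#'   cut positions; `enzymes()` the enzyme names; `parentId()` the parent
#'   protein identifier; `reportTable()` the per-peptide report;
#'   `provenance()` the configuration list; `contacted()`,
#'   `hotspotContacts()`, `otherContacts()` the contacted-residue labels.
#'
#' @name accessors
#' @rdname accessors
#' @examples
#' res <- digestProtein(proteinRecord("toy", "MKIIF"), defaultRules())
#' fragments(res)
#' cutSites(res)
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(object) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("cutSites", function(object) standardGeneric("cutSites"))

#' @rdname accessors
#' @export
setGeneric("enzymes", function(object) standardGeneric("enzymes"))

#' @rdname accessors
#' @export
setGeneric("parentId", function(object) standardGeneric("parentId"))

#' @rdname accessors
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("contacted", function(object) standardGeneric("contacted"))

#' @rdname accessors
#' @export
setGeneric("hotspotContacts", function(object) standardGeneric("hotspotContacts"))

#' @rdname accessors
#' @export
setGeneric("otherContacts", function(object) standardGeneric("otherContacts"))

#' @rdname accessors
#' @export
setMethod("fragments", "DigestResult", function(object) object@fragments)

#' @rdname accessors
#' @export
setMethod("cutSites", "DigestResult", function(object) object@cutSites)

#' @rdname accessors
#' @export
setMethod("enzymes", "DigestResult", function(object) object@enzymes)

#' @rdname accessors
#' @export
setMethod("parentId", "DigestResult", function(object) object@parentId)

#' @rdname accessors
#' @export
setMethod("reportTable", "ScreenReport", function(object) object@table)

#' @rdname accessors
#' @export
setMethod("provenance", "ScreenReport", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("contacted", "ContactReport", function(object) object@contacted)

#' @rdname accessors
#' @export
setMethod("hotspotContacts", "ContactReport",
          function(object) object@hotspotContacts)

#' @rdname accessors
#' @export
setMethod("otherContacts", "ContactReport",
          function(object) object@otherContacts)

setMethod("show", "CleavageRule", function(object) {
  cat("CleavageRule:", object@enzyme,
      if (length(object@ec) && nzchar(object@ec)) paste0("(EC ", object@ec, ")"),
      "\n  cut after: {", paste(object@cutAfter, collapse = ", "), "}\n")
  if (length(object@notBefore) > 0L) {
    cat("  not before: {", paste(object@notBefore, collapse = ", "), "}\n")
  }
})

setMethod("show", "DigestResult", function(object) {
  fr <- object@fragments
  cat("DigestResult for '", object@parentId, "' (",
      nchar(object@sequence), " aa)\n", sep = "")
  cat("  enzymes:", paste(object@enzymes, collapse = ", "), "\n")
  cat("  ", nrow(fr), " fragments from ", length(object@cutSites),
      " cut sites\n", sep = "")
  shown <- paste(utils::head(fr$sequence, 8L), collapse = "-")
  cat("  ", shown, if (nrow(fr) > 8L) "-..." else "", "\n", sep = "")
})

setMethod("show", "GridBox", function(object) {
  cat(sprintf(
    "GridBox: center (%.3f, %.3f, %.3f) A; %g x %g x %g points @ %.4f A\n",
    object@centerX, object@centerY, object@centerZ,
    object@sizeX, object@sizeY, object@sizeZ, object@spacing))
  cat(sprintf("  physical size: %.3f x %.3f x %.3f A\n",
              object@sizeX * object@spacing,
              object@sizeY * object@spacing,
              object@sizeZ * object@spacing))
})

setMethod("show", "ContactReport", function(object) {
  cat("ContactReport:", nrow(object@bonds), "hydrogen bond(s)\n")
  cat("  contacted:", paste(object@contacted, collapse = ", "), "\n")
  cat("  in hotspot set:",
      if (length(object@hotspotContacts)) paste(object@hotspotContacts, collapse = ", ") else "(none)",
      "\n")
  if (length(object@otherContacts) > 0L) {
    cat("  outside hotspot set:",
        paste(object@otherContacts, collapse = ", "), "\n")
  }
})

setMethod("show", "ScreenReport", function(object) {
  tb <- object@table
  cat("ScreenReport:", nrow(tb), "peptide(s) in the length window\n")
  cat("  scored:", sum(!tb$unscored), " high-affinity:", sum(tb$highAffinity),
      " orally absorbable:", sum(tb$highAffinity & tb$orallyAbsorbable, na.rm = TRUE), "\n")
  cand <- tb[tb$highAffinity, c("fraction", "peptide", "score", "mw",
                                "logp", "hbd", "hba", "violations",
                                "orallyAbsorbable")]
  if (nrow(cand) > 0L) {
    cat("  high-affinity candidates:\n")
    print(cand, row.names = FALSE)
  }
})
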