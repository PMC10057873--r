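#' @import methods
NULL

#' Protease cleavage specificity
#'
#' A `CleavageRule` describes one protease as a P1 specificity set
#' (`cutAfter`: cleavage occurs C-terminal to these residues) and an optional
#' P1' exception set (`notBefore`: no cleavage when the following residue is
#' one of these).
#'
#' @slot enzyme Enzyme name, e.g. `"pepsin (pH 1.3)"`.
#' @slot ec EC number string, e.g. `"3.4.23.1"`.
#' @slot cutAfter Character vector of one-letter residues; cleavage is
#'   C-terminal to any of them.
#' @slot notBefore Character vector of one-letter residues blocking cleavage
#'   when found immediately C-terminal to the scissile bond (may be empty).
#'
#' @seealso [cleavageRule()], [defaultRules()], [digestProtein()]
#' @exportClass CleavageRule
setClass("CleavageRule",
  representation(
    enzyme = "character",
    ec = "character",
    cutAfter = "character",
    notBefore = "character"
  )
)

setValidity("CleavageRule", function(object) {
  msg <- character()
  if (length(object@enzyme) != 1L || !nzchar(object@enzyme)) {
    msg <- c(msg, "'enzyme' must be a single non-empty string")
  }
  if (length(object@cutAfter) == 0L) {
    msg <- c(msg, "'cutAfter' must be non-empty")
  }
  bad <- setdiff(c(object@cutAfter, object@notBefore), AA_CANONICAL)
  if (length(bad) > 0L) {
    msg <- c(msg, paste0("non-canonical residue(s) in rule: ",
                         paste(bad, collapse = ", ")))
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Result of an in silico digestion
#'
#' Produced by [digestProtein()]. Fragments tile the parent sequence:
#' starts/ends are consecutive 0-based half-open coordinates, the first start
#' is 0, the last end is the parent length, and concatenating the fragment
#' sequences in order restores the parent.
#'
#' @slot parentId Identifier of the digested protein.
#' @slot sequence The parent sequence that was digested.
#' @slot cutSites Strictly increasing integer positions in `(0, length)`;
#'   a cut at position i separates `sequence[0:i]` from `sequence[i:]`
#'   (0-based half-open convention).
#' @slot fragments A `data.frame` with columns `parent_id`, `start`, `end`,
#'   `length`, `sequence`, one row per positional fragment (duplicate
#'   sequences retained as distinct rows).
#' @slot enzymes Names of the enzymes applied.
#'
#' @seealso [fragments()], [cutSites()], [classifyLengths()],
#'   [selectByLength()]
#' @exportClass DigestResult
setClass("DigestResult",
  representation(
    parentId = "character",
    sequence = "character",
    cutSites = "integer",
    fragments = "data.frame",
    enzymes = "character"
  )
)

setValidity("DigestResult", function(object) {
  msg <- character()
  n <- nchar(object@sequence)
  s <- object@cutSites
  if (length(s) > 0L && (any(diff(s) <= 0L) || any(s <= 0L) || any(s >= n))) {
    msg <- c(msg, "'cutSites' must be strictly increasing and inside (0, length)")
  }
  fr <- object@fragments
  need <- c("parent_id", "start", "end", "length", "sequence")
  if (!all(need %in% names(fr))) {
    msg <- c(msg, "'fragments' must have columns parent_id/start/end/length/sequence")
  } else if (nrow(fr) > 0L) {
    if (fr$start[1L] != 0L || fr$end[nrow(fr)] != n ||
        (nrow(fr) > 1L && any(fr$start[-1L] != fr$end[-nrow(fr)]))) {
      msg <- c(msg, "fragments must tile the parent sequence")
    }
    if (paste(fr$sequence, collapse = "") != object@sequence) {
      msg <- c(msg, "concatenated fragments must equal the parent sequence")
    }
  }
  if (length(msg) > 0L) msg else TRUE
})

#' Docking search box
#'
#' A rectangular grid box in the AutoDock convention: a centre in Angstrom,
#' integer numbers of grid points per axis, and a grid spacing in Angstrom.
#' The physical edge length of an axis is `points * spacing` Angstrom
#' (the Vina convention, which states sizes directly in Angstrom).
#'
#' @slot centerX,centerY,centerZ Box centre (Angstrom).
#' @slot sizeX,sizeY,sizeZ Number of grid points per axis.
#' @slot spacing Grid spacing (Angstrom).
#'
#' @seealso [gridBox()], [defaultGridBox()], [makeGridboxConfig()]
#' @exportClass GridBox
setClass("GridBox",
  representation(
    centerX = "numeric", centerY = "numeric", centerZ = "numeric",
    sizeX = "numeric", sizeY = "numeric", sizeZ = "numeric",
    spacing = "numeric"
  )
)

setValidity("GridBox", function(object) {
  sizes <- c(object@sizeX, object@sizeY, object@sizeZ)
  if (any(sizes <= 0) || object@spacing <= 0) {
    "box sizes and spacing must be positive"
  } else {
    TRUE
  }
})

#' Hydrogen-bond contacts of a docked pose
#'
#' Produced by [contactResidues()]: the hydrogen bonds of a pose, the unique
#' receptor residues they touch, and the intersection of those residues with
#' a hotspot set. Contacts outside the hotspot set are kept and flagged,
#' never dropped.
#'
#' @slot bonds The hydrogen-bond table from [detectHbonds()].
#' @slot contacted Unique receptor residues contacted, as `"CYS285"`-style
#'   labels.
#' @slot hotspotContacts Subset of `contacted` that lies in the hotspot set.
#' @slot otherContacts Contacted residues outside the hotspot set.
#'
#' @exportClass ContactReport
setClass("ContactReport",
  representation(
    bonds = "data.frame",
    contacted = "character",
    hotspotContacts = "character",
    otherContacts = "character"
  )
)

setValidity("ContactReport", function(object) {
  ok <- all(object@hotspotContacts %in% object@contacted) &&
    all(object@otherContacts %in% object@contacted)
  if (!ok) "hotspot/other contacts must be subsets of 'contacted'" else TRUE
})

#' End-to-end screening report
#'
#' Produced by [runPipeline()]. `reportTable()` returns one row per peptide
#' of the bioaccessible length window, with affinity score, high-affinity
#' flag, computed physicochemical properties and the Lipinski verdict;
#' `provenance()` returns the configuration that generated the report.
#'
#' @slot table The per-peptide report `data.frame`.
#' @slot provenance Named list: rule set, length window, affinity threshold,
#'   Lipinski thresholds, join mode, input summaries.
#'
#' @seealso [runPipeline()], [reportTable()], [provenance()]
#' @exportClass ScreenReport
setClass("ScreenReport",
  representation(
    table = "data.frame",
    provenance = "list"
  )
)
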