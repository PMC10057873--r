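#' Construct a protease cleavage rule
#'
#' @param enzyme Enzyme name.
#' @param ec EC number string (may be empty).
#' @param cutAfter One-letter residues; cleavage occurs C-terminal to any of
#'   them (P1 specificity).
#' @param notBefore One-letter residues blocking cleavage when immediately
#'   C-terminal to the scissile bond (P1' exceptions; default none).
#' @return A [CleavageRule-class] object.
#' @examples
#' cleavageRule("trypsin", "3.4.21.4", c("K", "R"))
#' @export
cleavageRule <- function(enzyme, ec = "", cutAfter, notBefore = character()) {
  new("CleavageRule", enzyme = enzyme, ec = ec,
      cutAfter = toupper(cutAfter), notBefore = toupper(notBefore))
}

#' Default gastrointestinal rule set
#'
#' The simultaneous pepsin + trypsin + chymotrypsin digestion used
#' throughout the package. Specificities follow the BIOPEP-style
#' conventions: pepsin at acidic pH cuts after F and L; trypsin after K and
#' R; chymotrypsin after the bulky/aromatic set W, Y, F, M, L, N, H. No P1'
#' exceptions are applied: the combined cut-after set {F, L, W, Y, M, K, R,
#' N, H} with empty exception sets reproduces the published fragment lists
#' of both packaged rice proteins exactly (including cleavage of Y|P bonds,
#' which a "not before proline" exception would forbid).
#'
#' @return A list of three [CleavageRule-class] objects.
#' @seealso [readRules()] to load a rule set from a YAML file.
#' @export
defaultRules <- function() {
  readRules(system.file("extdata", "enzymes.yaml", package = "PepScreen",
                        mustWork = TRUE))
}

#' Load a cleavage rule set from a YAML file
#'
#' The file maps enzyme names to `ec`, `cut_after` and optional `not_before`
#' entries (residues given as a string, e.g. `"KR"`). An entry without
#' `cut_after` is a configuration error, never a silent no-op.
#'
#' @param path Path to a YAML rule file (see `extdata/enzymes.yaml` for the
#'   packaged default).
#' @return A list of [CleavageRule-class] objects.
#' @export
readRules <- function(path) {
  if (!file.exists(path)) stop("rule file not found: ", path, call. = FALSE)
  spec <- yaml::read_yaml(path)
  if (length(spec) == 0L) stop("rule file is empty: ", path, call. = FALSE)
  lapply(names(spec), function(nm) {
    entry <- spec[[nm]]
    if (is.null(entry$cut_after) || !nzchar(entry$cut_after)) {
      stop("enzyme '", nm, "' has no cut_after specificity in ", path,
           call. = FALSE)
    }
    split1 <- function(s) if (is.null(s) || !nzchar(s)) character() else
      strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    cleavageRule(nm, ec = if (is.null(entry$ec)) "" else entry$ec,
                 cutAfter = split1(entry$cut_after),
                 notBefore = split1(entry$not_before))
  })
}

#' Find cleavage positions for a rule set
#'
#' Positions are 0-based half-open boundaries: a cut at position i separates
#' `sequence[0:i]` from `sequence[i:]`. Position i is a cut iff some rule
#' has residue i (1-based) in its `cutAfter` set and residue i+1 is not in
#' that same rule's `notBefore` set. The boundary after the final residue is
#' never returned. With several rules the union of their sites is taken
#' (simultaneous digestion).
#'
#' @param sequence Residue string (or an `AAStringSet` of length one).
#' @param rules A [CleavageRule-class] or list thereof.
#' @return Sorted integer vector of cut positions in `(0, length)`.
#' @examples
#' findCutSites("MKIIF", defaultRules())  # 1, 2
#' @export
findCutSites <- function(sequence, rules) {
  sequence <- asSequenceString(sequence)
  sequence <- checkResidues(sequence)
  rules <- asRuleList(rules)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sites <- integer()
  for (rule in rules) {
    idx <- which(chars %in% rule@cutAfter)
    idx <- idx[idx < n]
    if (length(rule@notBefore) > 0L && length(idx) > 0L) {
      idx <- idx[!chars[idx + 1L] %in% rule@notBefore]
    }
    sites <- union(sites, idx)
  }
  sort(as.integer(sites))
}

asRuleList <- function(rules) {
  if (is(rules, "CleavageRule")) rules <- list(rules)
  if (!is.list(rules) || length(rules) == 0L ||
      !all(vapply(rules, is, logical(1L), "CleavageRule"))) {
    stop("'rules' must be a non-empty list of CleavageRule objects",
         call. = FALSE)
  }
  rules
}

asSequenceString <- function(x) {
  if (is(x, "XStringSet")) {
    if (length(x) != 1L) stop("expected a single sequence", call. = FALSE)
    return(as.character(x[[1L]]))
  }
  if (is(x, "XString")) return(as.character(x))
  x
}

#' Digest a protein with a protease rule set
#'
#' Splits the parent sequence at every cleavage position and enumerates the
#' released fragments as maximal substrings between consecutive cut sites.
#' Duplicate fragment sequences are retained as distinct positional rows.
#' The default mode applies all enzymes simultaneously (union of cut
#' sites); `mode = "sequential"` applies them one after another, each round
#' re-digesting the fragments of the previous one (identical output for
#' rules without P1' exceptions).
#'
#' @param protein A record from [proteinRecord()]/[readFasta()] (an
#'   `AAStringSet` of length one) or a plain residue string.
#' @param rules A [CleavageRule-class] or list thereof; see [defaultRules()].
#' @param mode `"simultaneous"` (default) or `"sequential"`.
#' @param id Parent identifier used when `protein` is a bare string.
#' @return A [DigestResult-class] object.
#' @examples
#' digestProtein(riceProlamin(), defaultRules())
#' @export
digestProtein <- function(protein, rules,
                          mode = c("simultaneous", "sequential"),
                          id = "protein") {
  mode <- match.arg(mode)
  rules <- asRuleList(rules)
  if (is(protein, "XStringSet")) {
    if (length(protein) != 1L) {
      stop("digestProtein() takes one protein at a time", call. = FALSE)
    }
    id <- names(protein)
    sequence <- as.character(protein[[1L]])
  } else {
    sequence <- protein
  }
  sequence <- checkResidues(sequence)

  if (mode == "simultaneous") {
    sites <- findCutSites(sequence, rules)
  } else {
    # Each enzyme in turn digests the fragment set of the previous round;
    # cut positions are mapped back to parent coordinates.
    bounds <- c(0L, nchar(sequence))
    for (rule in rules) {
      starts <- utils::head(bounds, -1L)
      ends <- utils::tail(bounds, -1L)
      newSites <- unlist(lapply(seq_along(starts), function(i) {
        frag <- substr(sequence, starts[i] + 1L, ends[i])
        findCutSites(frag, rule) + starts[i]
      }))
      bounds <- sort(unique(c(bounds, as.integer(newSites))))
    }
    sites <- setdiff(bounds, c(0L, nchar(sequence)))
  }

  bounds <- c(0L, sites, nchar(sequence))
  starts <- utils::head(bounds, -1L)
  ends <- utils::tail(bounds, -1L)
  frag <- data.frame(
    parent_id = id,
    start = starts,
    end = ends,
    length = ends - starts,
    sequence = substring(sequence, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
  new("DigestResult", parentId = id, sequence = sequence,
      cutSites = as.integer(sites), fragments = frag,
      enzymes = vapply(rules, function(r) r@enzyme, character(1L)))
}

#' Fragment length-class statistics
#'
#' Counts digestion fragments in the three length classes used for
#' bioaccessibility triage — single residues, the passively absorbed 2-5
#' window, and longer than 5 — with percentages of the total reported to two
#' decimals (half-up rounding).
#'
#' @param result A [DigestResult-class].
#' @return A `data.frame` with columns `class` (`"1"`, `"2-5"`, `">5"`),
#'   `n` and `pct`; `sum(n)` is the total fragment count.
#' @examples
#' classifyLengths(digestProtein(riceProlamin(), defaultRules()))
#' @export
classifyLengths <- function(result) {
  stopifnot(is(result, "DigestResult"))
  len <- fragments(result)$length
  if (length(len) == 0L) stop("digest has no fragments", call. = FALSE)
  n <- c(sum(len == 1L), sum(len >= 2L & len <= 5L), sum(len > 5L))
  data.frame(
    class = c("1", "2-5", ">5"),
    n = n,
    pct = round2(100 * n / length(len)),
    stringsAsFactors = FALSE
  )
}

#' Select fragments by length
#'
#' The bioaccessibility filter: peptides of 2-5 residues are assumed to
#' cross the epithelial barrier passively and are the default selection.
#'
#' @param result A [DigestResult-class].
#' @param minLen,maxLen Inclusive length bounds (defaults 2 and 5).
#' @return The fragment `data.frame` rows with `minLen <= length <= maxLen`,
#'   in positional order, duplicates retained.
#' @export
selectByLength <- function(result, minLen = 2L, maxLen = 5L) {
  stopifnot(is(result, "DigestResult"))
  if (minLen < 1L || minLen > maxLen) {
    stop("need 1 <= minLen <= maxLen", call. = FALSE)
  }
  fr <- fragments(result)
  fr[fr$length >= minLen & fr$length <= maxLen, , drop = FALSE]
}

#' Render a digest in hyphenated fragment style
#'
#' @param result A [DigestResult-class].
#' @return A single string such as `"M-K-IIF"`.
#' @export
fragmentString <- function(result) {
  stopifnot(is(result, "DigestResult"))
  paste(fragments(result)$sequence, collapse = "-")
}

#' Write a digest fragment table to TSV
#'
#' @param result A [DigestResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDigestTsv <- function(result, path) {
  stopifnot(is(result, "DigestResult"))
  utils::write.table(fragments(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
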