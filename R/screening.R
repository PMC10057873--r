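#' Read a peptide affinity-score table
#'
#' Reads the TSV emitted by a blind protein-peptide docking server run:
#' column `peptide` (residue string) and `score` (dimensionless; more
#' negative = higher predicted affinity) are required; optional columns
#' (e.g. `binding_energy`, `interactions`, `fraction`) are passed through.
#' The packaged fixture `extdata/hpepdock_scores.tsv` carries the five
#' published high-affinity candidates.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` with validated `peptide` and numeric `score`.
#' @export
readAffinityScores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("peptide", "score") %in% names(x))) {
    stop("score file needs 'peptide' and 'score' columns: ", path,
         call. = FALSE)
  }
  x$peptide <- checkResiduesVec(x$peptide)
  if (!is.numeric(x$score)) stop("'score' column must be numeric",
                                 call. = FALSE)
  x
}

#' Filter affinity records at a score threshold
#'
#' High affinity is defined as a docking score at or below the threshold on
#' the server's native (negative) scale; the default -160 is the published
#' cut-off for the PPARgamma screen.
#'
#' @param records A `data.frame` with a numeric `score` column.
#' @param threshold Retain records with `score <= threshold`.
#' @return The retained rows, input order preserved.
#' @export
applyAffinityThreshold <- function(records, threshold = -160) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(records)
  records[records$score <= threshold, , drop = FALSE]
}

#' In vitro protein digestibility
#'
#' IVPD (%) = 100 * FP / IP, where FP is the protein percentage at the end
#' of the duodenal phase (120 min) and IP the protein percentage at time 0.
#'
#' @param fp Protein percentage at the end of the duodenal phase.
#' @param ip Protein percentage at time 0 (must be > 0).
#' @return Percentage, rounded to 2 decimals.
#' @examples
#' ivpd(fp = 21.535, ip = 50)  # 43.07
#' @export
ivpd <- function(fp, ip) {
  if (any(ip <= 0)) stop("'ip' must be > 0", call. = FALSE)
  if (any(fp < 0)) stop("'fp' must be >= 0", call. = FALSE)
  if (any(fp > ip)) {
    warning("fp > ip: digestibility above 100% is not physically meaningful")
  }
  round2(100 * fp / ip)
}

#' In vitro protein bioaccessibility
#'
#' IVPB (%) = 100 * Ptd / Pti, where Ptd is the dialyzed protein
#' concentration of the digested sample (mg/mL) and Pti the protein
#' concentration of the initial undigested sample (mg/mL).
#'
#' @param ptd Dialyzed protein concentration (mg/mL).
#' @param pti Initial undigested protein concentration (mg/mL; must be > 0).
#' @return Percentage, rounded to 2 decimals.
#' @examples
#' ivpb(ptd = 3.592, pti = 10)  # 35.92
#' @export
ivpb <- function(ptd, pti) {
  if (any(pti <= 0)) stop("'pti' must be > 0", call. = FALSE)
  if (any(ptd < 0)) stop("'ptd' must be >= 0", call. = FALSE)
  if (any(ptd > pti)) {
    warning("ptd > pti: bioaccessibility above 100% is not physically meaningful")
  }
  round2(100 * ptd / pti)
}

#' Run the end-to-end peptide screening pipeline
#'
#' Digests each input protein, keeps peptides of the bioaccessible length
#' window, joins externally computed docking affinity scores (peptides
#' without a score are flagged `unscored`, never dropped silently), flags
#' high-affinity candidates at the score threshold, computes
#' physicochemical properties, and applies the Lipinski rule. The result is
#' deterministic for a given configuration.
#'
#' @param proteins An [Biostrings::AAStringSet] (one entry per protein
#'   fraction), e.g. `c(riceGlutelin(), riceProlamin())`.
#' @param scores Affinity table from [readAffinityScores()] (or any
#'   `data.frame` with `peptide` and `score`).
#' @param rules Cleavage rule set; default [defaultRules()].
#' @param minLen,maxLen Bioaccessibility length window (defaults 2-5).
#' @param affinityThreshold High-affinity cut-off on the score scale
#'   (default -160).
#' @param thresholds Lipinski thresholds from [lipinskiThresholds()].
#' @param logp Optional named vector of external partition coefficients
#'   (see [peptideProperties()]).
#' @param joinMode `"lenient"` (default) reports score-file peptides absent
#'   from the digest window as a warning; `"strict"` makes them an error.
#'   Retained rows are identical in both modes for well-formed inputs.
#' @return A [ScreenReport-class] object.
#' @examples
#' scores <- readAffinityScores(system.file("extdata",
#'   "hpepdock_scores.tsv", package = "PepScreen"))
#' ilogp <- readLogPTable(system.file("extdata",
#'   "swissadme_ilogp.tsv", package = "PepScreen"))
#' rep <- runPipeline(c(riceGlutelin(), riceProlamin()), scores,
#'                    logp = ilogp)
#' candidates(rep)
#' @export
runPipeline <- function(proteins, scores,
                        rules = defaultRules(),
                        minLen = 2L, maxLen = 5L,
                        affinityThreshold = -160,
                        thresholds = lipinskiThresholds(),
                        logp = NULL,
                        joinMode = c("lenient", "strict")) {
  joinMode <- match.arg(joinMode)
  stopifnot(is(proteins, "XStringSet"), length(proteins) >= 1L)
  if (is.null(names(proteins)) || anyDuplicated(names(proteins))) {
    stop("'proteins' must have unique names", call. = FALSE)
  }
  stopifnot(is.data.frame(scores), all(c("peptide", "score") %in% names(scores)))

  windows <- lapply(seq_along(proteins), function(i) {
    res <- digestProtein(proteins[i], rules)
    selectByLength(res, minLen = minLen, maxLen = maxLen)
  })
  tb <- do.call(rbind, windows)
  names(tb)[names(tb) == "parent_id"] <- "fraction"
  names(tb)[names(tb) == "sequence"] <- "peptide"
  rownames(tb) <- NULL

  orphan <- setdiff(scores$peptide, tb$peptide)
  if (length(orphan) > 0L) {
    msg <- paste0("score file peptide(s) not released in the ", minLen, "-",
                  maxLen, " window: ", paste(orphan, collapse = ", "))
    if (joinMode == "strict") stop(msg, call. = FALSE) else warning(msg)
  }

  hit <- match(tb$peptide, scores$peptide)
  tb$score <- scores$score[hit]
  tb$unscored <- is.na(hit)
  extra <- setdiff(names(scores), c("peptide", "score"))
  for (col in extra) tb[[col]] <- scores[[col]][hit]
  tb$highAffinity <- !tb$unscored & tb$score <= affinityThreshold

  props <- peptideProperties(tb$peptide, logp = logp)
  tb <- cbind(tb, props[, c("formula", "mw", "hbd", "hba", "logp",
                            "logpSource")])
  tb <- cbind(tb, lipinski(tb$mw, tb$logp, tb$hbd, tb$hba,
                           thresholds = thresholds))

  prov <- list(
    proteins = data.frame(id = names(proteins),
                          length = Biostrings::width(proteins)),
    enzymes = vapply(asRuleList(rules), function(r) r@enzyme, character(1L)),
    lengthWindow = c(minLen, maxLen),
    affinityThreshold = affinityThreshold,
    lipinskiThresholds = thresholds,
    joinMode = joinMode,
    nScores = nrow(scores)
  )
  new("ScreenReport", table = tb, provenance = prov)
}

#' High-affinity candidates of a screening report
#'
#' @param report A [ScreenReport-class].
#' @param absorbableOnly Keep only peptides with a passing Lipinski verdict.
#' @return Report rows flagged high-affinity, most negative score first.
#' @export
candidates <- function(report, absorbableOnly = FALSE) {
  stopifnot(is(report, "ScreenReport"))
  tb <- reportTable(report)
  tb <- tb[tb$highAffinity, , drop = FALSE]
  if (absorbableOnly) tb <- tb[tb$orallyAbsorbable, , drop = FALSE]
  tb[order(tb$score), , drop = FALSE]
}

#' Read an external partition-coefficient table
#'
#' Two tab-separated columns, `peptide` and `logp`: externally computed
#' octanol/water partition coefficients to inject into
#' [peptideProperties()] / [runPipeline()] in place of the shipped additive
#' estimator. The packaged fixture `extdata/swissadme_ilogp.tsv` carries
#' the published iLOGP values of the five candidates.
#'
#' @param path Path to the TSV file.
#' @return A named numeric vector (names = peptide sequences).
#' @export
readLogPTable <- function(path) {
  if (!file.exists(path)) stop("logP file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("peptide", "logp") %in% names(x))) {
    stop("logP file needs 'peptide' and 'logp' columns: ", path,
         call. = FALSE)
  }
  stats::setNames(as.numeric(x$logp), checkResiduesVec(x$peptide))
}

#' Write a screening report to TSV
#'
#' The body is deterministic for a fixed configuration (no timestamps), so
#' re-running an identical pipeline reproduces it byte for byte.
#'
#' @param report A [ScreenReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "ScreenReport"))
  utils::write.table(reportTable(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
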