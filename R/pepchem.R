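# Residue (amino acid minus water) elemental compositions, canonical 20.
RESIDUE_FORMULA <- local({
  m <- matrix(c(
    # C  H  N  O  S
      3, 5, 1, 1, 0,  # A
      3, 5, 1, 1, 1,  # C
      4, 5, 1, 3, 0,  # D
      5, 7, 1, 3, 0,  # E
      9, 9, 1, 1, 0,  # F
      2, 3, 1, 1, 0,  # G
      6, 7, 3, 1, 0,  # H
      6, 11, 1, 1, 0, # I
      6, 12, 2, 1, 0, # K
      6, 11, 1, 1, 0, # L
      5, 9, 1, 1, 1,  # M
      4, 6, 2, 2, 0,  # N
      5, 7, 1, 1, 0,  # P
      5, 8, 2, 2, 0,  # Q
      6, 12, 4, 1, 0, # R
      3, 5, 1, 2, 0,  # S
      4, 7, 1, 2, 0,  # T
      5, 9, 1, 1, 0,  # V
      11, 10, 2, 1, 0,# W
      9, 9, 1, 2, 0   # Y
  ), ncol = 5L, byrow = TRUE,
  dimnames = list(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                  c("C", "H", "N", "O", "S")))
  m
})

# IUPAC standard (average) atomic weights, g/mol.
ATOMIC_MASS <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999,
                 S = 32.06, Cl = 35.45)

# Side-chain hydrogen-bond donor contributions (N/O atoms bearing >= 1 H,
# neutral-form convention).
HBD_SIDECHAIN <- c(S = 1, T = 1, Y = 1, N = 1, Q = 1, K = 1, W = 1, H = 1,
                   R = 3)

# Side-chain hydrogen-bond acceptor contributions (accepting N/O atoms,
# neutral-form convention; amide N of N/Q excluded, pyridine-type N of H
# included).
HBA_SIDECHAIN <- c(N = 1, Q = 1, D = 2, E = 2, S = 1, T = 1, Y = 1, H = 1,
                   R = 1, K = 1)

# Additive per-residue lipophilicity contributions for the shipped
# estimator (Crippen-style fragment logic collapsed to residue level):
# hydrophobic side chains positive, polar/charged negative. The free-termini
# correction LOGP_TERMINI is added once per peptide, so concatenation obeys
# logp(AB) = logp(A) + logp(B) - LOGP_TERMINI.
LOGP_RESIDUE <- c(A = 0.31, C = 0.62, D = -1.28, E = -1.21, F = 1.79,
                  G = 0.00, H = -0.60, I = 1.80, K = -1.10, L = 1.70,
                  M = 1.23, N = -1.03, P = 0.72, Q = -0.96, R = -1.56,
                  S = -0.52, T = -0.21, V = 1.32, W = 1.85, Y = 0.96)
LOGP_TERMINI <- -1.20

peptideChars <- function(sequence) {
  strsplit(checkResidues(sequence), "", fixed = TRUE)[[1L]]
}

#' Elemental formula of a peptide
#'
#' Sums residue compositions and adds one water for the free termini, so
#' the formula is additive over concatenation minus one water per peptide
#' bond formed.
#'
#' @param sequence Residue string.
#' @return Named integer vector with elements C, H, N, O, S.
#' @examples
#' peptideFormula("G")    # free glycine, C2 H5 N O2
#' peptideFormula("QPY")  # C19 H26 N4 O6
#' @export
peptideFormula <- function(sequence) {
  chars <- peptideChars(sequence)
  counts <- colSums(RESIDUE_FORMULA[chars, , drop = FALSE])
  counts["H"] <- counts["H"] + 2L
  counts["O"] <- counts["O"] + 1L
  storage.mode(counts) <- "integer"
  counts
}

#' Format an elemental formula as a Hill-style string
#'
#' @param formula Named integer vector of element counts.
#' @return A string such as `"C19H26N4O6"`, omitting zero counts.
#' @export
formatFormula <- function(formula) {
  formula <- formula[formula > 0]
  paste0(names(formula),
         ifelse(formula > 1, formula, ""), collapse = "")
}

#' Average molecular weight from an elemental formula
#'
#' Dot product of element counts with IUPAC standard (average, not
#' monoisotopic) atomic weights: C 12.011, H 1.008, N 14.007, O 15.999,
#' S 32.06, Cl 35.45.
#'
#' @param formula Named numeric vector of element counts (any subset of the
#'   supported elements).
#' @return Mass in g/mol (full precision; report rounded to 2 decimals).
#' @examples
#' averageMass(c(H = 2, O = 1))  # water, 18.02
#' @export
averageMass <- function(formula) {
  unknown <- setdiff(names(formula), names(ATOMIC_MASS))
  if (length(unknown) > 0L) {
    stop("unsupported element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(formula * ATOMIC_MASS[names(formula)])
}

#' Average molecular weight of a peptide
#'
#' @param sequence Residue string.
#' @return Mass in g/mol.
#' @examples
#' round(peptideMW("QPY"), 2)  # 406.44
#' @export
peptideMW <- function(sequence) {
  averageMass(peptideFormula(sequence))
}

#' Hydrogen-bond donor count of a peptide
#'
#' Counts N/O atoms bearing at least one hydrogen under the neutral
#' (non-zwitterionic) convention: +1 for the N-terminal amine (including
#' proline's secondary amine), +1 per non-proline backbone amide NH, +1 for
#' the C-terminal carboxylic OH, plus side-chain contributions (S/T/Y +1,
#' N/Q +1, K +1, W +1, H +1, R +3; D/E and all others 0).
#'
#' @param sequence Residue string.
#' @return Integer donor-atom count (>= 2 for any peptide).
#' @examples
#' countHBD("QPY")    # 5
#' countHBD("IIQGR")  # 10
#' @export
countHBD <- function(sequence) {
  chars <- peptideChars(sequence)
  backboneNH <- sum(chars[-1L] != "P")
  side <- HBD_SIDECHAIN[chars]
  as.integer(1L + backboneNH + 1L + sum(side, na.rm = TRUE))
}

#' Hydrogen-bond acceptor count of a peptide
#'
#' Counts accepting N/O atoms under the neutral convention: +1 per backbone
#' carbonyl oxygen (n - 1 for an n-mer), +2 for the two C-terminal carboxyl
#' oxygens, +1 for the N-terminal amine nitrogen, plus side-chain
#' contributions (N/Q +1 amide oxygen, D/E +2, S/T/Y +1, H +1 pyridine-type
#' nitrogen, R +1, K +1; others 0).
#'
#' @param sequence Residue string.
#' @return Integer acceptor-atom count (>= 3 for any peptide).
#' @examples
#' countHBA("QPY")    # 7
#' countHBA("IVPQH")  # 9
#' @export
countHBA <- function(sequence) {
  chars <- peptideChars(sequence)
  side <- HBA_SIDECHAIN[chars]
  as.integer((length(chars) - 1L) + 2L + 1L + sum(side, na.rm = TRUE))
}

#' Additive lipophilicity estimate for a peptide
#'
#' A deterministic residue-contribution estimator: hydrophobic side chains
#' contribute positively, polar and charged ones negatively, with a single
#' free-termini correction, so the score is additive over concatenation
#' minus one correction per peptide bond. It ranks peptides by
#' hydrophobicity; it is NOT numerically comparable to GB/SA-based
#' octanol/water models such as iLOGP, and pipeline code accepts externally
#' computed values in its place (see the `logp` argument of
#' [peptideProperties()] and [runPipeline()]).
#'
#' @param sequence Residue string.
#' @return Unitless lipophilicity score.
#' @examples
#' estimateLogP("FFFF") > estimateLogP("DDDD")  # TRUE
#' @export
estimateLogP <- function(sequence) {
  chars <- peptideChars(sequence)
  unname(sum(LOGP_RESIDUE[chars]) + LOGP_TERMINI)
}

#' Lipinski rule-of-five thresholds
#'
#' Defaults: molecular weight <= 500 g/mol, logP <= 5, hydrogen-bond donors
#' <= 5, acceptors <= 10; a molecule fails when it violates
#' `maxViolations` (2) or more criteria. All values are configurable.
#'
#' @param mwMax,logpMax,hbdMax,hbaMax Per-criterion upper bounds.
#' @param maxViolations Violations at or above which the molecule is not
#'   orally absorbable.
#' @return A named list of thresholds.
#' @export
lipinskiThresholds <- function(mwMax = 500, logpMax = 5, hbdMax = 5,
                               hbaMax = 10, maxViolations = 2L) {
  stopifnot(mwMax > 0, logpMax > 0, hbdMax > 0, hbaMax > 0,
            maxViolations >= 1L)
  list(mwMax = mwMax, logpMax = logpMax, hbdMax = hbdMax, hbaMax = hbaMax,
       maxViolations = as.integer(maxViolations))
}

#' Lipinski drug-likeness verdict
#'
#' Vectorised over property values: flags each criterion, counts
#' violations, and calls a molecule orally absorbable when the violation
#' count is below `thresholds$maxViolations`.
#'
#' @param mw,logp,hbd,hba Property vectors (recycled to common length).
#' @param thresholds From [lipinskiThresholds()].
#' @return A `data.frame` with logical columns `mwOk`, `logpOk`, `hbdOk`,
#'   `hbaOk`, integer `violations` and logical `orallyAbsorbable`.
#' @examples
#' lipinski(mw = 406.43, logp = 1.34, hbd = 5, hba = 7)  # 0 violations
#' @export
lipinski <- function(mw, logp, hbd, hba, thresholds = lipinskiThresholds()) {
  out <- data.frame(
    mwOk = mw <= thresholds$mwMax,
    logpOk = logp <= thresholds$logpMax,
    hbdOk = hbd <= thresholds$hbdMax,
    hbaOk = hba <= thresholds$hbaMax
  )
  out$violations <- as.integer(rowSums(!out[, c("mwOk", "logpOk", "hbdOk",
                                                "hbaOk")]))
  out$orallyAbsorbable <- out$violations < thresholds$maxViolations
  out
}

#' Physicochemical property table for peptides
#'
#' Computes, per peptide, the elemental formula, average molecular weight
#' (2 decimals), hydrogen-bond donor/acceptor counts and a lipophilicity
#' value. Lipophilicity defaults to the shipped additive estimator
#' ([estimateLogP()]); externally computed partition coefficients (e.g.
#' from a GB/SA model) can be injected through `logp` and take precedence,
#' with `logpSource` recording which route supplied each value.
#'
#' @param peptides Character vector of residue strings.
#' @param logp Optional named numeric vector of external logP values,
#'   names matching peptide sequences.
#' @return A `data.frame` with columns `peptide`, `formula`, `mw`, `hbd`,
#'   `hba`, `logp`, `logpSource`.
#' @examples
#' peptideProperties(c("QPY", "PIVF"), logp = c(QPY = 1.34))
#' @export
peptideProperties <- function(peptides, logp = NULL) {
  peptides <- checkResiduesVec(peptides)
  est <- vapply(peptides, estimateLogP, numeric(1L), USE.NAMES = FALSE)
  src <- rep("estimated", length(peptides))
  if (!is.null(logp)) {
    if (is.null(names(logp))) {
      stop("'logp' must be a named vector (names = peptide sequences)",
           call. = FALSE)
    }
    hit <- match(peptides, names(logp))
    est[!is.na(hit)] <- logp[hit[!is.na(hit)]]
    src[!is.na(hit)] <- "external"
  }
  data.frame(
    peptide = peptides,
    formula = vapply(peptides, function(p) formatFormula(peptideFormula(p)),
                     character(1L), USE.NAMES = FALSE),
    mw = round2(vapply(peptides, peptideMW, numeric(1L), USE.NAMES = FALSE)),
    hbd = vapply(peptides, countHBD, integer(1L), USE.NAMES = FALSE),
    hba = vapply(peptides, countHBA, integer(1L), USE.NAMES = FALSE),
    logp = est,
    logpSource = src,
    stringsAsFactors = FALSE
  )
}

#' The GW9662 control molecule
#'
#' GW9662 (2-chloro-5-nitro-N-phenylbenzamide) is the irreversible PPARgamma
#' antagonist used as the positive control of the screening workflow. It is
#' handled at the formula level, not as a peptide: its molecular weight is
#' computed from the elemental formula C13H9ClN2O3, while its donor/acceptor
#' counts and partition coefficient are fixed reference values.
#'
#' @return A list with `formula` (named counts), `mw` (g/mol, 2 decimals),
#'   `logp`, `hbd`, `hba`.
#' @examples
#' gw9662()$mw  # 276.68
#' @export
gw9662 <- function() {
  formula <- c(C = 13, H = 9, Cl = 1, N = 2, O = 3)
  list(formula = formula,
       mw = round2(averageMass(formula)),
       logp = 1.81, hbd = 1L, hba = 3L)
}
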