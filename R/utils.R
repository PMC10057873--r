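# Internal helpers shared across modules.

#' The 20 canonical one-letter amino-acid codes
#' @keywords internal
#' @noRd
AA_CANONICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Round half away from zero (so 0.005 -> 0.01), which base round() does not
# guarantee under IEC 60559 banker's rounding.
round2 <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate a residue string; returns the uppercased sequence or stops with a
# message naming the first offending position.
checkResidues <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    stop(what, " must be a single non-empty string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_CANONICAL)
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue '%s' in %s at position %d",
                 chars[bad[1L]], what, bad[1L]), call. = FALSE)
  }
  sequence
}

# Vectorised variant for sets of peptides.
checkResiduesVec <- function(x, what = "peptide") {
  vapply(x, checkResidues, character(1L), what = what, USE.NAMES = FALSE)
}
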