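# Independent brute-force digestion oracle: walk the sequence character by
# character and cut after every residue of `cutset` (except at the C
# terminus), honouring an optional blocked-follower set.
bruteDigest <- function(sequence, cutset, notBefore = character()) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out <- character()
  cur <- ""
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    if (i < length(chars) && chars[i] %in% cutset &&
        !(chars[i + 1L] %in% notBefore)) {
      out <- c(out, cur)
      cur <- ""
    }
  }
  c(out, cur)
}

DEFAULT_CUTSET <- c("F", "L", "W", "Y", "M", "K", "R", "N", "H")

randomSeq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               n, replace = TRUE), collapse = "")
}

prolaminFragments <- function() {
  PepScreen:::readFragmentList(system.file("extdata",
    "prolamin_fragments.txt", package = "PepScreen", mustWork = TRUE))
}

glutelinFragments <- function() {
  PepScreen:::readFragmentList(system.file("extdata",
    "glutelin_fragments.txt", package = "PepScreen", mustWork = TRUE))
}

fixturePipeline <- function(...) {
  scores <- readAffinityScores(system.file("extdata", "hpepdock_scores.tsv",
                                           package = "PepScreen"))
  ilogp <- readLogPTable(system.file("extdata", "swissadme_ilogp.tsv",
                                     package = "PepScreen"))
  runPipeline(c(riceGlutelin(), riceProlamin()), scores, logp = ilogp, ...)
}
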