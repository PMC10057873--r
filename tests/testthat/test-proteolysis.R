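test_that("cut sites follow P1 specificity with the union of all rules", {
  rules <- defaultRules()
  expect_identical(findCutSites("MKIIF", rules), c(1L, 2L))
  expect_identical(findCutSites("AAAA", rules), integer(0))
  expect_identical(findCutSites("PSICGIYPSYN", rules), c(7L, 10L))
  expect_error(findCutSites("", rules), "non-empty")
})

test_that("P1' exception sets block cleavage before the listed residues", {
  rule <- cleavageRule("toy chymotrypsin", cutAfter = "Y", notBefore = "P")
  # AYPAYA: Y at 2 is followed by P (blocked), Y at 5 is not
  expect_identical(findCutSites("AYPAYA", rule), 5L)
  expect_identical(bruteDigest("AYPAYA", "Y", "P"), c("AYPAY", "A"))
  expect_identical(fragments(digestProtein("AYPAYA", rule))$sequence,
                   c("AYPAY", "A"))
})

test_that("digestion yields maximal fragments tiling the parent", {
  res <- digestProtein("MKIIF", defaultRules(), id = "toy")
  expect_identical(fragments(res)$sequence, c("M", "K", "IIF"))
  expect_identical(fragments(res)$start, c(0L, 1L, 2L))
  expect_identical(fragments(res)$end, c(1L, 2L, 5L))

  # no cut after the terminal residue, even a cleavable one
  single <- digestProtein("M", defaultRules())
  expect_identical(fragments(single)$sequence, "M")
  expect_identical(cutSites(single), integer(0))
})

test_that("engine output equals the brute-force oracle on short sequences", {
  rules <- defaultRules()
  for (seed in 1:60) {
    n <- 1L + (seed %% 50L)
    s <- randomSeq(n, seed = 1000L + seed)
    expect_identical(fragments(digestProtein(s, rules))$sequence,
                     bruteDigest(s, DEFAULT_CUTSET),
                     info = paste("seed", seed))
  }
})

test_that("fragments conserve the input, are pure, and re-digest to themselves", {
  rules <- defaultRules()
  for (seed in 1:10) {
    s <- randomSeq(500, seed = 2000L + seed)
    fr <- fragments(digestProtein(s, rules))
    # conservation / tiling
    expect_identical(paste(fr$sequence, collapse = ""), s)
    expect_identical(fr$length, nchar(fr$sequence))
    # fragment-internal purity: no cut-after residue off the C terminus
    internal <- substr(fr$sequence, 1L, fr$length - 1L)
    expect_false(any(strsplit(paste(internal, collapse = ""), "")[[1]] %in%
                       DEFAULT_CUTSET))
    # idempotence: digesting a released fragment returns it unchanged
    for (f in fr$sequence[fr$length > 1L][1:3]) {
      expect_identical(fragments(digestProtein(f, rules))$sequence, f)
    }
  }
})

test_that("sequential multi-enzyme digestion matches simultaneous digestion", {
  rules <- defaultRules()
  for (seed in 1:5) {
    s <- randomSeq(200, seed = 3000L + seed)
    expect_identical(
      fragments(digestProtein(s, rules, mode = "sequential"))$sequence,
      fragments(digestProtein(s, rules, mode = "simultaneous"))$sequence)
  }
})

test_that("length classes reproduce the prolamin distribution", {
  res <- digestProtein(riceProlamin(), defaultRules())
  ld <- classifyLengths(res)
  expect_identical(sum(ld$n), 42L)
  expect_identical(ld$n, c(18L, 14L, 10L))
  expect_identical(ld$pct, c(42.86, 33.33, 23.81))

  one <- classifyLengths(digestProtein("AAAA", defaultRules()))
  expect_identical(one$n, c(0L, 1L, 0L))
  expect_identical(one$pct, c(0, 100, 0))
})

test_that("length classes match an independent histogram on random digests", {
  rules <- defaultRules()
  for (seed in 1:5) {
    s <- randomSeq(300, seed = 4000L + seed)
    len <- nchar(bruteDigest(s, DEFAULT_CUTSET))
    ld <- classifyLengths(digestProtein(s, rules))
    expect_identical(ld$n, c(sum(len == 1L), sum(len >= 2L & len <= 5L),
                             sum(len > 5L)))
    expect_equal(sum(ld$pct), 100, tolerance = 0.02)
  }
})

test_that("length selection retains positional duplicates in order", {
  res <- digestProtein(riceProlamin(), defaultRules())
  win <- selectByLength(res)
  expect_identical(nrow(win), 14L)
  expect_true(all(c("QSPVF", "QY") %in% win$sequence))
  expect_identical(sum(win$sequence == "QL"), 3L)

  all <- selectByLength(res, minLen = 1L, maxLen = Biostrings::width(riceProlamin()))
  expect_identical(all$sequence, fragments(res)$sequence)

  only5 <- selectByLength(res, minLen = 5L, maxLen = 5L)
  expect_identical(only5$sequence,
                   fragments(res)$sequence[fragments(res)$length == 5L])
  expect_error(selectByLength(res, minLen = 3L, maxLen = 2L), "minLen")
})

test_that("rule files load with validation and reject silent no-ops", {
  rules <- defaultRules()
  expect_length(rules, 3L)
  expect_setequal(unlist(lapply(rules, function(r) r@cutAfter)),
                  DEFAULT_CUTSET)
  expect_true(all(lengths(lapply(rules, function(r) r@notBefore)) == 0L))

  tf <- tempfile(fileext = ".yaml")
  writeLines(c("mystery:", "  ec: 0.0.0.0"), tf)
  expect_error(readRules(tf), "no cut_after")
})
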