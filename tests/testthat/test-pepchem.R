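test_that("elemental formulas sum residue compositions plus one water", {
  expect_identical(peptideFormula("G"), c(C = 2L, H = 5L, N = 1L, O = 2L,
                                          S = 0L))
  expect_identical(peptideFormula("QPY"), c(C = 19L, H = 26L, N = 4L,
                                            O = 6L, S = 0L))
  expect_identical(formatFormula(peptideFormula("QPY")), "C19H26N4O6")
  # additivity: formula(AB) = formula(A) + formula(B) - H2O
  water <- c(C = 0L, H = 2L, N = 0L, O = 1L, S = 0L)
  for (seed in 1:10) {
    a <- randomSeq(5, seed = 100L + seed)
    b <- randomSeq(7, seed = 200L + seed)
    expect_identical(peptideFormula(paste0(a, b)),
                     peptideFormula(a) + peptideFormula(b) - water)
  }
  expect_error(peptideFormula("MKX"), "illegal")
})

test_that("average molecular weights match the published candidate table", {
  expect_equal(averageMass(c(H = 2, O = 1)), 18.02, tolerance = 0.005)
  published <- c(QPY = 406.43, IVPQH = 592.69, PIVF = 474.59,
                 IIQGR = 585.70, QSPVF = 576.64)
  for (pep in names(published)) {
    expect_equal(peptideMW(pep), published[[pep]], tolerance = 0.05,
                 info = pep)
  }
  # MW additivity against the residue-sum route
  masses <- vapply(rownames(PepScreen:::RESIDUE_FORMULA),
                   function(a) averageMass(PepScreen:::RESIDUE_FORMULA[a, ]),
                   numeric(1))
  for (pep in names(published)) {
    chars <- strsplit(pep, "")[[1]]
    expect_equal(peptideMW(pep),
                 sum(masses[chars]) + averageMass(c(H = 2, O = 1)),
                 tolerance = 1e-6)
  }
  expect_error(averageMass(c(Zz = 1)), "unsupported")
})

test_that("GW9662 control mass comes from its elemental formula", {
  ctrl <- gw9662()
  expect_equal(ctrl$mw, 276.68, tolerance = 0.05)
  expect_identical(ctrl$hbd, 1L)
  expect_identical(ctrl$hba, 3L)
})

test_that("donor counts follow the neutral-form contribution table", {
  expect_identical(countHBD("QPY"), 5L)
  expect_identical(countHBD("IIQGR"), 10L)
  expect_identical(countHBD("IVPQH"), 7L)
  expect_identical(countHBD("QSPVF"), 7L)
  # poly-glycine closed form: n backbone/terminal donors + carboxyl OH
  for (n in c(1, 2, 5, 8)) {
    expect_identical(countHBD(strrep("G", n)), as.integer(n + 1L))
  }
  # proline contributes no backbone NH but keeps its N-terminal amine
  expect_identical(countHBD("P"), 2L)
  expect_identical(countHBD("GP"), 2L)
})

test_that("acceptor counts follow the neutral-form contribution table", {
  expect_identical(countHBA("QPY"), 7L)
  expect_identical(countHBA("IVPQH"), 9L)
  expect_identical(countHBA("IIQGR"), 9L)
  expect_identical(countHBA("QSPVF"), 9L)
  for (n in c(1, 2, 5, 8)) {
    expect_identical(countHBA(strrep("G", n)), as.integer(n + 2L))
  }
})

test_that("donor and acceptor counts never decrease when appending", {
  for (seed in 1:20) {
    s <- randomSeq(6, seed = 300L + seed)
    set.seed(400L + seed)
    extra <- sample(c("A", "P", "R", "D", "G"), 1)
    expect_gte(countHBD(paste0(s, extra)), countHBD(s))
    expect_gte(countHBA(paste0(s, extra)), countHBA(s))
  }
})

test_that("sequence counts agree with a structure-based toolkit", {
  # Frozen reference values computed once with rdkit 2024.09
  # (Chem.MolFromSequence + Descriptors.MolWt / Lipinski.NumHDonors /
  # Lipinski.NumHAcceptors). MW and donor counts agree exactly; rdkit's
  # acceptor SMARTS excludes the N-terminal amine nitrogen, which the
  # convention used here counts, hence the constant offset of one.
  rdkit <- data.frame(
    peptide = c("QPY", "IVPQH", "PIVF", "IIQGR", "QSPVF"),
    mw = c(406.44, 592.70, 474.60, 585.71, 576.65),
    hbd = c(5L, 7L, 5L, 10L, 7L),
    hba = c(6L, 8L, 5L, 8L, 8L))
  for (i in seq_len(nrow(rdkit))) {
    p <- rdkit$peptide[i]
    expect_equal(round(peptideMW(p), 2), rdkit$mw[i], info = p)
    expect_identical(countHBD(p), rdkit$hbd[i], info = p)
    expect_identical(countHBA(p), rdkit$hba[i] + 1L, info = p)
  }
})

test_that("the lipophilicity estimator is additive and ranks hydrophobicity", {
  expect_gt(estimateLogP("FFFF"), estimateLogP("DDDD"))
  for (seed in 1:10) {
    a <- randomSeq(4, seed = 500L + seed)
    b <- randomSeq(6, seed = 600L + seed)
    expect_equal(estimateLogP(paste0(a, b)),
                 estimateLogP(a) + estimateLogP(b) -
                   PepScreen:::LOGP_TERMINI,
                 tolerance = 1e-9)
  }
})

test_that("external partition coefficients override the estimator", {
  props <- peptideProperties(c("QPY", "AAA"), logp = c(QPY = 1.34))
  expect_identical(props$logp[props$peptide == "QPY"], 1.34)
  expect_identical(props$logpSource, c("external", "estimated"))
  expect_error(peptideProperties("QPY", logp = 1.34), "named")
})

test_that("Lipinski verdicts count violations against the thresholds", {
  # all published values inside the thresholds: no violations
  qpy <- lipinski(mw = 406.43, logp = 1.34, hbd = 5, hba = 7)
  expect_identical(qpy$violations, 0L)
  expect_true(qpy$orallyAbsorbable)
  # published IVPQH row violates MW and donors: not absorbable
  ivpqh <- lipinski(mw = 592.69, logp = 2.25, hbd = 7, hba = 9)
  expect_gte(ivpqh$violations, 2L)
  expect_false(ivpqh$orallyAbsorbable)
  # one violation is still absorbable under the two-violation rule
  one <- lipinski(mw = 600, logp = 1, hbd = 2, hba = 4)
  expect_identical(one$violations, 1L)
  expect_true(one$orallyAbsorbable)
  # configurable acceptor bound (e.g. the looser printed 10.6)
  loose <- lipinski(mw = 400, logp = 1, hbd = 2, hba = 10.5,
                    thresholds = lipinskiThresholds(hbaMax = 10.6))
  expect_identical(loose$violations, 0L)
})

test_that("raising any property never lowers the violation count", {
  set.seed(42)
  for (i in 1:40) {
    mw <- runif(1, 100, 900); lp <- runif(1, -2, 8)
    hbd <- sample(0:12, 1); hba <- sample(0:15, 1)
    base <- lipinski(mw, lp, hbd, hba)$violations
    expect_gte(lipinski(mw + runif(1, 0, 400), lp, hbd, hba)$violations, base)
    expect_gte(lipinski(mw, lp + runif(1, 0, 4), hbd, hba)$violations, base)
    expect_gte(lipinski(mw, lp, hbd + sample(0:4, 1), hba)$violations, base)
    expect_gte(lipinski(mw, lp, hbd, hba + sample(0:4, 1))$violations, base)
  }
})
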