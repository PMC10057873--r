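---
title: "Methods: in silico digestion and peptide drug-likeness screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico digestion and peptide drug-likeness screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PepScreen)
```

PepScreen models the discovery funnel for food-derived bioactive peptides:
simulated gastrointestinal proteolysis, a bioaccessibility length filter,
triage of externally computed docking scores, sequence-derived
physicochemical properties with a Lipinski rule-of-five verdict, and
hydrogen-bond contact analysis of docked poses against a receptor hotspot
set. This vignette explains the models behind each stage, the parameters
that matter, the numerical conventions, and what the synthetic-data tests
do and do not establish about real data.

## The cleavage model

A protease is abstracted as a `CleavageRule`: a P1 specificity set
(`cutAfter` — the rule cuts C-terminal to these residues) and an optional
P1′ exception set (`notBefore` — cleavage is blocked when the next residue
is listed). This is the classical keyword model used by digestion
predictors; it deliberately ignores everything kinetic: no missed
cleavages, no partial digestion, no pH switching, no steric accessibility.
Every scissile bond that matches a rule is cut, so the digest is the
unique fixed point of the rule set, and digesting any released fragment
again returns it unchanged (an invariant the test suite checks).

Multi-enzyme digestion defaults to *simultaneous* semantics: the cut-site
sets of all rules are unioned before splitting. A *sequential* mode
(each enzyme re-digests the previous round's fragments) is available; for
rules without P1′ exceptions the two agree, because a position's cleavage
context is unchanged inside a fragment, and the suite asserts this
equivalence on random sequences.

The default rule set assigns pepsin (pH 1.3) {F, L}, trypsin {K, R} and
chymotrypsin {W, Y, F, M, L, N, H}, all with empty exception sets. The
union {F, L, W, Y, M, K, R, N, H} was validated against the packaged
fragment inventories of the two rice storage proteins: digesting either
reconstruction regenerates its fragment list exactly, including cleavage
of a Y|P bond, which rules out a "not before proline" exception for this
rule set. The per-enzyme attribution of the M, N and H cuts is
convention rather than data — only the union is validated — which is why
rules live in an editable YAML file (`extdata/enzymes.yaml`) rather than
in code, and why an enzyme entry without a specificity is a configuration
error rather than a silent no-op.

Fragments are counted positionally: a pentapeptide released twice counts
twice. The glutelin reconstruction (499 aa) yields 185 fragments, the
prolamin one (149 aa) 42; length-class percentages are reported to two
decimals with half-up rounding so that printed class tables sum to 100
within rounding.

Coordinates are 0-based and half-open throughout (`start`/`end` of a
fragment index into the parent as `sequence[start:end]`), which makes the
tiling invariant — consecutive fragments share boundaries, the first
starts at 0, the last ends at the parent length — an exact arithmetic
statement that the `DigestResult` validity method enforces on every
object. Only the 20 canonical residues are accepted anywhere (no B/Z/X/U):
the property tables and cleavage rules are defined only for them.

## The bioaccessibility window and affinity triage

Peptides of 2–5 residues are assumed to cross the epithelial barrier
passively and are the default selection (`selectByLength(minLen = 2,
maxLen = 5)`). Docking affinity scores are *inputs*: the package never
computes a docking score or binding energy. Scores join the digest table
by peptide sequence; window peptides without a score are flagged
`unscored` and kept, so the report remains a complete audit of the
window. The high-affinity flag is `score <= -160` on the score scale
(more negative = stronger predicted binding); the threshold is an
argument, and the packaged fixture of five candidate scores all pass it.
A `strict` join mode turns score-file peptides that the digest never
released into an error instead of a warning; retained rows are identical
in both modes for well-formed inputs.

## Properties from sequence

Peptide properties are computed on the neutral (non-zwitterionic)
molecule, built conceptually from residue contributions plus the free
termini:

* **Elemental formula** — the sum of residue compositions plus one water;
  additivity (`formula(AB) = formula(A) + formula(B) − H2O`) is tested on
  random pairs.
* **Average molecular weight** — IUPAC standard (average, not
  monoisotopic) atomic weights (C 12.011, H 1.008, N 14.007, O 15.999,
  S 32.06, Cl 35.45), reported to two decimals. The control molecule
  GW9662 is handled at formula level (C13H9ClN2O3 → 276.68 g/mol); its
  donor/acceptor counts and partition coefficient are fixed reference
  values, since it is not a peptide.
* **Hydrogen-bond donors** — N/O atoms bearing at least one hydrogen: the
  N-terminal amine (including proline's secondary amine), each
  non-proline backbone amide NH, the C-terminal carboxylic OH, and side
  chains (S/T/Y/N/Q/K/W/H +1, R +3). Poly-glycine of length n therefore
  has n + 1 donors, a closed form the tests use.
* **Hydrogen-bond acceptors** — accepting N/O atoms: n − 1 backbone
  carbonyls, two carboxyl oxygens, the N-terminal amine nitrogen, and
  side chains (N/Q amide oxygen +1, D/E +2, S/T/Y +1, H +1, R +1, K +1);
  n + 2 for poly-glycine. Counting the N-terminal amine as an acceptor
  follows the convention of the drug-likeness calculators this mirrors;
  an independent cross-check against a structure-based toolkit (frozen
  into the tests) agrees exactly on masses and donors and differs by
  exactly that one nitrogen on acceptors.
* **Lipophilicity** — a deliberately simple additive residue-contribution
  score with a single free-termini correction. It preserves hydrophobicity
  ranking and additivity, but it is *not* numerically comparable to
  GB/SA-based octanol/water models, which cannot be rebuilt from their
  published descriptions. The pipeline therefore treats lipophilicity as
  pluggable: `readLogPTable()` injects externally computed values, which
  take precedence, and the report records per peptide whether its value
  was `estimated` or `external`. The packaged fixture injects the five
  candidates' externally computed coefficients.

The Lipinski thresholds default to MW ≤ 500 g/mol, logP ≤ 5, HBD ≤ 5,
HBA ≤ 10, failure at ≥ 2 violations. The acceptor bound is sometimes
printed as 10.6 in secondary sources — almost certainly a typographical
artifact of 10 — so 10 is the default and the threshold is configurable
if the looser bound is wanted. Violation counting is monotone: raising
any property value never lowers the count (tested by perturbation).

One known irreproducibility: the published donor count of 7 for PIVF
cannot be derived from the sequence — any standard count on P-I-V-F gives
5 (proline N-terminus, three backbone NHs, carboxyl OH), and the
structure-based cross-check agrees. The package reports 5; PIVF's verdict
(absorbable) is the same either way.

## Contact analysis of docked poses

`parsePdb()` reads fixed-column ATOM/HETATM records (first model only,
with a warning for multi-model files; insertion codes preserved).
Hydrogen-bond detection is geometric: a donor N/O of one molecule and an
acceptor N/O of the other within `dMax` (default 3.5 Å), and, when the
donor carries explicit hydrogens, a D–H···A angle of at least `angleMin`
(default 120°). These are standard survey values; nothing in the workflow
being reproduced fixes them, so both are arguments. Donor/acceptor typing
uses residue template tables for the 20 standard residues and an element
heuristic for ligand atoms: N/O are acceptors, and donors when an
explicit hydrogen is attached — or, for molecules deposited without any
hydrogens (where protonation is unknowable), donor candidates under the
distance-only criterion. Because hydroxyl-type atoms are both donors and
acceptors, the same physical contact can be found in both scan
directions; bonds are deduplicated as unordered atom pairs, preferring
the direction with a defined angle, which also makes detection symmetric
under swapping ligand and receptor.

`contactResidues()` reduces a bond list to the unique receptor residues
contacted and intersects them with a hotspot set — by default the
antiadipogenic pocket of the PPARγ ligand-binding domain (Phe264, His266,
Ile281, Cys285, Arg288, Ser289, Met348, His449). Contacts outside the set
(e.g. Tyr473, the activation-helix tyrosine that antagonist poses can
still touch) are flagged, never dropped, so reports expose rather than
hide disagreements between a pose and the expected pocket.

The docking search box is kept as a first-class object (`GridBox`):
centre in Å, integer grid points per axis, spacing in Å. The default —
centre (7.745, 50.606, 57.552), 70 × 40 × 40 points at 0.375 Å — covers
the antiadipogenic region; `makeGridboxConfig()` emits either the
physical-size (points × spacing, e.g. 26.25 × 15 × 15 Å) or raw
grid-point convention, because docking tools disagree about which one
`size_*` means, and the emitted text round-trips through
`parseGridboxConfig()`. Docking result logs are parsed
(`parseDockingLog()`), never produced.

## What the synthetic data emulate

`randomProtein()` draws i.i.d. residues from a composition specification
(e.g. `compositionSpec(c(Q = 0.18))` for a glutamine-rich storage-protein
profile). Under the i.i.d. model with combined cut-after frequency p, a
length-N sequence has N − 1 internal boundaries each cut independently
with probability p, so the fragment count is 1 + Binomial(N − 1, p); the
suite checks the observed count at N = 10⁵ and p = 9/20 against
1 + (N − 1)p within three standard errors. Real storage proteins are not
i.i.d. — they carry repeats and strongly clustered glutamines — so these
tests establish the correctness of the cleavage arithmetic, not the
realism of fragment-length distributions for any particular protein; the
packaged reconstructions cover that case exactly.

`makePlantedGeometry()` builds ligand/receptor coordinate sets with a
known number of hydrogen bonds at exact target geometry: each unit is a
receptor backbone amide (N with explicit H) donating to a ligand oxygen
placed by the law of cosines so the donor–acceptor distance and
D–H···A angle hit their targets to machine precision. Units are stacked
more than twice the detection cutoff apart and decoy heteroatoms are
placed far from everything, so recovery tests are exact (k planted ⇒ k
reported) rather than statistical; a seed-derived rigid rotation and
translation of the whole scene makes every run also a rigid-motion
invariance check. These scenes are geometric fixtures, not physical
poses: they say nothing about docking accuracy, only about the
correctness of the detection geometry.

## Numerical conventions and degenerate inputs

* Half-up rounding to 2 decimals for all reported percentages and masses
  (base `round()` is half-even, which breaks printed-table agreement).
* Empty sequences, empty fragment lists, empty FASTA files, zero
  denominators in the digestibility ratios (IVPD = 100·FP/IP,
  IVPB = 100·Ptd/Pti) and rule entries without specificity are errors;
  digestibility inputs where the digested exceeds the initial value warn
  but return the ratio.
* An empty hydrogen-bond result is valid output, not an error; a digest
  of a single residue yields one fragment and no cut sites (cuts after
  the terminal residue never occur).
* Equal-distance hydrogen bonds sort in the deduplicated detection
  order; ties are not further broken, so consumers needing a canonical
  order should sort on (distance, residue label).

## Problem sizes used by the test suite

The suite validates the digestion engine against a brute-force oracle on
random sequences up to 50 residues, conservation/idempotence at 500–1000
residues, the statistical fragment-count law at 10⁵ residues, and
composition convergence at 10⁵ residues; planted-geometry tests use up to
six bonds. These sizes make the whole suite run in seconds while keeping
every statistical check at small relative Monte-Carlo error.

## Known limitations

* No kinetic or partial-digestion modelling; every matching bond is cut.
* Docking scores, binding energies and poses are consumed, never
  computed; the package contains no search or scoring function.
* The lipophilicity estimator is a ranking tool, not a calibrated logP.
* Donor/acceptor counting is table-driven on the neutral species; no
  pKa/charge-state modelling, no 3D structure generation.
* π-stacking and hydrophobic contacts are out of scope for pose
  analysis; only hydrogen bonds are reported.
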