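toyAtoms <- function() {
  data.frame(
    type = "ATOM", serial = 1:3, atom = c("N", "CA", "O"),
    resid = "GLY", chain = "A", resno = 1L, insert = "",
    x = c(1.234, 2.345, 3.456), y = c(-0.5, 0.25, 1.125),
    z = c(10.001, 10.002, 10.003), element = c("N", "C", "O"),
    stringsAsFactors = FALSE)
}

test_that("PDB files round-trip through write and parse at 3 decimals", {
  tf <- tempfile(fileext = ".pdb")
  writePdb(toyAtoms(), tf, remarks = "toy fixture")
  at <- parsePdb(tf)
  expect_identical(nrow(at), 3L)
  expect_identical(at$atom, c("N", "CA", "O"))
  expect_equal(at$x, toyAtoms()$x, tolerance = 1e-9)
  expect_equal(at$y, toyAtoms()$y, tolerance = 1e-9)
  expect_identical(at$element, c("N", "C", "O"))
  expect_error(parsePdb(tempfile()), "not found")
})

test_that("only the first model of a multi-model PDB is used, with a warning", {
  tf <- tempfile(fileext = ".pdb")
  one <- toyAtoms()
  two <- toyAtoms(); two$x <- two$x + 100
  writeLines(c("MODEL     1",
               readLines(writePdb(one, tempfile()))[1:3],
               "ENDMDL",
               "MODEL     2",
               readLines(writePdb(two, tempfile()))[1:3],
               "ENDMDL", "END"), tf)
  expect_warning(at <- parsePdb(tf), "2 models")
  expect_identical(nrow(at), 3L)
  expect_equal(at$x, one$x, tolerance = 1e-9)
})

test_that("grid-box configs expose both point and Angstrom conventions", {
  box <- defaultGridBox()
  txt <- makeGridboxConfig(box)
  expect_true(any(grepl("^size_x = 26.25$", txt)))
  expect_true(any(grepl("^size_y = 15$", txt)))
  expect_true(any(grepl("^size_z = 15$", txt)))
  expect_true(any(grepl("^center_x = 7.745$", txt)))

  simple <- gridBox(center = c(0, 0, 0), size = c(10, 10, 10), spacing = 1)
  expect_true(any(grepl("^size_x = 10$", makeGridboxConfig(simple))))

  for (units in c("angstrom", "points")) {
    back <- parseGridboxConfig(makeGridboxConfig(box, units = units))
    expect_equal(back@sizeX, box@sizeX, tolerance = 1e-9)
    expect_equal(back@centerZ, box@centerZ, tolerance = 1e-9)
    expect_equal(back@spacing, box@spacing, tolerance = 1e-9)
  }
  expect_error(gridBox(c(0, 0, 0), c(-1, 1, 1)), "positive")
})

test_that("docking logs parse into rank-ordered affinities", {
  log <- parseDockingLog(system.file("extdata", "synthetic_vina_log.txt",
                                     package = "PepScreen"))
  expect_identical(nrow(log), 9L)
  expect_identical(log$rank[1], 1)
  expect_identical(log$affinity[1], -7.98)
  expect_true(all(diff(log$rank) == 1))
  expect_error(parseDockingLog(character()), "no docking result")
  expect_error(parseDockingLog("nothing tabular here"), "no docking result")
})

test_that("planted hydrogen bonds are recovered exactly", {
  for (n in c(0L, 1L, 3L, 6L)) {
    geom <- makePlantedGeometry(n, seed = 100L + n)
    bonds <- detectHbonds(geom$ligand, geom$receptor)
    expect_identical(nrow(bonds), n, info = paste("n =", n))
    if (n > 0L) {
      expect_equal(bonds$distance, rep(2.9, n), tolerance = 1e-6)
      expect_equal(bonds$angle, rep(160, n), tolerance = 1e-6)
    }
  }
})

test_that("bonds beyond the distance cutoff are not reported", {
  geom <- makePlantedGeometry(2, seed = 9, distance = 5.0)
  expect_identical(nrow(detectHbonds(geom$ligand, geom$receptor)), 0L)
  # but a looser cutoff finds them again
  expect_identical(nrow(detectHbonds(geom$ligand, geom$receptor,
                                     dMax = 5.5)), 2L)
})

test_that("poses below the angle cutoff are rejected when hydrogens exist", {
  geom <- makePlantedGeometry(2, seed = 9, angle = 100)
  expect_identical(nrow(detectHbonds(geom$ligand, geom$receptor)), 0L)
  expect_identical(nrow(detectHbonds(geom$ligand, geom$receptor,
                                     angleMin = 90)), 2L)
})

test_that("hydrogen-bond detection is invariant under rigid motion", {
  geom <- makePlantedGeometry(3, seed = 21)
  ref <- detectHbonds(geom$ligand, geom$receptor)
  R <- rotationMatrix(c(1, 2, 3), 1.1)
  shift <- c(-4, 8, 15)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + shift[1]; df$y <- xyz[, 2] + shift[2]
    df$z <- xyz[, 3] + shift[3]
    df
  }
  moved <- detectHbonds(move(geom$ligand), move(geom$receptor))
  expect_identical(nrow(moved), nrow(ref))
  # planted distances are all equal, so sorting may permute ties
  expect_equal(sort(moved$distance), sort(ref$distance), tolerance = 1e-6)
  expect_equal(sort(moved$angle), sort(ref$angle), tolerance = 1e-6)
  expect_identical(sort(moved$receptorRes), sort(ref$receptorRes))
})

test_that("swapping ligand and receptor yields the same unordered pairs", {
  geom <- makePlantedGeometry(3, seed = 33)
  fwd <- detectHbonds(geom$ligand, geom$receptor)
  rev <- detectHbonds(geom$receptor, geom$ligand)
  key <- function(b) sort(paste(pmin(b$donorRes, b$acceptorRes),
                                pmax(b$donorRes, b$acceptorRes)))
  expect_identical(key(fwd), key(rev))
  expect_equal(sort(fwd$distance), sort(rev$distance), tolerance = 1e-9)
})

test_that("contact reports intersect with the hotspot set without dropping", {
  geom <- makePlantedGeometry(2, seed = 5,
                              hotspotResidues = c("CYS285", "SER289"))
  bonds <- detectHbonds(geom$ligand, geom$receptor)
  rep <- contactResidues(bonds)
  expect_setequal(contacted(rep), c("CYS285", "SER289"))
  expect_setequal(hotspotContacts(rep), c("CYS285", "SER289"))
  expect_length(otherContacts(rep), 0L)

  # a pose bonded only to TYR473: outside the antiadipogenic set, flagged
  tyr <- makePlantedGeometry(1, seed = 6, hotspotResidues = "TYR473")
  repTyr <- contactResidues(detectHbonds(tyr$ligand, tyr$receptor))
  expect_length(hotspotContacts(repTyr), 0L)
  expect_identical(otherContacts(repTyr), "TYR473")

  none <- contactResidues(detectHbonds(geom$ligand, geom$receptor,
                                       dMax = 0.5))
  expect_length(contacted(none), 0L)
})
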