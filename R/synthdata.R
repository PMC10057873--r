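# Run code under a local RNG seed without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Residue composition specification
#'
#' Per-residue sampling probabilities for [randomProtein()]. Unnamed
#' defaults are uniform over the 20 canonical residues; a partial named
#' vector fixes those residues' probabilities and spreads the remainder
#' uniformly over the rest (so e.g. `compositionSpec(c(Q = 0.18))` emulates
#' a glutamine-rich storage protein).
#'
#' @param probs Optional named numeric vector of probabilities (subset of
#'   the 20 canonical residues, each in `[0, 1]`, summing to at most 1).
#' @return Named numeric vector over all 20 residues, summing to 1 within
#'   1e-9.
#' @export
compositionSpec <- function(probs = NULL) {
  p <- stats::setNames(rep(1 / 20, 20L), AA_CANONICAL)
  if (!is.null(probs)) {
    if (is.null(names(probs)) || !all(names(probs) %in% AA_CANONICAL)) {
      stop("'probs' must be named with canonical residues", call. = FALSE)
    }
    if (any(probs < 0) || sum(probs) > 1 + 1e-9) {
      stop("probabilities must be in [0, 1] and sum to at most 1",
           call. = FALSE)
    }
    rest <- setdiff(AA_CANONICAL, names(probs))
    p[names(probs)] <- probs
    p[rest] <- (1 - sum(probs)) / length(rest)
  }
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1",
                                   call. = FALSE)
  p
}

#' Generate a random protein with controlled composition
#'
#' Draws residues i.i.d. from a composition specification. Deterministic
#' for a given seed; empirical residue frequencies converge to the
#' specification as length grows. The provenance (seed and any fixed
#' probabilities) is recorded in the record's `source` metadata.
#'
#' @param length Sequence length (>= 1).
#' @param seed Integer random seed.
#' @param probs Composition from [compositionSpec()] (or the `probs`
#'   argument it accepts); default uniform.
#' @param id Record identifier.
#' @return An `AAStringSet` of length one.
#' @examples
#' randomProtein(50, seed = 1)
#' @export
randomProtein <- function(length, seed, probs = NULL, id = "synthetic") {
  stopifnot(length >= 1L)
  p <- if (is.null(probs) || is.null(names(probs)) ||
           !setequal(names(probs), AA_CANONICAL)) {
    compositionSpec(probs)
  } else {
    if (abs(sum(probs) - 1) > 1e-9) {
      stop("probabilities must sum to 1", call. = FALSE)
    }
    probs[AA_CANONICAL]
  }
  seq <- withSeed(seed, paste(
    sample(AA_CANONICAL, size = length, replace = TRUE, prob = p),
    collapse = ""))
  proteinRecord(id, seq,
                source = sprintf("synthetic: seed=%d length=%d", seed,
                                 as.integer(length)))
}

#' Coordinate sets with planted hydrogen bonds
#'
#' Builds a synthetic ligand/receptor atom pair carrying exactly `nBonds`
#' donor-acceptor contacts at a prescribed geometry: each planted unit is a
#' receptor backbone amide (N with explicit H) donating to a ligand
#' oxygen placed so that the donor-acceptor distance and donor-H-acceptor
#' angle hit the targets to machine precision. Units are stacked more than
#' twice the detection cutoff apart, decoy heteroatoms are placed far from
#' everything, and the whole scene is rigidly rotated and translated by a
#' seed-derived motion, so recovery with [detectHbonds()] is exact rather
#' than statistical.
#'
#' @param nBonds Number of hydrogen bonds to plant (>= 0).
#' @param seed Integer seed for the rigid motion.
#' @param distance Target donor-acceptor distance (Angstrom; default 2.9).
#' @param angle Target donor-H-acceptor angle (degrees; default 160).
#' @param hotspotResidues Optional character vector recycled over the
#'   planted receptor residues to give them specific `"CYS285"`-style
#'   identities (3-letter code + number parsed from each label).
#' @return A list with atom tables `ligand` and `receptor` (layout of
#'   [parsePdb()]), the planted `pairs` table, and the generation
#'   parameters.
#' @examples
#' geom <- makePlantedGeometry(3, seed = 7)
#' nrow(detectHbonds(geom$ligand, geom$receptor))  # 3
#' @export
makePlantedGeometry <- function(nBonds, seed, distance = 2.9, angle = 160,
                                hotspotResidues = NULL) {
  stopifnot(nBonds >= 0L, distance > 0, angle > 90, angle <= 180)
  sep <- 10  # > 2 * default 3.5 A cutoff between planted units
  dH <- 1.0  # donor-hydrogen bond length

  # law of cosines: |HA| so that the D-A distance hits `distance` given
  # |DH| = dH and the D-H-A angle
  ca <- cos(angle * pi / 180)
  hA <- dH * ca + sqrt(dH^2 * ca^2 - dH^2 + distance^2)
  if (!is.finite(hA) || hA <= 0) {
    stop("infeasible distance/angle combination", call. = FALSE)
  }
  phi <- (180 - angle) * pi / 180

  if (!is.null(hotspotResidues) && nBonds > 0L) {
    ids <- rep_len(hotspotResidues, nBonds)
    resid3 <- substr(ids, 1L, 3L)
    resno <- as.integer(sub("^[A-Za-z]+", "", ids))
  } else {
    resid3 <- rep("SER", nBonds)
    resno <- seq_len(max(nBonds, 0L))
  }

  rec <- list()
  lig <- list()
  mkAtom <- function(type, serial, atom, resid, resno, xyz, element) {
    data.frame(type = type, serial = serial, atom = atom, resid = resid,
               chain = "A", resno = resno, insert = "",
               x = xyz[1L], y = xyz[2L], z = xyz[3L], element = element,
               stringsAsFactors = FALSE)
  }
  for (k in seq_len(nBonds)) {
    z <- (k - 1L) * sep
    D <- c(0, 0, z)
    H <- c(dH, 0, z)
    A <- H + hA * c(cos(phi), sin(phi), 0)
    # the donor is the backbone amide N-H, a donor for every standard
    # residue, so planted units can carry arbitrary hotspot identities
    rec[[length(rec) + 1L]] <-
      mkAtom("ATOM", 3L * k - 2L, "CA", resid3[k], resno[k],
             c(-1.5, 0, z), "C")
    rec[[length(rec) + 1L]] <-
      mkAtom("ATOM", 3L * k - 1L, "N", resid3[k], resno[k], D, "N")
    rec[[length(rec) + 1L]] <-
      mkAtom("ATOM", 3L * k, "H", resid3[k], resno[k], H, "H")
    lig[[length(lig) + 1L]] <-
      mkAtom("HETATM", 2L * k - 1L, "C1", "LIG", k, A + c(1.2, 1.0, 0), "C")
    lig[[length(lig) + 1L]] <-
      mkAtom("HETATM", 2L * k, "O1", "LIG", k, A, "O")
  }
  # far decoy heteroatoms (one per molecule), > 2x cutoff from everything
  decoyZ <- max(nBonds, 1L) * sep + 30
  rec[[length(rec) + 1L]] <-
    mkAtom("ATOM", 3L * nBonds + 1L, "OG", "SER", max(resno, 0L) + 1L,
           c(40, 40, decoyZ), "O")
  lig[[length(lig) + 1L]] <-
    mkAtom("HETATM", 2L * nBonds + 1L, "N1", "LIG", nBonds + 1L,
           c(-40, -40, -decoyZ), "N")

  receptor <- do.call(rbind, rec)
  ligand <- do.call(rbind, lig)

  # seed-derived rigid motion applied to both molecules
  motion <- withSeed(seed, {
    ax <- stats::runif(3, -1, 1)
    list(axis = ax / sqrt(sum(ax^2)),
         theta = stats::runif(1, 0, 2 * pi),
         shift = stats::runif(3, -20, 20))
  })
  R <- rotationMatrix(motion$axis, motion$theta)
  applyMotion <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1L] + motion$shift[1L]
    df$y <- xyz[, 2L] + motion$shift[2L]
    df$z <- xyz[, 3L] + motion$shift[3L]
    df
  }
  receptor <- applyMotion(receptor)
  ligand <- applyMotion(ligand)

  pairs <- if (nBonds > 0L) {
    data.frame(donorRes = paste0(resid3, resno),
               donorAtom = "N", acceptorAtom = "O1",
               distance = distance, angle = angle)
  } else {
    data.frame(donorRes = character(), donorAtom = character(),
               acceptorAtom = character(), distance = numeric(),
               angle = numeric())
  }
  list(ligand = ligand, receptor = receptor, pairs = pairs,
       nBonds = as.integer(nBonds), seed = as.integer(seed),
       distance = distance, angle = angle)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Unit-norm length-3 axis.
#' @param theta Rotation angle (radians).
#' @return A 3x3 rotation matrix (Rodrigues form).
#' @keywords internal
#' @export
rotationMatrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3L], axis[2L],
                axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), nrow = 3L, byrow = TRUE)
  diag(3L) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Write a planted geometry to PDB fixtures
#'
#' Emits the ligand and receptor of [makePlantedGeometry()] as PDB files
#' whose REMARK headers carry the generation provenance (seed, bond count,
#' target geometry); both parse back with [parsePdb()] without warnings.
#'
#' @param geom Result of [makePlantedGeometry()].
#' @param ligandPath,receptorPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writePlantedGeometry <- function(geom, ligandPath, receptorPath) {
  prov <- sprintf(
    "synthetic planted-bond fixture: seed=%d n_bonds=%d distance=%.3f angle=%.1f",
    geom$seed, geom$nBonds, geom$distance, geom$angle)
  writePdb(geom$ligand, ligandPath, remarks = prov)
  writePdb(geom$receptor, receptorPath, remarks = prov)
  invisible(c(ligandPath, receptorPath))
}
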