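# Hydrogen-bond donor/acceptor atom templates for the 20 standard protein
# residues (N/O convention: sulfur is never counted). Backbone N is a donor
# except in proline; backbone O and the C-terminal OXT are acceptors.
# Histidine ND1/NE2 may each be protonated, so both are listed on both
# sides; SER/THR/TYR hydroxyls are both donors and acceptors.
DONOR_ATOMS <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1",
  HIS = c("ND1", "NE2")
)

ACCEPTOR_ATOMS <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)

STANDARD_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU",
                       "GLY", "HIS", "ILE", "LEU", "LYS", "MET", "PHE",
                       "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Parse atomic coordinates from a PDB file
#'
#' Reads fixed-column ATOM/HETATM records (via [bio3d::read.pdb()]) into a
#' flat atom table. Only the first MODEL of a multi-model file is used, with
#' a warning; insertion codes are preserved. Elements missing from the
#' element column are inferred from the atom name.
#'
#' @param path Path to a PDB file.
#' @return A `data.frame` with columns `type`, `serial`, `atom`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `element`.
#' @seealso [writePdb()] for the inverse, [detectHbonds()] for geometry.
#' @export
parsePdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path, call. = FALSE)
  nModels <- sum(grepl("^MODEL ", readLines(path, warn = FALSE)))
  if (nModels > 1L) {
    warning("PDB file has ", nModels, " models; using model 1 only: ", path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  element <- at$elesy
  noEl <- is.na(element) | !nzchar(trimws(element))
  element[noEl] <- substr(gsub("[^A-Za-z].*$", "", trimws(at$elety[noEl])), 1L, 1L)
  data.frame(
    type = at$type,
    serial = at$eleno,
    atom = trimws(at$elety),
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    element = toupper(trimws(element)),
    stringsAsFactors = FALSE
  )
}

#' Write an atom table to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (coordinates to 3 decimals, the
#' PDB precision) preceded by optional REMARK lines; round-trips with
#' [parsePdb()].
#'
#' @param atoms Atom `data.frame` in the [parsePdb()] layout.
#' @param path Output path.
#' @param remarks Character vector written as `REMARK` lines.
#' @return `path`, invisibly.
#' @export
writePdb <- function(atoms, path, remarks = character()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  name4 <- ifelse(nchar(atoms$atom) < 4L,
                  sprintf(" %-3s", atoms$atom),
                  substr(atoms$atom, 1L, 4L))
  lines <- sprintf(
    "%-6s%5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$type, atoms$serial, name4, atoms$resid,
    ifelse(nzchar(atoms$chain), atoms$chain, "A"), atoms$resno,
    ifelse(nzchar(atoms$insert), atoms$insert, " "),
    atoms$x, atoms$y, atoms$z, 1.00, 0.00, atoms$element)
  header <- if (length(remarks) > 0L) sprintf("REMARK   6 %s", remarks)
            else character()
  writeLines(c(header, lines, "END"), path)
  invisible(path)
}

#' Construct a docking grid box
#'
#' @param center Numeric length-3 centre (Angstrom).
#' @param size Numeric length-3 grid points per axis.
#' @param spacing Grid spacing (Angstrom).
#' @return A [GridBox-class].
#' @export
gridBox <- function(center, size, spacing = 0.375) {
  stopifnot(length(center) == 3L, length(size) == 3L)
  new("GridBox", centerX = center[1L], centerY = center[2L],
      centerZ = center[3L], sizeX = size[1L], sizeY = size[2L],
      sizeZ = size[3L], spacing = spacing)
}

#' Default PPARgamma antiadipogenic-region grid box
#'
#' The search box covering the antiadipogenic region of the PPARgamma
#' ligand-binding domain: centre (7.745, 50.606, 57.552) Angstrom, 70 x 40
#' x 40 grid points at 0.375 Angstrom spacing (physical size 26.25 x 15 x
#' 15 Angstrom). Both the grid-point and the physical-size interpretation
#' are available through [makeGridboxConfig()].
#'
#' @return A [GridBox-class].
#' @export
defaultGridBox <- function() {
  gridBox(center = c(7.745, 50.606, 57.552), size = c(70, 40, 40),
          spacing = 0.375)
}

#' Emit a docking-tool configuration for a grid box
#'
#' Writes the `center_*` / `size_*` key-value block used by docking tools.
#' With `units = "angstrom"` (default, the Vina convention) sizes are the
#' physical edge lengths `points * spacing`; with `units = "points"` the
#' raw grid-point counts are written. The spacing is included as a comment
#' so the text round-trips through [parseGridboxConfig()].
#'
#' @param box A [GridBox-class].
#' @param units `"angstrom"` or `"points"`.
#' @return The configuration text as a character vector of lines.
#' @examples
#' makeGridboxConfig(defaultGridBox())
#' @export
makeGridboxConfig <- function(box, units = c("angstrom", "points")) {
  stopifnot(is(box, "GridBox"))
  units <- match.arg(units)
  f <- if (units == "angstrom") box@spacing else 1
  num <- function(x) format(x, trim = TRUE, scientific = FALSE)
  c(sprintf("# grid units = %s", units),
    sprintf("# spacing_angstrom = %s", num(box@spacing)),
    sprintf("center_x = %s", num(box@centerX)),
    sprintf("center_y = %s", num(box@centerY)),
    sprintf("center_z = %s", num(box@centerZ)),
    sprintf("size_x = %s", num(box@sizeX * f)),
    sprintf("size_y = %s", num(box@sizeY * f)),
    sprintf("size_z = %s", num(box@sizeZ * f)))
}

#' Parse a grid-box configuration block
#'
#' Inverse of [makeGridboxConfig()].
#'
#' @param text Character vector of configuration lines.
#' @return A [GridBox-class].
#' @export
parseGridboxConfig <- function(text) {
  getNum <- function(key, default = NA_real_) {
    ln <- grep(paste0("^\\s*#?\\s*", key, "\\s*="), text, value = TRUE)
    if (length(ln) == 0L) return(default)
    as.numeric(sub(".*=\\s*", "", ln[1L]))
  }
  unitsLn <- grep("^\\s*#\\s*grid units\\s*=", text, value = TRUE)
  units <- if (length(unitsLn) > 0L) trimws(sub(".*=\\s*", "", unitsLn[1L]))
           else "angstrom"
  spacing <- getNum("spacing_angstrom", 0.375)
  size <- c(getNum("size_x"), getNum("size_y"), getNum("size_z"))
  if (units == "angstrom") size <- size / spacing
  gridBox(center = c(getNum("center_x"), getNum("center_y"),
                     getNum("center_z")),
          size = size, spacing = spacing)
}

#' Parse a docking result log
#'
#' Extracts the tabular result block of a docking run (columns: mode rank,
#' affinity in kcal/mol, RMSD bounds) into a rank/affinity table; the
#' best-scoring pose is first.
#'
#' @param text Character vector of log lines, or a path to a log file.
#' @return A `data.frame` with columns `rank` and `affinity`.
#' @export
parseDockingLog <- function(text) {
  if (length(text) == 1L && file.exists(text)) {
    text <- readLines(text, warn = FALSE)
  }
  header <- grep("^-+\\+-+", text)
  start <- if (length(header) > 0L) header[1L] + 1L else 1L
  rows <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?(\\s+-?\\d+(\\.\\d+)?)*\\s*$",
               text[start:length(text)], value = TRUE)
  if (length(rows) == 0L) {
    stop("no docking result block found in log", call. = FALSE)
  }
  fields <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
  data.frame(rank = vapply(fields, `[`, numeric(1L), 1L),
             affinity = vapply(fields, `[`, numeric(1L), 2L))
}

# Classify each atom of a molecule as potential hydrogen-bond donor and/or
# acceptor, and attach explicit hydrogens (same residue, within hCutoff of
# the heavy atom) to donors. Standard residues use the template tables;
# other residues (ligands, HETATM) fall back to the element heuristic:
# N/O are acceptors, and donors when an explicit hydrogen is attached.
typeAtoms <- function(atoms, hCutoff = 1.25) {
  isH <- atoms$element == "H"
  heavy <- atoms[!isH, , drop = FALSE]
  hyd <- atoms[isH, , drop = FALSE]
  hasHydrogens <- nrow(hyd) > 0L

  std <- heavy$resid %in% STANDARD_RESIDUES
  donor <- logical(nrow(heavy))
  acceptor <- logical(nrow(heavy))

  # template route for standard residues
  inTemplate <- function(table, i) {
    entry <- table[[heavy$resid[i]]]
    !is.null(entry) && heavy$atom[i] %in% entry
  }
  for (i in which(std)) {
    donor[i] <- (heavy$atom[i] %in% DONOR_ATOMS$backbone &&
                   heavy$resid[i] != "PRO") || inTemplate(DONOR_ATOMS, i)
    acceptor[i] <- heavy$atom[i] %in% ACCEPTOR_ATOMS$backbone ||
      inTemplate(ACCEPTOR_ATOMS, i)
  }

  # element heuristic for everything else
  het <- !std & heavy$element %in% c("N", "O")
  acceptor[het] <- TRUE

  # attach explicit hydrogens (same residue, within hCutoff)
  hList <- vector("list", nrow(heavy))
  if (hasHydrogens) {
    for (i in which(heavy$element %in% c("N", "O"))) {
      sameRes <- hyd$resid == heavy$resid[i] &
        hyd$resno == heavy$resno[i] & hyd$chain == heavy$chain[i]
      if (!any(sameRes)) next
      d <- sqrt((hyd$x[sameRes] - heavy$x[i])^2 +
                (hyd$y[sameRes] - heavy$y[i])^2 +
                (hyd$z[sameRes] - heavy$z[i])^2)
      hList[[i]] <- which(sameRes)[d <= hCutoff]
    }
    # hetero N/O are donors only when an explicit hydrogen is attached
    donor[het] <- lengths(hList)[het] > 0L
  } else {
    # without hydrogens, protonation is unknowable: treat hetero N/O as
    # donor candidates too (distance-only criterion)
    donor[het] <- TRUE
  }
  list(heavy = heavy, hyd = hyd, donor = donor, acceptor = acceptor,
       hList = hList, hasHydrogens = hasHydrogens)
}

vecAngle <- function(a, b) {
  cosang <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect intermolecular hydrogen bonds between two molecules
#'
#' Geometric criterion: a donor N/O of one molecule and an acceptor N/O of
#' the other within `dMax` Angstrom, and, whenever the donor carries
#' explicit hydrogens, a donor-H-acceptor angle of at least `angleMin`
#' degrees (distance-only otherwise). Donor/acceptor typing uses residue
#' templates for the 20 standard residues and an element heuristic for
#' ligand atoms. Both directions (ligand donor to receptor acceptor and
#' vice versa) are searched; results are sorted by donor-acceptor distance.
#'
#' @param ligand,receptor Atom `data.frame`s in the [parsePdb()] layout.
#' @param dMax Maximum donor-acceptor distance (Angstrom; default 3.5).
#' @param angleMin Minimum donor-H-acceptor angle (degrees; default 120),
#'   applied only when the donor has explicit hydrogens.
#' @return A `data.frame`, one row per bond: `donorMol`, `donorAtom`,
#'   `donorRes`, `acceptorAtom`, `acceptorRes`, `receptorRes` (the
#'   receptor-side residue label), `distance`, `angle` (NA without explicit
#'   hydrogens).
#' @seealso [contactResidues()], [makePlantedGeometry()]
#' @export
detectHbonds <- function(ligand, receptor, dMax = 3.5, angleMin = 120) {
  stopifnot(nrow(ligand) > 0L, nrow(receptor) > 0L)
  lt <- typeAtoms(ligand)
  rt <- typeAtoms(receptor)

  resLabel <- function(df, i) paste0(df$resid[i], df$resno[i])

  scan <- function(dt, at, donorMol) {
    dIdx <- which(dt$donor)
    aIdx <- which(at$acceptor)
    if (length(dIdx) == 0L || length(aIdx) == 0L) return(NULL)
    out <- list()
    for (i in dIdx) {
      dx <- at$heavy$x[aIdx] - dt$heavy$x[i]
      dy <- at$heavy$y[aIdx] - dt$heavy$y[i]
      dz <- at$heavy$z[aIdx] - dt$heavy$z[i]
      dist <- sqrt(dx^2 + dy^2 + dz^2)
      for (k in which(dist <= dMax)) {
        j <- aIdx[k]
        ang <- NA_real_
        hs <- dt$hList[[i]]
        if (length(hs) > 0L) {
          D <- c(dt$heavy$x[i], dt$heavy$y[i], dt$heavy$z[i])
          A <- c(at$heavy$x[j], at$heavy$y[j], at$heavy$z[j])
          angles <- vapply(hs, function(h) {
            H <- c(dt$hyd$x[h], dt$hyd$y[h], dt$hyd$z[h])
            vecAngle(D - H, A - H)
          }, numeric(1L))
          ang <- max(angles)
          if (ang < angleMin) next
        }
        otherMol <- if (donorMol == "ligand") "receptor" else "ligand"
        out[[length(out) + 1L]] <- data.frame(
          donorMol = donorMol,
          donorAtom = dt$heavy$atom[i],
          donorRes = resLabel(dt$heavy, i),
          acceptorAtom = at$heavy$atom[j],
          acceptorRes = resLabel(at$heavy, j),
          receptorRes = if (donorMol == "ligand") resLabel(at$heavy, j)
                        else resLabel(dt$heavy, i),
          distance = dist[k],
          angle = ang,
          pairKey = paste(sort(c(
            paste0(donorMol, ":", dt$heavy$serial[i]),
            paste0(otherMol, ":", at$heavy$serial[j]))), collapse = "|"),
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(out) > 0L) do.call(rbind, out) else NULL
  }

  bonds <- rbind(scan(lt, rt, "ligand"), scan(rt, lt, "receptor"))
  if (is.null(bonds)) {
    bonds <- data.frame(donorMol = character(), donorAtom = character(),
                        donorRes = character(), acceptorAtom = character(),
                        acceptorRes = character(),
                        receptorRes = character(), distance = numeric(),
                        angle = numeric(), stringsAsFactors = FALSE)
    return(bonds)
  }
  # a physical hydrogen bond is one unordered atom pair: when a pair is
  # picked up in both scan directions (possible for hydroxyl-type atoms or
  # hydrogen-free molecules), keep the direction with a defined angle
  bonds <- bonds[order(bonds$distance, is.na(bonds$angle)), , drop = FALSE]
  bonds <- bonds[!duplicated(bonds$pairKey), , drop = FALSE]
  bonds$pairKey <- NULL
  rownames(bonds) <- NULL
  bonds
}

#' The PPARgamma antiadipogenic hotspot residues
#'
#' The receptor residues of the PPARgamma ligand-binding domain whose
#' contact by a ligand is associated with antagonist (antiadipogenic)
#' binding: Phe264, His266, Ile281, Cys285, Arg288, Ser289, Met348, His449.
#'
#' @return Character vector of `"CYS285"`-style residue labels.
#' @export
ppargHotspots <- function() {
  c("PHE264", "HIS266", "ILE281", "CYS285", "ARG288", "SER289", "MET348",
    "HIS449")
}

#' Intersect pose contacts with a hotspot residue set
#'
#' Summarises the receptor residues touched by the hydrogen bonds of a
#' docked pose and intersects them with a hotspot set. Contacts outside the
#' hotspot set are flagged, never dropped.
#'
#' @param bonds Hydrogen-bond table from [detectHbonds()].
#' @param hotspots Character vector of `"CYS285"`-style labels; default
#'   [ppargHotspots()].
#' @return A [ContactReport-class].
#' @export
contactResidues <- function(bonds, hotspots = ppargHotspots()) {
  stopifnot(is.data.frame(bonds))
  contactedRes <- unique(bonds$receptorRes)
  new("ContactReport", bonds = bonds, contacted = contactedRes,
      hotspotContacts = intersect(contactedRes, hotspots),
      otherContacts = setdiff(contactedRes, hotspots))
}
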