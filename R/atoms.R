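# Per-element van der Waals radii (A), Kyte-Doolittle hydropathy, and the
# simplified fixed point-charge model used for the surface charge channel.

.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, SE = 1.90)
.VDW_DEFAULT <- 1.70

.KYTE_DOOLITTLE <- c(
  ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5, MET = 1.9,
  ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

# Simplified point charges (elementary units): ionizable side-chain termini
# carry the formal charge split over equivalent atoms; the backbone amide
# carries a small dipole. Not a force field; the channel is standardized
# per protein downstream.
.PARTIAL_CHARGES <- list(
  ARG = c(NH1 = 0.5, NH2 = 0.5),
  LYS = c(NZ = 1.0),
  ASP = c(OD1 = -0.5, OD2 = -0.5),
  GLU = c(OE1 = -0.5, OE2 = -0.5),
  HIS = c(ND1 = 0.1, NE2 = 0.1))
.BACKBONE_CHARGES <- c(N = -0.3, O = -0.4, C = 0.4, H = 0.3)

# Heavy-atom hydrogen-bond classes: nitrogens donate (+1) except the proline
# backbone amide, carbonyl/carboxylate oxygens accept (-1); hydroxyl oxygens
# (SER/THR/TYR OG*/OH) are left neutral as they both donate and accept.
.HBOND_NEUTRAL_O <- c("OG", "OG1", "OH")

.atom_hbond_class <- function(element, atom_name, residue_name) {
  cls <- numeric(length(element))
  isN <- element == "N"
  cls[isN] <- 1
  cls[isN & residue_name == "PRO" & atom_name == "N"] <- 0
  isO <- element == "O"
  cls[isO] <- -1
  cls[isO & atom_name %in% .HBOND_NEUTRAL_O] <- 0
  cls[element == "S" & atom_name == "SG"] <- 1   # cysteine thiol, weak donor
  cls
}

.atom_partial_charge <- function(residue_name, atom_name) {
  q <- unname(.BACKBONE_CHARGES[atom_name])
  q[is.na(q)] <- 0
  for (res in names(.PARTIAL_CHARGES)) {
    tab <- .PARTIAL_CHARGES[[res]]
    sel <- residue_name == res & atom_name %in% names(tab)
    if (any(sel)) q[sel] <- unname(tab[atom_name[sel]])
  }
  q
}

.guess_element <- function(elesy, atom_name) {
  ele <- toupper(trimws(elesy))
  bad <- is.na(ele) | ele == ""
  if (any(bad)) {
    # fall back to the first alphabetic character of the atom name
    nm <- gsub("[^A-Za-z].*", "", gsub("^[0-9]+", "", atom_name[bad]))
    ele[bad] <- toupper(substr(nm, 1, 1))
  }
  ele
}

#' Parse a PDB structure into an AtomSet
#'
#' Reads standard fixed-column PDB text (via bio3d), keeps ATOM records
#' (HETATM records, waters and ions are excluded by default), optionally
#' filters to a set of chains, and attaches the per-atom lookups the surface
#' featurization needs: van der Waals radius, simplified partial charge,
#' Kyte-Doolittle residue hydropathy and hydrogen-bond donor/acceptor class.
#' Hydrogens are kept if present; no protonation is attempted. Only the
#' first model of a multi-model file is used.
#'
#' @param pdb path to a PDB file, or a character vector/scalar of PDB text.
#' @param chains optional character vector of chain identifiers to keep.
#' @param includeHetero keep non-water HETATM records too (default FALSE).
#' @return an [AtomSet-class].
#' @examples
#' pdb <- makeToyPeptide(3, seed = 1)
#' parseStructure(pdb$text)
#' @export
parseStructure <- function(pdb, chains = NULL, includeHetero = FALSE) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(pdb, collapse = "\n"), "\n", fixed = TRUE))
  }
  # first model only
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (includeHetero & rec == "HETATM")
  alines <- lines[keep]
  lineno <- which(keep)
  if (!length(alines)) stop("no atoms: no ATOM records after filtering")

  coord_fields <- cbind(substr(alines, 31, 38), substr(alines, 39, 46),
                        substr(alines, 47, 54))
  suppressWarnings(xyz <- matrix(as.numeric(coord_fields), ncol = 3L))
  bad <- which(!stats::complete.cases(xyz))
  if (length(bad))
    stop(sprintf("parse error: malformed coordinate field on line %d: %s",
                 lineno[bad[1]], trimws(alines[bad[1]])))

  a <- data.frame(
    atom_id = suppressWarnings(as.integer(substr(alines, 7, 11))),
    atom_name = trimws(substr(alines, 13, 16)),
    residue_name = trimws(substr(alines, 18, 20)),
    chain_id = trimws(substr(alines, 22, 22)),
    residue_seq = suppressWarnings(as.integer(substr(alines, 23, 26))),
    insert = trimws(substr(alines, 27, 27)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    element = .guess_element(substr(alines, 77, 78), trimws(substr(alines, 13, 16))),
    stringsAsFactors = FALSE)

  a <- a[!(a$residue_name %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  ions <- c("NA", "CL", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "SO4", "PO4")
  a <- a[!(a$residue_name %in% ions), , drop = FALSE]
  if (!is.null(chains)) a <- a[a$chain_id %in% chains, , drop = FALSE]
  if (!nrow(a)) stop("no atoms: selection is empty after chain/solvent filtering")

  a$radius <- unname(.VDW_RADII[a$element])
  a$radius[is.na(a$radius)] <- .VDW_DEFAULT
  a$charge <- .atom_partial_charge(a$residue_name, a$atom_name)
  a$hydropathy <- unname(.KYTE_DOOLITTLE[a$residue_name])
  a$hydropathy[is.na(a$hydropathy)] <- 0
  a$hbond <- .atom_hbond_class(a$element, a$atom_name, a$residue_name)
  if (anyNA(a$atom_id)) a$atom_id[is.na(a$atom_id)] <- which(is.na(a$atom_id))
  rownames(a) <- NULL
  a <- a[, c("atom_id", "element", "x", "y", "z", "residue_name",
             "residue_seq", "insert", "chain_id", "atom_name", "radius",
             "charge", "hydropathy", "hbond")]
  new("AtomSet", atoms = a)
}

#' Subset an AtomSet by residue
#'
#' Selects atoms by chain and residue number, the way interface or CDR
#' annotations are supplied (chain + residue lists).
#'
#' @param atoms an [AtomSet-class].
#' @param chain character vector of chain ids (recycled against `resno`).
#' @param resno integer vector of residue sequence numbers.
#' @return an [AtomSet-class] with the selected atoms.
#' @export
selectResidues <- function(atoms, chain, resno) {
  a <- atomData(atoms)
  key <- paste(a$chain_id, a$residue_seq)
  want <- paste(rep(chain, length.out = length(resno)), resno)
  sel <- key %in% want
  if (!any(sel)) stop("no atoms match the residue selection")
  new("AtomSet", atoms = a[sel, , drop = FALSE])
}

#' Write an AtomSet as PDB text
#'
#' @param atoms an [AtomSet-class].
#' @param file optional path; if NULL the text is returned invisibly.
#' @return invisibly, the character vector of PDB lines.
#' @export
writeAtomsPDB <- function(atoms, file = NULL) {
  a <- atomData(atoms)
  name4 <- ifelse(nchar(a$atom_name) < 4 & nchar(a$element) == 1,
                  sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
  lines <- sprintf(
    "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$atom_id %% 100000L, name4, "", a$residue_name, a$chain_id,
    a$residue_seq %% 10000L, a$insert, a$x, a$y, a$z, 1, 0, a$element)
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
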