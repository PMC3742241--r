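# Atom tables: the flat coordinate representation shared by proteins and
# ligands. One row per atom; coordinates are Cartesian angstroms as in PDB.

#' Construct an atom table
#'
#' Builds the canonical per-atom data frame used throughout the package:
#' one row per atom with serial number, atom name, element symbol,
#' coordinates (angstrom), residue name/number, chain id, HETATM flag and
#' formal charge.
#'
#' @param serial integer atom serial numbers (unique within a structure).
#' @param name PDB-style atom names (e.g. `"CA"`, `"OD1"`).
#' @param element element symbols (`"C"`, `"N"`, ...).
#' @param x,y,z numeric coordinates in angstrom; must be finite.
#' @param resname three-letter residue codes.
#' @param resno integer residue numbers (taken verbatim from input files).
#' @param chain one-character chain identifiers.
#' @param het logical, `TRUE` for HETATM records.
#' @param charge integer formal charges (0 for uncharged atoms).
#' @return A `data.frame` with the columns above.
#' @export
atom_table <- function(serial = integer(), name = character(),
                       element = character(), x = numeric(), y = numeric(),
                       z = numeric(), resname = character(),
                       resno = integer(), chain = character(),
                       het = logical(), charge = integer()) {
  n <- length(serial)
  stopifnot(
    length(name) == n, length(element) == n, length(x) == n,
    length(y) == n, length(z) == n, length(resname) == n,
    length(resno) == n, length(het) == n
  )
  if (length(chain) == 1L) chain <- rep(chain, n)
  if (length(charge) == 0L && n > 0L) charge <- rep(0L, n)
  if (length(charge) == 1L) charge <- rep(charge, n)
  if (n > 0L && !all(is.finite(c(x, y, z)))) stop("non-finite coordinates")
  if (anyDuplicated(serial)) stop("duplicate atom serials")
  data.frame(
    serial = as.integer(serial), name = as.character(name),
    element = as.character(element), x = as.numeric(x), y = as.numeric(y),
    z = as.numeric(z), resname = as.character(resname),
    resno = as.integer(resno), chain = as.character(chain),
    het = as.logical(het), charge = as.integer(charge),
    stringsAsFactors = FALSE
  )
}

#' Extract an n x 3 coordinate matrix from an atom table
#' @param atoms an atom table (see [atom_table()]).
#' @return numeric matrix with columns x, y, z.
#' @export
atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

set_atom_coords <- function(atoms, xyz) {
  stopifnot(nrow(xyz) == nrow(atoms))
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

# All pairwise Euclidean distances between the rows of two coordinate
# matrices. Small-n geometry only; no neighbor lists needed at this scale.
cross_dist <- function(A, B) {
  A <- rbind(A)
  B <- rbind(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Monatomic ions stripped alongside waters; the het codes cover the common
# crystallographic additives.
.ion_codes <- c("NA", "K", "MG", "ZN", "CL", "CA", "MN", "FE", "CU", "NI",
                "CO", "CD", "BR", "IOD")
.water_codes <- c("HOH", "WAT", "DOD")

# Monoisotopic-free standard atomic weights for molecular-weight sums.
.atomic_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, B = 10.81, SI = 28.085
)

element_mass <- function(element) {
  m <- .atomic_mass[toupper(element)]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

.aa_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

#' Compact residue label
#'
#' One-letter amino-acid code followed by the residue number, the labelling
#' style used for binding-site residues (e.g. `"D296"`). Non-standard
#' residues are labelled `"X<number>"`.
#'
#' @param resname three-letter residue code(s).
#' @param resno residue number(s).
#' @return character vector of labels.
#' @export
residue_label <- function(resname, resno) {
  one <- .aa_one[toupper(resname)]
  one[is.na(one)] <- "X"
  paste0(unname(one), resno)
}

# unique residues of an atom table, in order of first appearance
residue_index <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resname, sep = "|")
  first <- !duplicated(key)
  data.frame(
    chain = atoms$chain[first], resno = atoms$resno[first],
    resname = atoms$resname[first],
    label = residue_label(atoms$resname[first], atoms$resno[first]),
    key = key[first], stringsAsFactors = FALSE
  )
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$resname, sep = "|")
}
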