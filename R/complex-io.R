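# Protein-ligand complex I/O and superposition. PDB parsing is delegated to
# bio3d; this file adds the complex-level bookkeeping (water/ion stripping,
# ligand extraction with CONECT bonds, altloc resolution) and the rigid-body
# geometry used to bring an ensemble of complexes into one reference frame.

#' Rigid-body transform
#'
#' @param rotation 3 x 3 proper rotation matrix (determinant +1).
#' @param translation length-3 numeric vector (angstrom).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (abs(det(rotation) - 1) > 1e-6) stop("rotation must be proper (det = +1)")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6) {
    stop("rotation must be orthonormal")
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 coordinate matrix.
#' @param tf a [rigid_transform()].
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, tf) {
  xyz <- rbind(xyz)
  sweep(xyz %*% t(tf$rotation), 2, -tf$translation)
}

#' Invert a rigid transform
#' @param tf a [rigid_transform()].
#' @return the inverse `rigid_transform`.
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation), -t(tf$rotation) %*% tf$translation)
}

#' Compose two rigid transforms (apply `a` then `b`)
#' @param a,b [rigid_transform()] objects.
#' @return composed `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Kabsch least-squares superposition
#'
#' Closed-form SVD solution for the proper rotation and translation that
#' minimize the RMSD of paired point sets, with the usual reflection guard
#' on the sign of the smallest singular direction. `bio3d::fit.xyz` solves
#' the same problem but returns fitted coordinates only; the explicit
#' transform returned here is reused to move whole complexes and ligand
#' poses, and the two routes are cross-checked in the test suite.
#'
#' @param P,Q paired n x 3 coordinate matrices (`P` is moved onto `Q`).
#' @return list with `transform` (a [rigid_transform()]) and `rmsd`
#'   (angstrom, after superposition).
#' @export
kabsch <- function(P, Q) {
  P <- rbind(P); Q <- rbind(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3L || ncol(Q) != 3L) {
    stop("point sets must be paired n x 3 matrices")
  }
  if (nrow(P) < 3L) stop("insufficient points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  S <- diag(c(1, 1, d))
  R <- sv$v %*% S %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  tf <- rigid_transform(R, t)
  moved <- apply_transform(P, tf)
  list(transform = tf, rmsd = sqrt(mean(rowSums((moved - Q)^2))))
}

# ---------------------------------------------------------------------------

.parse_pdb_charge <- function(ch) {
  ch <- trimws(ifelse(is.na(ch), "", ch))
  out <- integer(length(ch))
  has <- nzchar(ch)
  for (k in which(has)) {
    s <- ch[k]
    if (grepl("^[0-9]+[+-]$", s)) {
      v <- as.integer(substr(s, 1, nchar(s) - 1))
      if (substr(s, nchar(s), nchar(s)) == "-") v <- -v
      out[k] <- v
    } else if (grepl("^[+-]?[0-9]+$", s)) {
      out[k] <- as.integer(s)
    }
  }
  out
}

.guess_element <- function(name) {
  nm <- gsub("[0-9' ]", "", name)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "MN", "SI"),
         two, toupper(substr(nm, 1, 1)))
}

# CONECT records -> ligand bond list; duplicated partner entries encode
# higher bond orders (standard PDB convention for small molecules).
.conect_bonds <- function(pdb_lines, serials) {
  con <- grep("^CONECT", pdb_lines, value = TRUE)
  if (length(con) == 0L) return(NULL)
  pairs <- list()
  for (ln in con) {
    flds <- as.integer(substring(ln, seq(7, 61, by = 5), seq(11, 65, by = 5)))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2L) next
    a <- flds[1]
    for (b in flds[-1]) pairs[[length(pairs) + 1L]] <- c(min(a, b), max(a, b))
  }
  if (length(pairs) == 0L) return(NULL)
  m <- do.call(rbind, pairs)
  keep <- m[, 1] %in% serials & m[, 2] %in% serials
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) return(NULL)
  key <- paste(m[, 1], m[, 2])
  # each bond is listed from both end points; order = max multiplicity seen
  tab <- table(key)
  uq <- unique(key)
  i <- match(as.integer(sub(" .*", "", uq)), serials)
  j <- match(as.integer(sub(".* ", "", uq)), serials)
  order <- pmax(1L, as.integer(ceiling(tab[uq] / 2)))
  data.frame(i = i, j = j, order = unname(order))
}

# keep highest occupancy per (chain, resno, resname, atom name); ties first-seen
.resolve_altloc <- function(at) {
  if (nrow(at) == 0L) return(at)
  key <- paste(at$chain, at$resno, at$resid, at$elety, sep = "|")
  occ <- ifelse(is.na(at$o), 1, at$o)
  ord <- order(key, -occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at[!duplicated(key[ord]), , drop = FALSE]
}

#' Read a protein-ligand complex from PDB text
#'
#' Parses a PDB file (via bio3d), strips waters and common monatomic ions,
#' resolves alternate locations to the highest-occupancy copy, extracts the
#' named ligand (first copy when several are present) and returns protein
#' and ligand as one complex. Ligand bonds come from CONECT records when
#' present, otherwise from distance-based perception
#' ([perceive_bonds()]).
#'
#' @param pdb character: either a file path or PDB text (vector of lines or
#'   a single string with newlines).
#' @param ligand_code three-letter het code of the ligand of interest.
#' @param complex_id identifier stored on the complex; defaults to the
#'   ligand code.
#' @return object of class `pharm_complex` with elements `complex_id`,
#'   `protein` (atom table), `ligand` ([ligand_molecule()]) and `removed`
#'   (counts of dropped waters/ions).
#' @export
read_complex <- function(pdb, ligand_code, complex_id = NULL) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    lines <- readLines(pdb, warn = FALSE)
    if (is.null(complex_id)) {
      complex_id <- sub("\\.pdb$", "", basename(pdb), ignore.case = TRUE)
    }
  } else {
    lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  }
  if (is.null(complex_id)) complex_id <- ligand_code
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  p <- bio3d::read.pdb(tmp, verbose = FALSE)
  at <- .resolve_altloc(p$atom)
  at <- at[order(at$eleno), , drop = FALSE]

  is_water <- toupper(at$resid) %in% .water_codes
  is_ion <- at$type == "HETATM" & toupper(at$resid) %in% .ion_codes
  removed <- list(waters = sum(is_water), ions = sum(is_ion))
  at <- at[!is_water & !is_ion, , drop = FALSE]

  elem <- ifelse(is.na(at$elesy) | !nzchar(trimws(at$elesy)),
                 .guess_element(at$elety), toupper(trimws(at$elesy)))
  elem <- ifelse(nchar(elem) == 2,
                 paste0(substr(elem, 1, 1), tolower(substr(elem, 2, 2))), elem)
  tab <- atom_table(
    serial = at$eleno, name = trimws(at$elety), element = elem,
    x = at$x, y = at$y, z = at$z, resname = toupper(at$resid),
    resno = at$resno, chain = ifelse(is.na(at$chain), " ", at$chain),
    het = at$type == "HETATM", charge = .parse_pdb_charge(at$charge)
  )

  prot <- tab[!tab$het, , drop = FALSE]
  if (nrow(prot) == 0L) stop("no protein")
  lig_at <- tab[tab$het & tab$resname == toupper(ligand_code), , drop = FALSE]
  if (nrow(lig_at) == 0L) stop("ligand not found")
  # first copy when the het code occurs multiple times
  first <- paste(lig_at$chain[1], lig_at$resno[1])
  lig_at <- lig_at[paste(lig_at$chain, lig_at$resno) == first, , drop = FALSE]
  rownames(lig_at) <- NULL
  rownames(prot) <- NULL

  bonds <- .conect_bonds(lines, lig_at$serial)
  if (is.null(bonds)) bonds <- perceive_bonds(lig_at)
  lig <- ligand_molecule(lig_at, bonds,
                         multi_fragment = TRUE)  # validated below
  g <- ligand_graph(lig)
  lig$multi_fragment <- igraph::components(g)$no > 1L

  structure(
    list(complex_id = complex_id, protein = prot, ligand = lig,
         removed = removed),
    class = "pharm_complex"
  )
}

#' @export
print.pharm_complex <- function(x, ...) {
  cat(sprintf(
    "pharm_complex '%s': %d protein atoms (%d residues), ligand %d atoms; removed %d waters, %d ions\n",
    x$complex_id, nrow(x$protein), nrow(residue_index(x$protein)),
    nrow(x$ligand$atoms), x$removed$waters, x$removed$ions))
  invisible(x)
}

.pdb_atom_line <- function(rec, serial, name, resname, chain, resno,
                           x, y, z, element, charge) {
  name4 <- if (nchar(name) >= 4L) substr(name, 1, 4) else sprintf(" %-3s", name)
  chg <- if (charge == 0L) "  " else sprintf("%d%s", abs(charge),
                                             if (charge > 0) "+" else "-")
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s%2s",
          rec, serial, name4, " ", resname, chain, resno, " ",
          x, y, z, 1, 0, element, chg)
}

#' Write a complex to PDB text
#'
#' Emits ATOM records for the protein, HETATM records for the ligand and
#' CONECT records for ligand bonds (repeated entries encode bond order).
#' Output is deterministic: no timestamps, fixed formatting.
#'
#' @param complex a `pharm_complex`.
#' @param file optional path; when `NULL` the lines are returned invisibly.
#' @param header optional character vector of REMARK lines to prepend.
#' @return character vector of PDB lines (invisibly when written to file).
#' @export
write_complex_pdb <- function(complex, file = NULL, header = NULL) {
  pr <- complex$protein
  lg <- complex$ligand$atoms
  lines <- character()
  if (!is.null(header)) lines <- c(lines, header)
  for (k in seq_len(nrow(pr))) {
    lines <- c(lines, .pdb_atom_line(
      "ATOM", pr$serial[k], pr$name[k], pr$resname[k], pr$chain[k],
      pr$resno[k], pr$x[k], pr$y[k], pr$z[k], toupper(pr$element[k]),
      pr$charge[k]))
  }
  lines <- c(lines, "TER")
  for (k in seq_len(nrow(lg))) {
    lines <- c(lines, .pdb_atom_line(
      "HETATM", lg$serial[k], lg$name[k], lg$resname[k], lg$chain[k],
      lg$resno[k], lg$x[k], lg$y[k], lg$z[k], toupper(lg$element[k]),
      lg$charge[k]))
  }
  b <- complex$ligand$bonds
  for (k in seq_len(nrow(b))) {
    s1 <- lg$serial[b$i[k]]; s2 <- lg$serial[b$j[k]]
    for (rep_ in seq_len(b$order[k])) {
      lines <- c(lines, sprintf("CONECT%5d%5d", s1, s2),
                 sprintf("CONECT%5d%5d", s2, s1))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Binding-site residues around the ligand
#'
#' A residue belongs to the site when any of its atoms lies within `radius`
#' of any ligand atom (closed boundary: a distance exactly equal to the
#' radius counts).
#'
#' @param complex a `pharm_complex`.
#' @param radius cutoff in angstrom (default 12).
#' @return data frame of site residues (`chain`, `resno`, `resname`,
#'   `label`, `min_dist`).
#' @export
binding_site <- function(complex, radius = 12.0) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  D <- cross_dist(atom_coords(complex$protein),
                  atom_coords(complex$ligand$atoms))
  mind <- apply(D, 1, min)
  res <- residue_index(complex$protein)
  key <- residue_key(complex$protein)
  res$min_dist <- vapply(res$key, function(k) min(mind[key == k]), numeric(1))
  out <- res[res$min_dist <= radius, c("chain", "resno", "resname", "label",
                                       "min_dist")]
  rownames(out) <- NULL
  out
}

#' Apply a rigid transform to a whole complex
#' @param complex a `pharm_complex`.
#' @param tf a [rigid_transform()]; protein and ligand move together.
#' @return the transformed complex.
#' @export
transform_complex <- function(complex, tf) {
  complex$protein <- set_atom_coords(
    complex$protein, apply_transform(atom_coords(complex$protein), tf))
  complex$ligand$atoms <- set_atom_coords(
    complex$ligand$atoms,
    apply_transform(atom_coords(complex$ligand$atoms), tf))
  complex
}

# CA coordinates for a set of residue identifiers "chain:resno"
.ca_coords <- function(complex, ids) {
  pr <- complex$protein
  out <- matrix(NA_real_, nrow = length(ids), ncol = 3)
  for (k in seq_along(ids)) {
    parts <- strsplit(ids[k], ":", fixed = TRUE)[[1]]
    sel <- pr$chain == parts[1] & pr$resno == as.integer(parts[2]) &
      pr$name == "CA"
    if (!any(sel)) return(NULL)
    out[k, ] <- as.numeric(pr[which(sel)[1], c("x", "y", "z")])
  }
  out
}

#' Superpose a complex onto a reference
#'
#' Pairwise CA-based Kabsch superposition: the supplied residue pairing
#' names matching residues in mobile and reference; their CA atoms define
#' the least-squares fit and the whole mobile complex (protein plus ligand)
#' moves rigidly.
#'
#' @param mobile,reference `pharm_complex` objects.
#' @param pairing data frame with character columns `mobile` and
#'   `reference`, residue identifiers of the form `"chain:resno"`; at least
#'   3 rows.
#' @return list with `complex` (transformed mobile), `rmsd` (CA rmsd after
#'   fit, angstrom) and `transform`.
#' @export
superpose_to_reference <- function(mobile, reference, pairing) {
  stopifnot(is.data.frame(pairing), all(c("mobile", "reference") %in%
                                          names(pairing)))
  if (nrow(pairing) < 3L) stop("pairing must name at least 3 residues")
  P <- .ca_coords(mobile, pairing$mobile)
  Q <- .ca_coords(reference, pairing$reference)
  if (is.null(P) || is.null(Q)) stop("pairing unresolved")
  fit <- kabsch(P, Q)
  list(complex = transform_complex(mobile, fit$transform),
       rmsd = fit$rmsd, transform = fit$transform)
}
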