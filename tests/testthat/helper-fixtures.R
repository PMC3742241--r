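# Shared in-code fixtures: tiny molecules with known feature content, a toy
# PDB file, and small planted complexes. Everything is built fresh at test
# time; no binary fixtures.

make_mol <- function(elements, coords, bonds = NULL, charges = NULL,
                     multi_fragment = FALSE) {
  n <- length(elements)
  if (is.null(charges)) charges <- rep(0L, n)
  atoms <- atom_table(
    serial = seq_len(n), name = paste0(elements, seq_len(n)),
    element = elements, x = coords[, 1], y = coords[, 2], z = coords[, 3],
    resname = rep("LIG", n), resno = rep(1L, n), chain = "L",
    het = rep(TRUE, n), charge = as.integer(charges)
  )
  ligand_molecule(atoms, bonds, multi_fragment = multi_fragment)
}

mol_benzene <- function(center = c(0, 0, 0)) {
  ang <- 2 * pi * (0:5) / 6
  coords <- cbind(1.39 * cos(ang), 1.39 * sin(ang), 0)
  coords <- sweep(coords, 2, -center)
  make_mol(rep("C", 6), coords,
           data.frame(i = 1:6, j = c(2:6, 1L),
                      order = rep(c(2L, 1L), 3)))
}

mol_methylamine <- function(center = c(0, 0, 0)) {
  coords <- sweep(rbind(c(0, 0, 0), c(1.45, 0, 0)), 2, -center)
  make_mol(c("N", "C"), coords, data.frame(i = 1L, j = 2L, order = 1L))
}

mol_acetate <- function(center = c(0, 0, 0)) {
  coords <- sweep(rbind(c(1.9, 0, 0), c(0.4, 0, 0), c(-0.2, 1.1, 0),
                        c(-0.2, -1.1, 0)), 2, -center)
  make_mol(c("C", "C", "O", "O"), coords,
           data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                      order = c(1L, 2L, 1L)),
           charges = c(0L, 0L, 0L, -1L))
}

mol_ethanol <- function() {
  make_mol(c("C", "C", "O"), rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.1, 0)),
           data.frame(i = c(1L, 2L), j = c(2L, 3L), order = c(1L, 1L)))
}

# six hydroxyls on a hexane backbone: fails the donor gate on purpose
mol_hexaol <- function() {
  n <- 6
  cc <- cbind(1.5 * (0:(n - 1)), 0, 0)
  oo <- cbind(1.5 * (0:(n - 1)), 1.4, 0)
  make_mol(c(rep("C", n), rep("O", n)), rbind(cc, oo),
           data.frame(i = c(1:(n - 1), 1:n), j = c(2:n, n + 1:n),
                      order = 1L))
}

make_protein <- function(name, element, resname, resno, xyz,
                         chain = "A") {
  n <- length(name)
  atom_table(serial = seq_len(n), name = name, element = element,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], resname = resname,
             resno = as.integer(resno), chain = chain,
             het = rep(FALSE, n), charge = rep(0L, n))
}

make_complex_obj <- function(protein, ligand, id = "TEST") {
  structure(list(complex_id = id, protein = protein, ligand = ligand,
                 removed = list(waters = 0L, ions = 0L)),
            class = "pharm_complex")
}

# planted donor (amine N at hbd_center, backbone O at 2.9 A) and planted
# hydrophobe (propane centroid at hyd_center, CB carbon at 4.0 A)
planted_hbd_hyd_complex <- function(hbd_center = c(0, 0, 0),
                                    hyd_center = c(10, 0, 0), id = "PLT") {
  lig <- make_mol(
    c("N", "C", "C", "C", "C"),
    rbind(hbd_center, hbd_center + c(-1.45, 0, 0),
          hyd_center + c(-1.5, 0, 0), hyd_center, hyd_center + c(1.5, 0, 0)),
    data.frame(i = c(1L, 3L, 4L), j = c(2L, 4L, 5L), order = 1L),
    multi_fragment = TRUE
  )
  prot <- make_protein(
    c("O", "CB"), c("O", "C"), c("GLY", "ALA"), c(11L, 12L),
    rbind(hbd_center + c(2.9, 0, 0), hyd_center + c(0, 4.0, 0))
  )
  make_complex_obj(prot, lig, id)
}

toy_pdb_lines <- function() {
  fmt <- function(rec, serial, name, resname, chain, resno, x, y, z, elem) {
    sprintf("%-6s%5d  %-3s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s  ",
            rec, serial, name, " ", resname, chain, resno, " ", x, y, z,
            1, 0, elem)
  }
  c(
    fmt("ATOM", 1, "N", "GLY", "A", 1, 0, 0, 0, "N"),
    fmt("ATOM", 2, "CA", "GLY", "A", 1, 1.5, 0, 0, "C"),
    fmt("ATOM", 3, "C", "GLY", "A", 1, 2.3, 1.2, 0, "C"),
    fmt("ATOM", 4, "O", "GLY", "A", 1, 3.5, 1.2, 0, "O"),
    fmt("ATOM", 5, "CB", "ALA", "A", 2, 0, 4.0, 0, "C"),
    fmt("HETATM", 6, "O", "HOH", "W", 101, 20, 0, 0, "O"),
    fmt("HETATM", 7, "O", "HOH", "W", 102, 21, 0, 0, "O"),
    fmt("HETATM", 8, "O", "HOH", "W", 103, 22, 0, 0, "O"),
    fmt("HETATM", 9, "NA", "NA", "I", 201, 25, 0, 0, "Na"),
    fmt("HETATM", 10, "C1", "MSP", "L", 301, 5, 5, 0, "C"),
    fmt("HETATM", 11, "C2", "MSP", "L", 301, 6.5, 5, 0, "C"),
    fmt("HETATM", 12, "N1", "MSP", "L", 301, 7.2, 6.2, 0, "N"),
    fmt("HETATM", 13, "O1", "MSP", "L", 301, 4.3, 6.1, 0, "O"),
    "CONECT   10   11", "CONECT   11   10",
    "CONECT   11   12", "CONECT   12   11",
    "CONECT   10   13", "CONECT   13   10",
    "END"
  )
}

random_rigid <- function() {
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  rigid_transform(Q, rnorm(3, sd = 10))
}

# small consensus model straight from a hand-written cluster table
toy_model <- function(feats, tolerance = 1.6, evs = NULL) {
  sel <- data.frame(
    cluster_id = feats$id, kind = feats$kind, x = feats$x, y = feats$y,
    z = feats$z, tolerance = tolerance,
    count = rep(10L, nrow(feats)), frequency = rep(71L, nrow(feats)),
    stringsAsFactors = FALSE
  )
  build_model(sel, evs, n_complexes = 14L)
}

# deterministic consensus model + library used across mapping tests
table_pattern_model <- function(seed = 11) {
  spec <- fixture_spec(seed = seed)
  ens <- make_complex_ensemble(spec)
  pooled <- do.call(rbind, lapply(ens, perceive))
  cl <- cluster_features(pooled, n_complexes = spec$n_complexes)
  build_model(select_clusters(cl), excluded_volumes_for(ens),
              n_complexes = spec$n_complexes,
              provenance = vapply(ens, `[[`, "", "complex_id"))
}
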