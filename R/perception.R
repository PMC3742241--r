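# Pharmacophore feature perception. Chemistry-only candidate features are
# read off the ligand's bond graph; a candidate survives only when the
# receptor confirms the corresponding interaction (hydrogen bond, apolar
# contact, or a complementary charged group within range). All cutoffs are
# collected in a perception_rules block so the conventions are explicit.

#' Perception rule set
#'
#' All geometric cutoffs used during feature perception, hydrogen-bond
#' detection and excluded-volume construction, with Catalyst-style
#' defaults. Units are angstrom (distances, tolerances) and degrees
#' (angles).
#'
#' @param hbond_max_da maximum donor-acceptor distance for a hydrogen bond.
#' @param hbond_min_angle minimum D-H...A angle, applied only when the
#'   donor hydrogen is present in the structure.
#' @param hyd_contact maximum distance from a hydrophobic centroid to a
#'   protein apolar carbon.
#' @param ion_contact maximum distance from an ionizable feature to the
#'   complementary charged protein group.
#' @param tolerance radius of the feature tolerance sphere.
#' @param ev_contact ligand-protein distance defining excluded-volume
#'   candidate atoms.
#' @param ev_radius radius of each excluded-volume sphere.
#' @param ev_merge candidates closer than this are merged.
#' @param cluster_radius consensus clustering radius (see
#'   [cluster_features()]).
#' @return object of class `perception_rules`.
#' @export
perception_rules <- function(hbond_max_da = 3.5, hbond_min_angle = 120,
                             hyd_contact = 4.5, ion_contact = 5.5,
                             tolerance = 1.6, ev_contact = 5.0,
                             ev_radius = 1.2, ev_merge = 1.0,
                             cluster_radius = 2.0) {
  stopifnot(hbond_max_da > 0, hyd_contact > 0, ion_contact > 0,
            tolerance > 0, ev_contact > 0, ev_radius > 0, ev_merge >= 0,
            cluster_radius > 0, hbond_min_angle >= 0, hbond_min_angle <= 180)
  structure(as.list(environment()), class = "perception_rules")
}

#' Read perception rules from a YAML config block
#' @param path YAML file whose top-level keys match the arguments of
#'   [perception_rules()].
#' @return a `perception_rules` object.
#' @export
read_rules <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
  vals <- yaml::read_yaml(path)
  do.call(perception_rules, vals[names(vals) %in%
                                   names(formals(perception_rules))])
}

.feature_kinds <- c("HBD", "HBA", "HYD", "POS", "NEG")

# empty features frame; `atoms` is a list column of defining atom indices
features_frame <- function() {
  out <- data.frame(
    kind = character(), x = numeric(), y = numeric(), z = numeric(),
    tolerance = numeric(), dx = numeric(), dy = numeric(), dz = numeric(),
    complex_id = character(), contacts = character(),
    stringsAsFactors = FALSE
  )
  out$atoms <- list()
  out
}

.feature_row <- function(kind, center, atoms, tolerance = NA_real_,
                         direction = c(NA_real_, NA_real_, NA_real_),
                         complex_id = NA_character_,
                         contacts = NA_character_) {
  out <- data.frame(
    kind = kind, x = center[1], y = center[2], z = center[3],
    tolerance = tolerance, dx = direction[1], dy = direction[2],
    dz = direction[3], complex_id = complex_id, contacts = contacts,
    stringsAsFactors = FALSE
  )
  out$atoms <- list(as.integer(atoms))
  out
}

feature_coords <- function(features) {
  as.matrix(features[, c("x", "y", "z"), drop = FALSE])
}

#' Chemistry-only candidate feature points of a ligand
#'
#' Applies functional-group rules to the ligand alone, with no receptor in
#' sight: donors at N/O/S bearing hydrogen; acceptors at N/O with an
#' available lone pair (amide nitrogens, ring N-H and protonatable amines
#' excluded); hydrophobes at centroids of all-carbon rings and of chains of
#' at least three contiguous non-polar carbons; positive ionizable points
#' at protonatable amines, guanidines, quaternary and formally positive
#' nitrogens; negative ionizable points at carboxylate/sulfonate/
#' phosphonate groups and formally negative atoms. Ionization follows a
#' pH 7.4 functional-group lookup, not a pKa calculation.
#'
#' @param lig a [ligand_molecule()] with perceived bonds.
#' @return features data frame (kind, center, defining atom indices);
#'   tolerance and contacts are filled in later by [perceive()].
#' @export
ligand_feature_points <- function(lig) {
  at <- lig$atoms
  n <- nrow(at)
  if (n > 1L && nrow(lig$bonds) == 0L) stop("bond perception required")
  elem <- toupper(at$element)
  chg <- at$charge
  nH <- total_h(lig)
  nb <- ligand_neighbors(lig)
  osum <- bond_order_sum(lig)
  xyz <- atom_coords(at)
  rings <- ligand_rings(lig)
  ringflag <- logical(n)
  for (r in rings) ringflag[r] <- TRUE

  # neighbor C carrying a double bond to O (amide-type) or to N (amidine)
  dbl_to <- function(i, target) {
    b <- lig$bonds
    hits <- c(b$j[b$i == i & b$order >= 2L], b$i[b$j == i & b$order >= 2L])
    any(elem[hits] %in% target)
  }
  adj_carbonyl <- vapply(seq_len(n), function(i) {
    any(vapply(nb[[i]], function(j) elem[j] == "C" && dbl_to(j, "O"),
               logical(1)))
  }, logical(1))
  adj_amidine <- vapply(seq_len(n), function(i) {
    any(vapply(nb[[i]], function(j) elem[j] == "C" && dbl_to(j, "N"),
               logical(1)))
  }, logical(1))
  all_single <- vapply(seq_len(n), function(i) {
    b <- lig$bonds
    ords <- c(b$order[b$i == i], b$order[b$j == i])
    length(ords) == 0L || all(ords == 1L)
  }, logical(1))

  out <- features_frame()
  add <- function(row) out <<- rbind(out, row)

  # positive ionizable: formal positives, protonatable amines, guanidines
  pos_atoms <- integer()
  for (i in which(elem == "N")) {
    if (chg[i] > 0L) { pos_atoms <- c(pos_atoms, i); next }
    if (chg[i] == 0L && all_single[i] && !adj_carbonyl[i] &&
        !adj_amidine[i] && length(nb[[i]]) <= 3L) {
      pos_atoms <- c(pos_atoms, i)
    }
  }
  pos_atoms <- c(pos_atoms, setdiff(which(chg > 0L), pos_atoms))
  guanidine_c <- integer()
  for (i in which(elem == "C")) {
    nns <- nb[[i]][elem[nb[[i]]] == "N"]
    if (length(nns) == 3L && dbl_to(i, "N")) guanidine_c <- c(guanidine_c, i)
  }
  for (i in sort(unique(pos_atoms))) {
    add(.feature_row("POS", xyz[i, ], i))
  }
  for (i in guanidine_c) {
    grp <- c(i, nb[[i]][elem[nb[[i]]] == "N"])
    add(.feature_row("POS", colMeans(xyz[grp, , drop = FALSE]), grp))
  }

  # negative ionizable: acid groups then leftover formal negatives
  acid_oxygens <- integer()
  for (i in which(elem %in% c("C", "S", "P"))) {
    term_o <- nb[[i]][elem[nb[[i]]] == "O" &
                        vapply(nb[[i]], function(j) length(nb[[j]]) == 1L,
                               logical(1))]
    if (length(term_o) >= 2L &&
        (any(chg[term_o] < 0L) || any(nH[term_o] >= 1L))) {
      grp <- c(i, term_o)
      add(.feature_row("NEG", colMeans(xyz[grp, , drop = FALSE]), grp))
      acid_oxygens <- c(acid_oxygens, term_o)
    }
  }
  for (i in setdiff(which(chg < 0L), acid_oxygens)) {
    add(.feature_row("NEG", xyz[i, ], i))
  }

  # hydrogen-bond donors
  for (i in which(elem %in% c("N", "O", "S") & nH >= 1L)) {
    add(.feature_row("HBD", xyz[i, ], i))
  }

  # hydrogen-bond acceptors
  for (i in seq_len(n)) {
    if (elem[i] == "O" && chg[i] <= 0L) {
      add(.feature_row("HBA", xyz[i, ], i))
    } else if (elem[i] == "N" && chg[i] <= 0L && !(i %in% pos_atoms) &&
               !adj_carbonyl[i] && !(nH[i] >= 1L && ringflag[i]) &&
               osum[i] + nH[i] <= 3L) {
      add(.feature_row("HBA", xyz[i, ], i))
    }
  }

  # hydrophobes: all-carbon rings
  for (r in rings) {
    if (all(elem[r] == "C")) {
      add(.feature_row("HYD", colMeans(xyz[r, , drop = FALSE]), r))
    }
  }
  # hydrophobes: chains of >= 3 contiguous non-polar, non-ring carbons
  nonpolar <- vapply(seq_len(n), function(i) {
    elem[i] == "C" && !ringflag[i] &&
      all(elem[nb[[i]]] %in% c("C", "H"))
  }, logical(1))
  if (any(nonpolar)) {
    g <- ligand_graph(lig)
    sub <- igraph::induced_subgraph(g, which(nonpolar))
    comps <- igraph::components(sub)
    for (cid in seq_len(comps$no)) {
      mem <- as.integer(igraph::V(sub)$name[comps$membership == cid])
      if (length(mem) >= 3L) {
        add(.feature_row("HYD", colMeans(xyz[mem, , drop = FALSE]), mem))
      }
    }
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------

.protein_acceptor <- function(prot) {
  toupper(prot$element) == "O" |
    (toupper(prot$element) == "N" & prot$name %in% c("ND1", "NE2"))
}

.protein_donor <- function(prot) {
  (toupper(prot$element) %in% c("N", "S")) |
    prot$name %in% c("OG", "OG1", "OH")
}

.angle_deg <- function(a, b, c) {
  # angle at b in degrees
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Detect ligand-protein hydrogen bonds
#'
#' Geometric criterion: donor-acceptor distance at most `max_da`; when the
#' donor hydrogen is present as an atom, the D-H...A angle must also reach
#' `min_angle`. Crystal structures usually lack hydrogens, in which case
#' the distance criterion alone applies. Both directions are searched
#' (ligand donor to protein acceptor and protein donor to ligand
#' acceptor).
#'
#' @param complex a `pharm_complex` in the common frame.
#' @param max_da maximum donor-acceptor distance (angstrom).
#' @param min_angle minimum D-H...A angle (degrees), used only with an
#'   explicit hydrogen.
#' @return data frame, one row per hydrogen bond: donor/acceptor owner
#'   (`"ligand"`/`"protein"`), atom indices within the owner table,
#'   serials, residue labels, distance and angle (`NA` without hydrogen).
#' @export
detect_hbonds <- function(complex, max_da = 3.5, min_angle = 120) {
  lig <- complex$ligand
  lat <- lig$atoms
  prot <- complex$protein
  lelem <- toupper(lat$element)
  pelem <- toupper(prot$element)
  nH <- total_h(lig)
  lxyz <- atom_coords(lat)
  pxyz <- atom_coords(prot)
  plabel <- residue_label(prot$resname, prot$resno)
  llabel <- residue_label(lat$resname, lat$resno)

  lig_donor <- which(lelem %in% c("N", "O", "S") & nH >= 1L)
  lig_accept <- which(lelem %in% c("N", "O"))
  prot_accept <- which(.protein_acceptor(prot) & pelem != "H")
  prot_donor <- which(.protein_donor(prot) & pelem != "H")

  nb <- ligand_neighbors(lig)
  lig_h_of <- function(i) nb[[i]][lelem[nb[[i]]] == "H"]
  prot_h <- which(pelem == "H")
  prot_h_of <- function(i) {
    if (length(prot_h) == 0L) return(integer())
    d <- cross_dist(rbind(pxyz[i, ]), pxyz[prot_h, , drop = FALSE])
    prot_h[d[1, ] <= 1.25]
  }

  rows <- list()
  push <- function(downer, didx, aowner, aidx, dist, ang) {
    rows[[length(rows) + 1L]] <<- data.frame(
      donor_owner = downer, donor_index = didx,
      donor_serial = if (downer == "ligand") lat$serial[didx] else prot$serial[didx],
      donor_res = if (downer == "ligand") llabel[didx] else plabel[didx],
      acceptor_owner = aowner, acceptor_index = aidx,
      acceptor_serial = if (aowner == "ligand") lat$serial[aidx] else prot$serial[aidx],
      acceptor_res = if (aowner == "ligand") llabel[aidx] else plabel[aidx],
      distance = dist, angle = ang, stringsAsFactors = FALSE
    )
  }
  check_angle <- function(dpos, hs, hxyz, apos) {
    if (length(hs) == 0L) return(NA_real_)
    angs <- vapply(seq_along(hs), function(k) {
      .angle_deg(dpos, hxyz[k, ], apos)
    }, numeric(1))
    max(angs)
  }

  if (length(lig_donor) > 0L && length(prot_accept) > 0L) {
    D <- cross_dist(lxyz[lig_donor, , drop = FALSE],
                    pxyz[prot_accept, , drop = FALSE])
    for (a in seq_along(lig_donor)) {
      for (b in seq_along(prot_accept)) {
        if (D[a, b] > max_da) next
        i <- lig_donor[a]; j <- prot_accept[b]
        hs <- lig_h_of(i)
        ang <- check_angle(lxyz[i, ], hs, lxyz[hs, , drop = FALSE], pxyz[j, ])
        if (!is.na(ang) && ang < min_angle) next
        push("ligand", i, "protein", j, D[a, b], ang)
      }
    }
  }
  if (length(prot_donor) > 0L && length(lig_accept) > 0L) {
    D <- cross_dist(pxyz[prot_donor, , drop = FALSE],
                    lxyz[lig_accept, , drop = FALSE])
    for (a in seq_along(prot_donor)) {
      for (b in seq_along(lig_accept)) {
        if (D[a, b] > max_da) next
        i <- prot_donor[a]; j <- lig_accept[b]
        hs <- prot_h_of(i)
        ang <- check_angle(pxyz[i, ], hs, pxyz[hs, , drop = FALSE], lxyz[j, ])
        if (!is.na(ang) && ang < min_angle) next
        push("protein", i, "ligand", j, D[a, b], ang)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      donor_owner = character(), donor_index = integer(),
      donor_serial = integer(), donor_res = character(),
      acceptor_owner = character(), acceptor_index = integer(),
      acceptor_serial = integer(), acceptor_res = character(),
      distance = numeric(), angle = numeric(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Perceive interaction-filtered pharmacophore features of a complex
#'
#' A chemistry-only candidate from [ligand_feature_points()] is retained
#' only when the receptor confirms the interaction: donors/acceptors need a
#' detected hydrogen bond involving the candidate atom; hydrophobes need a
#' protein apolar carbon within `hyd_contact` of the centroid; positive
#' ionizable points need a protein carboxylate oxygen, and negative ones a
#' protein basic nitrogen, within `ion_contact`. Retained features record
#' the contacting residues and get their tolerance sphere from the rules.
#'
#' @param complex a `pharm_complex` in the common frame.
#' @param rules a [perception_rules()] block.
#' @return features data frame (possibly empty) with contacts, tolerance,
#'   direction (donor-to-acceptor unit vector for HBD/HBA) and
#'   `complex_id` filled in.
#' @export
perceive <- function(complex, rules = perception_rules()) {
  cand <- ligand_feature_points(complex$ligand)
  out <- features_frame()
  if (nrow(cand) == 0L) return(out)
  prot <- complex$protein
  pelem <- toupper(prot$element)
  pxyz <- atom_coords(prot)
  plabel <- residue_label(prot$resname, prot$resno)
  hb <- detect_hbonds(complex, rules$hbond_max_da, rules$hbond_min_angle)

  apolar_c <- which(pelem == "C" & !(prot$name %in% c("C", "CA")))
  carbox_o <- which(prot$name %in% c("OD1", "OD2", "OE1", "OE2"))
  basic_n <- which(prot$name %in% c("NZ", "NH1", "NH2", "NE", "ND1", "NE2"))

  unit <- function(v) {
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) c(NA_real_, NA_real_, NA_real_) else v / nv
  }

  for (k in seq_len(nrow(cand))) {
    row <- cand[k, , drop = FALSE]
    kind <- row$kind
    center <- as.numeric(row[1, c("x", "y", "z")])
    atoms <- row$atoms[[1]]
    contacts <- character()
    direction <- c(NA_real_, NA_real_, NA_real_)
    keep <- FALSE
    if (kind == "HBD") {
      m <- hb[hb$donor_owner == "ligand" & hb$donor_index %in% atoms, ,
              drop = FALSE]
      if (nrow(m) > 0L) {
        keep <- TRUE
        contacts <- unique(m$acceptor_res)
        best <- which.min(m$distance)
        apos <- pxyz[m$acceptor_index[best], ]
        direction <- unit(apos - center)
      }
    } else if (kind == "HBA") {
      m <- hb[hb$acceptor_owner == "ligand" & hb$acceptor_index %in% atoms, ,
              drop = FALSE]
      if (nrow(m) > 0L) {
        keep <- TRUE
        contacts <- unique(m$donor_res)
        best <- which.min(m$distance)
        dpos <- pxyz[m$donor_index[best], ]
        direction <- unit(center - dpos)
      }
    } else if (kind == "HYD") {
      if (length(apolar_c) > 0L) {
        d <- cross_dist(rbind(center), pxyz[apolar_c, , drop = FALSE])[1, ]
        sel <- apolar_c[d <= rules$hyd_contact]
        if (length(sel) > 0L) {
          keep <- TRUE
          contacts <- unique(plabel[sel])
        }
      }
    } else if (kind == "POS") {
      if (length(carbox_o) > 0L) {
        d <- cross_dist(rbind(center), pxyz[carbox_o, , drop = FALSE])[1, ]
        sel <- carbox_o[d <= rules$ion_contact]
        if (length(sel) > 0L) {
          keep <- TRUE
          contacts <- unique(plabel[sel])
        }
      }
    } else if (kind == "NEG") {
      if (length(basic_n) > 0L) {
        d <- cross_dist(rbind(center), pxyz[basic_n, , drop = FALSE])[1, ]
        sel <- basic_n[d <= rules$ion_contact]
        if (length(sel) > 0L) {
          keep <- TRUE
          contacts <- unique(plabel[sel])
        }
      }
    }
    if (keep) {
      out <- rbind(out, .feature_row(
        kind, center, atoms, tolerance = rules$tolerance,
        direction = direction, complex_id = complex$complex_id,
        contacts = paste(sort(contacts), collapse = ";")
      ))
    }
  }
  rownames(out) <- NULL
  out
}

# greedy agglomerative merging of points; returns list of member index
# vectors. `closed` controls whether the radius itself still merges.
greedy_cluster <- function(X, radius, closed = TRUE) {
  X <- rbind(X)
  n <- nrow(X)
  if (n == 0L) return(list())
  members <- as.list(seq_len(n))
  cent <- X
  repeat {
    m <- nrow(cent)
    if (m < 2L) break
    D <- cross_dist(cent, cent)
    diag(D) <- Inf
    idx <- which.min(D)
    dmin <- D[idx]
    ok <- if (closed) dmin <= radius else dmin < radius
    if (!ok) break
    j <- ((idx - 1L) %/% m) + 1L
    i <- idx - (j - 1L) * m
    a <- min(i, j); b <- max(i, j)
    members[[a]] <- c(members[[a]], members[[b]])
    members[[b]] <- NULL
    cent <- do.call(rbind, lapply(members, function(mm) {
      colMeans(X[mm, , drop = FALSE])
    }))
  }
  members
}

#' Excluded-volume spheres from an ensemble of complexes
#'
#' One candidate sphere per binding-site protein heavy atom lying within
#' `contact_cutoff` of any ligand atom of any complex; candidates closer
#' than `merge_radius` collapse to their centroid. Each sphere keeps the
#' residue label of its first contributing atom.
#'
#' @param complexes list of `pharm_complex` objects in a common frame.
#' @param contact_cutoff ligand-protein contact distance (angstrom).
#' @param radius sphere radius (angstrom).
#' @param merge_radius merge distance (strict less-than).
#' @return data frame of spheres (`x`, `y`, `z`, `radius`, `residue`,
#'   `n_merged`).
#' @export
excluded_volumes_for <- function(complexes, contact_cutoff = 5.0,
                                 radius = 1.2, merge_radius = 1.0) {
  if (length(complexes) == 0L) stop("no structures")
  cand_xyz <- NULL
  cand_res <- character()
  for (cx in complexes) {
    prot <- cx$protein
    heavy <- toupper(prot$element) != "H"
    D <- cross_dist(atom_coords(prot), atom_coords(cx$ligand$atoms))
    sel <- which(heavy & apply(D, 1, min) <= contact_cutoff)
    if (length(sel) > 0L) {
      cand_xyz <- rbind(cand_xyz, atom_coords(prot)[sel, , drop = FALSE])
      cand_res <- c(cand_res,
                    residue_label(prot$resname[sel], prot$resno[sel]))
    }
  }
  if (is.null(cand_xyz)) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric(), residue = character(),
                      n_merged = integer(), stringsAsFactors = FALSE))
  }
  members <- greedy_cluster(cand_xyz, merge_radius, closed = FALSE)
  out <- do.call(rbind, lapply(members, function(mm) {
    ctr <- colMeans(cand_xyz[mm, , drop = FALSE])
    data.frame(x = ctr[1], y = ctr[2], z = ctr[3], radius = radius,
               residue = cand_res[min(mm)], n_merged = length(mm),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
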