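# Synthetic, download-free fixtures. The generators plant minimal chemical
# groups (with the matching receptor partner atoms) at well-separated sites
# so that perception, clustering, screening and filtering can be exercised
# end-to-end with known ground truth. Everything is driven by one seed and
# is byte-deterministic.

#' Default planted-site pattern
#'
#' A 19-site arrangement over a 14-complex ensemble: two hydrogen-bond
#' acceptors, eight donors, six hydrophobes, two positive and one negative
#' ionizable site, with per-site multiplicities spanning 1 to 12 so that
#' the resulting cluster frequencies straddle a 60 percent retention
#' threshold (exactly six sites exceed it).
#'
#' @return data frame with columns `id`, `kind`, `multiplicity`.
#' @export
default_planted_sites <- function() {
  data.frame(
    id = c("A1", "A2", paste0("D", 1:8), paste0("H", 1:6), "Pos1", "Pos2",
           "Neg1"),
    kind = c("HBA", "HBA", rep("HBD", 8), rep("HYD", 6), "POS", "POS",
             "NEG"),
    multiplicity = c(1L, 1L, 11L, 9L, 2L, 1L, 1L, 1L, 1L, 1L,
                     12L, 10L, 9L, 5L, 2L, 1L, 9L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Fixture specification
#'
#' @param seed integer RNG seed; every random draw in the generators flows
#'   from it.
#' @param n_complexes ensemble size (default 14).
#' @param sites data frame `id`, `kind`, `multiplicity` and optionally
#'   `x`, `y`, `z`; missing coordinates are laid out on a cubic lattice
#'   with the given `spacing`.
#' @param noise_sd per-complex Gaussian positional noise on each planted
#'   site (angstrom); fragment and receptor partner move together, so the
#'   interaction survives while cluster members scatter.
#' @param spacing lattice spacing for auto-placed sites (angstrom).
#' @param library numeric pair `(n_actives, n_decoys)` used by default in
#'   [make_library()].
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_complexes = 14L,
                         sites = default_planted_sites(), noise_sd = 0.3,
                         spacing = 12, library = c(10L, 90L)) {
  stopifnot(noise_sd >= 0, n_complexes >= 1L)
  if (any(sites$multiplicity > n_complexes)) {
    stop("multiplicity exceeds n_complexes")
  }
  if (!all(c("x", "y", "z") %in% names(sites))) {
    grid <- expand.grid(x = 0:2, y = 0:2, z = 0:2)
    grid <- grid[seq_len(nrow(sites)), ]
    # fixed irregular offsets (up to 1.5 A per axis) break the lattice
    # symmetry so no two site arrangements are related by a rigid motion
    k <- seq_len(nrow(sites))
    sites$x <- grid$x * spacing + (((k * 7) %% 29) / 29 - 0.5) * 3
    sites$y <- grid$y * spacing + (((k * 11) %% 29) / 29 - 0.5) * 3
    sites$z <- grid$z * spacing + (((k * 13) %% 29) / 29 - 0.5) * 3
  }
  structure(list(seed = as.integer(seed),
                 n_complexes = as.integer(n_complexes), sites = sites,
                 noise_sd = noise_sd, library = library),
            class = "fixture_spec")
}

# random proper rotation from the seeded RNG stream
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Local geometry of the planted chemical group for each feature kind:
# ligand atom offsets (feature point at the local origin), bonds, formal
# charges and the receptor partner atom that makes the interaction real.
.site_blueprint <- function(kind) {
  switch(kind,
    HBD = list(  # methylamine-like donor; backbone O acceptor at 2.9 A
      elements = c("N", "C"), charges = c(0L, 0L),
      offsets = rbind(c(0, 0, 0), c(-1.45, 0, 0)),
      bonds = data.frame(i = 1L, j = 2L, order = 1L),
      partner = list(name = "O", element = "O", resname = "GLY",
                     offset = c(2.9, 0, 0))
    ),
    HBA = list(  # carbonyl acceptor; backbone N donor at 2.9 A
      elements = c("O", "C"), charges = c(0L, 0L),
      offsets = rbind(c(0, 0, 0), c(-1.23, 0, 0)),
      bonds = data.frame(i = 1L, j = 2L, order = 2L),
      partner = list(name = "N", element = "N", resname = "GLY",
                     offset = c(2.9, 0, 0))
    ),
    HYD = list(  # three-carbon chain; sidechain CB contact at 4.0 A
      elements = c("C", "C", "C"), charges = c(0L, 0L, 0L),
      offsets = rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0)),
      bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L), order = c(1L, 1L)),
      partner = list(name = "CB", element = "C", resname = "ALA",
                     offset = c(0, 4.0, 0))
    ),
    POS = list(  # protonatable amine; aspartate OD1 at 4.5 A (no H-bond)
      elements = c("N", "C"), charges = c(0L, 0L),
      offsets = rbind(c(0, 0, 0), c(1.45, 0, 0)),
      bonds = data.frame(i = 1L, j = 2L, order = 1L),
      partner = list(name = "OD1", element = "O", resname = "ASP",
                     offset = c(0, 4.5, 0))
    ),
    NEG = list(  # carboxylate (group centroid at origin); lysine NZ at 4.5 A
      elements = c("C", "O", "O", "C"), charges = c(0L, 0L, -1L, 0L),
      offsets = rbind(c(0.4, 0, 0), c(-0.2, 1.1, 0), c(-0.2, -1.1, 0),
                      c(1.9, 0, 0)),
      bonds = data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                         order = c(2L, 1L, 1L)),
      partner = list(name = "NZ", element = "N", resname = "LYS",
                     offset = c(0, 0, 4.5))
    ),
    stop("unknown feature kind: ", kind)
  )
}

.anchor_positions <- rbind(c(60, 0, 0), c(0, 60, 0), c(0, 0, 60),
                           c(60, 60, 60))

#' Generate a synthetic complex ensemble with planted features
#'
#' For each planted site, exactly `multiplicity` complexes (drawn from the
#' seeded RNG) receive the site's chemical group plus its receptor partner
#' atom, jointly shifted by Gaussian noise, so that perception detects the
#' planted kind at the planted position in exactly those complexes. Every
#' complex also carries four fixed CA anchor residues usable for
#' superposition pairings. With `scatter = TRUE` each complex is
#' additionally moved by a random rigid transform (the first complex stays
#' put as reference), which [superpose_to_reference()] can undo via the
#' anchors.
#'
#' @param spec a [fixture_spec()].
#' @param scatter logical; emit complexes in scattered frames instead of
#'   the common frame.
#' @return list of `pharm_complex` objects, with attributes `membership`
#'   (per-site complex indices) and `anchors` (residue identifiers usable
#'   as a superposition pairing).
#' @export
make_complex_ensemble <- function(spec, scatter = FALSE) {
  sites <- spec$sites
  S <- as.matrix(sites[, c("x", "y", "z")])
  if (nrow(S) > 1L) {
    D <- cross_dist(S, S)
    diag(D) <- Inf
    if (min(D) < 3 * perception_rules()$cluster_radius) {
      stop("sites collide")
    }
  }
  set.seed(spec$seed)
  membership <- lapply(seq_len(nrow(sites)), function(s) {
    sort(sample.int(spec$n_complexes, sites$multiplicity[s]))
  })
  names(membership) <- sites$id
  noise <- array(stats::rnorm(nrow(sites) * spec$n_complexes * 3,
                              sd = spec$noise_sd),
                 dim = c(nrow(sites), spec$n_complexes, 3))

  complexes <- vector("list", spec$n_complexes)
  for (ci in seq_len(spec$n_complexes)) {
    prot <- atom_table()
    lat <- atom_table()
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
    pserial <- 0L
    lserial <- 0L
    for (s in seq_len(nrow(sites))) {
      if (!(ci %in% membership[[s]])) next
      bp <- .site_blueprint(sites$kind[s])
      center <- S[s, ] + noise[s, ci, ]
      frag_xyz <- sweep(bp$offsets, 2, -center)
      off <- nrow(lat)
      lat <- rbind(lat, atom_table(
        serial = 5000L + lserial + seq_along(bp$elements),
        name = paste0(bp$elements, off + seq_along(bp$elements)),
        element = bp$elements, x = frag_xyz[, 1], y = frag_xyz[, 2],
        z = frag_xyz[, 3], resname = rep("LIG", length(bp$elements)),
        resno = rep(900L, length(bp$elements)), chain = "L",
        het = rep(TRUE, length(bp$elements)), charge = bp$charges
      ))
      lserial <- lserial + length(bp$elements)
      bonds <- rbind(bonds, data.frame(i = bp$bonds$i + off,
                                       j = bp$bonds$j + off,
                                       order = bp$bonds$order))
      ppos <- center + bp$partner$offset
      pserial <- pserial + 1L
      prot <- rbind(prot, atom_table(
        serial = pserial, name = bp$partner$name,
        element = bp$partner$element, x = ppos[1], y = ppos[2],
        z = ppos[3], resname = bp$partner$resname,
        resno = 100L + s, chain = "A", het = FALSE, charge = 0L
      ))
    }
    for (a in seq_len(nrow(.anchor_positions))) {
      pserial <- pserial + 1L
      prot <- rbind(prot, atom_table(
        serial = pserial, name = "CA", element = "C",
        x = .anchor_positions[a, 1], y = .anchor_positions[a, 2],
        z = .anchor_positions[a, 3], resname = "GLY",
        resno = 900L + a, chain = "A", het = FALSE, charge = 0L
      ))
    }
    lig <- ligand_molecule(lat, bonds, multi_fragment = TRUE)
    cx <- structure(
      list(complex_id = sprintf("SYN%02d", ci), protein = prot,
           ligand = lig, removed = list(waters = 0L, ions = 0L)),
      class = "pharm_complex"
    )
    if (scatter && ci > 1L) {
      tf <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 15))
      cx <- transform_complex(cx, tf)
    }
    complexes[[ci]] <- cx
  }
  attr(complexes, "membership") <- membership
  attr(complexes, "anchors") <- paste0("A:", 900L +
    seq_len(nrow(.anchor_positions)))
  complexes
}

#' Write an ensemble to PDB files
#'
#' One file per complex (`<id>.pdb`), each headed by REMARK lines that
#' record the generator seed, so regeneration is reproducible from the
#' files alone.
#'
#' @param complexes list from [make_complex_ensemble()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the headers.
#' @return character vector of file paths, invisibly.
#' @export
write_ensemble_pdb <- function(complexes, dir, seed = NA_integer_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (cx in complexes) {
    p <- file.path(dir, paste0(cx$complex_id, ".pdb"))
    write_complex_pdb(cx, p, header = c(
      sprintf("REMARK   1 SYNTHETIC COMPLEX %s", cx$complex_id),
      sprintf("REMARK   1 SEED %s", seed)))
    paths <- c(paths, p)
  }
  invisible(paths)
}

# fragment generating a candidate point of `kind` for library molecules
.library_fragment <- function(kind) {
  switch(kind,
    HYD = list(elements = c("C", "C", "C"), charges = c(0L, 0L, 0L),
               offsets = rbind(c(-1.5, 0, 0), c(0, 0, 0), c(1.5, 0, 0)),
               bonds = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                  order = c(1L, 1L))),
    HBD = list(elements = c("O", "C"), charges = c(0L, 0L),
               offsets = rbind(c(0, 0, 0), c(-1.43, 0, 0)),
               bonds = data.frame(i = 1L, j = 2L, order = 1L)),
    HBA = list(elements = c("O", "C"), charges = c(0L, 0L),
               offsets = rbind(c(0, 0, 0), c(-1.23, 0, 0)),
               bonds = data.frame(i = 1L, j = 2L, order = 2L)),
    POS = list(elements = c("N", "C"), charges = c(0L, 0L),
               offsets = rbind(c(0, 0, 0), c(1.45, 0, 0)),
               bonds = data.frame(i = 1L, j = 2L, order = 1L)),
    NEG = list(elements = c("C", "O", "O", "C"),
               charges = c(0L, 0L, -1L, 0L),
               offsets = rbind(c(0.4, 0, 0), c(-0.2, 1.1, 0),
                               c(-0.2, -1.1, 0), c(1.9, 0, 0)),
               bonds = data.frame(i = c(1L, 1L, 1L), j = c(2L, 3L, 4L),
                                  order = c(2L, 1L, 1L))),
    stop("unknown feature kind: ", kind)
  )
}

# kinds a fragment contributes as candidates besides its own
.fragment_cross_kinds <- list(
  HYD = character(), HBA = character(), POS = c("HBD"),
  HBD = c("HBA"), NEG = c("HBA")
)

.assemble_molecule <- function(model, placement_sd, skip_kind = NULL,
                               shift_kind = NULL, shift = 0) {
  feats <- model$features
  atoms <- atom_table()
  bonds <- data.frame(i = integer(), j = integer(), order = integer())
  for (k in seq_len(nrow(feats))) {
    kind <- feats$kind[k]
    if (!is.null(skip_kind) && kind == skip_kind) next
    bp <- .library_fragment(kind)
    center <- as.numeric(feats[k, c("x", "y", "z")]) +
      stats::rnorm(3, sd = placement_sd)
    if (!is.null(shift_kind) && kind == shift_kind) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      center <- center + shift * dir
    }
    R <- random_rotation()
    xyz <- sweep(bp$offsets %*% t(R), 2, -center)
    off <- nrow(atoms)
    atoms <- rbind(atoms, atom_table(
      serial = off + seq_along(bp$elements),
      name = paste0(bp$elements, off + seq_along(bp$elements)),
      element = bp$elements, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      resname = rep("LIG", length(bp$elements)),
      resno = rep(1L, length(bp$elements)), chain = "L",
      het = rep(TRUE, length(bp$elements)), charge = bp$charges
    ))
    bonds <- rbind(bonds, data.frame(i = bp$bonds$i + off,
                                     j = bp$bonds$j + off,
                                     order = bp$bonds$order))
  }
  ligand_molecule(atoms, bonds, multi_fragment = TRUE)
}

#' Generate a screening library with planted actives and decoys
#'
#' Actives carry, for every model feature, a minimal chemical group whose
#' candidate point sits at the feature center (plus small placement
#' noise), so one of their conformers maps onto all features. Decoys are
#' actives with every group of one required feature kind displaced beyond
#' tolerance (or deleted), so the all-feature requirement cannot be met.
#' Each molecule gets `n_conformers` conformers: one is the planted
#' geometry in a random rigid frame, the rest have their fragments
#' independently scrambled.
#'
#' @param model a `consensus_pharmacophore` (non-empty).
#' @param n_actives,n_decoys library composition.
#' @param seed RNG seed.
#' @param n_conformers conformers per molecule (default 3).
#' @param placement_sd Gaussian noise on planted feature points
#'   (angstrom).
#' @param decoy_kind feature kind sabotaged in decoys; by default the
#'   model kind whose candidate points cannot be rescued by the groups
#'   planted for other kinds.
#' @param decoy_shift displacement applied to the sabotaged groups
#'   (angstrom; must exceed the feature tolerance for decoys to be true
#'   decoys, and 0 turns decoys back into actives).
#' @param decoy_delete delete the groups instead of displacing them.
#' @return named list of [conformer_set()] objects (actives first), with
#'   attribute `manifest`: a data frame of `molecule_id`, `role`,
#'   `good_conformer`.
#' @export
make_library <- function(model, n_actives, n_decoys, seed = 1L,
                         n_conformers = 3L, placement_sd = 0.15,
                         decoy_kind = NULL, decoy_shift = 8.0,
                         decoy_delete = FALSE) {
  if (nrow(model$features) == 0L) stop("model has no features")
  kinds <- unique(model$features$kind)
  if (is.null(decoy_kind)) {
    contributed <- unique(unlist(.fragment_cross_kinds[kinds]))
    pref <- c("POS", "NEG", "HYD", "HBA", "HBD")
    safe <- setdiff(intersect(pref, kinds), contributed)
    decoy_kind <- if (length(safe) > 0L) safe[1] else kinds[1]
  }
  set.seed(seed)
  sets <- list()
  manifest <- data.frame(molecule_id = character(), role = character(),
                         good_conformer = integer(),
                         stringsAsFactors = FALSE)
  build <- function(id, role) {
    topo <- if (role == "active") {
      .assemble_molecule(model, placement_sd)
    } else if (decoy_delete) {
      .assemble_molecule(model, placement_sd, skip_kind = decoy_kind)
    } else {
      .assemble_molecule(model, placement_sd, shift_kind = decoy_kind,
                         shift = decoy_shift)
    }
    base <- atom_coords(topo$atoms)
    good <- sample.int(n_conformers, 1L)
    confs <- vector("list", n_conformers)
    for (cfi in seq_len(n_conformers)) {
      if (cfi == good) {
        tf <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 10))
        confs[[cfi]] <- apply_transform(base, tf)
      } else {
        # scramble fragments independently to break internal geometry
        xyz <- base
        for (comp in .fragment_components(topo)) {
          R <- random_rotation()
          ctr <- colMeans(base[comp, , drop = FALSE])
          local <- sweep(base[comp, , drop = FALSE], 2, ctr)
          xyz[comp, ] <- sweep(local %*% t(R), 2,
                               -(ctr + stats::rnorm(3, sd = 4)))
        }
        confs[[cfi]] <- xyz
      }
    }
    sets[[id]] <<- conformer_set(id, topo, confs)
    manifest <<- rbind(manifest, data.frame(
      molecule_id = id, role = role, good_conformer = good,
      stringsAsFactors = FALSE))
  }
  for (k in seq_len(n_actives)) build(sprintf("ACT%04d", k), "active")
  for (k in seq_len(n_decoys)) build(sprintf("DEC%04d", k), "decoy")
  attr(sets, "manifest") <- manifest
  attr(sets, "decoy_kind") <- decoy_kind
  sets
}

# connected components (fragments) of a ligand's bond graph
.fragment_components <- function(lig) {
  g <- ligand_graph(lig)
  comps <- igraph::components(g)
  lapply(seq_len(comps$no), function(cid) {
    as.integer(igraph::V(g)$name[comps$membership == cid])
  })
}
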