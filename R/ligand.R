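# Ligand molecules: an atom table plus an explicit bond graph. Implicit
# hydrogen counts are derived from standard valences so that donor/acceptor
# and ionization rules work on hydrogen-free crystal-structure ligands.

#' Construct a ligand molecule
#'
#' @param atoms atom table (see [atom_table()]); formal charges live in its
#'   `charge` column.
#' @param bonds data frame with integer columns `i`, `j` (1-based atom
#'   indices) and `order` (1, 2 or 3).
#' @param multi_fragment logical; `TRUE` flags a deliberately disconnected
#'   molecule (e.g. synthetic fixtures). Connectivity of unflagged
#'   molecules is checked.
#' @return object of class `ligand_molecule`.
#' @export
ligand_molecule <- function(atoms, bonds = NULL, multi_fragment = FALSE) {
  if (nrow(atoms) == 0L) stop("ligand has no atoms")
  if (is.null(bonds)) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  }
  bonds <- data.frame(i = as.integer(bonds$i), j = as.integer(bonds$j),
                      order = as.integer(bonds$order))
  if (nrow(bonds) > 0L &&
      (max(bonds$i, bonds$j) > nrow(atoms) || min(bonds$i, bonds$j) < 1L)) {
    stop("bond indices out of range")
  }
  lig <- structure(
    list(atoms = atoms, bonds = bonds, multi_fragment = isTRUE(multi_fragment)),
    class = "ligand_molecule"
  )
  if (!lig$multi_fragment && nrow(atoms) > 1L && nrow(bonds) > 0L) {
    g <- ligand_graph(lig)
    if (igraph::components(g)$no > 1L) {
      stop("disconnected ligand; set multi_fragment = TRUE if intended")
    }
  }
  lig
}

#' @export
print.ligand_molecule <- function(x, ...) {
  cat(sprintf("ligand_molecule: %d atoms, %d bonds%s\n", nrow(x$atoms),
              nrow(x$bonds), if (x$multi_fragment) " (multi-fragment)" else ""))
  invisible(x)
}

ligand_graph <- function(lig) {
  igraph::graph_from_data_frame(
    lig$bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(lig$atoms)))
  )
}

# adjacency as list of integer neighbor vectors
ligand_neighbors <- function(lig) {
  n <- nrow(lig$atoms)
  nb <- vector("list", n)
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

# sum of bond orders per atom
bond_order_sum <- function(lig) {
  n <- nrow(lig$atoms)
  s <- numeric(n)
  for (k in seq_len(nrow(lig$bonds))) {
    s[lig$bonds$i[k]] <- s[lig$bonds$i[k]] + lig$bonds$order[k]
    s[lig$bonds$j[k]] <- s[lig$bonds$j[k]] + lig$bonds$order[k]
  }
  s
}

# Default valences adjusted by formal charge. N+ gets 4, O- gets 1, etc.
.default_valence <- function(element, charge) {
  base <- c(C = 4, N = 3, O = 2, S = 2, P = 3, H = 1,
            F = 1, CL = 1, BR = 1, I = 1, B = 3, SI = 4)
  v <- base[toupper(element)]
  v[is.na(v)] <- 0
  adj <- ifelse(toupper(element) %in% c("N", "O", "S", "P"), charge, 0)
  pmax(unname(v) + adj, 0)
}

#' Implicit hydrogen counts
#'
#' Hydrogens implied by standard valences minus the explicit bond-order sum,
#' the usual convention for hydrogen-suppressed connection tables. Explicit
#' hydrogens present as atoms are respected (they consume valence through
#' their bonds).
#'
#' @param lig a [ligand_molecule()].
#' @return integer vector, one count per atom.
#' @export
implicit_h <- function(lig) {
  val <- .default_valence(lig$atoms$element, lig$atoms$charge)
  pmax(round(val - bond_order_sum(lig)), 0)
}

# explicit H neighbors per atom
explicit_h <- function(lig) {
  n <- nrow(lig$atoms)
  cnt <- integer(n)
  isH <- toupper(lig$atoms$element) == "H"
  for (k in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[k]; j <- lig$bonds$j[k]
    if (isH[j]) cnt[i] <- cnt[i] + 1L
    if (isH[i]) cnt[j] <- cnt[j] + 1L
  }
  cnt
}

total_h <- function(lig) implicit_h(lig) + explicit_h(lig)

# Covalent radii for fallback distance-based bond perception (angstrom).
.covalent_radius <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, B = 0.84, SI = 1.11
)

#' Perceive bonds from interatomic distances
#'
#' Fallback used when a PDB file carries no CONECT records: two atoms are
#' bonded when their distance is below the sum of covalent radii plus a
#' 0.45 angstrom slack. All perceived bonds are single; bond orders beyond
#' what the distance criterion can see must come from CONECT multiplicity
#' or an SDF bond block.
#'
#' @param atoms atom table of the ligand.
#' @param slack tolerance added to the covalent-radii sum (angstrom).
#' @return bond data frame (`i`, `j`, `order`).
#' @export
perceive_bonds <- function(atoms, slack = 0.45) {
  n <- nrow(atoms)
  if (n < 2L) return(data.frame(i = integer(), j = integer(), order = integer()))
  r <- .covalent_radius[toupper(atoms$element)]
  r[is.na(r)] <- 0.9
  D <- cross_dist(atom_coords(atoms), atom_coords(atoms))
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (D[i, j] <= r[i] + r[j] + slack && D[i, j] > 0.1) {
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(i = integer(), j = integer(), order = integer()))
  }
  m <- do.call(rbind, out)
  data.frame(i = m[, 1], j = m[, 2], order = 1L)
}

# Rings up to max_size, approximated as the set of shortest cycles through
# each non-bridge edge (adequate SSSR stand-in for drug-sized molecules).
ligand_rings <- function(lig, max_size = 8L) {
  if (nrow(lig$bonds) == 0L) return(list())
  g <- ligand_graph(lig)
  br <- igraph::bridges(g)
  cyc_edges <- setdiff(seq_len(igraph::ecount(g)), as.integer(br))
  rings <- list()
  seen <- character()
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  for (e in cyc_edges) {
    i <- as.integer(ends[e, 1]); j <- as.integer(ends[e, 2])
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = as.character(i), to = as.character(j), output = "vpath"
    ))$vpath[[1]]
    if (length(sp) == 0L) next
    ring <- as.integer(igraph::as_ids(sp))
    if (length(ring) > max_size) next
    key <- paste(sort(ring), collapse = "-")
    if (!(key %in% seen)) {
      seen <- c(seen, key)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

in_ring <- function(lig, max_size = 8L) {
  flag <- logical(nrow(lig$atoms))
  for (r in ligand_rings(lig, max_size)) flag[r] <- TRUE
  flag
}
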