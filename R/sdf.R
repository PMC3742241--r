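# SDF (V2000) input and output. Parsing is delegated to ChemmineR; formal
# charges are additionally lifted from the raw "M  CHG" property lines,
# which ChemmineR's atom block does not surface. Output is written as
# deterministic V2000 text so fixture libraries are byte-stable across runs.

# per-record M CHG charges from raw molblock lines
.molblock_charges <- function(block_lines, n_atoms) {
  chg <- integer(n_atoms)
  for (ln in grep("^M  CHG", block_lines, value = TRUE)) {
    flds <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)),
                                                 "\\s+")[[1]]))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 3L) next
    npair <- flds[1]
    for (p in seq_len(npair)) {
      idx <- flds[2 * p]
      val <- flds[2 * p + 1]
      if (!is.na(idx) && idx >= 1L && idx <= n_atoms) chg[idx] <- val
    }
  }
  chg
}

.sdf_to_ligand <- function(sdf, charges, title) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  n <- nrow(ab)
  atoms <- atom_table(
    serial = seq_len(n), name = paste0(elem, seq_len(n)), element = elem,
    x = ab[, 1], y = ab[, 2], z = ab[, 3],
    resname = rep("LIG", n), resno = rep(1L, n), chain = "L",
    het = rep(TRUE, n), charge = charges
  )
  bonds <- if (is.null(bb) || nrow(bb) == 0L) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  ligand_molecule(atoms, bonds, multi_fragment = TRUE)
}

#' Read a multi-conformer SDF library
#'
#' Reads a V2000 SDF file and groups consecutive records with the same
#' title into one [conformer_set()]: the first record supplies the
#' topology (elements, bonds, formal charges) and every record contributes
#' one conformer. Records whose atom count disagrees with their group's
#' topology, or that ChemmineR rejects, are skipped with a warning.
#'
#' @param path SDF file.
#' @return named list of `conformer_set` objects in first-appearance
#'   order, with attribute `n_skipped`.
#' @export
read_sdf_library <- function(path) {
  raw <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$", raw)
  if (length(ends) == 0L) stop("no SDF records found")
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ChemmineR::cid(sdfset) <- paste0("rec", seq_along(sdfset))
  if (length(sdfset) != length(ends)) {
    warning("record count mismatch between raw scan and ChemmineR parse")
  }
  n_skipped <- 0L
  sets <- list()
  order_ids <- character()
  for (k in seq_along(ends)) {
    block <- raw[starts[k]:ends[k]]
    title <- trimws(block[1])
    ok <- tryCatch({
      sdf <- sdfset[[k]]
      n <- nrow(ChemmineR::atomblock(sdf))
      chg <- .molblock_charges(block, n)
      lig <- .sdf_to_ligand(sdf, chg, title)
      coords <- atom_coords(lig$atoms)
      if (is.null(sets[[title]])) {
        sets[[title]] <- conformer_set(title, lig, list(coords))
        order_ids <- c(order_ids, title)
      } else {
        if (nrow(coords) != nrow(sets[[title]]$topology$atoms)) {
          stop("conformer atom count mismatch")
        }
        sets[[title]]$conformers <-
          c(sets[[title]]$conformers, list(coords))
      }
      TRUE
    }, error = function(e) {
      warning(sprintf("SDF record %d ('%s') skipped: %s", k, title,
                      conditionMessage(e)))
      FALSE
    })
    if (!ok) n_skipped <- n_skipped + 1L
  }
  out <- sets[order_ids]
  attr(out, "n_skipped") <- n_skipped
  out
}

.molblock_lines <- function(title, atoms, bonds, coords) {
  n <- nrow(atoms)
  lines <- c(
    title, "  phore", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nrow(bonds))
  )
  for (i in seq_len(n)) {
    lines <- c(lines, sprintf(
      "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      coords[i, 1], coords[i, 2], coords[i, 3], atoms$element[i]))
  }
  for (b in seq_len(nrow(bonds))) {
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$i[b], bonds$j[b],
                              bonds$order[b]))
  }
  charged <- which(atoms$charge != 0L)
  while (length(charged) > 0L) {
    grp <- utils::head(charged, 8L)
    charged <- charged[-seq_along(grp)]
    lines <- c(lines, paste0(
      sprintf("M  CHG%3d", length(grp)),
      paste0(vapply(grp, function(i) sprintf("%4d%4d", i,
                                             atoms$charge[i]),
                    character(1)), collapse = "")))
  }
  c(lines, "M  END", "$$$$")
}

#' Write conformer sets as a multi-conformer SDF file
#'
#' One V2000 record per conformer, grouped by title, with `M CHG` lines
#' for formal charges. Output formatting is fixed, so identical inputs
#' give byte-identical files.
#'
#' @param sets list of [conformer_set()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sdf_library <- function(sets, path) {
  lines <- character()
  for (cs in sets) {
    for (coords in cs$conformers) {
      lines <- c(lines, .molblock_lines(cs$molecule_id, cs$topology$atoms,
                                        cs$topology$bonds, coords))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
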