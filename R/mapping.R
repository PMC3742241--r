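# Mapping ligand conformers onto a consensus model. The assignment of
# ligand feature points to model features is searched exhaustively (models
# carry a handful of features, so the injective-assignment space is tiny),
# each candidate assignment is rigid-body aligned by Kabsch, and the best
# in-tolerance, clash-free assignment wins by geometric fit value.

#' Multi-conformer molecule
#'
#' @param molecule_id identifier (SDF title).
#' @param topology a [ligand_molecule()] giving elements, bonds, charges.
#' @param conformers list of n_atoms x 3 coordinate matrices sharing atom
#'   order with the topology.
#' @return object of class `conformer_set`.
#' @export
conformer_set <- function(molecule_id, topology, conformers) {
  stopifnot(inherits(topology, "ligand_molecule"), length(conformers) >= 1L)
  n <- nrow(topology$atoms)
  for (cf in conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3L) {
      stop("conformer dimensions do not match topology")
    }
  }
  structure(list(molecule_id = molecule_id, topology = topology,
                 conformers = conformers), class = "conformer_set")
}

#' Geometric fit value
#'
#' Weighted quadratic falloff inside each tolerance sphere:
#' `sum_f w_f * max(0, 1 - (d_f / t_f)^2)`. A feature matched dead-center
#' contributes its full weight; one at the sphere boundary contributes
#' zero; the total is bounded by `sum(w)`.
#'
#' @param displacements distances from matched points to feature centers
#'   (angstrom).
#' @param tolerances feature tolerance radii (angstrom, positive).
#' @param weights per-feature weights (default all 1).
#' @return non-negative scalar fit value.
#' @export
fit_value <- function(displacements, tolerances,
                      weights = rep(1, length(displacements))) {
  if (length(displacements) != length(tolerances) ||
      length(displacements) != length(weights)) {
    stop("arity")
  }
  if (any(tolerances <= 0)) stop("tolerances must be positive")
  sum(weights * pmax(0, 1 - (displacements / tolerances)^2))
}

.empty_mapping <- function(conformer_index = NA_integer_) {
  structure(
    list(assignment = data.frame(feature_id = character(),
                                 point = integer(),
                                 stringsAsFactors = FALSE),
         transform = rigid_transform(),
         displacements = numeric(0), fit = 0, valid = FALSE,
         ev_clash = FALSE, conformer_index = conformer_index),
    class = "mapping_result"
  )
}

#' @export
print.mapping_result <- function(x, ...) {
  if (!x$valid) {
    cat("mapping_result: no valid mapping (fit 0)\n")
  } else {
    cat(sprintf("mapping_result: fit %.3f over %d features (conformer %s)\n",
                x$fit, nrow(x$assignment),
                ifelse(is.na(x$conformer_index), "?", x$conformer_index)))
  }
  invisible(x)
}

# all injective assignments, depth-first over model features in order
.enumerate_assignments <- function(compat) {
  k <- length(compat)
  out <- list()
  rec <- function(depth, used, acc) {
    if (depth > k) {
      out[[length(out) + 1L]] <<- acc
      return(invisible())
    }
    for (p in compat[[depth]]) {
      if (p %in% used) next
      rec(depth + 1L, c(used, p), c(acc, p))
    }
  }
  rec(1L, integer(), integer())
  out
}

#' Map one conformer onto a consensus model
#'
#' Enumerates every kind-compatible injective assignment of the
#' conformer's candidate feature points to all model features, rigidly
#' aligns the matched points onto the feature centers (Kabsch), and keeps
#' the assignment with the highest fit value among those whose
#' displacements all stay within tolerance and whose heavy atoms avoid the
#' excluded volumes (an atom center strictly inside a sphere is a clash).
#' Matching is all-feature: a conformer lacking a required kind cannot map.
#'
#' @param conformer n_atoms x 3 coordinate matrix.
#' @param ligand_points candidate features of the conformer (from
#'   [ligand_feature_points()] evaluated at these coordinates).
#' @param model a `consensus_pharmacophore`.
#' @param weights optional per-feature weights for the fit value.
#' @param elements optional element vector for the conformer atoms, used to
#'   restrict the clash test to heavy atoms (all atoms are treated as heavy
#'   when omitted).
#' @return object of class `mapping_result`; `fit` is 0 when no valid
#'   mapping exists.
#' @export
map_conformer <- function(conformer, ligand_points, model, weights = NULL,
                          elements = NULL) {
  feats <- model$features
  k <- nrow(feats)
  if (k == 0L) stop("model has no features")
  if (is.null(weights)) weights <- rep(1, k)
  if (is.null(ligand_points) || nrow(ligand_points) == 0L) {
    return(.empty_mapping())
  }
  compat <- lapply(feats$kind, function(kind) {
    which(ligand_points$kind == kind)
  })
  if (any(vapply(compat, length, integer(1)) == 0L)) {
    return(.empty_mapping())
  }
  centers <- as.matrix(feats[, c("x", "y", "z")])
  tol <- feats$tolerance
  pts_all <- feature_coords(ligand_points)
  heavy <- if (is.null(elements)) rep(TRUE, nrow(conformer)) else
    toupper(elements) != "H"
  ev <- model$excluded_volumes
  has_ev <- !is.null(ev) && nrow(ev) > 0L
  ev_xyz <- if (has_ev) as.matrix(ev[, c("x", "y", "z")]) else NULL

  best <- NULL
  saw_clash <- FALSE
  for (asg in .enumerate_assignments(compat)) {
    P <- pts_all[asg, , drop = FALSE]
    if (k >= 3L) {
      fit <- kabsch(P, centers)
      tf <- fit$transform
    } else {
      tf <- rigid_transform(diag(3), colMeans(centers) - colMeans(P))
    }
    moved <- apply_transform(P, tf)
    disp <- sqrt(rowSums((moved - centers)^2))
    if (any(disp > tol)) next
    if (has_ev) {
      lig_xyz <- apply_transform(conformer[heavy, , drop = FALSE], tf)
      D <- cross_dist(lig_xyz, ev_xyz)
      if (any(sweep(D, 2, ev$radius, "<"))) {
        saw_clash <- TRUE
        next
      }
    }
    f <- fit_value(disp, tol, weights)
    if (is.null(best) || f > best$fit) {
      best <- list(asg = asg, tf = tf, disp = disp, fit = f)
    }
  }
  if (is.null(best)) {
    out <- .empty_mapping()
    out$ev_clash <- saw_clash
    return(out)
  }
  structure(
    list(assignment = data.frame(feature_id = feats$id, point = best$asg,
                                 stringsAsFactors = FALSE),
         transform = best$tf,
         displacements = stats::setNames(best$disp, feats$id),
         fit = best$fit, valid = TRUE, ev_clash = FALSE,
         conformer_index = NA_integer_),
    class = "mapping_result"
  )
}

#' Map a multi-conformer molecule onto a model
#'
#' Maps every conformer and returns the best result; the winning conformer
#' is assumed to approximate the bioactive conformation. Ties go to the
#' lowest conformer index.
#'
#' @param confset a [conformer_set()].
#' @param model a `consensus_pharmacophore`.
#' @param weights optional per-feature weights.
#' @return the best `mapping_result`, with `conformer_index` set.
#' @export
map_molecule <- function(confset, model, weights = NULL) {
  if (length(confset$conformers) == 0L) stop("no conformers")
  elements <- confset$topology$atoms$element
  best <- NULL
  for (ci in seq_along(confset$conformers)) {
    coords <- confset$conformers[[ci]]
    topo <- confset$topology
    topo$atoms <- set_atom_coords(topo$atoms, coords)
    pts <- ligand_feature_points(topo)
    res <- map_conformer(coords, pts, model, weights, elements)
    res$conformer_index <- ci
    if (is.null(best) || res$fit > best$fit ||
        (res$valid && !best$valid)) {
      best <- res
    }
  }
  best
}

#' RMSD between a bound pose and a mapped pose
#'
#' Plain heavy-atom RMSD in a shared frame, without re-superposition: both
#' poses are assumed to already sit in the model's reference frame, so the
#' number reflects how well mapping reproduced the bound geometry.
#'
#' @param bound,mapped n x 3 coordinate matrices in the same atom order.
#' @param elements optional element vector; hydrogen rows are dropped from
#'   both poses when supplied.
#' @return RMSD in angstrom.
#' @export
bound_vs_mapped_rmsd <- function(bound, mapped, elements = NULL) {
  bound <- rbind(bound); mapped <- rbind(mapped)
  if (!all(dim(bound) == dim(mapped))) stop("correspondence")
  if (!is.null(elements)) {
    if (length(elements) != nrow(bound)) stop("correspondence")
    keep <- toupper(elements) != "H"
    bound <- bound[keep, , drop = FALSE]
    mapped <- mapped[keep, , drop = FALSE]
  }
  sqrt(mean(rowSums((bound - mapped)^2)))
}

#' Screen a multi-conformer library against a model
#'
#' Maps every molecule ([map_molecule()]), keeps those with a valid
#' all-feature mapping, ranks by fit value (descending, ties by molecule
#' id) and truncates to the top `top_k` (or applies a minimum-fit cutoff
#' instead). Unreadable or failing molecules are skipped and counted.
#'
#' @param library list of [conformer_set()] objects, or the path of a
#'   multi-conformer SDF file (conformers grouped by title).
#' @param model a `consensus_pharmacophore`.
#' @param top_k maximum number of hits returned (default 1000).
#' @param min_fit optional fit-value cutoff applied instead of a fixed
#'   count truncation (both may be combined).
#' @param weights optional per-feature weights.
#' @return data frame of hits (`molecule_id`, `fit`, `conformer_index`,
#'   `rank`) with attributes `n_screened` and `n_failed`; the per-hit
#'   `mapping_result` objects are attached as attribute `mappings`.
#' @export
screen_library <- function(library, model, top_k = 1000, min_fit = NULL,
                           weights = NULL) {
  if (top_k < 1L) stop("top_k must be >= 1")
  if (is.character(library)) library <- read_sdf_library(library)
  n_failed <- 0L
  hits <- list()
  for (cs in library) {
    res <- tryCatch(map_molecule(cs, model, weights), error = function(e) {
      warning(sprintf("molecule '%s' skipped: %s", cs$molecule_id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    if (res$valid && res$fit > 0) {
      hits[[length(hits) + 1L]] <- list(id = cs$molecule_id, res = res)
    }
  }
  if (length(hits) == 0L) {
    out <- data.frame(molecule_id = character(), fit = numeric(),
                      conformer_index = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
    attr(out, "n_screened") <- length(library)
    attr(out, "n_failed") <- n_failed
    attr(out, "mappings") <- list()
    return(out)
  }
  ids <- vapply(hits, `[[`, character(1), "id")
  fits <- vapply(hits, function(h) h$res$fit, numeric(1))
  ords <- order(-fits, ids)
  keep <- utils::head(ords, top_k)
  out <- data.frame(
    molecule_id = ids[keep], fit = fits[keep],
    conformer_index = vapply(hits[keep], function(h) h$res$conformer_index,
                             integer(1)),
    rank = seq_along(keep), stringsAsFactors = FALSE
  )
  maps <- lapply(hits[keep], `[[`, "res")
  if (!is.null(min_fit)) {
    sel <- out$fit >= min_fit
    out <- out[sel, , drop = FALSE]
    maps <- maps[sel]
    rownames(out) <- NULL
  }
  attr(out, "n_screened") <- length(library)
  attr(out, "n_failed") <- n_failed
  attr(out, "mappings") <- maps
  out
}

#' Write a hit table as TSV
#' @param hits data frame from [screen_library()] or [final_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
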