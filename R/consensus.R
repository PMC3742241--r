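# Consensus model construction: pool per-complex features, cluster same-kind
# features agglomeratively, score each cluster by the fraction of complexes
# it appears in, retain clusters above a frequency threshold, and attach
# excluded volumes. The resulting model is a plain serializable document.

.kind_prefix <- c(HYD = "H", HBD = "D", HBA = "A", POS = "Pos", NEG = "Neg")

#' Statistical frequency of a feature cluster
#'
#' Percentage of complexes represented in a cluster, rounded half-up to an
#' integer percent: `round_half_up(100 * count / n_complexes)`. Over 14
#' complexes this maps counts 1, 2, 5, 9, 10, 11, 12 to 7, 14, 36, 64, 71,
#' 79, 86 percent.
#'
#' @param count number of distinct complexes contributing to the cluster.
#' @param n_complexes ensemble size.
#' @return integer percent (vectorized over `count`).
#' @export
frequency <- function(count, n_complexes) {
  if (length(n_complexes) != 1L || !is.finite(n_complexes) ||
      n_complexes <= 0) {
    stop("bad count")
  }
  if (any(!is.finite(count)) || any(count < 0) || any(count > n_complexes)) {
    stop("bad count")
  }
  as.integer(floor(100 * count / n_complexes + 0.5))
}

#' Cluster pooled pharmacophore features
#'
#' Greedy agglomerative, same-kind-only clustering: the two clusters of
#' equal kind with the smallest centroid distance are merged while that
#' distance stays at or below `cluster_radius`; centroids are recomputed
#' from all member features. Each cluster counts the distinct complexes
#' among its members (a complex contributing two same-kind features to one
#' cluster counts once) and is labelled per kind in descending count order
#' (H1, H2, ..., D1, ..., Pos1, ...), ties broken by lexicographic centroid
#' order.
#'
#' @param features pooled features data frame (rows from [perceive()] over
#'   all complexes, in a common frame).
#' @param cluster_radius merge distance in angstrom.
#' @param n_complexes ensemble size used for the frequency column; defaults
#'   to the number of distinct `complex_id` values in `features`.
#' @return data frame of clusters (`cluster_id`, `kind`, centroid `x`,
#'   `y`, `z`, `tolerance`, `count`, `frequency`, `n_members`) with the
#'   member features attached as a list column `members`.
#' @export
cluster_features <- function(features, cluster_radius = 2.0,
                             n_complexes = NULL) {
  if (is.null(features) || nrow(features) == 0L) {
    out <- data.frame(
      cluster_id = character(), kind = character(), x = numeric(),
      y = numeric(), z = numeric(), tolerance = numeric(),
      count = integer(), frequency = integer(), n_members = integer(),
      stringsAsFactors = FALSE
    )
    out$members <- list()
    return(out)
  }
  if (is.null(n_complexes)) {
    n_complexes <- length(unique(features$complex_id))
  }
  rows <- list()
  for (kind in intersect(.feature_kinds, unique(features$kind))) {
    sub <- features[features$kind == kind, , drop = FALSE]
    mem <- greedy_cluster(feature_coords(sub), cluster_radius, closed = TRUE)
    for (mm in mem) {
      grp <- sub[mm, , drop = FALSE]
      ctr <- colMeans(feature_coords(grp))
      cnt <- length(unique(grp$complex_id))
      rows[[length(rows) + 1L]] <- list(
        kind = kind, x = ctr[1], y = ctr[2], z = ctr[3],
        tolerance = if (all(is.na(grp$tolerance))) NA_real_
                    else max(grp$tolerance, na.rm = TRUE),
        count = cnt, n_members = nrow(grp), members = grp
      )
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(kind = r$kind, x = r$x, y = r$y, z = r$z,
               tolerance = r$tolerance, count = r$count,
               n_members = r$n_members, stringsAsFactors = FALSE)
  }))
  out$frequency <- frequency(out$count, n_complexes)
  out$members <- lapply(rows, `[[`, "members")
  # canonical labels: per kind, descending count, ties by centroid order
  ord <- order(match(out$kind, .feature_kinds), -out$count, out$x, out$y,
               out$z)
  out <- out[ord, , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(out)), out$kind, FUN = seq_along)
  out$cluster_id <- paste0(.kind_prefix[out$kind], idx)
  rownames(out) <- NULL
  out[, c("cluster_id", "kind", "x", "y", "z", "tolerance", "count",
          "frequency", "n_members", "members")]
}

#' Retain clusters above a frequency threshold
#'
#' Keeps clusters whose statistical frequency is strictly greater than the
#' threshold ("more than 60 percent"), preserving order. A 64 percent
#' cluster passes a 60 percent threshold; a 60 percent one would not.
#'
#' @param clusters output of [cluster_features()].
#' @param threshold integer percent (default 60).
#' @return the retained subset (warns, without erroring, when empty).
#' @export
select_clusters <- function(clusters, threshold = 60) {
  out <- clusters[clusters$frequency > threshold, , drop = FALSE]
  if (nrow(out) == 0L) warning("model has no features")
  rownames(out) <- NULL
  out
}

#' Assemble a consensus pharmacophore model
#'
#' @param selected retained clusters (see [select_clusters()]); must be
#'   non-empty.
#' @param excluded_volumes data frame from [excluded_volumes_for()] (may
#'   have zero rows).
#' @param n_complexes ensemble size behind the frequencies.
#' @param threshold retention threshold (percent).
#' @param provenance character vector of contributing complex ids.
#' @return object of class `consensus_pharmacophore` with elements
#'   `features`, `excluded_volumes`, `n_complexes`, `threshold`,
#'   `provenance`.
#' @export
build_model <- function(selected, excluded_volumes = NULL,
                        n_complexes = NA_integer_, threshold = 60,
                        provenance = character()) {
  if (is.null(selected) || nrow(selected) == 0L) stop("empty model")
  feats <- data.frame(
    id = selected$cluster_id, kind = selected$kind, x = selected$x,
    y = selected$y, z = selected$z, tolerance = selected$tolerance,
    count = selected$count, frequency = selected$frequency,
    stringsAsFactors = FALSE
  )
  if (is.null(excluded_volumes)) {
    excluded_volumes <- data.frame(x = numeric(), y = numeric(),
                                   z = numeric(), radius = numeric(),
                                   residue = character(),
                                   stringsAsFactors = FALSE)
  }
  structure(
    list(features = feats,
         excluded_volumes = excluded_volumes[, intersect(
           c("x", "y", "z", "radius", "residue"),
           names(excluded_volumes)), drop = FALSE],
         n_complexes = as.integer(n_complexes),
         threshold = as.numeric(threshold),
         provenance = as.character(provenance)),
    class = "consensus_pharmacophore"
  )
}

#' @export
print.consensus_pharmacophore <- function(x, ...) {
  cat(sprintf(
    "consensus_pharmacophore: %d features, %d excluded volumes (N = %d complexes, threshold > %g%%)\n",
    nrow(x$features), nrow(x$excluded_volumes), x$n_complexes, x$threshold))
  print(x$features[, c("id", "kind", "x", "y", "z", "tolerance", "count",
                       "frequency")], digits = 4)
  invisible(x)
}

#' Serialize a consensus model to JSON
#'
#' Schema (also published under `inst/extdata/model-schema.json`): a `meta`
#' block (`n_complexes`, `threshold`, `provenance`), a `features` array
#' (`id`, `kind`, `center`, `tolerance`, `count`, `frequency`) and an
#' `excluded_volumes` array (`center`, `radius`, `residue`). Numbers are
#' written at full precision so write/read round-trips are exact to within
#' double formatting.
#'
#' @param model a `consensus_pharmacophore`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  f <- model$features
  doc <- list(
    meta = list(n_complexes = model$n_complexes,
                threshold = model$threshold,
                provenance = as.list(model$provenance)),
    features = lapply(seq_len(nrow(f)), function(k) {
      list(id = f$id[k], kind = f$kind[k],
           center = c(f$x[k], f$y[k], f$z[k]), tolerance = f$tolerance[k],
           count = f$count[k], frequency = f$frequency[k])
    }),
    excluded_volumes = lapply(seq_len(nrow(model$excluded_volumes)),
                              function(k) {
      ev <- model$excluded_volumes[k, ]
      list(center = c(ev$x, ev$y, ev$z), radius = ev$radius,
           residue = ev$residue)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a consensus model from JSON
#' @param path file written by [write_model()].
#' @return a `consensus_pharmacophore`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  f <- do.call(rbind, lapply(doc$features, function(r) {
    data.frame(id = r$id, kind = r$kind, x = r$center[[1]],
               y = r$center[[2]], z = r$center[[3]],
               tolerance = r$tolerance, count = r$count,
               frequency = r$frequency, stringsAsFactors = FALSE)
  }))
  ev <- if (length(doc$excluded_volumes) == 0L) NULL else {
    do.call(rbind, lapply(doc$excluded_volumes, function(r) {
      data.frame(x = r$center[[1]], y = r$center[[2]], z = r$center[[3]],
                 radius = r$radius, residue = r$residue,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(features = f,
         excluded_volumes = if (is.null(ev)) data.frame(
           x = numeric(), y = numeric(), z = numeric(), radius = numeric(),
           residue = character(), stringsAsFactors = FALSE) else ev,
         n_complexes = as.integer(doc$meta$n_complexes),
         threshold = as.numeric(doc$meta$threshold),
         provenance = as.character(unlist(doc$meta$provenance))),
    class = "consensus_pharmacophore"
  )
}
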