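# hand-built pooled feature frame: one feature per (site, complex)
pooled_from_counts <- function(sites, n_complexes = 14, jitter = 0,
                               seed = 1) {
  set.seed(seed)
  rows <- list()
  grid <- expand.grid(x = 0:2, y = 0:2, z = 0:2)[seq_len(nrow(sites)), ] * 12
  for (s in seq_len(nrow(sites))) {
    members <- sample.int(n_complexes, sites$multiplicity[s])
    for (ci in members) {
      ctr <- as.numeric(grid[s, ]) + rnorm(3, sd = jitter)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = sites$kind[s], x = ctr[1], y = ctr[2], z = ctr[3],
        tolerance = 1.6, dx = NA_real_, dy = NA_real_, dz = NA_real_,
        complex_id = sprintf("CX%02d", ci), contacts = "D296",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$atoms <- rep(list(1L), nrow(out))
  out
}

test_that("statistical frequency reproduces the published percent table", {
  counts <- c(1, 2, 5, 9, 10, 11, 12)
  expect_equal(frequency(counts, 14), c(7, 14, 36, 64, 71, 79, 86))
  expect_equal(frequency(14, 14), 100L)
  expect_equal(frequency(0, 14), 0L)
  expect_error(frequency(15, 14), "bad count")
  expect_error(frequency(-1, 14), "bad count")
  expect_error(frequency(3, 0), "bad count")
})

test_that("clustering merges same-kind neighbours only", {
  f <- rbind(
    data.frame(kind = "HBD", x = 0, y = 0, z = 0, tolerance = 1.6,
               dx = NA, dy = NA, dz = NA, complex_id = "A",
               contacts = "", stringsAsFactors = FALSE),
    data.frame(kind = "HBD", x = 0.5, y = 0, z = 0, tolerance = 1.6,
               dx = NA, dy = NA, dz = NA, complex_id = "B",
               contacts = "", stringsAsFactors = FALSE),
    data.frame(kind = "HYD", x = 0, y = 0, z = 0, tolerance = 1.6,
               dx = NA, dy = NA, dz = NA, complex_id = "A",
               contacts = "", stringsAsFactors = FALSE)
  )
  f$atoms <- rep(list(1L), 3)
  cl <- cluster_features(f, n_complexes = 2)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$kind), c("HBD", "HYD"))
  expect_equal(cl$count[cl$kind == "HBD"], 2)

  # same complex twice still counts once
  f$complex_id <- c("A", "A", "A")
  cl2 <- cluster_features(f, n_complexes = 2)
  expect_equal(cl2$count[cl2$kind == "HBD"], 1)
  expect_equal(cl2$n_members[cl2$kind == "HBD"], 2)
})

test_that("clustering recovers the published count multiset and labels", {
  pooled <- pooled_from_counts(default_planted_sites(), jitter = 0.3)
  cl <- cluster_features(pooled, n_complexes = 14)
  expect_equal(nrow(cl), 19)
  expect_equal(sort(cl$count),
               sort(default_planted_sites()$multiplicity))
  expect_equal(cl$frequency, frequency(cl$count, 14))
  # labels descend by count within kind
  hyd <- cl[cl$kind == "HYD", ]
  expect_equal(hyd$cluster_id, paste0("H", 1:6))
  expect_equal(hyd$count, sort(hyd$count, decreasing = TRUE))

  # permutation invariance (canonical labels)
  for (k in 1:10) {
    set.seed(100 + k)
    perm <- pooled[sample(nrow(pooled)), ]
    clp <- cluster_features(perm, n_complexes = 14)
    expect_equal(clp$cluster_id, cl$cluster_id)
    expect_equal(clp$count, cl$count)
    expect_equal(as.matrix(clp[, c("x", "y", "z")]),
                 as.matrix(cl[, c("x", "y", "z")]), tolerance = 1e-9)
  }

  # idempotence: re-clustering the centroids changes nothing
  cl_as_features <- data.frame(
    kind = cl$kind, x = cl$x, y = cl$y, z = cl$z, tolerance = cl$tolerance,
    dx = NA, dy = NA, dz = NA, complex_id = cl$cluster_id, contacts = "",
    stringsAsFactors = FALSE
  )
  cl_as_features$atoms <- rep(list(1L), nrow(cl))
  recl <- cluster_features(cl_as_features, n_complexes = 19)
  expect_equal(nrow(recl), 19)
  expect_equal(sort(recl$x), sort(cl$x), tolerance = 1e-9)

  expect_equal(nrow(cluster_features(NULL)), 0)
})

test_that("threshold selection is strictly greater-than", {
  pooled <- pooled_from_counts(default_planted_sites(), jitter = 0.2)
  cl <- cluster_features(pooled, n_complexes = 14)
  sel <- select_clusters(cl, 60)
  expect_equal(nrow(sel), 6)
  expect_equal(sort(sel$count), c(9, 9, 9, 10, 11, 12))
  expect_setequal(sel$cluster_id, c("H1", "H2", "H3", "D1", "D2", "Pos1"))
  # a frequency exactly at the threshold does not pass
  expect_equal(nrow(select_clusters(cl, 64)), 3)
  expect_warning(empty <- select_clusters(cl, 100), "no features")
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(select_clusters(cl, 0)), 19)
})

test_that("model assembly and JSON round trip preserve all fields", {
  pooled <- pooled_from_counts(default_planted_sites(), jitter = 0.2)
  cl <- cluster_features(pooled, n_complexes = 14)
  sel <- select_clusters(cl)
  evs <- data.frame(x = rnorm(26), y = rnorm(26), z = rnorm(26),
                    radius = 1.2, residue = sprintf("P%d", 247:272),
                    stringsAsFactors = FALSE)
  model <- build_model(sel, evs, n_complexes = 14, threshold = 60,
                       provenance = sprintf("CX%02d", 1:14))
  expect_equal(nrow(model$features), 6)
  expect_equal(nrow(model$excluded_volumes), 26)
  expect_error(build_model(cl[0, ]), "empty model")

  tmp <- tempfile(fileext = ".json")
  write_model(model, tmp)
  back <- read_model(tmp)
  expect_equal(back$features$id, model$features$id)
  expect_equal(as.matrix(back$features[, c("x", "y", "z")]),
               as.matrix(model$features[, c("x", "y", "z")]),
               tolerance = 1e-9)
  expect_equal(back$features$tolerance, model$features$tolerance,
               tolerance = 1e-9)
  expect_equal(as.matrix(back$excluded_volumes[, c("x", "y", "z")]),
               as.matrix(model$excluded_volumes[, c("x", "y", "z")]),
               tolerance = 1e-9)
  expect_equal(back$n_complexes, model$n_complexes)
  expect_equal(back$threshold, model$threshold)
  expect_equal(back$provenance, model$provenance)
  unlink(tmp)

  # permuted input features give the identical model document
  set.seed(7)
  for (k in 1:10) {
    perm <- pooled[sample(nrow(pooled)), ]
    m2 <- build_model(select_clusters(cluster_features(perm,
                                                       n_complexes = 14)),
                      evs, n_complexes = 14, threshold = 60,
                      provenance = sprintf("CX%02d", 1:14))
    expect_equal(m2$features$id, model$features$id)
    expect_equal(as.matrix(m2$features[, c("x", "y", "z")]),
                 as.matrix(model$features[, c("x", "y", "z")]),
                 tolerance = 1e-9)
  }
})
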