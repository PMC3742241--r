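# well-separated 4-feature model used in several blocks
square_model <- function(tolerance = 1.6) {
  toy_model(data.frame(
    id = c("H1", "H2", "D1", "A1"),
    kind = c("HYD", "HYD", "HBD", "HBA"),
    x = c(0, 8, 0, 8), y = c(0, 0, 8, 8), z = 0,
    stringsAsFactors = FALSE
  ), tolerance = tolerance)
}

test_that("fit value follows the quadratic falloff and its bounds", {
  expect_equal(fit_value(rep(0, 6), rep(1.6, 6)), 6)
  expect_equal(fit_value(1.6, 1.6), 0)
  expect_equal(fit_value(0.8, 1.6), 0.75)
  expect_equal(fit_value(c(0, 0.8), c(1.6, 1.6), c(2, 1)), 2.75)
  expect_error(fit_value(c(0, 0), 1.6), "arity")
  expect_error(fit_value(0.5, -1), "positive")

  # monotone non-increasing in each displacement; order-invariant; bounded
  set.seed(5)
  for (k in 1:50) {
    d <- runif(6, 0, 2); t <- runif(6, 0.5, 2); w <- runif(6, 0.1, 2)
    f <- fit_value(d, t, w)
    expect_lte(f, sum(w) + 1e-12)
    expect_gte(f, 0)
    i <- sample(6, 1)
    d2 <- d; d2[i] <- d2[i] + runif(1, 0, 1)
    expect_lte(fit_value(d2, t, w), f + 1e-12)
    p <- sample(6)
    expect_equal(fit_value(d[p], t[p], w[p]), f, tolerance = 1e-12)
  }
})

test_that("a conformer matching all feature centers maps perfectly", {
  model <- square_model()
  centers <- as.matrix(model$features[, c("x", "y", "z")])
  pts <- points_df(model$features$kind, centers)
  res <- map_conformer(centers, pts, model)
  expect_true(res$valid)
  expect_equal(res$fit, 4, tolerance = 1e-9)
  expect_equal(unname(res$displacements), rep(0, 4), tolerance = 1e-6)

  # all-feature requirement: drop the HBA point and mapping dies
  res2 <- map_conformer(centers[1:3, ], pts[1:3, ], model)
  expect_false(res2$valid)
  expect_equal(res2$fit, 0)
})

test_that("assignment search equals the exhaustive oracle", {
  set.seed(8)
  kinds <- c("HYD", "HBD", "HBA", "POS", "NEG")
  for (k in 1:25) {
    n_feat <- sample(3:5, 1)
    fk <- sample(kinds, n_feat, replace = TRUE)
    centers <- matrix(runif(3 * n_feat, -10, 10), ncol = 3)
    model <- toy_model(data.frame(
      id = paste0("F", seq_len(n_feat)), kind = fk,
      x = centers[, 1], y = centers[, 2], z = centers[, 3],
      stringsAsFactors = FALSE
    ))
    # ligand points: jittered copies of the centers plus distractors
    n_extra <- sample(0:3, 1)
    pk <- c(fk, sample(kinds, n_extra, replace = TRUE))
    pxyz <- rbind(centers + matrix(rnorm(3 * n_feat, sd = 0.5), ncol = 3),
                  matrix(runif(3 * n_extra, -12, 12), ncol = 3))
    tf <- random_rigid()
    pts <- points_df(pk, apply_transform(pxyz, tf))
    res <- map_conformer(apply_transform(pxyz, tf), pts, model)
    expect_equal(res$fit, oracle_best_fit(pts, model), tolerance = 1e-9)
  }
})

test_that("excluded volumes veto clashing mappings", {
  ev <- data.frame(x = 4, y = 0, z = 0, radius = 1.2, residue = "A1",
                   stringsAsFactors = FALSE)
  model <- toy_model(data.frame(
    id = c("H1", "H2", "D1"), kind = c("HYD", "HYD", "HBD"),
    x = c(0, 8, 0), y = c(0, 0, 8), z = 0, stringsAsFactors = FALSE
  ), evs = ev)
  centers <- as.matrix(model$features[, c("x", "y", "z")])
  pts <- points_df(model$features$kind, centers)
  # conformer atom sitting inside the sphere -> rejected
  conf_clash <- rbind(centers, c(4, 0, 0))
  res <- map_conformer(conf_clash, pts, model)
  expect_false(res$valid)
  expect_true(res$ev_clash)
  # atom on the boundary is allowed (strictly-inside convention)
  conf_edge <- rbind(centers, c(4 - 1.2, 0, 0))
  expect_true(map_conformer(conf_edge, pts, model)$valid)
})

test_that("molecule mapping picks the best conformer with stable ties", {
  model <- square_model()
  centers <- as.matrix(model$features[, c("x", "y", "z")])
  good <- centers
  bad <- centers * 3  # internally stretched: cannot satisfy tolerances
  lig <- make_mol(c("C", "C", "C", "C"), centers,
                  data.frame(i = 1:3, j = 2:4, order = 1L))

  # feature points are recomputed per conformer, so build a molecule whose
  # chemistry yields one point per model kind
  frag_mol <- function(coords) {
    make_mol(
      c("C", "C", "C", "C", "C", "C", "N", "C", "O", "C"),
      rbind(coords[1, ] + c(-1.5, 0, 0), coords[1, ], coords[1, ] + c(1.5, 0, 0),
            coords[2, ] + c(-1.5, 0, 0), coords[2, ], coords[2, ] + c(1.5, 0, 0),
            coords[3, ], coords[3, ] + c(-1.45, 0, 0),
            coords[4, ], coords[4, ] + c(-1.23, 0, 0)),
      data.frame(i = c(1L, 2L, 4L, 5L, 7L, 9L),
                 j = c(2L, 3L, 5L, 6L, 8L, 10L),
                 order = c(1L, 1L, 1L, 1L, 1L, 2L)),
      multi_fragment = TRUE
    )
  }
  m_good <- frag_mol(good)
  m_bad <- frag_mol(bad)
  cs <- conformer_set("mol", m_good,
                      list(atom_coords(m_bad$atoms),
                           atom_coords(m_good$atoms),
                           atom_coords(m_bad$atoms)))
  res <- map_molecule(cs, model)
  expect_true(res$valid)
  expect_equal(res$conformer_index, 2L)

  # duplicate conformers: lowest index wins
  cs2 <- conformer_set("mol", m_good,
                       list(atom_coords(m_good$atoms),
                            atom_coords(m_good$atoms)))
  expect_equal(map_molecule(cs2, model)$conformer_index, 1L)

  # best-over-conformers dominates each single conformer
  per_conf <- vapply(seq_along(cs$conformers), function(ci) {
    one <- conformer_set("m", cs$topology, cs$conformers[ci])
    map_molecule(one, model)$fit
  }, numeric(1))
  expect_equal(res$fit, max(per_conf), tolerance = 1e-9)

  expect_error(map_molecule(structure(list(conformers = list()),
                                      class = "conformer_set"), model),
               "no conformers")
})

test_that("pose-vs-reference RMSD is computed without refitting", {
  A <- matrix(rnorm(12), ncol = 3)
  expect_equal(bound_vs_mapped_rmsd(A, A), 0)
  B <- A
  B[1, ] <- B[1, ] + c(1, 0, 0)
  expect_equal(bound_vs_mapped_rmsd(A, B), 0.5)
  expect_error(bound_vs_mapped_rmsd(A, B[1:3, ]), "correspondence")
  # co-moving both poses changes nothing
  tf <- random_rigid()
  expect_equal(bound_vs_mapped_rmsd(apply_transform(A, tf),
                                    apply_transform(B, tf)),
               0.5, tolerance = 1e-9)
  # hydrogens are excluded when elements are given
  expect_equal(bound_vs_mapped_rmsd(A, B, elements = c("H", "C", "C", "C")),
               0)
})

test_that("library screening ranks planted actives above all decoys", {
  model <- table_pattern_model(seed = 11)
  lib <- make_library(model, 6, 12, seed = 21)
  hits <- screen_library(lib, model)
  expect_equal(nrow(hits), 6)
  expect_true(all(grepl("^ACT", hits$molecule_id)))
  expect_equal(hits$rank, 1:6)
  expect_equal(hits$fit, sort(hits$fit, decreasing = TRUE))
  expect_equal(attr(hits, "n_screened"), 18)

  # top_k larger than the number of mappers returns all of them
  expect_equal(nrow(screen_library(lib, model, top_k = 1000)), 6)
  expect_equal(nrow(screen_library(lib, model, top_k = 3)), 3)
  expect_error(screen_library(lib, model, top_k = 0), "top_k")

  # min-fit cutoff variant
  strict <- screen_library(lib, model, min_fit = max(hits$fit) - 1e-9)
  expect_equal(nrow(strict), 1)

  # identical-fit ties are ordered by molecule id
  dup <- lib[1]
  dup[["AAA"]] <- dup[[1]]; dup[["AAA"]]$molecule_id <- "AAA"
  dup[["ZZZ"]] <- dup[[1]]; dup[["ZZZ"]]$molecule_id <- "ZZZ"
  h3 <- screen_library(dup[c("ZZZ", "AAA")], model)
  expect_equal(h3$molecule_id, c("AAA", "ZZZ"))

  # an unreadable molecule is skipped, counted, and screening continues
  broken <- lib
  broken[[3]]$conformers <- list()
  expect_warning(hb <- screen_library(broken, model), "skipped")
  expect_equal(attr(hb, "n_failed"), 1)
})

test_that("fits are invariant under a common rigid motion of the frame", {
  model <- square_model()
  centers <- as.matrix(model$features[, c("x", "y", "z")])
  set.seed(3)
  pxyz <- centers + matrix(rnorm(12, sd = 0.4), ncol = 3)
  pts <- points_df(model$features$kind, pxyz)
  f0 <- map_conformer(pxyz, pts, model)$fit
  for (k in 1:5) {
    tf <- random_rigid()
    m2 <- model
    m2$features[, c("x", "y", "z")] <-
      apply_transform(centers, tf)
    p2 <- apply_transform(pxyz, tf)
    f1 <- map_conformer(p2, points_df(pts$kind, p2), m2)$fit
    expect_equal(f1, f0, tolerance = 1e-6)
  }
})
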