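test_that("read_complex splits protein and ligand and counts removals", {
  cx <- read_complex(toy_pdb_lines(), "MSP")
  expect_s3_class(cx, "pharm_complex")
  expect_equal(nrow(cx$protein), 5)
  expect_equal(nrow(cx$ligand$atoms), 4)
  expect_equal(cx$removed$waters, 3)
  expect_equal(cx$removed$ions, 1)
  expect_false(any(cx$protein$resname %in% c("HOH", "WAT")))
  # CONECT bonds survive
  expect_equal(nrow(cx$ligand$bonds), 3)
})

test_that("read_complex errors are specific", {
  expect_error(read_complex(toy_pdb_lines(), "XXX"), "ligand not found")
  no_protein <- grep("^ATOM", toy_pdb_lines(), value = TRUE, invert = TRUE)
  expect_error(read_complex(no_protein, "MSP"), "no protein")
})

test_that("write/read PDB round trip preserves coordinates", {
  spec <- fixture_spec(seed = 5)
  ens <- make_complex_ensemble(spec)
  tmp <- tempfile(fileext = ".pdb")
  write_complex_pdb(ens[[1]], tmp)
  back <- read_complex(tmp, "LIG")
  expect_equal(nrow(back$protein), nrow(ens[[1]]$protein))
  expect_equal(nrow(back$ligand$atoms), nrow(ens[[1]]$ligand$atoms))
  expect_lt(max(abs(atom_coords(back$protein) -
                      atom_coords(ens[[1]]$protein))), 1e-3)
  expect_lt(max(abs(atom_coords(back$ligand$atoms) -
                      atom_coords(ens[[1]]$ligand$atoms))), 1e-3)
  expect_identical(back$ligand$atoms$charge, ens[[1]]$ligand$atoms$charge)
  unlink(tmp)
})

test_that("water/ion stripping leaves remaining coordinates untouched", {
  with_junk <- toy_pdb_lines()
  cx <- read_complex(with_junk, "MSP")
  clean <- grep("HOH|NA ", with_junk, value = TRUE, invert = TRUE)
  cx2 <- read_complex(clean, "MSP")
  expect_equal(atom_coords(cx$protein), atom_coords(cx2$protein))
  expect_equal(atom_coords(cx$ligand$atoms), atom_coords(cx2$ligand$atoms))
})

test_that("binding_site uses a closed boundary and matches brute force", {
  lig <- mol_methylamine()
  prot <- make_protein(
    c("CA", "CA", "CA"), c("C", "C", "C"), rep("GLY", 3), 1:3,
    rbind(c(5, 0, 0), c(12, 0, 0), c(20, 0, 0))
  )
  cx <- make_complex_obj(prot, lig)
  site <- binding_site(cx, radius = 12)
  # atom at exactly 12 A from the ligand N is included
  expect_true(2 %in% site$resno)
  expect_true(1 %in% site$resno)
  expect_false(3 %in% site$resno)
  expect_error(binding_site(cx, radius = 0), "radius")

  # 50-atom random fixture vs O(n^2) oracle
  set.seed(42)
  prot2 <- make_protein(
    rep("CA", 50), rep("C", 50), rep("GLY", 50), 1:50,
    matrix(rnorm(150, sd = 8), ncol = 3)
  )
  cx2 <- make_complex_obj(prot2, lig)
  r <- 6.5
  site2 <- binding_site(cx2, radius = r)
  lxyz <- atom_coords(lig$atoms)
  expected <- sort(unique(prot2$resno[vapply(seq_len(50), function(i) {
    any(sqrt(colSums((t(lxyz) - as.numeric(prot2[i, c("x", "y", "z")]))^2))
        <= r)
  }, logical(1))]))
  expect_equal(sort(site2$resno), expected)
})

test_that("kabsch recovers exact transforms and is optimal", {
  set.seed(1)
  P <- matrix(rnorm(30), ncol = 3)
  # identity case
  fit0 <- kabsch(P, P)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$transform$rotation, diag(3), tolerance = 1e-9)

  # constructed rotation + translation is recovered
  Rz <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  Q <- sweep(P %*% t(Rz), 2, -c(1, 2, 3))
  fit <- kabsch(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$transform$rotation, Rz, tolerance = 1e-9)
  expect_equal(fit$transform$translation, c(1, 2, 3), tolerance = 1e-9)

  expect_error(kabsch(P[1:2, ], Q[1:2, ]), "insufficient points")

  # optimality: no random rigid transform of P lands closer to Q
  Qn <- Q + matrix(rnorm(30, sd = 0.4), ncol = 3)
  best <- kabsch(P, Qn)
  sq <- function(X) mean(rowSums((X - Qn)^2))
  best_sq <- sq(apply_transform(P, best$transform))
  for (k in 1:1000) {
    cand_sq <- sq(apply_transform(P, random_rigid()))
    expect_gte(cand_sq, best_sq - 1e-9)
  }
})

test_that("superposition agrees with the bio3d fitting route", {
  set.seed(17)
  for (k in 1:5) {
    P <- matrix(rnorm(45), ncol = 3)
    Q <- apply_transform(P, random_rigid()) +
      matrix(rnorm(45, sd = 0.3), ncol = 3)
    ours <- apply_transform(P, kabsch(P, Q)$transform)
    ref <- matrix(bio3d::fit.xyz(
      fixed = as.numeric(t(Q)), mobile = as.numeric(t(P)),
      fixed.inds = 1:45, mobile.inds = 1:45
    ), ncol = 3, byrow = TRUE)
    expect_lt(max(abs(ours - ref)), 1e-6)
  }
})

test_that("rigid transforms are proper and invertible", {
  set.seed(2)
  tf <- random_rigid()
  expect_equal(det(tf$rotation), 1, tolerance = 1e-6)
  X <- matrix(rnorm(30), ncol = 3)
  back <- apply_transform(apply_transform(X, tf), invert_transform(tf))
  expect_lt(max(abs(back - X)), 1e-6)
  tf2 <- random_rigid()
  one <- apply_transform(apply_transform(X, tf), tf2)
  two <- apply_transform(X, compose_transform(tf, tf2))
  expect_lt(max(abs(one - two)), 1e-9)
})

test_that("superposition restores scattered complexes and is idempotent", {
  spec <- fixture_spec(seed = 9)
  ens <- make_complex_ensemble(spec, scatter = TRUE)
  anchors <- attr(ens, "anchors")
  pairing <- data.frame(mobile = anchors, reference = anchors,
                        stringsAsFactors = FALSE)
  ref <- ens[[1]]

  # trivial self-pairing
  self <- superpose_to_reference(ref, ref, pairing)
  expect_equal(self$rmsd, 0, tolerance = 1e-9)

  # rigidly displaced copy comes back exactly, ligand included
  aligned <- make_complex_ensemble(spec, scatter = FALSE)
  sup <- superpose_to_reference(ens[[3]], ref, pairing)
  expect_equal(sup$rmsd, 0, tolerance = 1e-6)
  expect_lt(max(abs(atom_coords(sup$complex$ligand$atoms) -
                      atom_coords(aligned[[3]]$ligand$atoms))), 1e-6)

  # idempotent: superposing the superposed complex moves nothing
  again <- superpose_to_reference(sup$complex, ref, pairing)
  expect_lt(max(abs(atom_coords(again$complex$protein) -
                      atom_coords(sup$complex$protein))), 1e-6)

  expect_error(
    superpose_to_reference(ens[[2]], ref,
                           data.frame(mobile = c("A:901", "A:902", "B:1"),
                                      reference = anchors[1:3])),
    "pairing unresolved")
})

test_that("noisy anchor superposition lands at the expected residual", {
  spec <- fixture_spec(seed = 4)
  ens <- make_complex_ensemble(spec)
  ref <- ens[[1]]
  anchors <- attr(ens, "anchors")
  pairing <- data.frame(mobile = anchors, reference = anchors,
                        stringsAsFactors = FALSE)
  rmsds <- vapply(1:20, function(s) {
    set.seed(s)
    mob <- ens[[2]]
    is_ca <- mob$protein$name == "CA"
    xyz <- atom_coords(mob$protein)
    xyz[is_ca, ] <- xyz[is_ca, ] +
      matrix(rnorm(3 * sum(is_ca), sd = 0.5), ncol = 3)
    mob$protein <- mob$protein
    mob$protein$x <- xyz[, 1]; mob$protein$y <- xyz[, 2]
    mob$protein$z <- xyz[, 3]
    superpose_to_reference(mob, ref, pairing)$rmsd
  }, numeric(1))
  expect_gt(mean(rmsds), 0.3)
  expect_lt(mean(rmsds), 0.8)
})
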