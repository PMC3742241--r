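# Independent brute-force references used by both the unit and the
# acceptance suites.

# candidate feature point frame for hand-built mapping instances
points_df <- function(kind, xyz) {
  data.frame(kind = kind, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

# exhaustive assignment search: expand.grid over all candidate
# combinations, filter injective, score with the public primitives
oracle_best_fit <- function(pts, model) {
  feats <- model$features
  cand <- lapply(feats$kind, function(k) which(pts$kind == k))
  if (any(lengths(cand) == 0)) return(0)
  grid <- do.call(expand.grid, cand)
  centers <- as.matrix(feats[, c("x", "y", "z")])
  best <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    if (anyDuplicated(asg)) next
    P <- as.matrix(pts[asg, c("x", "y", "z")])
    tf <- kabsch(P, centers)$transform
    disp <- sqrt(rowSums((apply_transform(P, tf) - centers)^2))
    if (any(disp > feats$tolerance)) next
    best <- max(best, fit_value(disp, feats$tolerance))
  }
  best
}

# brute-force ligand/protein hydrogen-bond pair scan (distance-only form)
oracle_hbond_pairs <- function(cx) {
  lig <- cx$ligand
  nH <- implicit_h(lig)
  lelem <- toupper(lig$atoms$element)
  don <- which(lelem %in% c("N", "O", "S") & nH >= 1)
  acc <- which(lelem %in% c("N", "O"))
  prot <- cx$protein
  pacc <- which(toupper(prot$element) == "O" |
                  prot$name %in% c("ND1", "NE2"))
  pdon <- which(toupper(prot$element) %in% c("N", "S") |
                  prot$name %in% c("OG", "OG1", "OH"))
  lxyz <- atom_coords(lig$atoms)
  pxyz <- atom_coords(prot)
  pairs <- character()
  for (i in don) for (j in pacc) {
    if (sqrt(sum((lxyz[i, ] - pxyz[j, ])^2)) <= 3.5) {
      pairs <- c(pairs, paste("L", i, "P", j))
    }
  }
  for (i in pdon) for (j in acc) {
    if (sqrt(sum((pxyz[i, ] - lxyz[j, ])^2)) <= 3.5) {
      pairs <- c(pairs, paste("P", i, "L", j))
    }
  }
  pairs
}
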