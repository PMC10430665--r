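# Independent oracles: deliberately naive re-implementations (plain loops,
# closed forms, exhaustive enumeration) used to cross-check the package's
# vectorized/recursive implementations.

# ---- brute-force PLIF predicate oracle -------------------------------------
# Re-implements every interaction predicate with O(atoms^2) double loops,
# independent of the package's detector internals.

oracle_detect <- function(pose, receptor, criteria = interaction_criteria()) {
  la <- pose$atoms
  lheavy <- la[la$element != "H", , drop = FALSE]
  lh <- la[la$element == "H", , drop = FALSE]
  has_h <- nrow(lh) > 0
  d3 <- function(a, b) sqrt(sum((a - b)^2))
  lig_xyz <- function(df, i) as.numeric(df[i, c("x", "y", "z")])

  # ligand donors: N/O with an H within 1.25 A (or all N/O when no H anywhere)
  lig_donors <- list()
  for (i in seq_len(nrow(lheavy))) {
    if (!(lheavy$element[i] %in% c("N", "O", "S"))) next
    if (!has_h) {
      if (lheavy$element[i] %in% c("N", "O")) lig_donors[[length(lig_donors) + 1]] <- list(d = lig_xyz(lheavy, i), h = NULL)
    } else {
      for (q in seq_len(nrow(lh))) {
        if (d3(lig_xyz(lheavy, i), lig_xyz(lh, q)) < 1.25)
          lig_donors[[length(lig_donors) + 1]] <- list(d = lig_xyz(lheavy, i), h = lig_xyz(lh, q))
      }
    }
  }
  # ligand aromatic rings (same component rule, naive loops)
  arom <- which(la$aromatic & la$element != "H")
  lrings <- list()
  if (length(arom) >= 5) {
    left <- arom
    while (length(left) >= 5) {
      comp <- left[1]; grew <- TRUE
      while (grew) {
        grew <- FALSE
        for (cand in setdiff(left, comp)) {
          for (m in comp) {
            if (d3(lig_xyz(la, cand), lig_xyz(la, m)) < 1.75) {
              comp <- c(comp, cand); grew <- TRUE; break
            }
          }
        }
      }
      if (length(comp) >= 5) {
        xyz <- as.matrix(la[comp, c("x", "y", "z")])
        degs <- sapply(seq_along(comp), function(ii)
          sum(sapply(seq_along(comp), function(jj)
            ii != jj && d3(xyz[ii, ], xyz[jj, ]) < 1.75)))
        if (all(degs >= 2))
          lrings[[length(lrings) + 1]] <- list(centroid = colMeans(xyz),
                                               normal = a2ascreen:::ring_normal(xyz))
      }
      left <- setdiff(left, comp)
    }
  }

  gate <- max(criteria$hydrophobic_max_dist, criteria$hbond_max_dist,
              criteria$saltbridge_max_dist, criteria$ring_centroid_max_dist,
              criteria$metal_max_dist) + 1
  out <- NULL
  for (res in receptor$residues) {
    ra <- res$atoms
    rxyz <- function(i) as.numeric(ra[i, c("x", "y", "z")])
    near <- FALSE
    for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(lheavy)))
      if (ra$element[i] != "H" && d3(rxyz(i), lig_xyz(lheavy, j)) <= gate) near <- TRUE
    if (!near) next
    bits <- rep(FALSE, 8)
    # b0
    if (res$name %in% a2ascreen:::HYDROPHOBIC_RESIDUES) {
      for (i in which(ra$element %in% c("C", "S")))
        for (j in which(lheavy$element %in% c("C", "S")))
          if (d3(rxyz(i), lig_xyz(lheavy, j)) <= criteria$hydrophobic_max_dist) bits[1] <- TRUE
    }
    # rings
    for (ring_names in (res$aromatic_ring_atoms %||% list())) {
      ix <- match(ring_names, ra$name); ix <- ix[!is.na(ix)]
      if (length(ix) < 5) next
      xyz <- as.matrix(ra[ix, c("x", "y", "z")])
      rc <- colMeans(xyz); rn <- a2ascreen:::ring_normal(xyz)
      for (lr in lrings) {
        if (d3(rc, lr$centroid) > criteria$ring_centroid_max_dist) next
        ang <- a2ascreen:::normal_angle(rn, lr$normal)
        if (ang <= criteria$face_face_max_normal_angle) bits[2] <- TRUE
        else if (ang >= criteria$edge_face_normal_angle_range[1] &&
                 ang <= criteria$edge_face_normal_angle_range[2]) bits[3] <- TRUE
      }
    }
    # b3: residue acceptors
    accs <- c(which(ra$name == "O"),
              which(ra$name %in% a2ascreen:::ACCEPTOR_ATOMS[[res$name]]))
    for (i in unique(accs)) for (dn in lig_donors) {
      if (d3(rxyz(i), dn$d) > criteria$hbond_max_dist) next
      if (!is.null(dn$h)) {
        ang <- a2ascreen:::vec_angle(dn$d - dn$h, rxyz(i) - dn$h)
        if (ang < criteria$hbond_min_angle) next
      }
      bits[4] <- TRUE
    }
    # b4: residue donors vs ligand N/O
    dons <- c(if (res$name != "PRO") which(ra$name == "N"),
              which(ra$name %in% a2ascreen:::DONOR_ATOMS[[res$name]]))
    for (i in unique(dons)) for (j in which(lheavy$element %in% c("N", "O")))
      if (d3(rxyz(i), lig_xyz(lheavy, j)) <= criteria$hbond_max_dist) bits[5] <- TRUE
    # b5/b6
    is_metal <- res$name %in% a2ascreen:::METAL_RESIDUES
    if (!is_metal && res$name %in% a2ascreen:::POSITIVE_RESIDUES) {
      grp <- a2ascreen:::CHARGED_GROUP_ATOMS[[res$name]]
      ix <- which(ra$name %in% grp)
      cc <- colMeans(as.matrix(ra[ix, c("x", "y", "z"), drop = FALSE]))
      for (j in which(lheavy$charge < 0))
        if (d3(cc, lig_xyz(lheavy, j)) <= criteria$saltbridge_max_dist) bits[6] <- TRUE
    }
    if (res$name %in% a2ascreen:::NEGATIVE_RESIDUES) {
      grp <- a2ascreen:::CHARGED_GROUP_ATOMS[[res$name]]
      ix <- which(ra$name %in% grp)
      cc <- colMeans(as.matrix(ra[ix, c("x", "y", "z"), drop = FALSE]))
      for (j in which(lheavy$charge > 0))
        if (d3(cc, lig_xyz(lheavy, j)) <= criteria$saltbridge_max_dist) bits[7] <- TRUE
    }
    # b7
    if (is_metal) {
      for (i in seq_len(nrow(ra)))
        for (j in which(lheavy$element %in% c("N", "O") | lheavy$charge != 0))
          if (d3(rxyz(i), lig_xyz(lheavy, j)) <= criteria$metal_max_dist) bits[8] <- TRUE
    }
    row <- data.frame(residue_key = a2ascreen:::residue_key(res))
    for (b in seq_along(a2ascreen:::PLIF_BIT_NAMES))
      row[[a2ascreen:::PLIF_BIT_NAMES[b]]] <- bits[b]
    out <- rbind(out, row)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# compare a detector table against the oracle (keyed by residue)
expect_same_bits <- function(got, want) {
  if (is.null(want)) want <- got[0, , drop = FALSE]
  expect_setequal(got$residue_key, want$residue_key)
  if (!nrow(got)) return(invisible(TRUE))
  got <- got[order(got$residue_key), , drop = FALSE]
  want <- want[order(want$residue_key), , drop = FALSE]
  for (b in a2ascreen:::PLIF_BIT_NAMES)
    expect_equal(got[[b]], want[[b]], info = paste("bit", b))
}

# check a detector table against a fixture manifest (absent residue = all 0)
manifest_holds <- function(blocks, manifest) {
  for (r in seq_len(nrow(manifest))) {
    key <- manifest$residue_key[r]
    row <- blocks[blocks$residue_key == key, , drop = FALSE]
    got <- if (!nrow(row)) FALSE else row[[manifest$bit[r]]]
    if (got != manifest$expected[r]) return(FALSE)
  }
  TRUE
}

# ---- confusion-matrix and AUC oracles --------------------------------------

oracle_metrics <- function(scores, labels, threshold = 0.5) {
  y <- labels == "agonist" | labels == 1
  tp <- fp <- fn <- tn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= threshold
    if (pred && y[i]) tp <- tp + 1
    if (pred && !y[i]) fp <- fp + 1
    if (!pred && y[i]) fn <- fn + 1
    if (!pred && !y[i]) tn <- tn + 1
  }
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(precision = prec, recall = rec, f1 = f1,
    accuracy = (tp + tn) / length(y))
}

# AUC as the Mann-Whitney pair statistic (independent of the trapezoid rule)
oracle_auc <- function(scores, labels) {
  y <- labels == "agonist" | labels == 1
  pos <- scores[y]; neg <- scores[!y]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# ---- exhaustive Shapley oracle for tree ensembles --------------------------

# conditional expectation of one tree given the feature subset S
oracle_expvalue <- function(tree, x, S, node = 1L) {
  if (tree$leaf[node]) return(tree$value[node])
  f <- tree$feature[node]
  l <- tree$left[node]; r <- tree$right[node]
  if (f %in% S) {
    nxt <- if (x[f] <= tree$threshold[node]) l else r
    oracle_expvalue(tree, x, S, nxt)
  } else {
    (tree$cover[l] * oracle_expvalue(tree, x, S, l) +
     tree$cover[r] * oracle_expvalue(tree, x, S, r)) / tree$cover[node]
  }
}

# Shapley values by full coalition enumeration over M model features
oracle_tree_shapley <- function(tree, x, n_features) {
  M <- n_features
  phi <- numeric(M)
  feats <- seq_len(M)
  subsets <- unlist(lapply(0:(M - 1), function(sz)
    combn(M, sz, simplify = FALSE)), recursive = FALSE)
  for (i in feats) {
    for (S in subsets) {
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(M - length(S) - 1) / factorial(M)
      phi[i] <- phi[i] + w * (oracle_expvalue(tree, x, c(S, i)) -
                              oracle_expvalue(tree, x, S))
    }
  }
  phi
}

# ---- Tanimoto popcount oracle ----------------------------------------------

oracle_tanimoto <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i] || b[i]) uni <- uni + 1
  }
  if (uni == 0) 1 else inter / uni
}

# ---- analytic linear cascade -----------------------------------------------

# closed-form solution of the two-compartment linear cascade (constant ATP):
#   G*(t)  = (A/B) (1 - exp(-B t)),  A = k_act R_occ G_tot, B = k_act R_occ + k_hyd
#   cAMP'  = a0 + a1 (1 - exp(-B t)) - kp cAMP
oracle_linear_cascade <- function(params, occ, t) {
  A <- params$k_G_act * params$receptor_total * occ * params$G_total
  B <- params$k_G_act * params$receptor_total * occ + params$k_G_hyd
  kp <- params$k_PDE
  a0 <- params$k_PDE * params$cAMP_basal
  a1 <- params$k_AC_cat * params$ATP_total * A / B
  c0 <- params$cAMP_basal
  stopifnot(abs(kp - B) > 1e-9)
  const <- c0 - (a0 + a1) / kp + a1 / (kp - B)
  (a0 + a1) / kp - a1 * exp(-B * t) / (kp - B) + const * exp(-kp * t)
}

# ---- tiny text fixtures ----------------------------------------------------

sdf_record <- function(id, atoms, bonds = NULL, fields = list()) {
  n <- nrow(atoms); nb <- if (is.null(bonds)) 0 else nrow(bonds)
  lines <- c(id, "  synth", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i]))
  for (i in seq_len(nb))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", bonds$i[i], bonds$j[i], bonds$order[i]))
  lines <- c(lines, "M  END")
  for (nm in names(fields)) lines <- c(lines, sprintf("> <%s>", nm), fields[[nm]], "")
  c(lines, "$$$$")
}

write_sdf_fixture <- function(path, records) {
  writeLines(unlist(records), path)
  path
}

two_atom_sdf <- function(id, score = NULL) {
  fields <- if (is.null(score)) list() else list(score = score)
  sdf_record(id, data.frame(element = c("C", "O"), x = c(0, 1.4), y = 0, z = 0),
             data.frame(i = 1, j = 2, order = 1), fields)
}

pdb_fixture_lines <- function() c(
  "ATOM      1  N   ALA A 253      11.104   6.134  -6.504  1.00  0.00           N",
  "ATOM      2  CA  ALA A 253      12.560   6.134  -6.504  1.00  0.00           C",
  "ATOM      3  CB AALA A 253      13.000   7.000  -5.000  0.40  0.00           C",
  "ATOM      4  CB BALA A 253      13.100   7.100  -5.100  0.60  0.00           C",
  "ATOM      5  N   GLY A 254      14.000   8.000  -4.000  1.00  0.00           N",
  "ATOM      6  CA  GLY A 254      15.400   8.000  -4.000  1.00  0.00           C",
  "HETATM    7  O   HOH A 401       0.000   0.000   0.000  1.00  0.00           O",
  "HETATM    8  C1  LIG A 500       1.000   1.000   1.000  1.00  0.00           C",
  "END")
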