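crit <- interaction_criteria()

test_that("constructed geometries trigger exactly the intended bits", {
  # donor-acceptor pair at 2.9 A with a 165-degree D-H...A angle
  fx <- make_pocket_fixture(data.frame(bit = "hbond_acceptor", distance = 2.9, angle = 165))
  bl <- detect_interactions(fx$pose, fx$receptor, crit)
  expect_true(bl$hbond_acceptor[bl$residue_key == "A:101:ASN"])
  # same pair at 4.5 A: beyond the cutoff
  fx2 <- make_pocket_fixture(data.frame(bit = "hbond_acceptor", distance = 4.5,
                                        angle = 165, expect = FALSE))
  bl2 <- detect_interactions(fx2$pose, fx2$receptor, crit)
  expect_false(any(bl2$hbond_acceptor))
  # parallel rings, centroids 3.6 A apart, normals at 5 degrees
  fx3 <- make_pocket_fixture(data.frame(bit = "aromatic_face_face", distance = 3.6, angle = 5))
  bl3 <- detect_interactions(fx3$pose, fx3$receptor, crit)
  expect_true(bl3$aromatic_face_face[bl3$residue_key == "A:101:PHE"])
  expect_false(bl3$aromatic_edge_face[bl3$residue_key == "A:101:PHE"])
  # carboxylate-like charged oxygen 3.5 A from the arginine guanidinium
  fx4 <- make_pocket_fixture(data.frame(bit = "saltbridge_positive", distance = 3.5))
  bl4 <- detect_interactions(fx4$pose, fx4$receptor, crit)
  expect_true(bl4$saltbridge_positive[bl4$residue_key == "A:101:ARG"])
})

test_that("a low D-H...A angle vetoes the H-bond when hydrogens are explicit", {
  fx <- make_pocket_fixture(data.frame(bit = "hbond_acceptor", distance = 3.0, angle = 95))
  bl <- detect_interactions(fx$pose, fx$receptor, crit)
  expect_false(any(bl$hbond_acceptor))
})

test_that("a pose without heavy atoms is rejected", {
  fx <- make_pocket_fixture(data.frame(bit = "hydrophobic", distance = 3.5))
  fx$pose$atoms$element <- "H"
  expect_error(detect_interactions(fx$pose, fx$receptor), "heavy")
})

test_that("shrinking distance cutoffs never sets a new bit (monotonicity)", {
  for (seed in c(11, 12, 13, 14, 15)) {
    fx <- make_pocket_fixture(random_pocket_spec(seed))
    wide <- detect_interactions(fx$pose, fx$receptor, crit)
    narrow_crit <- interaction_criteria(
      hydrophobic_max_dist = 3.0, hbond_max_dist = 2.6,
      saltbridge_max_dist = 3.0, ring_centroid_max_dist = 4.0,
      metal_max_dist = 2.0)
    narrow <- detect_interactions(fx$pose, fx$receptor, narrow_crit)
    for (key in narrow$residue_key) {
      nb <- narrow[narrow$residue_key == key, a2ascreen:::PLIF_BIT_NAMES]
      wb <- wide[wide$residue_key == key, a2ascreen:::PLIF_BIT_NAMES]
      if (!nrow(wb)) wb <- nb & FALSE
      expect_true(all(!unlist(nb) | unlist(wb)),
                  info = paste("seed", seed, key))
    }
  }
})

test_that("the detector agrees with the brute-force predicate oracle on random fixtures", {
  for (seed in 1:40) {
    fx <- make_pocket_fixture(random_pocket_spec(seed))
    got <- detect_interactions(fx$pose, fx$receptor, crit)
    want <- oracle_detect(fx$pose, fx$receptor, crit)
    expect_same_bits(got, want)
    expect_true(manifest_holds(got, fx$manifest), info = paste("seed", seed))
  }
})

test_that("interaction bits are invariant under rigid motions", {
  for (seed in c(3, 7)) {
    fx <- make_pocket_fixture(random_pocket_spec(seed))
    ref <- detect_interactions(fx$pose, fx$receptor, crit)
    for (tseed in 1:3) {
      moved <- rigid_transform_fixture(fx, seed = tseed)
      got <- detect_interactions(moved$pose, moved$receptor, crit)
      expect_same_bits(got, ref)
    }
  }
})

test_that("feature matrices have 8 columns per residue plus an optional score", {
  fx <- make_pocket_fixture(data.frame(
    bit = c("hbond_acceptor", "aromatic_face_face", "hydrophobic"),
    distance = c(2.9, 3.6, 3.5), angle = c(165, 5, NA)))
  pv <- plif_vector(fx$pose, fx$receptor)
  pv2 <- pv; pv2$docking_score_feature <- -9.5
  ord <- plif_residue_order(list(pv, pv2))
  expect_length(ord, 3L)
  X <- build_feature_matrix(list(pv, pv2), ord, include_score = FALSE)
  expect_equal(dim(X), c(2L, 24L))
  Xs <- build_feature_matrix(list(pv, pv2), ord, include_score = TRUE)
  expect_equal(dim(Xs), c(2L, 25L))
  expect_equal(unname(Xs[, "docking_score"]), c(-8, -9.5))
  # unknown residues are dropped with a warning
  expect_warning(Xd <- build_feature_matrix(list(pv, pv2), ord[1:2]), "dropped")
  expect_equal(ncol(Xd), 17L)
  expect_error(build_feature_matrix(list()), "empty")
})

test_that("bit frequencies are per-class count ratios", {
  X <- matrix(0, 6, 2, dimnames = list(NULL, c("A:1:SER.hbond_acceptor",
                                               "A:2:LEU.hydrophobic")))
  X[1:2, 1] <- 1          # set for 2 of 4 agonist rows
  labels <- c(rep("agonist", 4), rep("antagonist", 2))
  fr <- summarize_bit_frequencies(X, labels)
  expect_equal(fr$agonist, c(0.5, 0))
  expect_equal(fr$antagonist, c(0, 0))
  expect_error(summarize_bit_frequencies(X, rep("agonist", 6)), NA)
  expect_error(summarize_bit_frequencies(X[0, , drop = FALSE], character(0)))
})

test_that("a planted marker bit reaches frequency 1.0 in its class", {
  lib <- make_labeled_library(library_spec(n_per_class = 6, poses_per_molecule = 2,
                                           pose_noise = 0, overlap = 0, seed = 2))
  # force the marker on for every agonist molecule, then recount by brute force
  col <- "A:278:HIS.hbond_acceptor"
  lib$plif[lib$pose_labels == "agonist", col] <- 1
  fr <- summarize_bit_frequencies(lib$plif[, -ncol(lib$plif)], lib$pose_labels)
  brute <- mean(lib$plif[lib$pose_labels == "agonist", col] > 0)
  expect_equal(fr$agonist[fr$feature == col], brute)
  expect_equal(brute, 1)
})
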