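## Synthetic fixtures: every pipeline stage is testable without downloads.
##
## Pocket fixtures are built from hard-coded idealized side-chain
## geometries (no rotamer libraries; sufficient for predicate testing):
## each requested interaction gets its own template residue, placed 25 A
## from its neighbors, with ligand probe atoms constructed to realize the
## requested geometry exactly. The accompanying manifest states which bits
## must be set or unset, so fixtures are self-validating.

# ---- idealized residue templates -------------------------------------------

RESIDUE_TEMPLATES <- list(
  GLY = data.frame(
    name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
    x = c(0, 1.46, 2.0, 1.5), y = c(0, 0, 1.3, 2.4), z = c(0, 0, 0, 0)),
  ALA = data.frame(
    name = c("N", "CA", "C", "O", "CB"), element = c("N", "C", "C", "O", "C"),
    x = c(0, 1.46, 2.0, 1.5, 1.9), y = c(0, 0, 1.3, 2.4, -0.8),
    z = c(0, 0, 0, 0, 1.1)),
  LEU = data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CD2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "C"),
    x = c(0, 1.46, 2.0, 1.5, 1.9, 2.6, 4.1, 2.1),
    y = c(0, 0, 1.3, 2.4, -0.8, -1.9, -1.8, -3.2),
    z = c(0, 0, 0, 0, 1.1, 1.8, 1.7, 1.2)),
  SER = data.frame(
    name = c("N", "CA", "C", "O", "CB", "OG"),
    element = c("N", "C", "C", "O", "C", "O"),
    x = c(0, 1.46, 2.0, 1.5, 1.9, 3.3),
    y = c(0, 0, 1.3, 2.4, -0.8, -0.9),
    z = c(0, 0, 0, 0, 1.1, 1.2)),
  ASN = data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
    element = c("N", "C", "C", "O", "C", "C", "O", "N"),
    x = c(0, 1.46, 2.0, 1.5, 1.9, 3.0, 4.2, 2.5),
    y = c(0, 0, 1.3, 2.4, -0.8, -1.2, -1.0, -2.4),
    z = c(0, 0, 0, 0, 1.1, 1.5, 1.7, 1.6)),
  ARG = data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
    element = c("N", "C", "C", "O", "C", "C", "C", "N", "C", "N", "N"),
    x = c(0, 1.46, 2.0, 1.5, 1.9, 2.6, 3.4, 4.0, 5.0, 5.0, 6.1),
    y = c(0, 0, 1.3, 2.4, -0.8, -1.9, -1.6, -0.6, 0, 1.33, -0.6),
    z = c(0, 0, 0, 0, 1.1, 1.8, 2.9, 3.4, 3.4, 3.4, 3.4)),
  ASP = data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
    element = c("N", "C", "C", "O", "C", "C", "O", "O"),
    x = c(0, 1.46, 2.0, 1.5, 1.9, 3.0, 4.2, 2.7),
    y = c(0, 0, 1.3, 2.4, -0.8, -1.2, -1.0, -2.4),
    z = c(0, 0, 0, 0, 1.1, 1.4, 1.4, 1.6)),
  MG = data.frame(name = "MG", element = "MG", x = 0, y = 0, z = 0)
)

# hexagonal aromatic ring at local origin, plane z = 0 (radius 1.39 A)
hexagon_ring <- function() {
  ang <- seq(0, 300, by = 60) * pi / 180
  cbind(x = 1.39 * cos(ang), y = 1.39 * sin(ang), z = 0)
}

PHE_TEMPLATE <- local({
  ring <- hexagon_ring()
  ring[, "x"] <- ring[, "x"] + 4  # ring center at (4, 0, 0)
  data.frame(
    name = c("N", "CA", "C", "O", "CB", "CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
    element = c("N", "C", "C", "O", "C", rep("C", 6)),
    x = c(0, 1.46, 2.0, 1.5, 1.9, ring[c(4, 3, 2, 1, 6, 5), "x"]),
    y = c(0, 0, 1.3, 2.4, -0.8, ring[c(4, 3, 2, 1, 6, 5), "y"]),
    z = c(0, 0, 0, 0, 1.1, ring[c(4, 3, 2, 1, 6, 5), "z"]))
})
RESIDUE_TEMPLATES$PHE <- PHE_TEMPLATE

# interaction-site anchors per (template, bit): anchor atom(s) and the
# outward direction along which probes are placed
FIXTURE_SITES <- list(
  hydrophobic = list(res = "LEU", anchor = "CD1", dir = c(1, -0.2, 0.4)),
  aromatic_face_face = list(res = "PHE", anchor = "ring", dir = c(0, 0, 1)),
  aromatic_edge_face = list(res = "PHE", anchor = "ring", dir = c(0, 0, 1)),
  hbond_acceptor = list(res = "ASN", anchor = "OD1", dir = c(1, 0.15, 0.15)),
  hbond_donor = list(res = "GLY", anchor = "N", dir = c(-1, -0.3, 0.2)),
  saltbridge_positive = list(res = "ARG", anchor = "guanidinium", dir = c(0.6, 0, 1)),
  saltbridge_negative = list(res = "ASP", anchor = "carboxylate", dir = c(0.8, -0.6, 0.6)),
  metal = list(res = "MG", anchor = "MG", dir = c(1, 1, 1))
)

# rotate `xyz` so that +z maps onto angle `deg` from +z (tilt about x axis)
tilt_about_x <- function(xyz, deg) {
  a <- deg * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  xyz %*% t(R)
}

# place a donor H so the D-H...A angle equals `deg` (|D-H| = 0.96 A)
place_donor_h <- function(D, A, deg = 165) {
  u <- unit(A - D)
  v <- unit(if (abs(u[1]) < 0.9) pracma_cross(u, c(1, 0, 0)) else pracma_cross(u, c(0, 1, 0)))
  angle_at <- function(theta) {
    H <- D + 0.96 * (cos(theta) * u + sin(theta) * v)
    vec_angle(D - H, A - H)
  }
  f <- function(theta) angle_at(theta) - deg
  theta <- tryCatch(stats::uniroot(f, c(1e-6, pi / 2))$root, error = function(e) 1e-6)
  D + 0.96 * (cos(theta) * u + sin(theta) * v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Build a pocket fixture realizing specified interactions
#'
#' Each spec row instantiates one template residue (25 A from its
#' neighbors) and ligand probe atoms constructed so the requested
#' interaction geometry holds exactly. A row with `expect = FALSE` places
#' the probe outside every trigger region, so all bits for that residue
#' must stay clear.
#'
#' @param spec data.frame with columns `bit` (a `PLIF_BIT_NAMES` entry),
#'   `distance` (A), optional `angle` (degrees; ring-normal angle for the
#'   aromatic bits, D-H...A angle for `hbond_acceptor`), optional `expect`
#'   (default `TRUE`).
#' @param receptor_id,state_label receptor metadata.
#' @param docking_score docking score stored on the pose.
#' @return list: `receptor`, `pose`, and `manifest` (data.frame
#'   `residue_key`, `bit`, `expected`).
#' @export
make_pocket_fixture <- function(spec, receptor_id = "fixture",
                                state_label = "inactive", docking_score = -8) {
  stopifnot(is.data.frame(spec), "bit" %in% names(spec), "distance" %in% names(spec))
  if (!all(spec$bit %in% PLIF_BIT_NAMES))
    stop_fmt("unknown bit(s): %s", paste(setdiff(spec$bit, PLIF_BIT_NAMES), collapse = ", "))
  if (is.null(spec$expect)) spec$expect <- TRUE
  if (is.null(spec$angle)) spec$angle <- NA_real_
  residues <- list(); latoms <- NULL; manifest <- NULL
  for (i in seq_len(nrow(spec))) {
    site <- FIXTURE_SITES[[spec$bit[i]]]
    tmpl <- RESIDUE_TEMPLATES[[site$res]]
    offset <- c(25 * i, 0, 0)
    ratoms <- tmpl
    ratoms$x <- ratoms$x + offset[1]; ratoms$y <- ratoms$y + offset[2]
    ratoms$z <- ratoms$z + offset[3]
    res <- residue(chain = "A", number = 100 + i, name = site$res, atoms = ratoms)
    residues[[i]] <- res
    d <- spec$distance[i]
    u <- unit(site$dir)
    probe <- NULL
    if (site$anchor == "ring") {
      centroid <- colMeans(as.matrix(ratoms[ratoms$name %in%
        c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"), c("x", "y", "z")]))
      ang <- if (is.na(spec$angle[i]))
        switch(spec$bit[i], aromatic_face_face = 5, aromatic_edge_face = 75) else spec$angle[i]
      ring <- tilt_about_x(hexagon_ring(), ang)
      ring <- sweep(ring, 2, centroid + d * u, "+")
      probe <- data.frame(element = "C", x = ring[, 1], y = ring[, 2],
                          z = ring[, 3], charge = 0, aromatic = TRUE)
    } else {
      anchor <- if (site$anchor == "guanidinium") {
        colMeans(as.matrix(ratoms[ratoms$name %in% c("CZ", "NH1", "NH2"), c("x", "y", "z")]))
      } else if (site$anchor == "carboxylate") {
        colMeans(as.matrix(ratoms[ratoms$name %in% c("OD1", "OD2"), c("x", "y", "z")]))
      } else {
        as.numeric(ratoms[ratoms$name == site$anchor, c("x", "y", "z")])
      }
      pxyz <- anchor + d * u
      probe <- switch(spec$bit[i],
        hydrophobic = data.frame(element = "C", x = pxyz[1], y = pxyz[2],
                                 z = pxyz[3], charge = 0, aromatic = FALSE),
        hbond_acceptor = {
          hxyz <- place_donor_h(pxyz, anchor,
                                if (is.na(spec$angle[i])) 165 else spec$angle[i])
          data.frame(element = c("O", "H"), x = c(pxyz[1], hxyz[1]),
                     y = c(pxyz[2], hxyz[2]), z = c(pxyz[3], hxyz[3]),
                     charge = 0, aromatic = FALSE)
        },
        hbond_donor = data.frame(element = "O", x = pxyz[1], y = pxyz[2],
                                 z = pxyz[3], charge = 0, aromatic = FALSE),
        saltbridge_positive = data.frame(element = "O", x = pxyz[1], y = pxyz[2],
                                         z = pxyz[3], charge = -1, aromatic = FALSE),
        saltbridge_negative = data.frame(element = "N", x = pxyz[1], y = pxyz[2],
                                         z = pxyz[3], charge = 1, aromatic = FALSE),
        metal = data.frame(element = "O", x = pxyz[1], y = pxyz[2],
                           z = pxyz[3], charge = 0, aromatic = FALSE))
    }
    latoms <- rbind(latoms, probe)
    key <- residue_key(res)
    manifest <- rbind(manifest, if (spec$expect[i]) {
      data.frame(residue_key = key, bit = spec$bit[i], expected = TRUE)
    } else {
      data.frame(residue_key = key, bit = PLIF_BIT_NAMES, expected = FALSE)
    })
  }
  rec <- receptor(receptor_id, residues, state_label = state_label)
  pz <- pose("probe_ligand", receptor_id, latoms, docking_score = docking_score)
  list(receptor = rec, pose = pz, manifest = manifest)
}

#' Random interaction spec for fixture-based property tests
#'
#' Draws a random subset of interaction bits; each is realized either
#' inside its trigger region (`expect = TRUE`) or well outside every
#' cutoff (`expect = FALSE`).
#'
#' @param seed RNG seed.
#' @param criteria the [interaction_criteria()] the fixture should probe.
#' @return a spec data.frame for [make_pocket_fixture()].
#' @export
random_pocket_spec <- function(seed, criteria = interaction_criteria()) {
  set.seed(seed)
  bits <- sample(PLIF_BIT_NAMES, sample(3:8, 1))
  rows <- lapply(bits, function(b) {
    positive <- runif(1) < 0.6
    max_d <- switch(b,
      hydrophobic = criteria$hydrophobic_max_dist,
      aromatic_face_face = criteria$ring_centroid_max_dist,
      aromatic_edge_face = criteria$ring_centroid_max_dist,
      hbond_acceptor = criteria$hbond_max_dist,
      hbond_donor = criteria$hbond_max_dist,
      saltbridge_positive = criteria$saltbridge_max_dist,
      saltbridge_negative = criteria$saltbridge_max_dist,
      metal = criteria$metal_max_dist)
    ring_bit <- b %in% c("aromatic_face_face", "aromatic_edge_face")
    d <- if (positive) runif(1, if (ring_bit) 3.2 else 2.2, max_d - 0.05)
         else runif(1, if (ring_bit) 8.5 else 6.0, if (ring_bit) 10 else 7)
    angle <- if (b == "aromatic_face_face") runif(1, 0, criteria$face_face_max_normal_angle - 2)
      else if (b == "aromatic_edge_face") runif(1, criteria$edge_face_normal_angle_range[1] + 2, 88)
      else if (b == "hbond_acceptor") runif(1, criteria$hbond_min_angle + 10, 178)
      else NA_real_
    data.frame(bit = b, distance = d, angle = angle, expect = positive)
  })
  do.call(rbind, rows)
}

#' Apply a rigid motion to a fixture
#'
#' Rotates and translates receptor and pose coordinates together; every
#' interaction bit must be invariant under such motions.
#'
#' @param fixture a [make_pocket_fixture()] result.
#' @param seed seed for the random rotation and translation.
#' @return the transformed fixture.
#' @export
rigid_transform_fixture <- function(fixture, seed = 1L) {
  set.seed(seed)
  # random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- runif(3, -40, 40)
  move <- function(df) {
    xyz <- as.matrix(df[, c("x", "y", "z")]) %*% t(R)
    df$x <- xyz[, 1] + tr[1]; df$y <- xyz[, 2] + tr[2]; df$z <- xyz[, 3] + tr[3]
    df
  }
  fixture$receptor$residues <- lapply(fixture$receptor$residues, function(res) {
    res$atoms <- move(res$atoms); res
  })
  fixture$pose$atoms <- move(fixture$pose$atoms)
  fixture
}

# ---- two-class ligand library ----------------------------------------------

SYNTH_RESIDUE_PANEL <- c("A:88:THR", "A:168:PHE", "A:169:GLU", "A:249:LEU",
                         "A:253:ASN", "A:271:TYR", "A:277:SER", "A:278:HIS",
                         "A:84:VAL", "A:66:ILE")

SYNTH_AGONIST_MARKERS <- c("A:278:HIS.hbond_acceptor", "A:277:SER.hbond_acceptor",
                           "A:88:THR.hbond_donor", "A:271:TYR.hbond_acceptor",
                           "A:253:ASN.hbond_donor")
SYNTH_ANTAGONIST_MARKERS <- c("A:168:PHE.hydrophobic", "A:249:LEU.hydrophobic",
                              "A:84:VAL.hydrophobic", "A:66:ILE.hydrophobic",
                              "A:168:PHE.aromatic_edge_face")
SYNTH_ANCHORS <- c("A:168:PHE.aromatic_face_face", "A:169:GLU.saltbridge_negative")

#' Specification for the synthetic two-class ligand library
#'
#' Defaults mirror the structure of a receptor-ligand training set built
#' from the best five poses of each molecule docked to three receptor
#' states: agonists are enriched in ribose-like H-bond marker bits
#' (HIS278/SER277/THR88-style contacts), antagonists in hydrophobic anchor
#' bits, both share common anchoring interactions, and docking scores are
#' drawn per (class, state) with agonists scoring better (lower) against
#' the active state. The score separation alone supports only ~0.75
#' accuracy, so classifiers must also use the interaction bits.
#'
#' @param n_per_class molecules per class (default 50).
#' @param poses_per_molecule poses per molecule per state (default 5).
#' @param states receptor states (default the three activation states).
#' @param overlap fraction of marker signal shared between classes, in
#'   `[0, 1]` (default 0.3).
#' @param score_means list of per-class, per-state docking-score means.
#' @param score_sd docking-score standard deviation.
#' @param pose_noise per-pose bit flip rate around the molecule tendency.
#' @param background_rate rate of uninformative bits.
#' @param n_ecfp_bits length of the synthetic chemical fingerprints.
#' @param seed RNG seed.
#' @return list of class `library_spec`.
#' @export
library_spec <- function(n_per_class = 50L, poses_per_molecule = 5L,
                         states = c("inactive", "active", "intermediate"),
                         overlap = 0.3,
                         score_means = list(
                           agonist = c(inactive = -7.5, active = -9.5, intermediate = -8.5),
                           antagonist = c(inactive = -6.5, active = -6.5, intermediate = -6.5)),
                         score_sd = 1, pose_noise = 0.1,
                         background_rate = 0.08, n_ecfp_bits = 512L, seed = 1L) {
  if (n_per_class < 2) stop_fmt("need at least 2 molecules per class")
  if (overlap < 0 || overlap > 1) stop_fmt("overlap must lie in [0, 1]")
  if (overlap == 1 &&
      !isTRUE(all.equal(score_means$agonist, score_means$antagonist)))
    warn_fmt("overlap = 1: classes are indistinguishable by bits; only scores differ")
  structure(list(n_per_class = n_per_class,
                 poses_per_molecule = poses_per_molecule, states = states,
                 overlap = overlap, score_means = score_means,
                 score_sd = score_sd, pose_noise = pose_noise,
                 background_rate = background_rate,
                 n_ecfp_bits = n_ecfp_bits, seed = seed),
            class = "library_spec")
}

#' Generate the synthetic two-class ligand library
#'
#' @param spec a [library_spec()].
#' @return list: `plif` (pose x feature matrix incl. docking score),
#'   `pose_labels`, `groups` (molecule id per pose), `pose_state`,
#'   `ecfp` (molecule x bit matrix), `molecule_labels`, `molecule_ids`,
#'   `spec`. Fully reproducible from the spec seed.
#' @export
make_labeled_library <- function(spec = library_spec()) {
  stopifnot(inherits(spec, "library_spec"))
  set.seed(spec$seed)
  classes <- c("agonist", "antagonist")
  mol_ids <- c(sprintf("ago%03d", seq_len(spec$n_per_class)),
               sprintf("ant%03d", seq_len(spec$n_per_class)))
  mol_label <- rep(classes, each = spec$n_per_class)
  cols <- as.vector(t(outer(SYNTH_RESIDUE_PANEL, PLIF_BIT_NAMES, paste, sep = ".")))
  p_on <- 0.85
  n_pose_per_mol <- spec$poses_per_molecule * length(states <- spec$states)
  n_pose <- length(mol_ids) * n_pose_per_mol

  # molecule-level bit tendencies
  mol_tendency <- matrix(0, length(mol_ids), length(cols),
                         dimnames = list(mol_ids, cols))
  for (m in seq_along(mol_ids)) {
    own <- if (mol_label[m] == "agonist") SYNTH_AGONIST_MARKERS else SYNTH_ANTAGONIST_MARKERS
    other <- if (mol_label[m] == "agonist") SYNTH_ANTAGONIST_MARKERS else SYNTH_AGONIST_MARKERS
    pr <- rep(spec$background_rate, length(cols))
    pr[match(own, cols)] <- p_on
    pr[match(other, cols)] <- p_on * spec$overlap
    pr[match(SYNTH_ANCHORS, cols)] <- 0.8
    mol_tendency[m, ] <- rbinom(length(cols), 1, pr)
  }

  plif <- matrix(0, n_pose, length(cols) + 1,
                 dimnames = list(NULL, c(cols, "docking_score")))
  groups <- character(n_pose); pose_state <- character(n_pose)
  row <- 0L
  for (m in seq_along(mol_ids)) {
    means <- spec$score_means[[mol_label[m]]]
    for (st in states) for (p in seq_len(spec$poses_per_molecule)) {
      row <- row + 1L
      flip <- rbinom(length(cols), 1, spec$pose_noise)
      bits <- abs(mol_tendency[m, ] - flip * (runif(length(cols)) < 0.5))
      plif[row, seq_along(cols)] <- bits
      plif[row, "docking_score"] <- rnorm(1, means[[st]], spec$score_sd)
      groups[row] <- mol_ids[m]; pose_state[row] <- st
    }
  }
  rownames(plif) <- sprintf("%s@%s#%d", groups, pose_state, seq_len(n_pose))

  # synthetic chemical fingerprints (sampled bit vectors, not real molecules)
  n_marker <- 40L
  ago_bits <- sample(spec$n_ecfp_bits, n_marker)
  n_shared <- round(spec$overlap * n_marker)
  ant_bits <- c(sample(ago_bits, n_shared),
                sample(setdiff(seq_len(spec$n_ecfp_bits), ago_bits), n_marker - n_shared))
  ecfp <- matrix(0L, length(mol_ids), spec$n_ecfp_bits,
                 dimnames = list(mol_ids, NULL))
  for (m in seq_along(mol_ids)) {
    arch <- if (mol_label[m] == "agonist") ago_bits else ant_bits
    keep <- arch[runif(n_marker) < 0.9]
    extra <- sample(spec$n_ecfp_bits, 20)
    ecfp[m, unique(c(keep, extra))] <- 1L
  }

  list(plif = plif,
       pose_labels = setNames(mol_label[match(groups, mol_ids)], rownames(plif)),
       groups = groups, pose_state = pose_state,
       ecfp = ecfp, molecule_labels = setNames(mol_label, mol_ids),
       molecule_ids = mol_ids, spec = spec)
}

#' Planted-partition fingerprint blobs
#'
#' `k` archetype bit vectors with bounded pairwise Tanimoto similarity;
#' cluster members are archetypes with bits flipped at `within_flip_rate`.
#'
#' @param k number of planted clusters (>= 2).
#' @param per_cluster members per cluster.
#' @param within_flip_rate per-set-bit drop rate (matched by random
#'   additions) within a cluster.
#' @param max_archetype_tc upper bound on pairwise archetype Tanimoto.
#' @param nbits fingerprint length.
#' @param n_set set bits per archetype.
#' @param seed RNG seed.
#' @return list: `fps` (0/1 matrix), `labels` (planted cluster per row),
#'   `archetypes`.
#' @export
make_fingerprint_blobs <- function(k, per_cluster = 10L, within_flip_rate = 0.02,
                                   max_archetype_tc = 0.2, nbits = 512L,
                                   n_set = 60L, seed = 1L) {
  if (k < 2) stop_fmt("need k >= 2")
  if (k * n_set > nbits * 0.9 && max_archetype_tc < 0.1)
    warn_fmt("archetypes may overlap more than requested (k * n_set near nbits)")
  set.seed(seed)
  arch <- matrix(0L, k, nbits)
  for (i in seq_len(k)) {
    for (try in 1:200) {
      cand <- integer(nbits); cand[sample(nbits, n_set)] <- 1L
      ok <- i == 1 || all(vapply(seq_len(i - 1), function(j)
        tanimoto(cand > 0, arch[j, ] > 0), 0) <= max_archetype_tc)
      if (ok) { arch[i, ] <- cand; break }
      if (try == 200) stop_fmt("could not place %d archetypes below Tc %.2f", k, max_archetype_tc)
    }
  }
  fps <- matrix(0L, k * per_cluster, nbits)
  labels <- rep(seq_len(k), each = per_cluster)
  add_rate <- within_flip_rate * n_set / (nbits - n_set)
  for (r in seq_len(nrow(fps))) {
    v <- arch[labels[r], ]
    drop <- v == 1 & runif(nbits) < within_flip_rate
    add <- v == 0 & runif(nbits) < add_rate
    fps[r, ] <- as.integer((v == 1 & !drop) | add)
  }
  rownames(fps) <- sprintf("blob%d_m%02d", labels, sequence(rep(per_cluster, k)))
  list(fps = fps, labels = labels, archetypes = arch)
}

#' Bundled toy SMILES set
#'
#' A handful of real, parseable SMILES (xanthine- and adenosine-flavored
#' plus simple controls) for exercising the fingerprint code on genuine
#' chemical graphs.
#'
#' @return named character vector of SMILES.
#' @export
example_smiles <- function() {
  c(caffeine = "CN1C=NC2=C1C(=O)N(C)C(=O)N2C",
    theobromine = "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
    adenine = "Nc1ncnc2[nH]cnc12",
    adenosine = "OCC1OC(n2cnc3c(N)ncnc32)C(O)C1O",
    neca_like = "CCNC(=O)C1OC(n2cnc3c(N)ncnc32)C(O)C1O",
    furan_nitrile = "N#Cc1ccco1",
    benzene = "c1ccccc1",
    ethanol = "CCO")
}
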