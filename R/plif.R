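## Per-residue 8-bit protein-ligand interaction fingerprints.
##
## Bit layout (per residue):
##   b0 hydrophobic contact          b4 residue is H-bond donor
##   b1 aromatic face-to-face        b5 salt bridge, protein positive
##   b2 aromatic edge-to-face        b6 salt bridge, protein negative
##   b3 residue is H-bond acceptor   b7 ionic bond with a metal ion
##
## All predicates are distance (and, for rings/H-bonds, angle) thresholds;
## shrinking any distance cutoff can only clear bits, never set them.

PLIF_BIT_NAMES <- c("hydrophobic", "aromatic_face_face", "aromatic_edge_face",
                    "hbond_acceptor", "hbond_donor", "saltbridge_positive",
                    "saltbridge_negative", "metal")

#' Geometric criteria for interaction detection
#'
#' Defaults follow common interaction-fingerprint practice: 4.0 A
#' hydrophobic C/S contact; 3.5 A heavy-atom H-bond distance with a
#' donor-H...acceptor angle of at least 120 degrees applied only when
#' explicit hydrogens are present; 4.0 A between charged-group centers for
#' salt bridges; ring centroids within 5.0 A with a face-face normal angle
#' up to 30 degrees or an edge-face angle of 60-90 degrees; 2.8 A for
#' metal coordination.
#'
#' @param hydrophobic_max_dist,hbond_max_dist,saltbridge_max_dist,ring_centroid_max_dist,metal_max_dist distances in Angstrom.
#' @param hbond_min_angle minimum D-H...A angle in degrees.
#' @param face_face_max_normal_angle maximum ring-normal angle (degrees) for
#'   a face-to-face contact.
#' @param edge_face_normal_angle_range two-element degree range for
#'   edge-to-face contacts.
#' @return list of class `interaction_criteria`.
#' @export
interaction_criteria <- function(hydrophobic_max_dist = 4.0,
                                 hbond_max_dist = 3.5,
                                 hbond_min_angle = 120,
                                 saltbridge_max_dist = 4.0,
                                 ring_centroid_max_dist = 5.0,
                                 face_face_max_normal_angle = 30,
                                 edge_face_normal_angle_range = c(60, 90),
                                 metal_max_dist = 2.8) {
  cr <- list(hydrophobic_max_dist = hydrophobic_max_dist,
             hbond_max_dist = hbond_max_dist,
             hbond_min_angle = hbond_min_angle,
             saltbridge_max_dist = saltbridge_max_dist,
             ring_centroid_max_dist = ring_centroid_max_dist,
             face_face_max_normal_angle = face_face_max_normal_angle,
             edge_face_normal_angle_range = edge_face_normal_angle_range,
             metal_max_dist = metal_max_dist)
  dists <- unlist(cr[c(1, 2, 4, 5, 8)])
  if (any(dists <= 0)) stop_fmt("all distance cutoffs must be positive")
  angs <- c(face_face_max_normal_angle, edge_face_normal_angle_range)
  if (any(angs < 0 | angs > 90)) stop_fmt("normal-angle bounds must lie in [0, 90]")
  structure(cr, class = "interaction_criteria")
}

# ---- ligand-side typing ----------------------------------------------------

# Rings among aromatic-flagged pose atoms: connected components (bond =
# inter-atom distance < 1.75 A) of size >= 5 in which every atom has at
# least two in-component neighbors.
ligand_rings <- function(atoms) {
  arom <- which(atoms$aromatic & atoms$element != "H")
  if (length(arom) < 5) return(list())
  xyz <- as.matrix(atoms[arom, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  adj <- d < 1.75 & d > 0
  comp <- rep(0L, length(arom)); cid <- 0L
  for (s in seq_along(arom)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L; queue <- s; comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid; queue <- c(queue, nb)
    }
  }
  rings <- list()
  for (k in seq_len(cid)) {
    mem <- which(comp == k)
    if (length(mem) >= 5 && all(rowSums(adj[mem, mem, drop = FALSE]) >= 2)) {
      rxyz <- xyz[mem, , drop = FALSE]
      rings[[length(rings) + 1L]] <- list(centroid = colMeans(rxyz),
                                          normal = ring_normal(rxyz))
    }
  }
  rings
}

ligand_typing <- function(atoms) {
  heavy <- atoms$element != "H"
  has_h <- any(!heavy)
  hxyz <- as.matrix(atoms[!heavy, c("x", "y", "z"), drop = FALSE])
  polar <- heavy & atoms$element %in% c("N", "O", "S")
  donors <- integer(0); donor_h <- list()
  if (has_h) {
    for (a in which(polar)) {
      axyz <- as.numeric(atoms[a, c("x", "y", "z")])
      dh <- sqrt(rowSums(sweep(hxyz, 2, axyz)^2))
      hs <- which(dh < 1.25)
      if (length(hs)) { donors <- c(donors, a); donor_h[[as.character(a)]] <- hxyz[hs, , drop = FALSE] }
    }
  } else {
    donors <- which(heavy & atoms$element %in% c("N", "O"))
  }
  list(heavy = which(heavy),
       apolar = which(heavy & atoms$element %in% c("C", "S")),
       acceptors = which(heavy & atoms$element %in% c("N", "O")),
       donors = donors, donor_h = donor_h, has_h = has_h,
       neg = which(heavy & atoms$charge < 0),
       pos = which(heavy & atoms$charge > 0),
       metal_partners = which(heavy & (atoms$element %in% c("N", "O") | atoms$charge != 0)),
       rings = ligand_rings(atoms))
}

# ---- residue-side typing ---------------------------------------------------

residue_typing <- function(res) {
  at <- res$atoms
  backbone_n <- at$name == "N"
  backbone_o <- at$name == "O"
  don_names <- DONOR_ATOMS[[res$name]]
  acc_names <- ACCEPTOR_ATOMS[[res$name]]
  donors <- which((backbone_n & res$name != "PRO") | at$name %in% don_names)
  acceptors <- which(backbone_o | at$name %in% acc_names)
  rings <- lapply(res$aromatic_ring_atoms %||% list(), function(rn) {
    ix <- match(rn, at$name); ix <- ix[!is.na(ix)]
    rxyz <- as.matrix(at[ix, c("x", "y", "z")])
    list(centroid = colMeans(rxyz), normal = ring_normal(rxyz))
  })
  grp <- CHARGED_GROUP_ATOMS[[res$name]]
  charge_center <- NULL
  if (res$formal_charge_class != "neutral") {
    ix <- if (!is.null(grp)) which(at$name %in% grp) else which(at$element %in% c("N", "O"))
    if (!length(ix)) ix <- seq_len(nrow(at))
    charge_center <- colMeans(as.matrix(at[ix, c("x", "y", "z"), drop = FALSE]))
  }
  is_metal <- res$name %in% METAL_RESIDUES
  list(xyz = as.matrix(at[, c("x", "y", "z")]),
       heavy = which(at$element != "H"),
       apolar = which(at$element %in% c("C", "S")),
       donors = donors, acceptors = acceptors, rings = rings,
       charge_center = charge_center,
       charge_class = if (is_metal) "positive" else res$formal_charge_class,
       is_metal = is_metal,
       hydrophobic = res$name %in% HYDROPHOBIC_RESIDUES)
}

min_cross_dist <- function(A, B) {
  if (!nrow(A) || !nrow(B)) return(Inf)
  ## nrow(A) * nrow(B) pair distances
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

# ---- the detector ----------------------------------------------------------

#' Detect protein-ligand interactions for one docked pose
#'
#' Computes the per-residue 8-bit interaction block for every receptor
#' residue that has a heavy atom within `max(distance cutoffs) + 1` A of
#' any ligand heavy atom; all other residues are implicitly all-zero.
#'
#' @param pose an [pose()] object (same coordinate frame as the receptor).
#' @param receptor an [receptor()] object.
#' @param criteria an [interaction_criteria()] list.
#' @return data.frame with `residue_key` and eight logical bit columns
#'   (named as in `PLIF_BIT_NAMES`).
#' @export
detect_interactions <- function(pose, receptor, criteria = interaction_criteria()) {
  la <- pose$atoms
  if (!any(la$element != "H")) stop_fmt("pose has no heavy atoms")
  lt <- ligand_typing(la)
  lxyz <- as.matrix(la[, c("x", "y", "z")])
  gate <- max(criteria$hydrophobic_max_dist, criteria$hbond_max_dist,
              criteria$saltbridge_max_dist, criteria$ring_centroid_max_dist,
              criteria$metal_max_dist) + 1
  blocks <- list()
  for (res in receptor$residues) {
    rt <- residue_typing(res)
    if (min_cross_dist(rt$xyz[rt$heavy, , drop = FALSE],
                       lxyz[lt$heavy, , drop = FALSE]) > gate) next
    bits <- rep(FALSE, 8)

    # b0 hydrophobic: apolar C/S pair within cutoff, hydrophobic residues only
    if (rt$hydrophobic && length(rt$apolar) && length(lt$apolar))
      bits[1] <- min_cross_dist(rt$xyz[rt$apolar, , drop = FALSE],
                                lxyz[lt$apolar, , drop = FALSE]) <=
        criteria$hydrophobic_max_dist

    # b1/b2 aromatic ring orientations (exclusive per ring pair)
    for (rring in rt$rings) for (lring in lt$rings) {
      if (vnorm(rring$centroid - lring$centroid) > criteria$ring_centroid_max_dist) next
      ang <- normal_angle(rring$normal, lring$normal)
      if (ang <= criteria$face_face_max_normal_angle) bits[2] <- TRUE
      else if (ang >= criteria$edge_face_normal_angle_range[1] &&
               ang <= criteria$edge_face_normal_angle_range[2]) bits[3] <- TRUE
    }

    # b3 residue accepts from a ligand donor
    if (length(rt$acceptors) && length(lt$donors)) {
      for (acc in rt$acceptors) for (don in lt$donors) {
        axyz <- rt$xyz[acc, ]
        dxyz <- lxyz[don, ]
        if (vnorm(axyz - dxyz) > criteria$hbond_max_dist) next
        if (lt$has_h) {
          hs <- lt$donor_h[[as.character(don)]]
          ok <- FALSE
          for (q in seq_len(nrow(hs))) {
            ang <- vec_angle(dxyz - hs[q, ], axyz - hs[q, ])
            if (ang >= criteria$hbond_min_angle) { ok <- TRUE; break }
          }
          if (!ok) next
        }
        bits[4] <- TRUE
      }
    }

    # b4 residue donates to a ligand acceptor (protein H unknown: distance only)
    if (length(rt$donors) && length(lt$acceptors))
      bits[5] <- min_cross_dist(rt$xyz[rt$donors, , drop = FALSE],
                                lxyz[lt$acceptors, , drop = FALSE]) <=
        criteria$hbond_max_dist

    # b5/b6 salt bridges between charged-group centers and charged ligand atoms
    if (!is.null(rt$charge_center) && !rt$is_metal) {
      if (rt$charge_class == "positive" && length(lt$neg))
        bits[6] <- min_cross_dist(matrix(rt$charge_center, 1),
                                  lxyz[lt$neg, , drop = FALSE]) <=
          criteria$saltbridge_max_dist
      if (rt$charge_class == "negative" && length(lt$pos))
        bits[7] <- min_cross_dist(matrix(rt$charge_center, 1),
                                  lxyz[lt$pos, , drop = FALSE]) <=
          criteria$saltbridge_max_dist
    }

    # b7 metal coordination
    if (rt$is_metal && length(lt$metal_partners))
      bits[8] <- min_cross_dist(rt$xyz, lxyz[lt$metal_partners, , drop = FALSE]) <=
        criteria$metal_max_dist

    blocks[[length(blocks) + 1L]] <- c(list(residue_key = residue_key(res)),
                                       as.list(setNames(bits, PLIF_BIT_NAMES)))
  }
  if (!length(blocks)) {
    out <- data.frame(residue_key = character(0))
    for (b in PLIF_BIT_NAMES) out[[b]] <- logical(0)
    return(out)
  }
  do.call(rbind, lapply(blocks, as.data.frame))
}

#' PLIF vector for one pose
#'
#' @inheritParams detect_interactions
#' @param include_score attach the pose docking score as an extra feature.
#' @return list of class `plif_vector`: `molecule_id`, `receptor_id`,
#'   `blocks` (the [detect_interactions()] table) and
#'   `docking_score_feature`.
#' @export
plif_vector <- function(pose, receptor, criteria = interaction_criteria(),
                        include_score = TRUE) {
  structure(list(molecule_id = pose$molecule_id,
                 receptor_id = receptor$id,
                 receptor_state = receptor$state_label,
                 blocks = detect_interactions(pose, receptor, criteria),
                 docking_score_feature = if (include_score) pose$docking_score else NULL),
            class = "plif_vector")
}

#' Residue order for a PLIF feature matrix
#'
#' The union of residues contacted by any supplied vector, sorted by
#' (receptor state, chain, residue number) so column order is deterministic
#' across runs.
#'
#' @param plifs list of [plif_vector()]s.
#' @return character vector of `receptor_id|chain:number:name` keys.
#' @export
plif_residue_order <- function(plifs) {
  rows <- do.call(rbind, lapply(plifs, function(p) {
    if (!nrow(p$blocks)) return(NULL)
    data.frame(receptor_id = p$receptor_id, state = p$receptor_state %||% "",
               key = p$blocks$residue_key, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(character(0))
  rows <- unique(rows)
  parts <- strsplit(rows$key, ":", fixed = TRUE)
  chain <- vapply(parts, `[`, "", 1)
  num <- as.integer(vapply(parts, `[`, "", 2))
  rows <- rows[order(rows$state, rows$receptor_id, chain, num), , drop = FALSE]
  paste(rows$receptor_id, rows$key, sep = "|")
}

#' Assemble the pose-by-feature PLIF matrix
#'
#' One row per pose, `8 * length(residue_order)` bit columns (plus one
#' docking-score column when scores are present and `include_score`).
#' Residues absent from a vector contribute zero bits; residues not in
#' `residue_order` are dropped with a warning.
#'
#' @param plifs list of [plif_vector()]s.
#' @param residue_order keys from [plif_residue_order()] (computed from
#'   `plifs` when `NULL`).
#' @param include_score include the docking-score feature column.
#' @return numeric matrix; row names are `molecule_id@receptor_id#i`,
#'   column names `residue_key.bit_name`. Attributes: `molecule_id`,
#'   `receptor_id` per row, `residue_order`.
#' @export
build_feature_matrix <- function(plifs, residue_order = NULL, include_score = TRUE) {
  if (!length(plifs)) stop_fmt("empty PLIF list")
  residue_order <- residue_order %||% plif_residue_order(plifs)
  cols <- as.vector(t(outer(residue_order, PLIF_BIT_NAMES, paste, sep = ".")))
  have_scores <- include_score &&
    all(vapply(plifs, function(p) !is.null(p$docking_score_feature), TRUE))
  X <- matrix(0, nrow = length(plifs), ncol = length(cols) + as.integer(have_scores),
              dimnames = list(NULL, c(cols, if (have_scores) "docking_score")))
  dropped <- 0L
  for (i in seq_along(plifs)) {
    p <- plifs[[i]]
    if (nrow(p$blocks)) {
      keys <- paste(p$receptor_id, p$blocks$residue_key, sep = "|")
      known <- keys %in% residue_order
      dropped <- dropped + sum(!known)
      for (r in which(known)) {
        bits <- as.numeric(p$blocks[r, PLIF_BIT_NAMES])
        X[i, paste(keys[r], PLIF_BIT_NAMES, sep = ".")] <- bits
      }
    }
    if (have_scores) X[i, "docking_score"] <- p$docking_score_feature
  }
  if (dropped > 0)
    warn_fmt("%d residue block(s) not in residue_order were dropped", dropped)
  rownames(X) <- vapply(seq_along(plifs), function(i)
    sprintf("%s@%s#%d", plifs[[i]]$molecule_id, plifs[[i]]$receptor_id, i), "")
  attr(X, "molecule_id") <- vapply(plifs, function(p) p$molecule_id, "")
  attr(X, "receptor_id") <- vapply(plifs, function(p) p$receptor_id, "")
  attr(X, "residue_order") <- residue_order
  X
}

#' Per-class interaction-bit frequencies
#'
#' Fraction of poses in each class with each bit set, the quantity shown in
#' per-residue interaction histograms for agonist vs. antagonist pose sets.
#'
#' @param matrix feature matrix from [build_feature_matrix()].
#' @param labels per-row class labels.
#' @return data.frame: `feature`, one frequency column per class.
#' @export
summarize_bit_frequencies <- function(matrix, labels) {
  stopifnot(nrow(matrix) == length(labels))
  if (!nrow(matrix)) stop_fmt("no rows to summarize")
  classes <- sort(unique(as.character(labels)))
  for (cl in classes) if (!sum(labels == cl))
    stop_fmt("class '%s' has zero rows", cl)
  bitcols <- setdiff(colnames(matrix), "docking_score")
  out <- data.frame(feature = bitcols, stringsAsFactors = FALSE)
  for (cl in classes)
    out[[cl]] <- colMeans(matrix[labels == cl, bitcols, drop = FALSE] > 0)
  out
}
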