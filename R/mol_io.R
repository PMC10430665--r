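## Molecular I/O and the shared structural data model.
##
## Receptors are parsed from PDB ATOM records (author residue numbering is
## preserved, since binding-site residues are referred to by author numbers,
## e.g. ASN253). Docked poses come from SDF with a named numeric score
## property. Molecule tables are plain delimited text.

# ---- residue chemistry templates -------------------------------------------
# Protein-side typing is template-based because docked complexes routinely
# lack protein hydrogens.

HYDROPHOBIC_RESIDUES <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

POSITIVE_RESIDUES <- c("ARG", "LYS")
NEGATIVE_RESIDUES <- c("ASP", "GLU")
METAL_RESIDUES <- c("MG", "ZN", "CA", "NA", "K", "MN", "FE", "CU", "NI", "CO")

AROMATIC_RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(
    c("CG", "CD1", "NE1", "CE2", "CD2"),
    c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3")
  )
)

# side-chain H-bond donor heavy atoms (backbone N is a donor for all but PRO)
DONOR_ATOMS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", TRP = "NE1",
  HIS = c("ND1", "NE2"), CYS = "SG"
)

# side-chain H-bond acceptor heavy atoms (backbone O accepts for all)
ACCEPTOR_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD"
)

# atoms defining the charged-group center of ionizable side chains
CHARGED_GROUP_ATOMS <- list(
  ARG = c("CZ", "NH1", "NH2"), LYS = "NZ",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

residue_charge_class <- function(name) {
  if (name %in% POSITIVE_RESIDUES || name %in% METAL_RESIDUES) "positive"
  else if (name %in% NEGATIVE_RESIDUES) "negative"
  else "neutral"
}

# ---- constructors ----------------------------------------------------------

#' Build a residue record
#'
#' @param chain chain identifier.
#' @param number author residue number (integer, as in the PDB record).
#' @param name three-letter residue code.
#' @param atoms data.frame with columns `name`, `element`, `x`, `y`, `z`
#'   (coordinates in Angstrom).
#' @return a list of class `a2a_residue` with derived `formal_charge_class`
#'   and, for aromatic residues, `aromatic_ring_atoms`.
#' @export
residue <- function(chain, number, name, atoms) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "element", "x", "y", "z") %in% names(atoms)))
  name <- toupper(name)
  rings <- AROMATIC_RING_ATOMS[[name]]
  ring_atoms <- NULL
  if (!is.null(rings)) {
    ring_atoms <- Filter(function(r) sum(r %in% atoms$name) >= 5, rings)
    if (!length(ring_atoms)) ring_atoms <- NULL
  }
  structure(list(
    chain = as.character(chain), number = as.integer(number), name = name,
    atoms = atoms, formal_charge_class = residue_charge_class(name),
    aromatic_ring_atoms = ring_atoms
  ), class = "a2a_residue")
}

residue_key <- function(res) paste(res$chain, res$number, res$name, sep = ":")

#' Build a receptor from residues
#'
#' @param id receptor identifier.
#' @param residues list of [residue()] records.
#' @param state_label one of `"active"`, `"inactive"`, `"intermediate"`.
#'   The state is a user-supplied provenance label, never inferred from the
#'   coordinates.
#' @return list of class `a2a_receptor`; residues ordered by (chain, number).
#' @export
receptor <- function(id, residues, state_label = c("inactive", "active", "intermediate")) {
  state_label <- match.arg(state_label)
  keys <- vapply(residues, residue_key, "")
  if (anyDuplicated(keys))
    stop_fmt("duplicate residue identifiers: %s",
             paste(unique(keys[duplicated(keys)]), collapse = ", "))
  ord <- order(vapply(residues, function(r) r$chain, ""),
               vapply(residues, function(r) r$number, 1L))
  structure(list(id = id, residues = residues[ord], state_label = state_label),
            class = "a2a_receptor")
}

#' @export
print.a2a_receptor <- function(x, ...) {
  cat(sprintf("<a2a_receptor> %s (%s state): %d residues\n",
              x$id, x$state_label, length(x$residues)))
  invisible(x)
}

#' Build a docked ligand pose
#'
#' @param molecule_id,receptor_id identifiers.
#' @param atoms data.frame with columns `element`, `x`, `y`, `z`, and
#'   optionally `charge` (formal charge) and `aromatic` (logical).
#' @param docking_score finite numeric; more negative is better.
#' @return list of class `a2a_pose`.
#' @export
pose <- function(molecule_id, receptor_id, atoms, docking_score) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1,
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (!is.finite(docking_score)) stop_fmt("docking_score must be finite")
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  structure(list(molecule_id = molecule_id, receptor_id = receptor_id,
                 atoms = atoms, docking_score = docking_score),
            class = "a2a_pose")
}

# ---- PDB reading -----------------------------------------------------------

#' Read a receptor from a PDB file
#'
#' ATOM records become residues; HETATM ligands and waters are excluded.
#' Metal ions appearing as single-atom HETATM groups are retained (they can
#' carry the ionic-metal interaction bit). Alternate locations keep the
#' highest-occupancy conformer, ties broken by altloc letter order.
#'
#' @param path PDB file path.
#' @param id receptor id; defaults to the file base name.
#' @param state_label receptor activation-state label (provenance, not
#'   inferred): `"inactive"`, `"active"` or `"intermediate"`.
#' @param include_waters keep crystallographic waters as residues; their
#'   oxygens can then act as H-bond partners in interaction detection
#'   (excluded by default).
#' @return an [receptor()] object.
#' @export
read_receptor <- function(path, id = NULL,
                          state_label = c("inactive", "active", "intermediate"),
                          include_waters = FALSE) {
  state_label <- match.arg(state_label)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop_fmt("unparseable PDB '%s': %s", path, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || !nrow(at) || !any(at$type == "ATOM"))
    stop_fmt("no ATOM records in '%s'", path)
  keep <- at$type == "ATOM" |
    (at$type == "HETATM" & toupper(at$resid) %in% METAL_RESIDUES) |
    (include_waters & at$type == "HETATM" & toupper(at$resid) == "HOH")
  if (!include_waters) keep <- keep & toupper(at$resid) != "HOH"
  at <- at[keep, , drop = FALSE]
  at$elesy[is.na(at$elesy) | at$elesy == ""] <- substr(at$elety[is.na(at$elesy) | at$elesy == ""], 1, 1)
  # altloc: highest occupancy wins, ties by altloc letter order
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]

  split_key <- paste(at$chain, at$resno, at$resid, sep = "\r")
  residues <- lapply(split(seq_len(nrow(at)), split_key), function(ix) {
    a <- at[ix, , drop = FALSE]
    residue(chain = a$chain[1], number = a$resno[1], name = a$resid[1],
            atoms = data.frame(name = a$elety, element = toupper(a$elesy),
                               x = a$x, y = a$y, z = a$z,
                               stringsAsFactors = FALSE))
  })
  receptor(id = id %||% sub("\\.pdb$", "", basename(path), ignore.case = TRUE),
           residues = unname(residues), state_label = state_label)
}

# ---- SDF pose reading ------------------------------------------------------

#' Read docked poses from an SDF file
#'
#' One pose per SDF record. Records missing the named score property are
#' skipped with a warning; the number skipped is attached as attribute
#' `n_skipped`.
#'
#' @param path SDF file path.
#' @param score_field name of the numeric SDF data field holding the docking
#'   score (e.g. `"r_i_docking_score"`).
#' @param receptor_id receptor the poses were docked to.
#' @return list of [pose()] objects with attribute `n_skipped`.
#' @export
read_poses <- function(path, score_field, receptor_id = "receptor") {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  sdfs <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                   error = function(e) stop_fmt("unparseable SDF '%s': %s", path, conditionMessage(e)))
  n <- length(sdfs)
  poses <- list(); skipped <- 0L
  for (i in seq_len(n)) {
    sdf <- sdfs[[i]]
    db <- ChemmineR::datablock(sdf)
    if (!(score_field %in% names(db))) { skipped <- skipped + 1L; next }
    score <- suppressWarnings(as.numeric(db[[score_field]]))
    if (is.na(score))
      stop_fmt("non-numeric score '%s' in record %d of '%s'", db[[score_field]], i, path)
    ab <- ChemmineR::atomblock(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    chg_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, nrow(ab))
    charge <- ifelse(chg_code == 0, 0, 4 - chg_code)  # V2000 charge codes
    poses[[length(poses) + 1L]] <- pose(
      molecule_id = ChemmineR::sdfid(sdf), receptor_id = receptor_id,
      atoms = data.frame(element = toupper(elem), x = ab[, 1], y = ab[, 2],
                         z = ab[, 3], charge = charge,
                         aromatic = FALSE, stringsAsFactors = FALSE),
      docking_score = score)
  }
  if (skipped > 0)
    warn_fmt("%d of %d SDF records missing score field '%s'; skipped", skipped, n, score_field)
  if (!length(poses)) stop_fmt("no valid records with score field '%s' in '%s'", score_field, path)
  attr(poses, "n_skipped") <- skipped
  poses
}

# ---- molecule tables -------------------------------------------------------

#' Read a molecule table (id, smiles, optional label / pKd)
#'
#' Rows whose SMILES do not parse are dropped and reported with their row
#' numbers. Duplicate ids are an error.
#'
#' @param path comma- or tab-delimited file with a header; columns `id`,
#'   `smiles` required, `label` (`agonist`/`antagonist`) and `pKd` optional.
#' @param sep field separator; guessed from the extension by default.
#' @return data.frame of valid molecules with attribute `rejected_rows`.
#' @export
read_molecule_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  sep <- sep %||% if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   quote = "\"", comment.char = "")
  if (!all(c("id", "smiles") %in% names(df)))
    stop_fmt("molecule table must have columns 'id' and 'smiles'")
  if (anyDuplicated(df$id))
    stop_fmt("duplicate molecule ids: %s",
             paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  ok <- vapply(df$smiles, smiles_is_valid, TRUE)
  if (any(!ok))
    warn_fmt("rejected %d row(s) with invalid SMILES (rows: %s)",
             sum(!ok), paste(which(!ok), collapse = ", "))
  out <- df[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected_rows") <- unname(which(!ok))
  out
}

#' Write and re-read a results table losslessly
#'
#' Reals are serialized to 15 significant digits so a write/read round trip
#' reproduces them to at least 12 significant digits.
#'
#' @param df data.frame to write.
#' @param path output path (tab-delimited).
#' @export
write_results_table <- function(df, path) {
  fmt <- df
  for (j in seq_along(fmt)) {
    if (is.numeric(fmt[[j]]) && !is.integer(fmt[[j]]))
      fmt[[j]] <- formatC(fmt[[j]], digits = 15, format = "g")
  }
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
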