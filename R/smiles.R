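## SMILES handling and the internal molecular graph.
##
## Parsing and canonicalization are delegated to Open Babel (via
## ChemmineOB/ChemmineR); the graph is reduced to the atom/bond tables the
## fingerprint code needs. Input SMILES are canonicalized first so the
## fingerprint of a molecule does not depend on how its SMILES was written.

#' Canonicalize a SMILES string
#'
#' @param smiles a single SMILES string.
#' @return the canonical SMILES, or `NA` if the string does not parse.
#' @export
canonical_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1)
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", source = smiles)),
    error = function(e) "")
  out <- strsplit(out, "[\t\n ]")[[1]][1]
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

#' Test whether a SMILES string parses to a valid chemical graph
#'
#' @param smiles a single SMILES string.
#' @return logical.
#' @export
smiles_is_valid <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) || !nzchar(smiles))
    return(FALSE)
  can <- canonical_smiles(smiles)
  if (is.na(can)) return(FALSE)
  mg <- tryCatch(parse_smiles(smiles), error = function(e) NULL)
  !is.null(mg) && nrow(mg$atoms) >= 1
}

# Parse a SMILES into an internal graph: atoms (element, charge, nH, degree,
# in_ring) and bonds (i, j, order). Hydrogens are made implicit.
parse_smiles <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop_fmt("invalid SMILES: '%s'", smiles)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(can)),
                  error = function(e) stop_fmt("invalid SMILES: '%s'", smiles))
  mol_graph_from_sdf(sdf[[1]])
}

# Shared conversion from a ChemmineR SDF object to the internal graph.
mol_graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- toupper(sub("_.*$", "", rownames(ab)))
  n <- length(elem)
  chg_code <- if (ncol(ab) >= 5) ab[, 5] else rep(0, n)
  charge <- ifelse(chg_code == 0, 0, 4 - chg_code)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0 || ncol(bb) < 3) {
    data.frame(i = integer(), j = integer(), order = integer())
  } else {
    data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  bonds <- bonds[!is.na(bonds$i) & bonds$i > 0 & bonds$j > 0, , drop = FALSE]
  # drop explicit hydrogens, counting them onto their heavy neighbor
  explicit_h <- which(elem == "H")
  h_count <- integer(n)
  if (length(explicit_h)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (elem[i] == "H" && elem[j] != "H") h_count[j] <- h_count[j] + 1L
      if (elem[j] == "H" && elem[i] != "H") h_count[i] <- h_count[i] + 1L
    }
    keep <- setdiff(seq_len(n), explicit_h)
    remap <- integer(n); remap[keep] <- seq_along(keep)
    bonds <- bonds[elem[bonds$i] != "H" & elem[bonds$j] != "H", , drop = FALSE]
    bonds$i <- remap[bonds$i]; bonds$j <- remap[bonds$j]
    elem <- elem[keep]; charge <- charge[keep]; h_count <- h_count[keep]
    n <- length(elem)
  }
  deg <- integer(n); bond_order_sum <- integer(n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]
    deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
    o <- bonds$order[r]
    if (o == 4) o <- 1.5  # aromatic bond order, if present
    bond_order_sum[i] <- bond_order_sum[i] + o
    bond_order_sum[j] <- bond_order_sum[j] + o
  }
  # implicit hydrogens from default valences
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1, BR = 1, I = 1, B = 3)
  for (a in seq_len(n)) {
    v <- valence[elem[a]]
    if (!is.na(v)) {
      imp <- round(v + charge[a] * ifelse(elem[a] %in% c("N", "P"), 1, -1) - bond_order_sum[a])
      if (elem[a] %in% c("O", "S") && charge[a] < 0) imp <- round(v + charge[a] - bond_order_sum[a])
      h_count[a] <- max(h_count[a], max(0L, as.integer(imp)))
    }
  }
  in_ring <- ring_membership(n, bonds)
  list(atoms = data.frame(element = elem, charge = charge, nH = h_count,
                          degree = deg, in_ring = in_ring,
                          stringsAsFactors = FALSE),
       bonds = bonds)
}

# atom-in-ring flags: an edge is in a ring iff it is not a bridge
ring_membership <- function(n, bonds) {
  in_ring <- rep(FALSE, n)
  if (!nrow(bonds)) return(in_ring)
  adj <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    adj[[bonds$i[r]]] <- c(adj[[bonds$i[r]]], r)
    adj[[bonds$j[r]]] <- c(adj[[bonds$j[r]]], r)
  }
  reachable <- function(from, to, skip_edge) {
    seen <- rep(FALSE, n); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == skip_edge) next
        w <- if (bonds$i[e] == v) bonds$j[e] else bonds$i[e]
        if (w == to) return(TRUE)
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    FALSE
  }
  for (r in seq_len(nrow(bonds))) {
    if (reachable(bonds$i[r], bonds$j[r], r)) {
      in_ring[bonds$i[r]] <- TRUE
      in_ring[bonds$j[r]] <- TRUE
    }
  }
  in_ring
}

atomic_number <- function(elem) {
  z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
         CL = 17, BR = 35, I = 53)
  out <- z[toupper(elem)]
  out[is.na(out)] <- 0
  unname(out)
}
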