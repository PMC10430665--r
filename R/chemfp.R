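## Hashed circular (Morgan) fingerprints, Tanimoto similarity and
## chemotype-novelty scoring.
##
## The fingerprint is an ECFP-style iterative-neighborhood hash: initial
## atom invariants (atomic number, heavy degree, total bond order, implicit
## hydrogen count, formal charge, ring flag) are refined for `radius`
## rounds by hashing each atom's invariant together with the sorted
## (bond order, neighbor invariant) pairs, and every identifier from every
## round is folded into a fixed-length bit vector. The construction is
## invariant to input atom order; SMILES are additionally canonicalized
## before parsing.

#' Circular (Morgan) bit fingerprint of a molecule
#'
#' Defaults follow standard ECFP4 usage: radius 2, 4096 bits.
#'
#' @param molecule a SMILES string, a molecule-graph list from
#'   `parse_smiles()`, or a row of a molecule table (list with `$smiles`).
#' @param length fingerprint length in bits (positive power of two).
#' @param radius neighborhood radius (ECFP4 = radius 2).
#' @param molecule_id identifier stored on the fingerprint.
#' @return an object of class `bitfp`: logical vector of `length` bits with
#'   attributes `radius` and `molecule_id`.
#' @export
ecfp4 <- function(molecule, length = 4096L, radius = 2L, molecule_id = NULL) {
  if (length <= 0 || bitwAnd(length, length - 1L) != 0)
    stop_fmt("fingerprint length must be a positive power of two (got %d)", length)
  mg <- if (is.character(molecule)) parse_smiles(molecule)
        else if (is.list(molecule) && !is.null(molecule$atoms)) molecule
        else if (is.list(molecule) && !is.null(molecule$smiles)) parse_smiles(molecule$smiles)
        else stop_fmt("cannot interpret 'molecule'")
  at <- mg$atoms; bonds <- mg$bonds
  n <- nrow(at)
  nbr <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds$i[r]; j <- bonds$j[r]; o <- bonds$order[r]
    nbr[[i]] <- rbind(nbr[[i]], c(j, o))
    nbr[[j]] <- rbind(nbr[[j]], c(i, o))
  }
  inv <- vapply(seq_len(n), function(a) hash_ints(c(
    atomic_number(at$element[a]), at$degree[a], at$nH[a],
    at$charge[a] + 8, as.integer(at$in_ring[a]))), 0)
  ids <- inv
  for (it in seq_len(radius)) {
    inv <- vapply(seq_len(n), function(a) {
      nb <- nbr[[a]]
      parts <- c(it, inv[a])
      if (!is.null(nb)) {
        pairs <- nb[order(nb[, 2], inv[nb[, 1]]), , drop = FALSE]
        for (q in seq_len(nrow(pairs)))
          parts <- c(parts, pairs[q, 2], inv[pairs[q, 1]])
      }
      hash_ints(parts)
    }, 0)
    ids <- c(ids, inv)
  }
  bits <- rep(FALSE, length)
  bits[(ids %% length) + 1] <- TRUE
  structure(bits, class = "bitfp", radius = radius,
            molecule_id = molecule_id %||% attr(molecule, "id"))
}

#' @export
print.bitfp <- function(x, ...) {
  cat(sprintf("<bitfp> %d bits, %d set (radius %d)%s\n", length(x), sum(x),
              attr(x, "radius"),
              if (!is.null(attr(x, "molecule_id"))) paste0(" [", attr(x, "molecule_id"), "]") else ""))
  invisible(x)
}

#' Tanimoto similarity of two bit fingerprints
#'
#' `|A and B| / |A or B|`; defined as 1 when both fingerprints are all-zero
#' (identical empty sets).
#'
#' @param a,b logical bit vectors of equal length (e.g. from [ecfp4()]).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop_fmt("fingerprint length mismatch: %d vs %d", length(a), length(b))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Chemotype novelty against a reference set
#'
#' A candidate is "novel" when its maximum Tanimoto similarity to any
#' reference molecule is strictly below the threshold (default 0.4).
#'
#' @param query SMILES string or `bitfp` for the query molecule.
#' @param reference non-empty list of SMILES strings or `bitfp`s (or a 0/1
#'   matrix with one fingerprint per row).
#' @param threshold novelty threshold on the maximum Tanimoto (default 0.4,
#'   strict inequality).
#' @param length,radius fingerprint parameters used when SMILES are given.
#' @return list of class `novelty_report`: `query_id`,
#'   `nearest_reference_id`, `max_tanimoto`, `novel`.
#' @export
novelty <- function(query, reference, threshold = 0.4,
                    length = 4096L, radius = 2L) {
  as_fp <- function(m, id) {
    if (inherits(m, "bitfp") || is.logical(m)) m
    else ecfp4(m, length = length, radius = radius, molecule_id = id)
  }
  qfp <- as_fp(query, "query")
  if (is.matrix(reference))
    reference <- lapply(seq_len(nrow(reference)), function(i)
      structure(reference[i, ] > 0, molecule_id = rownames(reference)[i]))
  if (!length(reference)) stop_fmt("reference set is empty")
  ids <- names(reference) %||% vapply(seq_along(reference), function(i)
    attr(reference[[i]], "molecule_id") %||% paste0("ref", i), "")
  tcs <- vapply(seq_along(reference), function(i)
    tanimoto(qfp, as_fp(reference[[i]], ids[i])), 0)
  best <- which.max(tcs)
  structure(list(query_id = attr(qfp, "molecule_id") %||% "query",
                 nearest_reference_id = ids[best],
                 max_tanimoto = tcs[best],
                 novel = tcs[best] < threshold,
                 threshold = threshold),
            class = "novelty_report")
}

#' @export
print.novelty_report <- function(x, ...) {
  cat(sprintf("<novelty> %s: max Tc = %.3f to %s -> %s (threshold %.2f)\n",
              x$query_id, x$max_tanimoto, x$nearest_reference_id,
              if (x$novel) "NOVEL" else "known chemotype", x$threshold))
  invisible(x)
}

#' Fingerprint as a hexadecimal string
#'
#' @param fp a `bitfp` or logical vector whose length is a multiple of 4.
#' @return character scalar of hex digits, most significant bit first.
#' @export
fp_to_hex <- function(fp) {
  stopifnot(length(fp) %% 4 == 0)
  nib <- matrix(as.integer(fp), nrow = 4)
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[
    colSums(nib * c(8, 4, 2, 1)) + 1], collapse = "")
}
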