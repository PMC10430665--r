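## Chemical-diversity clustering on Tanimoto distances.
##
## Clustering runs on the raw 1 - Tanimoto distance matrix (average-linkage
## agglomerative by default); PCA is used only en route to the 2-D t-SNE
## inspection map. The number of clusters is chosen by silhouette score,
## ties toward the smaller k. The traditional "visual inspection" step of
## cluster-based compound picking is replaced by medoid representatives
## plus an exported inspection sheet a human can override.

#' Tanimoto distance matrix of a fingerprint set
#'
#' @param fps list of `bitfp`s (equal length) or a 0/1 matrix with one
#'   fingerprint per row.
#' @return symmetric matrix of `1 - Tanimoto`, zero diagonal, with
#'   molecule ids as dimnames. Class `dist_tanimoto` (plain matrix).
#' @export
tanimoto_distance_matrix <- function(fps) {
  if (is.list(fps)) {
    lens <- vapply(fps, length, 1L)
    if (length(unique(lens)) != 1)
      stop_fmt("fingerprint length mismatch: %s", paste(unique(lens), collapse = ", "))
    ids <- vapply(seq_along(fps), function(i)
      attr(fps[[i]], "molecule_id") %||% (names(fps)[i] %||% paste0("m", i)), "")
    M <- do.call(rbind, lapply(fps, as.numeric))
    rownames(M) <- ids
  } else {
    M <- (fps > 0) * 1
  }
  if (nrow(M) < 2) stop_fmt("need at least 2 fingerprints")
  inter <- M %*% t(M)
  rs <- rowSums(M)
  uni <- outer(rs, rs, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  D <- 1 - sim
  diag(D) <- 0
  dimnames(D) <- list(rownames(M), rownames(M))
  D
}

#' PCA embedding of a distance matrix
#'
#' Rows of the distance matrix are treated as feature vectors. Components
#' are ordered by decreasing explained variance and the sign of each is
#' fixed by forcing its largest-magnitude loading positive, so the
#' embedding is deterministic.
#'
#' @param matrix symmetric distance matrix.
#' @param components number of components (default 50; clamped to `n`).
#' @return n x min(components, n) score matrix with attribute
#'   `explained_variance`.
#' @export
pca_embed <- function(matrix, components = 50L) {
  n <- nrow(matrix)
  if (n < 2) stop_fmt("need at least 2 rows")
  ncomp <- min(components, n, ncol(matrix))
  pc <- prcomp(matrix, center = TRUE, scale. = FALSE, rank. = ncomp)
  scores <- pc$x[, seq_len(min(ncomp, ncol(pc$x))), drop = FALSE]
  for (j in seq_len(ncol(scores))) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  attr(scores, "explained_variance") <- pc$sdev^2 / sum(pc$sdev^2)
  scores
}

#' Agglomerative clustering at a fixed number of clusters
#'
#' @param matrix Tanimoto distance matrix.
#' @param k number of clusters (`2 <= k <= n - 1`).
#' @param linkage agglomeration method (default `"average"`).
#' @return list of class `cluster_assignment`: `k`, `labels`,
#'   `silhouette` (mean silhouette width on the precomputed distances),
#'   `representatives` (per-cluster medoids).
#' @export
cluster_hierarchical <- function(matrix, k, linkage = "average") {
  n <- nrow(matrix)
  if (k < 2 || k > n - 1) stop_fmt("k must lie in [2, n-1] = [2, %d] (got %d)", n - 1, k)
  hc <- hclust(as.dist(matrix), method = linkage)
  labels <- cutree(hc, k = k)
  sil <- cluster::silhouette(labels, dmatrix = matrix)
  structure(list(k = k, labels = labels,
                 silhouette = mean(sil[, "sil_width"]),
                 representatives = pick_representatives(labels, matrix),
                 linkage = linkage),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, mean silhouette = %.3f\n",
              x$k, x$silhouette))
  invisible(x)
}

#' Choose the number of clusters by silhouette score
#'
#' @param matrix Tanimoto distance matrix.
#' @param k_range candidate cluster counts.
#' @param linkage agglomeration method.
#' @return the [cluster_hierarchical()] assignment maximizing the mean
#'   silhouette; ties broken toward smaller k. Attribute `silhouettes`
#'   holds the profile over `k_range`.
#' @export
select_k_by_silhouette <- function(matrix, k_range, linkage = "average") {
  if (!length(k_range)) stop_fmt("empty k range")
  k_range <- sort(unique(as.integer(k_range)))
  fits <- lapply(k_range, function(k) cluster_hierarchical(matrix, k, linkage))
  sils <- vapply(fits, function(f) f$silhouette, 0)
  best <- which(sils >= max(sils) - 1e-12)[1]  # ties toward smaller k
  out <- fits[[best]]
  attr(out, "silhouettes") <- setNames(sils, k_range)
  out
}

#' Cluster medoids
#'
#' The representative of each cluster is its medoid: the member minimizing
#' the summed distance to all other members, ties broken by id (row) order.
#'
#' @param assignment a `cluster_assignment` or an integer label vector.
#' @param matrix the distance matrix the labels refer to.
#' @return named integer vector (or ids, when the matrix has dimnames) of
#'   one representative per cluster.
#' @export
pick_representatives <- function(assignment, matrix) {
  labels <- if (inherits(assignment, "cluster_assignment")) assignment$labels else assignment
  ids <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))
  reps <- vapply(sort(unique(labels)), function(cl) {
    mem <- which(labels == cl)
    sums <- rowSums(matrix[mem, mem, drop = FALSE])
    mem[which.min(sums)]  # first minimum = id order tie-break
  }, 1L)
  setNames(ids[reps], paste0("cluster", sort(unique(labels))))
}
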