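test_that("tanimoto distance matrix matches hand values and the pairwise loop", {
  fps <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0))
  rownames(fps) <- paste0("m", 1:4)
  D <- tanimoto_distance_matrix(fps)
  expect_equal(D["m1", "m2"], 0)        # identical pair
  expect_equal(D["m1", "m3"], 1)        # disjoint pair
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  expect_equal(D, t(D))
  set.seed(8)
  rnd <- matrix(rbinom(4 * 32, 1, 0.3), nrow = 4,
                dimnames = list(paste0("r", 1:4), NULL))
  Dr <- tanimoto_distance_matrix(rnd)
  for (i in 1:4) for (j in 1:4)
    expect_equal(Dr[i, j], 1 - oracle_tanimoto(rnd[i, ] > 0, rnd[j, ] > 0))
  expect_error(tanimoto_distance_matrix(rnd[1, , drop = FALSE]), "at least 2")
})

test_that("PCA embedding is variance-ordered, clamped, and complete", {
  # rank-1 data: points on a line embedded in 5-D
  t <- seq(-2, 2, length.out = 12)
  X <- outer(t, c(1, 2, -1, 0.5, 3))
  E <- pca_embed(X, components = 5)
  ev <- attr(E, "explained_variance")
  expect_gt(ev[1], 0.999)
  expect_true(all(diff(ev) <= 1e-12))
  # clamped to n when components exceed it
  D3 <- tanimoto_distance_matrix(matrix(rbinom(3 * 16, 1, 0.4), nrow = 3))
  expect_equal(ncol(pca_embed(D3, components = 50)), 3L)
  # full-rank reconstruction from all components is lossless
  set.seed(2)
  M <- matrix(rnorm(36), 6)
  M <- M + t(M)
  pc <- prcomp(M, center = TRUE)
  rec <- pc$x %*% t(pc$rotation)
  rec <- sweep(rec, 2, -pc$center, "-")
  expect_equal(rec, M, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("two well-separated blobs are recovered unmixed with a high silhouette", {
  b <- make_fingerprint_blobs(2, per_cluster = 10, within_flip_rate = 0.02, seed = 3)
  D <- tanimoto_distance_matrix(b$fps)
  a <- cluster_hierarchical(D, 2)
  expect_gt(a$silhouette, 0.5)
  expect_equal(length(unique(tapply(a$labels, b$labels, function(v) unique(v)[1]))), 2L)
  expect_true(all(tapply(a$labels, b$labels, function(v) length(unique(v))) == 1))
})

test_that("cutting at k = n - 1 yields one pair and duplicates co-cluster", {
  fps <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0),
               c(0, 1, 1, 0))
  rownames(fps) <- paste0("m", 1:5)
  D <- tanimoto_distance_matrix(fps)
  a <- cluster_hierarchical(D, 4)
  sizes <- table(a$labels)
  expect_equal(sort(as.integer(sizes)), c(1, 1, 1, 2))
  expect_equal(a$labels[["m1"]], a$labels[["m2"]])  # zero-distance duplicates
  expect_error(cluster_hierarchical(D, 5), "k must lie")
  expect_error(cluster_hierarchical(D, 1), "k must lie")
})

test_that("silhouette model selection recovers planted k and breaks ties low", {
  hits <- 0
  for (seed in 1:10) {
    b <- make_fingerprint_blobs(3, per_cluster = 8, within_flip_rate = 0.02, seed = seed)
    D <- tanimoto_distance_matrix(b$fps)
    a <- select_k_by_silhouette(D, 2:6)
    hits <- hits + (a$k == 3)
  }
  expect_gte(hits, 9)
  # one blob: low silhouette everywhere, plateau resolved toward small k
  b1 <- make_fingerprint_blobs(2, per_cluster = 10, within_flip_rate = 0.5, seed = 2)
  D1 <- tanimoto_distance_matrix(b1$fps[b1$labels == 1, ])
  a1 <- select_k_by_silhouette(D1, 2:4)
  sils <- attr(a1, "silhouettes")
  expect_equal(a1$k, as.integer(names(sils)[which.max(sils)]))
  expect_lt(a1$silhouette, 0.3)
  # degenerate range
  a2 <- select_k_by_silhouette(D1, 2)
  expect_equal(a2$k, 2L)
  expect_error(select_k_by_silhouette(D1, integer(0)), "empty")
})

test_that("medoids equal the brute-force argmin of summed intra-cluster distance", {
  # hand-computable 3-member cluster
  D <- matrix(c(0, .2, .9, .2, 0, .5, .9, .5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  reps <- pick_representatives(rep(1L, 3), D)
  expect_equal(unname(reps), "b")   # rowsums: a=1.1, b=0.7, c=1.4
  # singleton cluster returns its only member
  reps2 <- pick_representatives(c(1L, 1L, 2L), D)
  expect_equal(unname(reps2["cluster2"]), "c")
  # random clusters vs exhaustive argmin
  set.seed(13)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    M <- matrix(runif(n * n), n); M <- (M + t(M)) / 2; diag(M) <- 0
    rownames(M) <- colnames(M) <- paste0("x", seq_len(n))
    labels <- sample(1:3, n, replace = TRUE)
    labels[1:3] <- 1:3
    reps <- pick_representatives(labels, M)
    for (cl in 1:3) {
      mem <- which(labels == cl)
      sums <- vapply(mem, function(i) sum(M[i, mem]), 0)
      expect_equal(reps[[paste0("cluster", cl)]],
                   rownames(M)[mem[which.min(sums)]])
    }
  }
})

test_that("cluster structure is invariant under input permutation", {
  b <- make_fingerprint_blobs(3, per_cluster = 6, seed = 5)
  D <- tanimoto_distance_matrix(b$fps)
  a <- cluster_hierarchical(D, 3)
  set.seed(1)
  perm <- sample(nrow(D))
  a2 <- cluster_hierarchical(D[perm, perm], 3)
  # same partition up to label renaming
  co <- function(lab) outer(lab, lab, "==")
  expect_equal(co(a$labels[perm]), co(a2$labels), ignore_attr = TRUE)
})

test_that("t-SNE is seed-deterministic, separates planted blobs, rejects tiny n", {
  b <- make_fingerprint_blobs(2, per_cluster = 10, within_flip_rate = 0.03, seed = 6)
  D <- tanimoto_distance_matrix(b$fps)
  expect_warning(Y1 <- tsne_embed(D, perplexity = 30, iterations = 300, seed = 4),
                 "perplexity")
  Y2 <- suppressWarnings(tsne_embed(D, perplexity = 30, iterations = 300, seed = 4))
  expect_identical(Y1, Y2)
  seps <- 0
  for (seed in 1:5) {
    Y <- suppressWarnings(tsne_embed(D, perplexity = 5, iterations = 350, seed = seed))
    c1 <- colMeans(Y[b$labels == 1, ]); c2 <- colMeans(Y[b$labels == 2, ])
    spread <- mean(c(sqrt(rowSums(sweep(Y[b$labels == 1, ], 2, c1)^2)),
                     sqrt(rowSums(sweep(Y[b$labels == 2, ], 2, c2)^2))))
    seps <- seps + (sqrt(sum((c1 - c2)^2)) > spread)
  }
  expect_gte(seps, 4)
  expect_error(tsne_embed(D[1:4, 1:4]), "at least 5")
})
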