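# barcode set whose four channel distances to a reference are prescribed:
# a single point (0, w*sqrt(2)) is at W_{2,2} distance w from the empty diagram
bs_with_w <- function(id, w) {
  mk <- function(x, deg) if (x == 0) persistence_diagram(degree = deg) else
    persistence_diagram(0, x * sqrt(2), deg)
  barcode_set(id, B0u = mk(w[1], 0L), B1u = mk(w[2], 1L),
              B0v = mk(w[3], 0L), B1v = mk(w[4], 1L))
}

test_that("composite node metrics combine channel distances as defined", {
  a <- bs_with_w("a", c(1, 2, 0, 2))
  b <- bs_with_w("b", c(0, 0, 0, 0))
  expect_equal(node_distance(a, b, "d1"), 5)
  expect_equal(node_distance(a, b, "d2"), 3)
  expect_equal(node_distance(a, b, "dinf"), 2)
  # the literal channel-wise sqrt(W^2) reading collapses to d1
  expect_equal(node_distance(a, b, "d2", literal_d2 = TRUE), 5)
  expect_equal(node_distance(a, a, "d1"), 0)
  expect_equal(node_distance(a, a, "dinf"), 0)
})

test_that("dinf <= d1 and the distance matrix is a symmetric premetric", {
  set.seed(12)
  nodes <- lapply(1:8, function(i) bs_with_w(paste0("n", i), runif(4, 0, 3)))
  D <- distance_matrix(nodes, "d1")
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0))
  Dinf <- distance_matrix(nodes, "dinf")
  expect_true(all(Dinf <= D + 1e-12))
  # triangle inequality for d1 (sum of metrics is a metric)
  for (i in 1:8) for (j in 1:8) for (k in 1:8)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-10)
})

blob_matrix <- function(n_per = 10, within = 0.1, between = 10) {
  n <- 2 * n_per
  D <- matrix(between, n, n)
  D[1:n_per, 1:n_per] <- within
  D[(n_per + 1):n, (n_per + 1):n] <- within
  diag(D) <- 0
  dimnames(D) <- list(paste0("n", 1:n), paste0("n", 1:n))
  D
}

test_that("well-separated blobs are recovered by every linkage", {
  D <- blob_matrix()
  for (lk in c("single", "complete", "average")) {
    lab <- cluster_nodes(D, lk, 2)
    expect_equal(length(unique(lab[1:10])), 1L)
    expect_equal(length(unique(lab[11:20])), 1L)
    expect_false(lab[1] == lab[20])
  }
  expect_equal(length(unique(cluster_nodes(D, "average", 20))), 20L)
  expect_equal(length(unique(cluster_nodes(D, "average", 1))), 1L)
  expect_error(cluster_nodes(D, "average", 21), "exceeds")
})

test_that("silhouette scores match their defining formula", {
  D <- blob_matrix()
  expect_gt(silhouette_score(D, rep(1:2, each = 10)), 0.9)
  expect_error(silhouette_score(D, rep(1, 20)), "at least 2")

  # all distances equal: any balanced split scores 0
  E <- matrix(1, 10, 10); diag(E) <- 0
  expect_equal(silhouette_score(E, rep(1:2, each = 5)), 0)

  # two clusters of exact duplicates: a = 0, score 1
  Z <- matrix(5, 8, 8)
  Z[1:4, 1:4] <- 0; Z[5:8, 5:8] <- 0
  expect_equal(silhouette_score(Z, rep(1:2, each = 4)), 1)
})

test_that("silhouette selection picks the planted number of blobs", {
  D <- blob_matrix()
  sel <- select_clustering(D, k_range = 2:5)
  expect_equal(sel$k, 2L)
  expect_gt(sel$silhouette, 0.9)
  expect_error(select_clustering(D, k_range = integer(0)), "empty")

  # minimal case: 3 distinct points, k = 2 still returns a valid clustering
  D3 <- matrix(c(0, 1, 3, 1, 0, 2, 3, 2, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  sel3 <- select_clustering(D3, k_range = 2)
  expect_equal(sort(unique(sel3$labels)), 1:2)
})

test_that("clustering is invariant to node input order", {
  set.seed(13)
  g <- build_grid(10, 10, 1)
  nodes <- c(lapply(1:4, function(s)
    field_barcode_set(make_pattern("spots", g, 3, 3, noise_sd = 0.05,
                                   seed = s)$field, paste0("sp", s))),
    lapply(1:4, function(s)
      field_barcode_set(make_pattern("stripes", g, 4, noise_sd = 0.05,
                                     seed = s)$field, paste0("st", s))))
  D <- distance_matrix(nodes)
  sel <- select_clustering(D, k_range = 2:4)
  perm <- sample(length(nodes))
  Dp <- distance_matrix(nodes[perm])
  selp <- select_clustering(Dp, k_range = 2:4)
  expect_equal(selp$k, sel$k)
  # same partition after undoing the permutation
  relabel <- function(l) match(l, unique(l))
  expect_equal(relabel(selp$labels[order(perm)]), relabel(sel$labels))
})
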