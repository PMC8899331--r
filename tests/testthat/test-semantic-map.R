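# t-SNE runs here are scaled down (small n, few iterations/restarts) to keep
# the default suite fast; the full-scale settings run in test-acceptance.R.

test_that("embed_tsne is deterministic under a fixed seed and reports min KL", {
  blobs <- make_blobs(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)),
                      n_per = 12L, sd = 1, seed = 5)
  m1 <- embed_tsne(blobs$X, perplexity = 8, n_iter = 300, n_restarts = 1,
                   seed = 9)
  m2 <- embed_tsne(blobs$X, perplexity = 8, n_iter = 300, n_restarts = 1,
                   seed = 9)
  expect_identical(m1$coords2d, m2$coords2d)

  m3 <- embed_tsne(blobs$X, perplexity = 8, n_iter = 300, n_restarts = 4,
                   seed = 0)
  expect_equal(m3$kl_divergence, min(m3$restart_log$kl))
  expect_true(all(m3$kl_divergence <= m3$restart_log$kl))
  expect_equal(nrow(m3$restart_log), 4L)
  expect_gte(m3$kl_divergence, 0)
})

test_that("t-SNE preserves well-separated blob structure (ARI > 0.9)", {
  blobs <- make_blobs(rbind(c(0, 0, 0, 0), c(10, 0, 0, 0), c(0, 10, 0, 0)),
                      n_per = 20L, sd = 1, seed = 6)
  map <- embed_tsne(blobs$X, perplexity = 10, n_iter = 500, n_restarts = 2,
                    seed = 1)
  lab <- cluster_kmeans(map, k = 3, seed = 1)
  expect_gt(adjusted_rand_index(lab$mapping[map$items], blobs$labels), 0.9)
})

test_that("perplexity guards fire", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("i", 1:10), NULL))
  expect_error(embed_tsne(X, perplexity = 10), "perplexity")
  expect_warning(embed_tsne(X, perplexity = 2, n_iter = 260, n_restarts = 1),
                 "recommended")
  X30 <- matrix(rnorm(60), 30, 2, dimnames = list(paste0("i", 1:30), NULL))
  expect_warning(embed_tsne(X30, perplexity = 5, n_iter = 200, n_restarts = 1),
                 "unstable")
})

test_that("k-means labeling: trivial cases, determinism, planted recovery", {
  two <- structure(list(items = c("a", "b"),
                        coords2d = rbind(a = c(0, 0), b = c(100, 100))),
                   class = "semantic_map")
  lab <- cluster_kmeans(two, k = 2, seed = 0)
  expect_equal(length(unique(lab$mapping)), 2L)

  blobs <- make_blobs(rbind(c(10, 10), c(10, -10), c(-10, 10), c(-10, -10)),
                      n_per = 25L, sd = 1, seed = 7)
  map <- structure(list(items = rownames(blobs$X), coords2d = blobs$X),
                   class = "semantic_map")
  l1 <- cluster_kmeans(map, k = 4, seed = 3)
  l2 <- cluster_kmeans(map, k = 4, seed = 3)
  expect_identical(l1$mapping, l2$mapping)
  expect_equal(adjusted_rand_index(l1$mapping, blobs$labels), 1.0)
  expect_error(cluster_kmeans(map, k = 1), "k must")
})

test_that("k-means labels are invariant under rigid motion of the map", {
  blobs <- make_blobs(rbind(c(10, 10), c(10, -10), c(-10, 10), c(-10, -10)),
                      n_per = 25L, sd = 1, seed = 8)
  theta <- 0.7
  Rot <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  m0 <- structure(list(items = rownames(blobs$X), coords2d = blobs$X),
                  class = "semantic_map")
  m1 <- structure(list(items = rownames(blobs$X),
                       coords2d = sweep(blobs$X %*% Rot, 2L, c(3, -5), `+`)),
                  class = "semantic_map")
  rownames(m1$coords2d) <- rownames(blobs$X)
  a <- cluster_kmeans(m0, k = 4, seed = 1)
  b <- cluster_kmeans(m1, k = 4, seed = 1)
  expect_gt(adjusted_rand_index(a$mapping, b$mapping), 0.99)
})

test_that("manual label maps enforce coverage and unambiguity", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("cat\tpets", "crow\tbirds"), p)
  lab <- load_manual_labels(p, c("cat", "crow"))
  expect_equal(sort(lab$labels), c("birds", "pets"))
  expect_equal(unname(lab$mapping["cat"]), "pets")
  expect_equal(lab$source, "manual")

  writeLines(c("cat\tpets", "cat\tfarm"), p)
  expect_error(load_manual_labels(p, "cat"), "more than one label")

  writeLines("cat\tpets", p)
  expect_error(load_manual_labels(p, c("cat", "crow")), "crow")
})

test_that("adjusted Rand index: identity, chance, label permutation", {
  a <- rep(1:4, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  perm <- c("d", "a", "c", "b")[a]          # renamed labels only
  expect_equal(adjusted_rand_index(a, perm), 1)
  set.seed(30)
  aris <- replicate(200, adjusted_rand_index(a, sample(a)))
  expect_lt(abs(mean(aris)), 0.05)          # chance-corrected ~ 0
  expect_error(adjusted_rand_index(1:3, 1:4), "equal length")
})

test_that("stability analysis: duplicate conditions agree exactly", {
  blobs <- make_blobs(rbind(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0),
                            c(12, 12, 0)), n_per = 15L, sd = 1, seed = 9)
  mdsish <- structure(list(items = rownames(blobs$X),
                           coordinates = blobs$X, k_selected = 3L),
                      class = "mds_result")
  rep <- stability_analysis(mdsish, perplexities = c(10, 10), seeds = 4L,
                            k = 4, n_iter = 400, n_restarts = 1)
  expect_equal(dim(rep$ari_matrix), c(2L, 2L))
  expect_equal(rep$ari_matrix[1, 2], 1)     # same perplexity, same seed
  expect_equal(diag(rep$ari_matrix), c(1, 1))
  expect_equal(rep$ari_matrix, t(rep$ari_matrix))
  expect_error(stability_analysis(mdsish, 10, 4L), "at least 2")
})
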