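# all umap-learn work for this file happens in one batched invocation;
# the fixtures are reused across blocks
blobFixture <- function() memoFixture("blobFixture", {
  set.seed(42)
  centers <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40 * 10), 40, 10), 2,
          c(centers[k, ], rep(0, 7)), `+`)))
  labels <- rep(c("a", "b", "c"), each = 40)
  emb <- umapEmbedBatch(list(blob = X, blob_again = X),
                        umapConfig(seeds = 42:51), seeds = 42:51)
  list(X = X, labels = labels, emb = emb)
})

test_that("embeddings are deterministic, 2-D, and separate planted blobs", {
  fx <- blobFixture()
  e1 <- fx$emb$blob[["seed42"]]
  expect_equal(dim(e1), c(120, 2))
  expect_true(all(is.finite(e1)))
  # same input, same seed, same batch -> identical coordinates
  expect_identical(e1, fx$emb$blob_again[["seed42"]])
  # 20-sigma blobs separate cleanly in the embedding
  expect_gt(silhouetteScore(e1, fx$labels), 0.5)
})

test_that("ten seeds yield ten candidate embeddings and one stable choice", {
  fx <- blobFixture()
  expect_length(fx$emb$blob, 10)
  expect_named(fx$emb$blob, paste0("seed", 42:51))
  res <- selectStableEmbedding(fx$emb$blob, labels = fx$labels)
  expect_s4_class(res, "EmbeddingResult")
  expect_true(res@seed %in% 42:51)
  expect_gte(res@stabilityDisparity, 0)
  expect_gt(res@silhouette, 0.5)
})

test_that("stability selection is rotation-invariant and spots corruption", {
  set.seed(10)
  base <- matrix(rnorm(60), 30, 2)
  rot <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  embs <- lapply(c(0, 0.5, 1.2, 2.5), function(a) base %*% rot(a))
  res <- selectStableEmbedding(embs, seeds = 1:4)
  expect_lt(res@stabilityDisparity, 1e-10)
  expect_equal(res@seed, 1L)   # tie broken toward the lowest seed
  # a row-shuffled sibling is never retained
  for (rep in 1:5) {
    shuffled <- base[sample(nrow(base)), ]
    cand <- c(embs, list(shuffled))
    res2 <- selectStableEmbedding(cand, seeds = 1:5)
    expect_lt(res2@seed, 5L)
  }
  # permutation invariance in the order embeddings are supplied
  resR <- selectStableEmbedding(rev(embs), seeds = 4:1)
  expect_equal(resR@seed, res@seed)
  expect_equal(resR@stabilityDisparity, res@stabilityDisparity,
               tolerance = 1e-12)
  expect_error(selectStableEmbedding(list(base, base[-1, ])), "mismatched")
  expect_error(selectStableEmbedding(list(base)), "at least 2")
})

test_that("silhouette matches hand arithmetic on the two-pair layout", {
  coords <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  labels <- c("x", "x", "y", "y")
  # a = 1 for every point; b = mean(10, sqrt(101)) = 10.02494
  b <- mean(c(10, sqrt(101)))
  expect_equal(silhouetteScore(coords, labels), (b - 1) / b,
               tolerance = 1e-12)
  expect_equal(round(silhouetteScore(coords, labels), 3), 0.900)
  expect_equal(bruteSilhouette(coords, labels), (b - 1) / b,
               tolerance = 1e-12)
})

test_that("silhouette equals the brute-force double loop on random data", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    k <- sample(2:5, 1)
    coords <- matrix(rnorm(2 * n), n, 2)
    labels <- sample(rep_len(letters[1:k], n))
    expect_equal(silhouetteScore(coords, labels),
                 bruteSilhouette(coords, labels), tolerance = 1e-12)
  }
})

test_that("silhouette agrees with the cluster package implementation", {
  skip_if_not_installed("cluster")
  set.seed(17)
  coords <- matrix(rnorm(160), 80, 2)
  labels <- sample(rep_len(1:3, 80))
  cs <- mean(cluster::silhouette(labels, dist(coords))[, "sil_width"])
  expect_equal(silhouetteScore(coords, labels), cs, tolerance = 1e-12)
})

test_that("random label splits of one cloud score near zero", {
  set.seed(8)
  scores <- replicate(20, {
    coords <- matrix(rnorm(400), 200, 2)
    silhouetteScore(coords, sample(rep(c("u", "v"), each = 100)))
  })
  expect_true(all(abs(scores) < 0.1))
})

test_that("silhouette is undefined for singleton or single-label input", {
  coords <- matrix(rnorm(20), 10, 2)
  expect_error(silhouetteScore(coords, rep("a", 10)), "undefined")
  expect_error(silhouetteScore(coords, c(rep("a", 9), "b")), "undefined")
})

test_that("before/after comparison with k = all channels is a no-op", {
  fx <- blobFixture()
  wn <- seq(1000, by = 10, length.out = 10)
  rs <- RamanSpectra(wn, t(fx$X),
                     data.frame(tissue_class = ifelse(fx$labels == "a",
                                                      "NA", "CAA")))
  rk <- rankWavenumbers(trainRFCV(rs, "tissue_class",
                                  rfConfig(seed = 1), cv = FALSE))
  cmp <- compareBeforeAfter(rs, rk, k = 10, config = umapConfig(seeds = 42:44))
  expect_equal(cmp$silhouetteBefore, cmp$silhouetteAfter, tolerance = 1e-6)
  expect_equal(cmp$delta, 0, tolerance = 1e-6)
  # the record serializes through CSV
  rec <- data.frame(silhouette_before = cmp$silhouetteBefore,
                    silhouette_after = cmp$silhouetteAfter,
                    delta = cmp$delta, k = cmp$k)
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(rec, p, row.names = FALSE)
  expect_equal(utils::read.csv(p)$delta, rec$delta, tolerance = 1e-12)
})
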