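test_that("distance metrics reproduce hand values", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  expect_equal(pairwise_distances(m, "rows", "euclidean")["a", "b"], 5)
  m2 <- rbind(a = c(1, 5), b = c(4, 1))
  expect_equal(pairwise_distances(m2, "rows", "maximum")["a", "b"], 4)
  expect_equal(pairwise_distances(m2, "rows", "manhattan")["a", "b"], 7)
  expect_equal(pairwise_distances(m2, "rows", "minkowski", minkowski_p = 2)["a", "b"], 5)
  expect_error(pairwise_distances(m2, "rows", "minkowski", minkowski_p = -1),
               class = "phylocog_usage_error")
  expect_error(pairwise_distances(m2[1, , drop = FALSE], "rows"),
               class = "phylocog_domain_error")
  d <- pairwise_distances(matrix(runif(30), 5), "rows")
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
})

test_that("two items merge at their distance for every linkage", {
  D <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  for (lk in linkage_names) {
    dend <- agglomerate(D, lk)
    expect_equal(dend$height, 3, info = lk)
    expect_equal(nrow(dend$merge), 1L)
  }
})

test_that("three collinear points agglomerate bottom-up", {
  pts <- matrix(c(0, 1, 10), dimnames = list(c("p0", "p1", "p10"), NULL))
  dend <- agglomerate(pairwise_distances(pts, "rows"), "complete")
  tr <- merge_trace(dend)
  expect_equal(tr$sets, list(c(1L, 2L), c(1L, 2L, 3L)))
  expect_equal(tr$heights, c(1, 10))
  cl <- cut_dendrogram(dend, 2)
  expect_equal(cl[["p0"]], cl[["p1"]])
  expect_true(cl[["p10"]] != cl[["p0"]])
  expect_equal(length(unique(cl)), 2L)
})

test_that("merge count is n - 1 and cut spans k = 1 .. n", {
  withr::local_seed(13)
  m <- random_tiefree_matrix(7, 4)
  dend <- agglomerate(pairwise_distances(m, "rows"), "average")
  expect_equal(nrow(dend$merge), 6L)
  expect_equal(sort(dend$order), 1:7)
  expect_equal(unname(cut_dendrogram(dend, 1)), rep(1L, 7))
  expect_equal(length(unique(cut_dendrogram(dend, 7))), 7L)
  expect_error(cut_dendrogram(dend, 8), class = "phylocog_usage_error")
  # clusters are contiguous along the leaf order, numbered by first appearance
  for (k in 2:6) {
    lab <- cut_dendrogram(dend, k)[dend$labels[dend$order]]
    expect_equal(length(unique(lab)), k)
    runs <- rle(unname(lab))
    expect_equal(length(runs$values), k)          # contiguous
    expect_equal(runs$values, seq_len(k))         # numbered along leaf order
  }
})

test_that("agglomeration matches the naive Lance-Williams oracle", {
  withr::local_seed(99)
  for (rep in 1:6) {
    m <- random_tiefree_matrix(sample(5:9, 1), sample(3:6, 1))
    for (metric in metric_names) {
      D <- pairwise_distances(m, "rows", metric, minkowski_p = 3)
      for (lk in linkage_names) {
        got <- merge_trace(agglomerate(D, lk))
        want <- naive_lance_williams(D, lk)
        expect_equal(got$sets, want$sets, info = paste(metric, lk))
        expect_equal(got$heights, want$heights, tolerance = 1e-9,
                     info = paste(metric, lk))
      }
    }
  }
})

test_that("agglomeration agrees with stats::hclust on tie-free input", {
  withr::local_seed(7)
  for (rep in 1:5) {
    n <- sample(6:10, 1)
    m <- random_tiefree_matrix(n, 5)
    D <- stats::dist(m)
    for (lk in linkage_names) {
      ours <- agglomerate(as.matrix(D), lk)
      ref <- stats::hclust(D, method = hclust_equivalent[[lk]])
      expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-9,
                   info = lk)
      for (k in c(2, 3, n - 1)) {
        ours_cut <- cut_dendrogram(ours, k)[rownames(m)]
        ref_cut <- stats::cutree(ref, k)[rownames(m)]
        expect_equal(adjusted_rand_index(ours_cut, ref_cut), 1, info = lk)
      }
    }
  }
})

test_that("permuting input rows permutes labels without changing partitions", {
  withr::local_seed(31)
  m <- random_tiefree_matrix(8, 4)
  g1 <- cut_dendrogram(agglomerate(pairwise_distances(m, "rows")), 3)
  perm <- sample.int(8)
  g2 <- cut_dendrogram(agglomerate(pairwise_distances(m[perm, ], "rows")), 3)
  expect_equal(adjusted_rand_index(g1[rownames(m)], g2[rownames(m)]), 1)
})

test_that("a planted 4x4 block matrix yields its two blocks as modules", {
  m <- matrix(0L, 4, 4, dimnames = list(paste0("cl", 1:4), paste0("g", 1:4)))
  m[1:2, 1:2] <- 850L
  m[3:4, 3:4] <- 920L
  grid <- suppressWarnings(build_grid(m, k_cog = 2, k_phylo = 2))
  expect_equal(nrow(grid$modules), 4L)
  addr <- function(groups, clades) {
    hit <- vapply(seq_len(nrow(grid$modules)), function(i)
      setequal(grid$modules$groups[[i]], groups) &&
        setequal(grid$modules$clades[[i]], clades), logical(1))
    sum(hit)
  }
  expect_equal(addr(c("g1", "g2"), c("cl1", "cl2")), 1L)
  expect_equal(addr(c("g3", "g4"), c("cl3", "cl4")), 1L)
  sizes <- vapply(seq_len(4), function(i)
    length(grid$modules$groups[[i]]) * length(grid$modules$clades[[i]]), integer(1))
  expect_equal(sum(sizes), 16L)
})

test_that("grid shape follows the requested centers and warns off-preset", {
  withr::local_seed(2)
  m <- random_tiefree_matrix(6, 8)
  grid <- build_grid(m, k_cog = 3, k_phylo = 3, metric = "manhattan",
                     linkage = "average")
  expect_equal(nrow(grid$modules), 9L)
  expect_warning(build_grid(m, k_cog = 7, k_phylo = 3), "preset")
  expect_error(build_grid(m[1, , drop = FALSE], 2, 3),
               class = "phylocog_domain_error")
})

test_that("dendrograms export as Newick readable by ape", {
  withr::local_seed(4)
  m <- random_tiefree_matrix(6, 3)
  dend <- agglomerate(pairwise_distances(m, "rows"), "complete")
  txt <- dendrogram_newick(dend)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, rownames(m))
})
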