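test_that("fixture specs are validated before any file is written", {
  expect_error(fixture_spec(n_clades = 1), class = "phylocog_usage_error")
  expect_error(fixture_spec(block_design = matrix(1.5, 2, 2)),
               class = "phylocog_validation_error")
  expect_error(fixture_spec(noise_rate = 0,
                            block_design = matrix(c(1, 0.4, 0, 1), 2)),
               class = "phylocog_validation_error")
  expect_error(fixture_spec(score_ranges = list(c(100, 200), c(800, 900),
                                                c(920, 990)), cutoff = 700),
               class = "phylocog_validation_error")
  dir <- withr::local_tempdir()
  expect_error(generate_fixture(list(), dir), class = "phylocog_usage_error")
  expect_length(list.files(dir), 0L)
})

test_that("a noiseless diagonal design realizes an exactly block-diagonal binary matrix", {
  dir <- withr::local_tempdir()
  spec <- small_spec(rng_seed = 5)
  res <- profile_from_bundle(spec, dir)
  truth <- res$bundle$ground_truth
  bin <- (res$wpm$values > 0) * 1L
  for (cl in rownames(bin)) for (g in setdiff(colnames(bin), spec$seed_group)) {
    expect_equal(bin[cl, g],
                 as.integer(truth$clade_blocks[[cl]] == truth$group_blocks[[g]]),
                 info = paste(cl, g))
  }
  expect_true(all(bin[, spec$seed_group] == 1L))  # seed present everywhere
})

test_that("bundles are byte-identical under the same spec and seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_fixture(small_spec(rng_seed = 3, noise_rate = 0.2), d1)
  generate_fixture(small_spec(rng_seed = 3, noise_rate = 0.2), d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  d3 <- withr::local_tempdir()
  generate_fixture(small_spec(rng_seed = 4, noise_rate = 0.2), d3)
  expect_false(identical(readLines(file.path(d1, "memberships.txt")),
                         readLines(file.path(d3, "memberships.txt"))))
})

test_that("decoy groups fall below the design cutoff by construction", {
  dir <- withr::local_tempdir()
  spec <- small_spec(rng_seed = 6, off_network_groups = 3)
  bundle <- generate_fixture(spec, dir)
  links <- read_links(file.path(dir, "links.txt"))
  net <- select_neighbors(links, spec$seed_group, spec$cutoff)
  expect_length(intersect(net$neighbors$group_id, bundle$ground_truth$decoys), 0L)
  expect_setequal(net$neighbors$group_id,
                  names(bundle$ground_truth$group_blocks))
})

test_that("generated bundles drive the whole pipeline without errors", {
  withr::local_seed(23)
  for (seed in sample.int(1000, 3)) {
    dir <- withr::local_tempdir()
    spec <- small_spec(rng_seed = seed, noise_rate = 0.1)
    res <- profile_from_bundle(spec, dir)
    grid <- build_grid(res$wpm, 3, 3)
    enr <- module_enrichment(res$wpm, grid)
    expect_equal(nrow(enr), 9L)
  }
})

test_that("adjusted Rand index matches hand and reference calculations", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  # one 2-cluster truth vs all singletons on 4 items, by the contingency
  # formula: sum_ij C(n_ij,2)=0, sum_i C(a_i,2)=2, sum_j C(b_j,2)=0,
  # expected = 0, denominator = 1, ARI = 0
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), 1:4), 0)
  # hand contingency case: x = {1,1,2,2}, y = {1,2,2,2}
  # sum_ij C = 1, rows = 2, cols = 3, exp = 1, denom = 1.5 -> ARI = 0
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)
  expect_equal(adjusted_rand_index(c(1, 2, 1, 2), c(1, 2, 1, 3)),
               mclust::adjustedRandIndex(c(1, 2, 1, 2), c(1, 2, 1, 3)))
  withr::local_seed(19)
  for (rep in 1:10) {
    x <- sample(1:4, 12, replace = TRUE)
    y <- sample(1:3, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))
  }
  expect_error(adjusted_rand_index(1:3, 1:4), class = "phylocog_usage_error")
})

test_that("recovery evaluation scores planted against recovered labels", {
  dir <- withr::local_tempdir()
  spec <- small_spec(rng_seed = 2)
  res <- profile_from_bundle(spec, dir, include_seed = FALSE)
  grid <- build_grid(res$wpm, 3, 3)
  ari <- evaluate_recovery(res$bundle$ground_truth, grid)
  expect_named(ari, c("rows", "cols"))
  expect_equal(unname(ari), c(1, 1))
})
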