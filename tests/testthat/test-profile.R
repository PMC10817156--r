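mk_members <- function(...) {
  rows <- list(...)
  data.frame(group_id = vapply(rows, `[[`, "", 1),
             taxon_id = as.integer(vapply(rows, `[[`, "", 2)),
             protein_id = vapply(rows, `[[`, "", 3),
             stringsAsFactors = FALSE)
}

test_that("presence counts organisms, not proteins", {
  roster <- list(A = 1:4, B = 5:7)
  mem <- mk_members(c("COG0002", "1", "p1"), c("COG0002", "2", "p1"),
                    # five paralogs of organism 5 count once
                    c("COG0002", "5", "p1"), c("COG0002", "5", "p2"),
                    c("COG0002", "5", "p3"), c("COG0002", "5", "p4"),
                    c("COG0002", "5", "p5"))
  freq <- presence_frequency(mem, roster, c("COG0002", "COG0003"))
  expect_equal(freq$freq["A", "COG0002"], 0.5)
  expect_equal(freq$freq["B", "COG0002"], 1 / 3)
  # group with no memberships keeps an all-zero column
  expect_equal(unname(freq$freq[, "COG0003"]), c(0, 0))
  # denominator exactness: frequency * roster size is the integer count
  expect_equal(freq$freq * lengths(roster)[rownames(freq$freq)], freq$counts + 0)
})

test_that("empty-roster clades are excluded with a warning", {
  mem <- mk_members(c("COG0002", "1", "p1"))
  expect_warning(freq <- presence_frequency(mem, list(A = 1L, B = integer()),
                                            c("COG0002")),
                 "empty roster")
  expect_equal(rownames(freq$freq), "A")
})

test_that("binarization boundary is inclusive at the threshold", {
  freq <- structure(list(freq = matrix(c(0.49, 0.50, 0.51, 1.0), 2,
                                       dimnames = list(c("r1", "r2"), c("c1", "c2"))),
                         counts = matrix(c(49L, 50L, 51L, 100L), 2),
                         roster_sizes = c(r1 = 100L, r2 = 100L)),
                    class = "presence_matrix")
  b <- binarize(freq)
  expect_equal(unname(b$values), matrix(c(0L, 1L, 1L, 1L), 2))
  # monotone: raising a frequency never flips 1 -> 0
  withr::local_seed(3)
  f1 <- matrix(runif(20), 4, 5, dimnames = list(letters[1:4], letters[5:9]))
  f2 <- pmin(f1 + runif(20, 0, 0.3), 1)
  pm <- function(f) structure(list(freq = f, counts = round(f * 10),
                                   roster_sizes = setNames(rep(10L, 4), letters[1:4])),
                              class = "presence_matrix")
  expect_true(all(binarize(pm(f2))$values >= binarize(pm(f1))$values))
  expect_error(binarize(pm(f1), threshold = 0), class = "phylocog_usage_error")
})

test_that("weighting multiplies presence by the seed-link score", {
  net <- select_neighbors(seed_links("COG0009", c(COG0002 = 850L)), "COG0009", 850)
  roster <- list(A = 1:2, B = 3:4)
  mem <- mk_members(c("COG0002", "1", "p1"), c("COG0002", "2", "p2"),
                    c("COG0009", "1", "p0"), c("COG0009", "2", "p0"),
                    c("COG0009", "3", "p0"), c("COG0009", "4", "p0"))
  wpm <- weight_matrix(binarize(presence_frequency(
    mem, roster, network_columns(net, TRUE))), net, TRUE)
  expect_equal(wpm$values["A", "COG0002"], 850L)   # binary 1 x 850
  expect_equal(wpm$values["B", "COG0002"], 0L)     # binary 0
  expect_equal(wpm$values["A", "COG0009"], 1000L)  # seed self-weight
  # column without a recorded weight is a consistency error
  bad <- binarize(presence_frequency(mem, roster, c("COG0002", "COG0042")))
  expect_error(weight_matrix(bad, net, TRUE), class = "phylocog_consistency_error")
})

test_that("nonzero values in a column all equal the column weight", {
  withr::local_seed(21)
  for (rep in 1:15) {
    n <- sample(3:8, 1)
    scores <- sample(700:1000, n)
    names(scores) <- sprintf("COG%04d", sample(2:9999, n))
    net <- select_neighbors(seed_links("COG0001", scores), "COG0001", 700)
    roster <- split(1:12, rep(c("A", "B", "C"), each = 4))
    present <- expand.grid(taxon_id = 1:12, group_id = c("COG0001", names(scores)))
    present <- present[runif(nrow(present)) < 0.5, ]
    mem <- data.frame(group_id = as.character(present$group_id),
                      taxon_id = present$taxon_id,
                      protein_id = "p1", stringsAsFactors = FALSE)
    wpm <- weight_matrix(binarize(presence_frequency(
      mem, roster, network_columns(net, TRUE))), net, TRUE)
    for (col in colnames(wpm$values)) {
      nz <- unique(wpm$values[wpm$values[, col] > 0, col])
      expect_lte(length(nz), 1L)
      if (length(nz)) expect_equal(unname(nz), unname(wpm$column_weights[col]))
    }
    expect_true(all(wpm$column_weights >= wpm$cutoff | names(wpm$column_weights) == "COG0001"))
    # permutation invariance of the membership records
    perm <- mem[sample.int(nrow(mem)), ]
    wpm2 <- weight_matrix(binarize(presence_frequency(
      perm, roster, network_columns(net, TRUE))), net, TRUE)
    expect_equal(wpm2$values, wpm$values)
  }
})

test_that("cell annotation carries the four hover fields per cell", {
  net <- select_neighbors(seed_links("COG0009", c(COG0199 = 850L)), "COG0009", 850)
  roster <- list(cladeA = 1:10, cladeB = 11:12)
  mem <- do.call(mk_members, c(
    lapply(1:7, function(i) c("COG0199", as.character(i), "p1")),
    list(c("COG0009", "1", "p0"), c("COG0009", "11", "p0"), c("COG0009", "12", "p0"))))
  wpm <- weight_matrix(binarize(presence_frequency(
    mem, roster, network_columns(net, TRUE))), net, TRUE)
  ann <- suppressMessages(
    cell_annotation(wpm, c(COG0199 = "Ribosomal protein S14")))
  expect_equal(nrow(ann), nrow(wpm$values) * ncol(wpm$values))
  rec <- ann[ann$clade == "cladeA" & grepl("COG0199", ann$cog), ]
  expect_equal(rec$cog, "COG0199: Ribosomal protein S14")
  expect_equal(rec$organism_count, 7L)
  expect_equal(rec$score, 850L)
  # a zero cell reports its below-threshold count and score 0
  zero <- ann[ann$clade == "cladeB" & grepl("COG0199", ann$cog), ]
  expect_equal(zero$organism_count, 0L)
  expect_equal(zero$score, 0L)
})
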