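test_that("species reader parses ids and names and enforces uniqueness", {
  f <- tmpfile(c("# header", "9606\tHomo sapiens", "562\tEscherichia coli"))
  sp <- read_species(f)
  expect_equal(sp$taxon_id, c(9606L, 562L))
  expect_equal(sp$name, c("Homo sapiens", "Escherichia coli"))

  expect_equal(nrow(read_species(tmpfile(character()))), 0L)
  expect_error(read_species(tmpfile(c("9606\ta", "9606\tb"))),
               class = "phylocog_validation_error")
  expect_error(read_species(tmpfile("abc\tname")),
               class = "phylocog_parse_error")
  err <- tryCatch(read_species(tmpfile(c("1\tok", "x\tbad"))),
                  error = function(e) conditionMessage(e))
  expect_match(err, ":2:")  # line number reported
})

test_that("lineage reader handles the dump dialect", {
  f <- tmpfile("9606\t|\tHomo sapiens\t|\tcellular organisms; Eukaryota; Chordata; Mammalia\t|")
  lin <- read_lineages(f)
  expect_equal(lin$taxon_id, 9606L)
  expect_equal(lin$lineage[[1]],
               c("cellular organisms", "Eukaryota", "Chordata", "Mammalia"))

  trail <- read_lineages(tmpfile("2\t|\tBacteria\t|\tBacteria; \t|"))
  expect_equal(trail$lineage[[1]], "Bacteria")

  expect_error(read_lineages(tmpfile("9606\t|\tonly two fields\t|")),
               class = "phylocog_parse_error")
})

test_that("membership reader validates group ids in both layouts", {
  three <- read_memberships(tmpfile("562\tb0001\tCOG0199"))
  expect_equal(three, data.frame(group_id = "COG0199", taxon_id = 562L,
                                 protein_id = "b0001", stringsAsFactors = FALSE))
  string <- read_memberships(tmpfile("562.b0001\tCOG0199"))
  expect_equal(string, three)
  # KOG accepted, protein ids may contain dots in the combined layout
  kog <- read_memberships(tmpfile("9606.ENSP00000269.2\tKOG0985"))
  expect_equal(kog$group_id, "KOG0985")
  expect_equal(kog$protein_id, "ENSP00000269.2")

  expect_error(read_memberships(tmpfile("562\tb0001\tXOG0001")),
               class = "phylocog_validation_error")
  expect_error(read_memberships(tmpfile(c("562\tp1\tCOG0001", "562\tp1\tCOG0001"))),
               class = "phylocog_validation_error")
})

test_that("links reader builds a symmetric score table with range checks", {
  tab <- read_links(tmpfile(c("COG0001 COG0002 900", "COG0001\tCOG0003\t700")))
  expect_equal(assoc_score(tab, "COG0002", "COG0001"), 900L)
  expect_equal(assoc_score(tab, "COG0001", "COG0003"), 700L)
  expect_true(is.na(assoc_score(tab, "COG0002", "COG0003")))

  expect_error(read_links(tmpfile("COG0001 COG0002 1001")),
               class = "phylocog_validation_error")
  expect_error(read_links(tmpfile(c("COG0001 COG0002 900",
                                    "COG0002 COG0001 850"))),
               class = "phylocog_validation_error")
  # equal duplicate is tolerated, self-pair is not
  dup <- read_links(tmpfile(c("COG0001 COG0002 900", "COG0002 COG0001 900")))
  expect_equal(nrow(dup$pairs), 1L)
  expect_error(read_links(tmpfile("COG0001 COG0001 500")),
               class = "phylocog_validation_error")
})

test_that("fasta reader takes first header token, uppercases, validates", {
  f <- tmpfile(c(">p1 some description", "MKV", "LT", ">p2", "acdef"))
  seqs <- read_fasta(f)
  expect_equal(seqs, c(p1 = "MKVLT", p2 = "ACDEF"))
  expect_length(read_fasta(tmpfile(character())), 0L)
  err <- tryCatch(read_fasta(tmpfile(c(">p1", "MK9V"))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "p1")
})

test_that("write/read round-trips are the identity on records", {
  withr::local_seed(11)
  dir <- withr::local_tempdir()
  for (rep in 1:5) {
    n <- sample(0:20, 1)
    sp <- data.frame(taxon_id = sample.int(1e6, n),
                     name = vapply(seq_len(n), function(i)
                       paste(sample(letters, 8), collapse = ""), character(1)),
                     stringsAsFactors = FALSE)
    f <- file.path(dir, "sp.txt")
    write_species(sp, f)
    expect_equal(read_species(f), sp)

    lin <- data.frame(taxon_id = sample.int(1e6, max(n, 1)))
    lin$lineage <- replicate(max(n, 1), c("cellular organisms",
                                          sample(LETTERS, sample(1:5, 1))),
                             simplify = FALSE)
    write_lineages(lin, f)
    expect_equal(read_lineages(f), lin)

    mem <- data.frame(group_id = sprintf("COG%04d", sample.int(9999, max(n, 1))),
                      taxon_id = sample.int(1e5, max(n, 1)),
                      protein_id = sprintf("prot%d", seq_len(max(n, 1))),
                      stringsAsFactors = FALSE)
    for (fmt in c("string", "three_column")) {
      write_memberships(mem, f, format = fmt)
      expect_equal(read_memberships(f), mem)
    }

    m <- max(n, 2)
    ids <- sprintf("COG%04d", sample.int(9999, 2 * m))
    tab <- association_table(ids[1:m], ids[(m + 1):(2 * m)],
                             sample(0:1000, m, replace = TRUE))
    write_links(tab, f)
    expect_equal(read_links(f), tab)

    seqs <- stats::setNames(vapply(seq_len(max(n, 1)), function(i)
      random_aa(sample(5:40, 1)), ""), sprintf("q%d", seq_len(max(n, 1))))
    write_fasta(seqs, f)
    expect_equal(read_fasta(f), seqs)
  }
  # empty membership table round-trips too
  f <- file.path(dir, "empty.txt")
  write_memberships(read_memberships(tmpfile(character())), f)
  expect_equal(nrow(read_memberships(f)), 0L)
})
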