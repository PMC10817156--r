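# Programmatic fixtures shared across test files.

tmpfile <- function(lines) {
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# association table around a seed with given neighbor scores
seed_links <- function(seed = "COG0001", scores = c(COG0002 = 900L)) {
  association_table(rep(seed, length(scores)), names(scores),
                    unname(scores))
}

# minimal weighted-profile object for unit tests that bypass the pipeline
make_profile <- function(values, counts = NULL, sizes = NULL,
                         cutoff = 700L, seed = "COG0001") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(counts)) counts <- (values > 0) * 1L
  structure(list(values = values,
                 column_weights = apply(values, 2, max),
                 cutoff = cutoff, seed = seed,
                 counts = counts,
                 roster_sizes = sizes %||%
                   stats::setNames(rep(4L, nrow(values)), rownames(values))),
            class = "weighted_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_aa <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# substitute a fraction of positions with random residues
mutate_aa <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ch[hit] <- sample(alphabet, length(hit), replace = TRUE)
  paste(ch, collapse = "")
}

# a family of sequences derived from one parent, plus the parent
protein_family <- function(size, length, rate = 0.05, prefix = "s") {
  parent <- random_aa(length)
  seqs <- c(parent, vapply(seq_len(size - 1L),
                           function(i) mutate_aa(parent, rate), ""))
  stats::setNames(seqs, sprintf("%s%02d", prefix, seq_len(size)))
}

# small, fast fixture spec for tests
small_spec <- function(rng_seed = 1L, noise_rate = 0,
                       n_clades = 9L, organisms_per_clade = 4L,
                       n_groups = 12L, ...) {
  fixture_spec(n_clades = n_clades, organisms_per_clade = organisms_per_clade,
               n_groups = n_groups, rng_seed = rng_seed,
               noise_rate = noise_rate, ...)
}

# generate a bundle, read it back, and build the weighted profile
profile_from_bundle <- function(spec, dir, include_seed = TRUE) {
  bundle <- generate_fixture(spec, dir)
  memberships <- read_memberships(file.path(dir, "memberships.txt"))
  links <- read_links(file.path(dir, "links.txt"))
  lineages <- read_lineages(file.path(dir, "lineages.dmp"))
  assignment <- suppressMessages(assign_clades(lineages, "phylum"))
  roster <- clade_roster(assignment)
  net <- select_neighbors(links, spec$seed_group, spec$cutoff)
  cols <- network_columns(net, include_seed)
  wpm <- weight_matrix(binarize(presence_frequency(memberships, roster, cols)),
                       net, include_seed)
  list(bundle = bundle, net = net, wpm = wpm)
}
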