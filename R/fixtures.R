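# Synthetic STRING-style datasets with planted clade x group module
# structure, so every pipeline stage can be exercised without external
# downloads. The generator writes the same four flat files the readers
# consume, plus the ground-truth block labels and the realized frequency
# matrix.
#
# One RNG stream per file type, each derived from rng_seed, so adding a file
# type never perturbs the others' draws. All identifiers are deterministic
# functions of the spec, which makes bundles byte-stable.

#' Describe a synthetic dataset with planted block structure
#'
#' Clades are split contiguously into \code{nrow(block_design)} blocks and
#' network groups into \code{ncol(block_design)} blocks; the entry
#' \code{block_design[r, b]} is the probability that an organism of a
#' clade-block-\code{r} clade possesses a block-\code{b} group (optionally
#' XOR a Bernoulli noise flip). Each group block draws its seed-association
#' scores uniformly from its own integer interval, so blocks are
#' distinguishable by score as well as by pattern. Decoy groups receive
#' scores strictly below \code{cutoff} and are therefore excluded from the
#' seed neighborhood by construction.
#'
#' Defaults describe the reference simulation used throughout the package:
#' 12 clades of 6 organisms, 20 network groups in a 3 x 3 diagonal block
#' design with disjoint score intervals, 3 decoys, no noise.
#'
#' @param n_clades Number of clades (>= 2).
#' @param organisms_per_clade Scalar or per-clade integer vector (>= 1).
#' @param n_groups Number of network (non-decoy, non-seed) groups (>= 2).
#' @param seed_group Seed group id.
#' @param block_design Probability matrix (clade blocks x group blocks).
#'   A noiseless spec must use probabilities only from {0, 1}.
#' @param score_ranges List of integer intervals \code{c(lo, hi)}, one per
#'   group block, each within \code{[cutoff, 1000]}.
#' @param off_network_groups Number of decoy groups scored below the cutoff.
#' @param noise_rate Per-cell presence flip probability in \[0, 1\].
#' @param cutoff The STRING cutoff the bundle is designed for.
#' @param rng_seed Integer seed; bundles are byte-identical given the spec.
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_clades = 12L, organisms_per_clade = 6L,
                         n_groups = 20L, seed_group = "COG0001",
                         block_design = diag(3), score_ranges = NULL,
                         off_network_groups = 3L, noise_rate = 0,
                         cutoff = 700L, rng_seed = 1L) {
  n_clades <- .check_scalar_count(n_clades, "n_clades", 2L)
  n_groups <- .check_scalar_count(n_groups, "n_groups", 2L)
  off_network_groups <- .check_scalar_count(off_network_groups, "off_network_groups", 0L)
  cutoff <- .check_scalar_count(cutoff, "cutoff", 0L)
  if (cutoff > 1000L) .validation_error("'cutoff' must be within [0, 1000]")
  rng_seed <- .check_scalar_count(rng_seed, "rng_seed", 0L)
  if (length(organisms_per_clade) == 1L)
    organisms_per_clade <- rep(organisms_per_clade, n_clades)
  if (length(organisms_per_clade) != n_clades || any(organisms_per_clade < 1L))
    .validation_error("'organisms_per_clade' must be >= 1 for every clade")
  organisms_per_clade <- as.integer(organisms_per_clade)
  block_design <- as.matrix(block_design)
  if (any(block_design < 0) || any(block_design > 1))
    .validation_error("block presence probabilities must be in [0, 1]")
  if (length(noise_rate) != 1L || is.na(noise_rate) || noise_rate < 0 || noise_rate > 1)
    .validation_error("'noise_rate' must be in [0, 1]")
  if (noise_rate == 0 && !all(block_design %in% c(0, 1)))
    .validation_error("a noiseless spec must use presence probabilities only from {0, 1}")
  if (nrow(block_design) > n_clades || ncol(block_design) > n_groups)
    .validation_error("more blocks than clades/groups")
  if (is.null(score_ranges))
    score_ranges <- .default_score_ranges(ncol(block_design), cutoff)
  if (length(score_ranges) != ncol(block_design))
    .validation_error("need one score range per group block")
  for (r in score_ranges) {
    if (length(r) != 2L || r[1L] > r[2L] || r[1L] < cutoff || r[2L] > 1000L)
      .validation_error("score ranges must be integer intervals within [cutoff, 1000]")
  }
  if (!.is_group_id(seed_group)) .validation_error("invalid seed group id")
  if (off_network_groups > 0L && cutoff < 1L)
    .validation_error("decoy groups need 'cutoff' >= 1 to be scored below it")
  structure(list(n_clades = n_clades, organisms_per_clade = organisms_per_clade,
                 n_groups = n_groups, seed_group = seed_group,
                 block_design = block_design,
                 score_ranges = lapply(score_ranges, as.integer),
                 off_network_groups = off_network_groups,
                 noise_rate = as.numeric(noise_rate), cutoff = cutoff,
                 rng_seed = rng_seed),
            class = "fixture_spec")
}

# disjoint intervals spread over [cutoff, 1000], highest block darkest
.default_score_ranges <- function(b, cutoff) {
  edges <- round(seq(cutoff, 1000L, length.out = b + 1L))
  lapply(seq_len(b), function(i) c(edges[i] + (i > 1L) * 10L, edges[i + 1L] - 10L))
}

# contiguous, balanced assignment of n items to b blocks
.block_of <- function(n, b) {
  sizes <- diff(round(seq(0, n, length.out = b + 1L)))
  rep(seq_len(b), times = sizes)
}

#' Generate a synthetic file bundle with planted structure
#'
#' Writes \code{species.txt}, \code{lineages.dmp}, \code{memberships.txt}
#' (explicit three-column layout), \code{links.txt},
#' \code{ground_truth.json} and \code{README.txt} into \code{dir}. The seed
#' group is present in every organism; decoy groups are present at random
#' and scored below the cutoff.
#'
#' @param spec A \code{fixture_spec}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with \code{dir}, \code{files} (named paths) and
#'   \code{ground_truth} (clade/group block labels, taxon rosters and the
#'   realized presence-frequency matrix).
#' @export
generate_fixture <- function(spec, dir) {
  if (!inherits(spec, "fixture_spec"))
    .usage_error("'spec' must be a fixture_spec")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  B_r <- nrow(spec$block_design); B_c <- ncol(spec$block_design)
  clades <- sprintf("Clade%02d", seq_len(spec$n_clades))
  clade_block <- stats::setNames(.block_of(spec$n_clades, B_r), clades)
  groups <- sprintf("COG%04d", 100L + seq_len(spec$n_groups))
  group_block <- stats::setNames(.block_of(spec$n_groups, B_c), groups)
  decoys <- if (spec$off_network_groups > 0L)
    sprintf("COG%04d", 900L + seq_len(spec$off_network_groups)) else character()
  taxids <- 1000L + seq_len(sum(spec$organisms_per_clade))
  clade_of_taxon <- rep(clades, spec$organisms_per_clade)

  species <- data.frame(taxon_id = taxids,
                        name = sprintf("Synthetic organism %d", taxids),
                        stringsAsFactors = FALSE)
  lineages <- data.frame(taxon_id = taxids, stringsAsFactors = FALSE)
  lineages$lineage <- lapply(seq_along(taxids), function(i)
    c("cellular organisms", "Bacteria", clade_of_taxon[i],
      paste0(clade_of_taxon[i], "_class"), sprintf("Synthetic organism %d", taxids[i])))

  # membership stream
  set.seed(spec$rng_seed)
  p <- spec$block_design[clade_block[clade_of_taxon], group_block[groups], drop = FALSE]
  pres <- matrix(stats::runif(length(p)) < p, nrow = length(taxids),
                 dimnames = list(taxids, groups))
  if (spec$noise_rate > 0) {
    flip <- matrix(stats::runif(length(p)) < spec$noise_rate, nrow = length(taxids))
    pres <- xor(pres, flip)
  }
  decoy_pres <- matrix(stats::runif(length(taxids) * length(decoys)) < 0.5,
                       nrow = length(taxids), dimnames = list(taxids, decoys))

  all_groups <- c(spec$seed_group, groups, decoys)
  present <- cbind(matrix(TRUE, length(taxids), 1L,
                          dimnames = list(taxids, spec$seed_group)),
                   pres, decoy_pres)
  idx <- which(present, arr.ind = TRUE)
  memberships <- data.frame(
    group_id = all_groups[idx[, 2L]],
    taxon_id = taxids[idx[, 1L]],
    protein_id = sprintf("p%03d", idx[, 2L]),
    stringsAsFactors = FALSE)
  memberships <- memberships[order(memberships$taxon_id, memberships$group_id), ]

  # links stream
  set.seed(spec$rng_seed + 1L)
  draw_from <- function(lo, hi, n) {
    vals <- lo:hi
    vals[sample.int(length(vals), n, replace = TRUE)]
  }
  score <- integer(length(groups))
  for (b in seq_len(B_c)) {
    sel <- group_block[groups] == b
    rng <- spec$score_ranges[[b]]
    score[sel] <- draw_from(rng[1L], rng[2L], sum(sel))
  }
  decoy_lo <- max(0L, min(100L, spec$cutoff - 1L))
  decoy_score <- if (length(decoys))
    draw_from(decoy_lo, spec$cutoff - 1L, length(decoys)) else integer()
  link_a <- c(rep(spec$seed_group, length(groups) + length(decoys)), groups[1L])
  link_b <- c(groups, decoys, groups[min(2L, length(groups))])
  link_s <- c(score, decoy_score, 999L)  # one neighbor-neighbor edge, unused downstream
  if (groups[1L] == groups[min(2L, length(groups))]) {
    link_a <- link_a[-length(link_a)]; link_b <- link_b[-length(link_b)]
    link_s <- link_s[-length(link_s)]
  }
  links <- association_table(link_a, link_b, link_s)

  files <- c(species = file.path(dir, "species.txt"),
             lineages = file.path(dir, "lineages.dmp"),
             memberships = file.path(dir, "memberships.txt"),
             links = file.path(dir, "links.txt"),
             ground_truth = file.path(dir, "ground_truth.json"),
             readme = file.path(dir, "README.txt"))
  write_species(species, files[["species"]])
  write_lineages(lineages, files[["lineages"]])
  write_memberships(memberships, files[["memberships"]], format = "three_column")
  write_links(links, files[["links"]])

  roster <- split(taxids, clade_of_taxon)[clades]
  realized <- presence_frequency(memberships, roster, c(spec$seed_group, groups))
  truth <- list(seed = spec$seed_group, cutoff = spec$cutoff,
                clade_blocks = as.list(clade_block),
                group_blocks = as.list(group_block),
                decoys = as.list(decoys),
                rosters = lapply(roster, as.integer),
                frequency = apply(realized$freq, 1L, as.list, simplify = FALSE))
  jsonlite::write_json(truth, files[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c("Synthetic bundle with planted clade x group block structure.",
               sprintf("clades: %d (blocks: %d)  organisms: %d", spec$n_clades,
                       B_r, length(taxids)),
               sprintf("network groups: %d (blocks: %d)  decoys: %d",
                       spec$n_groups, B_c, length(decoys)),
               sprintf("seed group: %s  design cutoff: %d  noise rate: %g",
                       spec$seed_group, spec$cutoff, spec$noise_rate),
               sprintf("score ranges: %s",
                       paste(vapply(spec$score_ranges,
                                    function(r) sprintf("[%d, %d]", r[1L], r[2L]), ""),
                             collapse = " ")),
               sprintf("rng seed: %d", spec$rng_seed),
               "membership layout: three_column (taxon_id, protein_id, group_id)"),
             files[["readme"]])

  invisible(list(dir = dir, files = files,
                 ground_truth = list(seed = spec$seed_group, cutoff = spec$cutoff,
                                     clade_blocks = clade_block,
                                     group_blocks = group_block,
                                     decoys = decoys, rosters = roster,
                                     frequency = realized$freq)))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' computed from the closed-form contingency formula. When both partitions
#' are trivial (zero-variance contingency), the index is 1 if they agree and
#' 0 otherwise.
#'
#' @param x,y Label vectors of equal length (any atomic type).
#' @return A number in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) .usage_error("label vectors must have equal length")
  if (length(x) == 0L) .usage_error("label vectors must be non-empty")
  tab <- table(x, y)
  n <- length(x)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  denom <- (sum_i + sum_j) / 2 - expected
  if (denom == 0) return(as.numeric(sum_ij == expected))
  (sum_ij - expected) / denom
}

#' Recovery of planted blocks by a module grid
#'
#' @param truth Ground truth as returned in \code{generate_fixture()$ground_truth}
#'   (named \code{clade_blocks} and \code{group_blocks} label vectors).
#' @param grid A \code{module_grid} built from the corresponding bundle.
#' @return Named numeric vector \code{c(rows = ..., cols = ...)} of adjusted
#'   Rand indices between planted and recovered partitions on each axis.
#' @export
evaluate_recovery <- function(truth, grid) {
  stopifnot(inherits(grid, "module_grid"))
  rows <- names(grid$row_clusters)
  cols <- names(grid$col_clusters)
  tr <- unlist(truth$clade_blocks)[rows]
  tc <- unlist(truth$group_blocks)[cols]
  if (anyNA(tr) || anyNA(tc))
    .usage_error("grid labels missing from the ground truth")
  c(rows = adjusted_rand_index(tr, grid$row_clusters),
    cols = adjusted_rand_index(tc, grid$col_clusters))
}
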