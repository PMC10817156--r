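# End-to-end pipeline: (optional) seed resolution -> neighborhood selection
# -> clade profiling -> biclustering -> enrichment -> rendering and tables.
# Any stage failure is surfaced with the stage name; partially written
# outputs are removed.

#' Pipeline run configuration
#'
#' Defaults mirror the analysis defaults of the method: euclidean distance,
#' complete linkage, cutoff 850 (the most common case-study setting), phylum
#' rank, 4 COG clusters and 3 phylogenetic clusters.
#'
#' @param data_dir Directory holding the four flat files.
#' @param out_dir Output directory (created if needed).
#' @param seed_group Seed group id; may be \code{NULL} when
#'   \code{query_fasta} plus a reference is supplied.
#' @param query_fasta Optional FASTA with a single query protein used to
#'   resolve the seed group by sequence similarity.
#' @param reference_fasta,reference_map Reference protein FASTA and
#'   two-column TSV (protein id, group id) used only for seed resolution.
#' @param cutoff STRING score cutoff in \[0, 1000\]; default 850.
#' @param rank Taxonomic rank, \code{"phylum"} (default) or \code{"class"}.
#' @param k_cog,k_phylo Cluster counts for columns / rows (defaults 4 / 3).
#' @param metric,linkage,minkowski_p Clustering parameters (defaults
#'   euclidean / complete / 3).
#' @param include_seed Show the seed as first column with imputed weight
#'   1000 (default \code{TRUE}).
#' @param drop_empty Drop all-zero clade rows before clustering (default
#'   \code{FALSE}: all-light rows are kept, as in the reference analyses).
#' @param binarize_threshold Within-clade presence threshold (default 0.5).
#' @param core_list Optional path to a file of taxon ids; rosters are
#'   restricted to these "core" organisms.
#' @param descriptions Optional path to a two-column TSV (group id,
#'   description) used in annotations.
#' @param membership_format Passed to [read_memberships()].
#' @param files Named character vector overriding the default bundle file
#'   names (\code{species}, \code{lineages}, \code{memberships},
#'   \code{links}).
#' @return Object of class \code{run_config}.
#' @export
run_config <- function(data_dir, out_dir,
                       seed_group = NULL, query_fasta = NULL,
                       reference_fasta = NULL, reference_map = NULL,
                       cutoff = 850L, rank = "phylum",
                       k_cog = 4L, k_phylo = 3L,
                       metric = "euclidean", linkage = "complete",
                       minkowski_p = 3, include_seed = TRUE,
                       drop_empty = FALSE, binarize_threshold = 0.5,
                       core_list = NULL, descriptions = NULL,
                       membership_format = "auto",
                       files = NULL) {
  if (missing(data_dir) || missing(out_dir))
    .usage_error("'data_dir' and 'out_dir' are required")
  if (is.null(seed_group) && is.null(query_fasta))
    .usage_error("either 'seed_group' or 'query_fasta' is required")
  defaults <- c(species = "species.txt", lineages = "lineages.dmp",
                memberships = "memberships.txt", links = "links.txt")
  if (!is.null(files)) defaults[names(files)] <- files
  cfg <- list(data_dir = data_dir, out_dir = out_dir, seed_group = seed_group,
              query_fasta = query_fasta, reference_fasta = reference_fasta,
              reference_map = reference_map, cutoff = as.integer(cutoff),
              rank = rank, k_cog = as.integer(k_cog),
              k_phylo = as.integer(k_phylo), metric = metric,
              linkage = linkage, minkowski_p = minkowski_p,
              include_seed = isTRUE(include_seed),
              drop_empty = isTRUE(drop_empty),
              binarize_threshold = binarize_threshold,
              core_list = core_list, descriptions = descriptions,
              membership_format = membership_format, files = defaults)
  if (cfg$cutoff < 0L || cfg$cutoff > 1000L)
    .usage_error("'cutoff' must be within [0, 1000]")
  structure(cfg, class = "run_config")
}

.stage <- function(name, expr) {
  withCallingHandlers(expr, error = function(e) {
    if (inherits(e, "phylocog_stage_error")) return()
    stop(errorCondition(sprintf("pipeline stage '%s': %s", name, conditionMessage(e)),
                        class = c("phylocog_stage_error", class(e))))
  })
}

.read_two_col_tsv <- function(path) {
  ln <- .read_data_lines(path)
  if (length(ln$text) == 0L) return(stats::setNames(character(), character()))
  fields <- lapply(ln$text, function(l) .split_fields(l))
  if (any(lengths(fields) < 2L))
    .parse_error(sprintf("%s: expected two tab-separated columns", path))
  stats::setNames(vapply(fields, function(f) paste(f[-1L], collapse = " "), ""),
                  vapply(fields, `[`, "", 1L))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline
#'
#' Executes seed resolution (when configured), neighborhood selection,
#' clade profiling, biclustering, enrichment and rendering, and writes
#' \code{matrix.tsv}, \code{cog_groups.tsv}, \code{phylo_groups.tsv},
#' \code{enrichment.tsv}, \code{cells.tsv}, \code{heatmap.svg} and
#' \code{run_log.txt} into the output directory. Outputs are deterministic:
#' rerunning an identical configuration reproduces them byte for byte.
#'
#' @param config A \code{run_config}.
#' @return Invisibly, a list with the intermediate objects (\code{network},
#'   \code{profile}, \code{grid}, \code{enrichment}, \code{annotation}) and
#'   the output \code{files}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- function(f) file.path(config$data_dir, config$files[[f]])

  species <- .stage("read species", read_species(p("species")))
  lineages <- .stage("read lineages", read_lineages(p("lineages")))
  memberships <- .stage("read memberships",
                        read_memberships(p("memberships"), config$membership_format))
  links <- .stage("read links", read_links(p("links")))

  seed <- config$seed_group
  if (is.null(seed)) {
    seed <- .stage("resolve seed", {
      if (is.null(config$reference_fasta) || is.null(config$reference_map))
        .usage_error("seed resolution needs 'reference_fasta' and 'reference_map'")
      q <- read_fasta(config$query_fasta)
      if (length(q) != 1L) .usage_error("query FASTA must hold exactly one sequence")
      ref_seqs <- read_fasta(config$reference_fasta)
      map <- .read_two_col_tsv(config$reference_map)
      by_group <- split(ref_seqs[names(map)], unname(map))
      hit <- resolve_seed(q, build_reference(by_group))
      if (is.null(hit)) .domain_error("query could not be resolved to any group")
      message(sprintf("resolved query to %s (identity %.3f%s)", hit$group_id,
                      hit$identity, if (hit$low_confidence) ", low confidence" else ""))
      hit$group_id
    })
  }

  assignment <- .stage("taxonomy", {
    lineages <- lineages[lineages$taxon_id %in% species$taxon_id, , drop = FALSE]
    assign_clades(lineages, config$rank)
  })
  roster <- .stage("taxonomy", {
    r <- clade_roster(assignment)
    if (!is.null(config$core_list)) {
      core <- .read_data_lines(config$core_list)
      ids <- .parse_taxon_id(vapply(strsplit(core$text, "[ \t]"), `[`, "", 1L),
                             core$lineno, config$core_list)
      r <- lapply(r, intersect, ids)
      r <- r[lengths(r) > 0L]
    }
    r
  })

  net <- .stage("seed network", select_neighbors(links, seed, config$cutoff))
  columns <- network_columns(net, config$include_seed)

  wpm <- .stage("profile", {
    freq <- presence_frequency(memberships, roster, columns)
    x <- weight_matrix(binarize(freq, config$binarize_threshold), net,
                       config$include_seed)
    if (config$drop_empty) x <- drop_empty_rows(x)
    x
  })

  grid <- .stage("module grid",
                 build_grid(wpm, k_cog = config$k_cog, k_phylo = config$k_phylo,
                            metric = config$metric, linkage = config$linkage,
                            minkowski_p = config$minkowski_p))
  enr <- .stage("enrichment", module_enrichment(wpm, grid))
  desc <- if (!is.null(config$descriptions))
    .stage("annotation", .read_two_col_tsv(config$descriptions)) else NULL
  cells <- .stage("annotation", cell_annotation(wpm, desc))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(config$out_dir,
                     c(matrix = "matrix.tsv", cog_groups = "cog_groups.tsv",
                       phylo_groups = "phylo_groups.tsv",
                       enrichment = "enrichment.tsv", cells = "cells.tsv",
                       heatmap = "heatmap.svg", log = "run_log.txt"))
  names(files) <- c("matrix", "cog_groups", "phylo_groups", "enrichment",
                    "cells", "heatmap", "log")
  written <- character()
  tryCatch(.stage("write outputs", {
    mat_df <- data.frame(clade = rownames(wpm$values), wpm$values,
                         check.names = FALSE, stringsAsFactors = FALSE)
    .write_tsv(mat_df, files[["matrix"]]); written <- c(written, files[["matrix"]])

    cog_order <- grid$col_order
    cg <- data.frame(group_id = cog_order,
                     description = if (is.null(desc)) "" else
                       ifelse(is.na(desc[cog_order]), "", desc[cog_order]),
                     col_cluster = unname(grid$col_clusters[cog_order]),
                     stringsAsFactors = FALSE)
    .write_tsv(cg, files[["cog_groups"]]); written <- c(written, files[["cog_groups"]])

    pg <- data.frame(clade = grid$row_order,
                     row_cluster = unname(grid$row_clusters[grid$row_order]),
                     stringsAsFactors = FALSE)
    .write_tsv(pg, files[["phylo_groups"]]); written <- c(written, files[["phylo_groups"]])

    ed <- enr
    ed$groups <- vapply(ed$groups, paste, "", collapse = ";")
    ed$clades <- vapply(ed$clades, paste, "", collapse = ";")
    .write_tsv(ed, files[["enrichment"]]); written <- c(written, files[["enrichment"]])

    .write_tsv(cells, files[["cells"]]); written <- c(written, files[["cells"]])
    render_heatmap(wpm, grid, files[["heatmap"]])
    written <- c(written, files[["heatmap"]])

    writeLines(c(
      "run parameters and conventions",
      sprintf("seed_group\t%s", seed),
      sprintf("cutoff\t%d (boundary inclusive: score >= cutoff)", config$cutoff),
      sprintf("rank\t%s", config$rank),
      sprintf("binarize_threshold\t%g (boundary inclusive: frequency >= threshold)",
              config$binarize_threshold),
      sprintf("include_seed\t%s (seed column weight imputed at 1000)",
              config$include_seed),
      sprintf("metric\t%s", config$metric),
      sprintf("linkage\t%s (merge ties: lexicographically smallest pair)",
              config$linkage),
      sprintf("k_cog\t%d", config$k_cog),
      sprintf("k_phylo\t%d", config$k_phylo),
      sprintf("drop_empty\t%s", config$drop_empty),
      "cluster numbering\tby first appearance along dendrogram leaf order",
      "module address\t(COG cluster, phylogenetic cluster)",
      "enrichment upper tail\tinclusive, P[X >= h]",
      sprintf("organisms excluded as unassigned\t%d", length(assignment$unassigned)),
      sprintf("neighbors at cutoff\t%d", nrow(net$neighbors))),
      files[["log"]], useBytes = TRUE)
    written <- c(written, files[["log"]])
  }), error = function(e) { unlink(written); stop(e) })

  invisible(list(config = config, seed = seed, network = net, profile = wpm,
                 grid = grid, enrichment = enr, annotation = cells,
                 files = files))
}
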