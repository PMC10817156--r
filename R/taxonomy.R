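# Clade assignment from lineage records.
#
# Lineage dumps carry names without rank labels, so clades are extracted by a
# positional convention on lineages rooted at "cellular organisms":
# (root, superkingdom, phylum, class, ...), i.e. phylum = 3rd element and
# class = 4th. Organisms whose lineage is too short, or not rooted at
# "cellular organisms", are collected in `unassigned` rather than silently
# placed in a clade: a misassigned organism would corrupt the within-clade
# presence denominator downstream.

.default_rank_index <- c(phylum = 3L, class = 4L)

#' Assign organisms to clades at the phylum or class level
#'
#' @param lineages Data frame as returned by [read_lineages()].
#' @param rank \code{"phylum"} or \code{"class"}.
#' @param rank_index_map Optional named integer vector overriding the
#'   positional convention, e.g. \code{c(phylum = 3, class = 4)} (1-based
#'   position in the lineage vector).
#' @param overrides Optional data frame (\code{taxon_id}, \code{clade})
#'   forcing specific organisms into named clades regardless of lineage.
#' @return An object of class \code{clade_assignment}: list with \code{rank},
#'   \code{mapping} (named character vector, names are taxon ids) and
#'   \code{unassigned} (integer vector of taxon ids). Mapping and unassigned
#'   are disjoint.
#' @examples
#' lin <- data.frame(taxon_id = 562)
#' lin$lineage <- list(c("cellular organisms", "Bacteria",
#'                       "Proteobacteria", "Gammaproteobacteria"))
#' assign_clades(lin, "phylum")$mapping
#' @export
assign_clades <- function(lineages, rank = c("phylum", "class"),
                          rank_index_map = NULL, overrides = NULL) {
  if (length(rank) == 1L && !rank %in% c("phylum", "class"))
    .usage_error(sprintf("unknown rank '%s' (expected 'phylum' or 'class')", rank))
  rank <- match.arg(rank)
  idx_map <- rank_index_map %||% .default_rank_index
  if (is.null(idx_map[[rank]])) .usage_error(sprintf("rank_index_map lacks '%s'", rank))
  idx <- as.integer(idx_map[[rank]])

  clade <- vapply(lineages$lineage, function(l) {
    if (length(l) >= idx && identical(l[[1L]], "cellular organisms")) l[[idx]] else NA_character_
  }, character(1L))

  if (!is.null(overrides) && nrow(overrides) > 0L) {
    m <- match(lineages$taxon_id, overrides$taxon_id)
    clade[!is.na(m)] <- as.character(overrides$clade[m[!is.na(m)]])
  }
  if (any(!is.na(clade) & !nzchar(clade)))
    .validation_error("empty clade name in override table")

  assigned <- !is.na(clade)
  if (any(!assigned))
    message(sprintf("assign_clades: %d organism(s) without a resolvable %s excluded",
                    sum(!assigned), rank))
  structure(list(rank = rank,
                 mapping = stats::setNames(clade[assigned],
                                           lineages$taxon_id[assigned]),
                 unassigned = as.integer(lineages$taxon_id[!assigned])),
            class = "clade_assignment")
}

#' @export
print.clade_assignment <- function(x, ...) {
  cat(sprintf("<clade_assignment: rank=%s, %d organisms in %d clades, %d unassigned>\n",
              x$rank, length(x$mapping), length(unique(x$mapping)),
              length(x$unassigned)))
  invisible(x)
}

#' Roster of taxon ids per clade
#'
#' @param assignment A \code{clade_assignment}.
#' @return Named list mapping clade name to an integer vector of taxon ids.
#'   Rosters are pairwise disjoint and their union equals the mapped taxa.
#' @export
clade_roster <- function(assignment) {
  stopifnot(inherits(assignment, "clade_assignment"))
  if (length(assignment$mapping) == 0L) return(stats::setNames(list(), character()))
  taxa <- as.integer(names(assignment$mapping))
  split(taxa, assignment$mapping)
}

#' Read a clade-override table
#'
#' Two-column TSV: taxon id, clade name.
#' @param path Path to the TSV.
#' @return Data frame with columns \code{taxon_id}, \code{clade}.
#' @export
read_clade_overrides <- function(path) {
  ln <- .read_data_lines(path)
  if (length(ln$text) == 0L)
    return(data.frame(taxon_id = integer(), clade = character(),
                      stringsAsFactors = FALSE))
  fields <- lapply(ln$text, .split_fields)
  if (any(lengths(fields) < 2L))
    .parse_error(sprintf("%s: expected two columns (taxon_id, clade)", path))
  data.frame(taxon_id = .parse_taxon_id(vapply(fields, `[`, "", 1L), ln$lineno, path),
             clade = vapply(fields, function(f) paste(f[-1L], collapse = " "), ""),
             stringsAsFactors = FALSE)
}
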