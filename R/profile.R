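# Clade x COG profiling: per-clade presence frequencies of each group in the
# seed neighborhood, binarization at the 50% rule, and weighting of present
# cells by the seed-association score.
#
# The denominator of every frequency is the full clade roster (all organisms
# assigned to the clade), not just organisms bearing proteins in the network:
# absence is informative.

#' Per-clade presence frequencies of orthologous groups
#'
#' An organism possesses a group if it has at least one protein assigned to
#' it (paralogs count once). The frequency of a group in a clade is the
#' number of possessing organisms divided by the clade roster size.
#'
#' @param memberships Data frame as returned by [read_memberships()].
#' @param roster Named list mapping clade name to integer taxon ids, as
#'   returned by [clade_roster()].
#' @param columns Character vector of group ids defining the column universe
#'   (typically [network_columns()]). Groups with no memberships yield
#'   all-zero columns, which are retained.
#' @return An object of class \code{presence_matrix}: list with \code{freq}
#'   (numeric matrix, values in \[0, 1\]), \code{counts} (integer matrix of
#'   possessing-organism counts) and \code{roster_sizes} (named integer).
#' @export
presence_frequency <- function(memberships, roster, columns) {
  if (length(roster) == 0L) .usage_error("'roster' must not be empty")
  if (length(columns) == 0L) .usage_error("'columns' must not be empty")
  if (anyDuplicated(columns)) .usage_error("duplicate group ids in 'columns'")
  empty <- lengths(roster) == 0L
  if (any(empty)) {
    warning(sprintf("excluding %d clade(s) with empty roster: %s",
                    sum(empty), paste(names(roster)[empty], collapse = ", ")),
            call. = FALSE)
    roster <- roster[!empty]
    if (length(roster) == 0L) .domain_error("all clades have empty rosters")
  }
  clades <- names(roster)
  clade_of <- stats::setNames(rep(clades, lengths(roster)),
                              unlist(roster, use.names = FALSE))
  mem <- unique(memberships[memberships$group_id %in% columns,
                            c("taxon_id", "group_id")])
  cl <- clade_of[as.character(mem$taxon_id)]
  keep <- !is.na(cl)
  counts <- table(factor(cl[keep], levels = clades),
                  factor(mem$group_id[keep], levels = columns))
  counts <- matrix(as.integer(counts), nrow = length(clades),
                   dimnames = list(clades, columns))
  sizes <- stats::setNames(lengths(roster), clades)
  structure(list(freq = counts / sizes, counts = counts, roster_sizes = sizes),
            class = "presence_matrix")
}

#' Binarize a presence-frequency matrix
#'
#' A cell becomes 1 when its frequency is at least \code{threshold}
#' (inclusive boundary: a clade in which exactly half the organisms possess
#' the group is scored present), and 0 otherwise.
#'
#' @param freq A \code{presence_matrix}.
#' @param threshold Fraction in (0, 1]; default 0.5.
#' @return An object of class \code{binary_profile}: list with \code{values}
#'   (integer 0/1 matrix), plus \code{counts}, \code{roster_sizes} and
#'   \code{threshold} carried through for annotation.
#' @export
binarize <- function(freq, threshold = 0.5) {
  stopifnot(inherits(freq, "presence_matrix"))
  threshold <- .check_fraction(threshold, "threshold")
  values <- matrix(as.integer(freq$freq >= threshold), nrow = nrow(freq$freq),
                   dimnames = dimnames(freq$freq))
  structure(list(values = values, counts = freq$counts,
                 roster_sizes = freq$roster_sizes, threshold = threshold),
            class = "binary_profile")
}

#' Weight a binary profile by seed-association scores
#'
#' Each present cell takes the value of its column's seed-association score
#' (the seed's own column carries the imputed self-weight 1000); absent cells
#' stay 0.
#'
#' @param binary A \code{binary_profile}.
#' @param net The \code{seed_network} the columns were drawn from.
#' @param include_seed Must match the \code{include_seed} used to build the
#'   column universe.
#' @return An object of class \code{weighted_profile}: list with
#'   \code{values} (integer matrix), \code{column_weights} (named integer),
#'   \code{cutoff}, \code{seed}, plus \code{counts} and \code{roster_sizes}.
#' @export
weight_matrix <- function(binary, net, include_seed = TRUE) {
  stopifnot(inherits(binary, "binary_profile"), inherits(net, "seed_network"))
  w <- network_weights(net, include_seed)
  cols <- colnames(binary$values)
  missing <- setdiff(cols, names(w))
  if (length(missing))
    .consistency_error(sprintf("column(s) without a recorded seed-association weight: %s",
                               paste(missing, collapse = ", ")))
  values <- sweep(binary$values, 2L, w[cols], `*`)
  storage.mode(values) <- "integer"
  structure(list(values = values,
                 column_weights = w[cols],
                 cutoff = net$cutoff, seed = net$seed,
                 counts = binary$counts, roster_sizes = binary$roster_sizes),
            class = "weighted_profile")
}

#' @export
print.weighted_profile <- function(x, ...) {
  cat(sprintf("<weighted_profile: %d clades x %d groups, seed=%s, cutoff=%d, %d present cells>\n",
              nrow(x$values), ncol(x$values), x$seed, x$cutoff, sum(x$values > 0)))
  invisible(x)
}

#' Drop all-zero clade rows from a weighted profile
#'
#' @param x A \code{weighted_profile}.
#' @return The profile without rows whose cells are all zero.
#' @export
drop_empty_rows <- function(x) {
  stopifnot(inherits(x, "weighted_profile"))
  keep <- rowSums(x$values) > 0L
  if (all(keep)) return(x)
  message(sprintf("dropping %d all-zero clade row(s): %s", sum(!keep),
                  paste(rownames(x$values)[!keep], collapse = ", ")))
  x$values <- x$values[keep, , drop = FALSE]
  x$counts <- x$counts[keep, , drop = FALSE]
  x$roster_sizes <- x$roster_sizes[keep]
  x
}

#' Per-cell annotation table
#'
#' One record per heatmap cell carrying the four hover fields: the
#' phylogenetic group, the group id with its description, the count of
#' organisms possessing the group in that clade, and the cell's score.
#'
#' @param matrix A \code{weighted_profile} (cell counts are retained on it).
#' @param descriptions Optional named character vector mapping group id to a
#'   free-text description; missing descriptions render as the bare id and
#'   are reported via \code{message()}.
#' @return Data frame with columns \code{clade}, \code{cog},
#'   \code{organism_count}, \code{score}; one row per cell
#'   (rows x columns of the matrix).
#' @export
cell_annotation <- function(matrix, descriptions = NULL) {
  stopifnot(inherits(matrix, "weighted_profile"))
  clades <- rownames(matrix$values)
  groups <- colnames(matrix$values)
  desc <- stats::setNames(rep(NA_character_, length(groups)), groups)
  if (!is.null(descriptions)) {
    hit <- intersect(groups, names(descriptions))
    desc[hit] <- descriptions[hit]
  }
  if (anyNA(desc))
    message(sprintf("cell_annotation: no description for %d group(s)", sum(is.na(desc))))
  label <- ifelse(is.na(desc), groups, paste0(groups, ": ", desc))
  data.frame(clade = rep(clades, times = length(groups)),
             cog = rep(label, each = length(clades)),
             organism_count = as.vector(matrix$counts),
             score = as.vector(matrix$values),
             stringsAsFactors = FALSE)
}
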