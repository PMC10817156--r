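# Seed functional neighborhood: the orthologous groups whose direct
# association with the seed group meets the STRING score cutoff. These
# groups become the heatmap columns. Only seed-incident edges define
# membership; neighbor-neighbor edges in the association table are unused
# because every heatmap cell is weighted by the seed-to-column score.

.preset_cutoffs <- c(900L, 850L, 800L, 750L, 700L)

#' Select the seed group's functional neighborhood
#'
#' Returns every group whose association score with \code{seed} is at least
#' \code{cutoff} (the boundary is inclusive). Neighbors are ordered by
#' descending score, ties by ascending group id.
#'
#' @param links An \code{association_table}.
#' @param seed Seed group id.
#' @param cutoff Integer score threshold in \[0, 1000\]. The web presets are
#'   900, 850, 800, 750, 700; other values are accepted with a warning.
#' @return An object of class \code{seed_network}: list with \code{seed},
#'   \code{cutoff} and \code{neighbors} (data frame \code{group_id},
#'   \code{score}).
#' @export
select_neighbors <- function(links, seed, cutoff) {
  stopifnot(inherits(links, "association_table"))
  if (length(cutoff) != 1L || !is.numeric(cutoff) || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1000 || cutoff != floor(cutoff))
    .usage_error("'cutoff' must be an integer in [0, 1000]")
  cutoff <- as.integer(cutoff)
  if (!cutoff %in% .preset_cutoffs)
    warning(sprintf("cutoff %d is outside the preset ladder (%s)",
                    cutoff, paste(sort(.preset_cutoffs), collapse = ", ")),
            call. = FALSE)
  p <- links$pairs
  inc <- p$a == seed | p$b == seed
  if (!any(inc)) .domain_error(sprintf("seed '%s' has no recorded associations", seed))
  other <- ifelse(p$a[inc] == seed, p$b[inc], p$a[inc])
  score <- p$score[inc]
  keep <- score >= cutoff
  other <- other[keep]; score <- score[keep]
  ord <- order(-score, other)
  structure(list(seed = seed, cutoff = cutoff,
                 neighbors = data.frame(group_id = other[ord],
                                        score = as.integer(score[ord]),
                                        stringsAsFactors = FALSE)),
            class = "seed_network")
}

#' @export
print.seed_network <- function(x, ...) {
  cat(sprintf("<seed_network: seed=%s, cutoff=%d, %d neighbors>\n",
              x$seed, x$cutoff, nrow(x$neighbors)))
  invisible(x)
}

#' Heatmap column universe of a seed network
#'
#' @param net A \code{seed_network}.
#' @param include_seed If \code{TRUE} (default) the seed group is prepended
#'   as the first column.
#' @return Character vector of group ids in display order.
#' @export
network_columns <- function(net, include_seed = TRUE) {
  stopifnot(inherits(net, "seed_network"))
  if (include_seed) c(net$seed, net$neighbors$group_id) else net$neighbors$group_id
}

# Column weights: the seed-to-column association score. STRING stores no
# self-score, so the seed's own column is imputed at the scale maximum 1000,
# keeping it on the same color scale as its neighbors.
#' Seed-association weight per heatmap column
#'
#' @inheritParams network_columns
#' @return Named integer vector of column weights; the seed column (when
#'   included) carries the imputed self-weight 1000.
#' @export
network_weights <- function(net, include_seed = TRUE) {
  stopifnot(inherits(net, "seed_network"))
  w <- stats::setNames(net$neighbors$score, net$neighbors$group_id)
  if (include_seed) w <- c(stats::setNames(1000L, net$seed), w)
  w
}
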