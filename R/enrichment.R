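# Hypergeometric module enrichment. A heatmap cell is a "success" iff its
# weighted value is greater than 0. For each module the four parameters are:
#   N = total cells in the heatmap (clades x groups)
#   H = total cells with value > 0
#   n = cells in the module
#   h = cells with value > 0 in the module
# Both tails are always reported (the consumer picks over- or
# under-representation); the upper tail is inclusive, P[X >= h].

#' Hypergeometric tail probability
#'
#' Exact tail probabilities of the hypergeometric law with population
#' \code{N}, \code{H} successes and \code{n} draws, delegated to
#' \code{stats::phyper}/\code{dhyper} (which work on log scale internally).
#' The upper tail is inclusive: \code{P[X >= h]}.
#'
#' @param N Population size.
#' @param H Successes in the population.
#' @param n Draws (sample size).
#' @param h Observed successes in the sample.
#' @param tail \code{"upper"} (\code{P[X >= h]}), \code{"lower"}
#'   (\code{P[X <= h]}) or \code{"point"} (\code{P[X = h]}).
#' @return Probability in \[0, 1\].
#' @examples
#' hypergeom_tail(4, 2, 2, 2, "upper")  # 1/6
#' @export
hypergeom_tail <- function(N, H, n, h, tail = c("upper", "lower", "point")) {
  tail <- match.arg(tail)
  for (v in list(N = N, H = H, n = n, h = h))
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != floor(v))
      .domain_error("N, H, n, h must be single integers")
  if (H < 0 || H > N || n < 0 || n > N)
    .domain_error("require 0 <= H <= N and 0 <= n <= N")
  if (h < max(0, n + H - N) || h > min(n, H))
    .domain_error("h outside the hypergeometric support [max(0, n+H-N), min(n, H)]")
  switch(tail,
         upper = stats::phyper(h - 1, H, N - H, n, lower.tail = FALSE),
         lower = stats::phyper(h, H, N - H, n),
         point = stats::dhyper(h, H, N - H, n))
}

#' Module enrichment over a grid
#'
#' Scores every module of a grid for over- and under-representation of
#' present (value > 0) cells. The \code{e_over}/\code{e_under} columns are
#' Bonferroni-style expected counts: tail probability times the number of
#' modules, capped at the module count.
#'
#' @param matrix The \code{weighted_profile} the grid was built from.
#' @param grid A \code{module_grid} built from the same matrix.
#' @return Data frame with one row per module: \code{col_cluster},
#'   \code{row_cluster}, \code{N}, \code{H}, \code{n}, \code{h},
#'   \code{p_over}, \code{p_under}, \code{p_point}, \code{e_over},
#'   \code{e_under}, plus list columns \code{groups} and \code{clades}.
#' @export
module_enrichment <- function(matrix, grid) {
  stopifnot(inherits(grid, "module_grid"))
  m <- if (inherits(matrix, "weighted_profile")) matrix$values else as.matrix(matrix)
  if (!setequal(rownames(m), names(grid$row_clusters)) ||
      !setequal(colnames(m), names(grid$col_clusters)))
    .consistency_error("grid labels do not match matrix dimnames")
  N <- length(m)
  H <- sum(m > 0)
  k <- nrow(grid$modules)
  res <- grid$modules
  res$N <- N; res$H <- H
  res$n <- vapply(seq_len(k), function(i)
    length(res$groups[[i]]) * length(res$clades[[i]]), integer(1L))
  res$h <- vapply(seq_len(k), function(i)
    sum(m[res$clades[[i]], res$groups[[i]], drop = FALSE] > 0), integer(1L))
  res$p_over <- mapply(hypergeom_tail, N, H, res$n, res$h,
                       MoreArgs = list(tail = "upper"))
  res$p_under <- mapply(hypergeom_tail, N, H, res$n, res$h,
                        MoreArgs = list(tail = "lower"))
  res$p_point <- mapply(hypergeom_tail, N, H, res$n, res$h,
                        MoreArgs = list(tail = "point"))
  res$e_over <- pmin(res$p_over * k, k)
  res$e_under <- pmin(res$p_under * k, k)
  res[, c("col_cluster", "row_cluster", "N", "H", "n", "h",
          "p_over", "p_under", "p_point", "e_over", "e_under",
          "groups", "clades")]
}
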