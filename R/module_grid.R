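# Hierarchical biclustering of the weighted profile and the rectangular
# module grid read off the two dendrograms.
#
# Agglomeration is implemented via the Lance-Williams recurrence so that the
# tie-break rule is fully specified: when two candidate merges share the
# minimal distance, the pair with the lexicographically smallest
# (smaller position, larger position) wins, where a merged cluster inherits
# the smaller parent position. Heights for ward_d2 are computed on squared
# distances internally and reported back on the input-distance scale, as in
# the conventional Ward.D2 variant; ward_d, centroid and median apply the
# recurrence to the distances as given.

.linkages <- c("complete", "single", "average", "median", "ward_d", "ward_d2",
               "centroid")
.metrics <- c("euclidean", "manhattan", "minkowski", "maximum")

#' Pairwise distances between rows or columns of a weighted profile
#'
#' @param matrix A \code{weighted_profile} or plain numeric matrix.
#' @param axis \code{"rows"} (clades) or \code{"columns"} (groups).
#' @param metric One of \code{"euclidean"} (default), \code{"manhattan"},
#'   \code{"minkowski"}, \code{"maximum"}.
#' @param minkowski_p Exponent for the Minkowski metric (> 0); defaults to 3
#'   since p = 1, 2 and infinity are already named metrics.
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
pairwise_distances <- function(matrix, axis = c("rows", "columns"),
                               metric = .metrics, minkowski_p = 3) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  m <- if (inherits(matrix, "weighted_profile")) matrix$values else as.matrix(matrix)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2L)
    .domain_error(sprintf("need at least 2 items on the '%s' axis", axis))
  if (metric == "minkowski" &&
      (length(minkowski_p) != 1L || !is.numeric(minkowski_p) || minkowski_p <= 0))
    .usage_error("'minkowski_p' must be a positive real")
  d <- stats::dist(m, method = metric, p = minkowski_p)
  as.matrix(d)
}

# Lance-Williams coefficients for merging clusters i and j, seen from k.
.lw_coef <- function(linkage, ni, nj, nk) {
  switch(linkage,
    single   = c(0.5, 0.5, 0, -0.5),
    complete = c(0.5, 0.5, 0, 0.5),
    average  = c(ni / (ni + nj), nj / (ni + nj), 0, 0),
    median   = c(0.5, 0.5, -0.25, 0),
    centroid = c(ni / (ni + nj), nj / (ni + nj), -ni * nj / (ni + nj)^2, 0),
    ward_d   = ,
    ward_d2  = c((ni + nk) / (ni + nj + nk), (nj + nk) / (ni + nj + nk),
                 -nk / (ni + nj + nk), 0))
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering under the named Lance-Williams update,
#' with a deterministic tie-break (see the package vignette). The returned
#' object is an \code{hclust}-compatible dendrogram; within each merge row
#' the earlier-created subtree comes first (leaves before merges, smaller
#' leaf position first), which also defines the leaf display order.
#'
#' @param distances Symmetric distance matrix or \code{dist} object.
#' @param linkage One of \code{"complete"} (default), \code{"single"},
#'   \code{"average"}, \code{"median"}, \code{"ward_d"}, \code{"ward_d2"},
#'   \code{"centroid"}.
#' @return Object of classes \code{c("phylocog_dendrogram", "hclust")} with
#'   \code{merge}, \code{height}, \code{order}, \code{labels}.
#' @export
agglomerate <- function(distances, linkage = .linkages) {
  linkage <- match.arg(linkage)
  D <- as.matrix(distances)
  n <- nrow(D)
  if (n < 2L) .domain_error("need at least 2 items to cluster")
  if (!isTRUE(all.equal(D, t(D))) || any(diag(D) != 0) || any(D < 0))
    .usage_error("'distances' must be a symmetric non-negative zero-diagonal matrix")
  labels <- rownames(D) %||% as.character(seq_len(n))

  W <- if (linkage == "ward_d2") D^2 else D
  size <- rep(1L, n)
  code <- -seq_len(n)            # hclust codes: negative leaf, positive merge
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(W) <- Inf

  for (s in seq_len(n - 1L)) {
    act <- which(active)
    sub <- W[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    mn <- min(sub)
    hit <- which(sub == mn, arr.ind = TRUE)
    # lexicographically smallest (i, j): smallest row, then smallest column
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- act[hit[1L, 1L]]; j <- act[hit[1L, 2L]]

    height[s] <- if (linkage == "ward_d2") sqrt(mn) else mn
    # earlier-created subtree first: leaves (negative codes) precede merges,
    # two leaves ordered by position (i < j), two merges by step
    ci <- code[i]; cj <- code[j]
    merge[s, ] <- if (ci < 0 && cj >= 0) c(ci, cj)
                  else if (cj < 0 && ci >= 0) c(cj, ci)
                  else if (ci < 0) c(ci, cj)      # both leaves: i < j already
                  else sort(c(ci, cj))            # both merges: earlier first

    ks <- act[act != i & act != j]
    if (length(ks)) {
      co <- vapply(ks, function(k) {
        cf <- .lw_coef(linkage, size[i], size[j], size[k])
        cf[1L] * W[i, k] + cf[2L] * W[j, k] + cf[3L] * mn +
          cf[4L] * abs(W[i, k] - W[j, k])
      }, numeric(1L))
      W[i, ks] <- co; W[ks, i] <- co
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- s
  }

  order_leaves <- function(node)
    if (node < 0L) -node else c(order_leaves(merge[node, 1L]),
                                order_leaves(merge[node, 2L]))
  structure(list(merge = merge, height = height,
                 order = order_leaves(n - 1L), labels = labels,
                 method = linkage, call = match.call(),
                 dist.method = attr(distances, "method") %||% NA_character_),
            class = c("phylocog_dendrogram", "hclust"))
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last \code{k - 1} merges (equivalently, removes the
#' \code{k - 1} highest merges for monotone linkages) and numbers the
#' resulting clusters 1..k by order of first appearance along the dendrogram
#' leaf order, so cluster labels read left-to-right (columns) or
#' top-to-bottom (rows) on the rendered heatmap.
#'
#' @param dendrogram An object from [agglomerate()] (any \code{hclust} works).
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector of cluster labels (names are leaf labels).
#' @export
cut_dendrogram <- function(dendrogram, k) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$order)
  k <- .check_scalar_count(k, "k", min = 1L)
  if (k > n) .usage_error(sprintf("k = %d exceeds the number of leaves (%d)", k, n))
  comp <- seq_len(n)
  if (k < n) {
    members <- vector("list", n - 1L)
    for (s in seq_len(n - k)) {
      pick <- function(x) if (x < 0L) -x else members[[x]]
      members[[s]] <- c(pick(dendrogram$merge[s, 1L]),
                        pick(dendrogram$merge[s, 2L]))
      comp[members[[s]]] <- n + s
    }
  }
  # renumber by first appearance along the leaf order
  in_order <- comp[dendrogram$order]
  lev <- unique(in_order)
  labels <- dendrogram$labels %||% as.character(seq_len(n))
  stats::setNames(match(comp, lev), labels)
}

#' Bicluster a weighted profile into a module grid
#'
#' Rows (clades) and columns (groups) are clustered independently with the
#' same metric and linkage; each axis is cut into the requested number of
#' clusters, and every (column cluster c, row cluster r) intersection forms
#' a module addressed \code{(c, r)}.
#'
#' @param matrix A \code{weighted_profile} (or numeric matrix) with at least
#'   2 rows and 2 columns.
#' @param k_cog Number of column (COG) clusters; web presets are 2..6, other
#'   values are accepted with a warning.
#' @param k_phylo Number of row (phylogenetic) clusters; presets 3..5.
#' @param metric,minkowski_p Passed to [pairwise_distances()].
#' @param linkage Passed to [agglomerate()].
#' @return Object of class \code{module_grid}: row/column cluster labels,
#'   leaf orders, both dendrograms, and a \code{modules} data frame with one
#'   row per (c, r) address carrying the member group and clade sets.
#' @export
build_grid <- function(matrix, k_cog, k_phylo, metric = "euclidean",
                       linkage = "complete", minkowski_p = 3) {
  m <- if (inherits(matrix, "weighted_profile")) matrix$values else as.matrix(matrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    .domain_error("matrix must have at least 2 rows and 2 columns; widen the clade set or lower the cutoff")
  k_cog <- .check_scalar_count(k_cog, "k_cog", 1L)
  k_phylo <- .check_scalar_count(k_phylo, "k_phylo", 1L)
  if (!k_cog %in% 2:6)
    warning(sprintf("k_cog = %d is outside the preset range 2..6", k_cog), call. = FALSE)
  if (!k_phylo %in% 3:5)
    warning(sprintf("k_phylo = %d is outside the preset range 3..5", k_phylo), call. = FALSE)

  row_dend <- agglomerate(pairwise_distances(m, "rows", metric, minkowski_p), linkage)
  col_dend <- agglomerate(pairwise_distances(m, "columns", metric, minkowski_p), linkage)
  row_clusters <- cut_dendrogram(row_dend, k_phylo)
  col_clusters <- cut_dendrogram(col_dend, k_cog)

  modules <- expand.grid(col_cluster = seq_len(k_cog),
                         row_cluster = seq_len(k_phylo))
  modules$groups <- lapply(modules$col_cluster, function(c)
    names(col_clusters)[col_clusters == c])
  modules$clades <- lapply(modules$row_cluster, function(r)
    names(row_clusters)[row_clusters == r])

  structure(list(row_clusters = row_clusters, col_clusters = col_clusters,
                 row_order = row_dend$labels[row_dend$order],
                 col_order = col_dend$labels[col_dend$order],
                 row_dendrogram = row_dend, col_dendrogram = col_dend,
                 modules = modules, k_cog = k_cog, k_phylo = k_phylo,
                 params = list(metric = metric, linkage = linkage,
                               minkowski_p = minkowski_p)),
            class = "module_grid")
}

#' @export
print.module_grid <- function(x, ...) {
  cat(sprintf("<module_grid: %d x %d modules (%s/%s), %d clades x %d groups>\n",
              x$k_cog, x$k_phylo, x$params$metric, x$params$linkage,
              length(x$row_clusters), length(x$col_clusters)))
  invisible(x)
}

#' Export a dendrogram as Newick text
#'
#' Leaf names are the clade/group labels; branch lengths derive from the
#' merge heights.
#'
#' @param dendrogram An \code{hclust}-compatible object.
#' @param path Optional output file; if \code{NULL} the Newick string is
#'   returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  phy <- ape::as.phylo(dendrogram)
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
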