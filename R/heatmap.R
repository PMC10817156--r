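# Heatmap rendering. The renderer emits SVG text directly: one <rect
# class="cell"> per matrix cell, <line class="cluster-boundary"> marks at
# cluster boundaries, row/column labels, and a 0..1000 color-scale legend.
# Writing the SVG ourselves keeps the output diff-able and structurally
# checkable, which device-based renderers cannot guarantee.

#' Heatmap color and layout style
#'
#' The color scale runs from a light yellow at 0 through cherry red to black
#' at 1000: weak to strong functional association. Anchors are stylistic;
#' the mapping is strictly monotone in luminance (darker = higher).
#'
#' @param anchor_values Numeric anchor positions over \[0, 1000\]
#'   (equally spaced).
#' @param anchor_colors Colors at the anchors, light to dark.
#' @param cell_size Cell edge length in pixels.
#' @param boundary_color Color of the module boundary lines.
#' @param show_dendrograms Reserved display flag (leaf orders are always
#'   applied; tree glyphs are not drawn).
#' @return Object of class \code{heatmap_style}.
#' @export
heatmap_style <- function(anchor_values = c(0, 500, 1000),
                          anchor_colors = c("#FFFFCC", "#C40233", "#000000"),
                          cell_size = 18, boundary_color = "#1E90FF",
                          show_dendrograms = FALSE) {
  if (length(anchor_values) != length(anchor_colors) || length(anchor_values) < 2L)
    .usage_error("need matching anchor values and colors (>= 2)")
  if (is.unsorted(anchor_values, strictly = TRUE))
    .usage_error("anchor values must be strictly increasing")
  structure(list(anchor_values = anchor_values, anchor_colors = anchor_colors,
                 cell_size = cell_size, boundary_color = boundary_color,
                 show_dendrograms = show_dendrograms),
            class = "heatmap_style")
}

#' Map scores to heatmap colors
#'
#' @param values Numeric scores in \[0, 1000\].
#' @param style A \code{heatmap_style}.
#' @return Character vector of hex colors.
#' @export
score_color <- function(values, style = heatmap_style()) {
  ramp <- grDevices::colorRamp(style$anchor_colors)
  v <- pmin(pmax(values, min(style$anchor_values)), max(style$anchor_values))
  v <- (v - min(style$anchor_values)) / diff(range(style$anchor_values))
  rgb <- ramp(v)
  grDevices::rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L], maxColorValue = 255)
}

.svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.fmt <- function(x) sprintf("%.2f", x)

#' Render a clustered heatmap as SVG
#'
#' Rows and columns are displayed in dendrogram leaf order with boundary
#' lines at cluster breaks ((k_cog - 1) + (k_phylo - 1) marks) and a legend
#' reproducing the 0..1000 scale.
#'
#' @param matrix A \code{weighted_profile} (or numeric matrix).
#' @param grid The \code{module_grid} computed from the same matrix.
#' @param file Output path for the SVG.
#' @param style A \code{heatmap_style}.
#' @return The path, invisibly.
#' @export
render_heatmap <- function(matrix, grid, file, style = heatmap_style()) {
  stopifnot(inherits(grid, "module_grid"))
  m <- if (inherits(matrix, "weighted_profile")) matrix$values else as.matrix(matrix)
  if (nrow(m) == 0L || ncol(m) == 0L) .domain_error("cannot render a zero-area matrix")
  m <- m[grid$row_order, grid$col_order, drop = FALSE]
  counts <- if (inherits(matrix, "weighted_profile"))
    matrix$counts[grid$row_order, grid$col_order, drop = FALSE] else NULL

  cs <- style$cell_size
  left <- 110; top <- 80; legend_h <- 46
  w <- left + ncol(m) * cs + 20
  h <- top + nrow(m) * cs + legend_h + 30

  out <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">', ceiling(w), ceiling(h)),
           sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#FFFFFF"/>', ceiling(w), ceiling(h)))

  for (j in seq_len(ncol(m))) for (i in seq_len(nrow(m))) {
    title <- if (is.null(counts)) sprintf("%s | %s | score %s", rownames(m)[i], colnames(m)[j], as.character(m[i, j]))
             else sprintf("%s | %s | %d organisms | score %s",
                          rownames(m)[i], colnames(m)[j], counts[i, j], as.character(m[i, j]))
    out <- c(out, sprintf(
      '<rect class="cell" x="%s" y="%s" width="%s" height="%s" fill="%s"><title>%s</title></rect>',
      .fmt(left + (j - 1) * cs), .fmt(top + (i - 1) * cs), .fmt(cs), .fmt(cs),
      score_color(m[i, j], style), .svg_escape(title)))
  }

  # cluster boundaries: one line wherever adjacent leaves change cluster
  col_lab <- grid$col_clusters[grid$col_order]
  row_lab <- grid$row_clusters[grid$row_order]
  for (j in which(diff(col_lab) != 0))
    out <- c(out, sprintf(
      '<line class="cluster-boundary" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2"/>',
      .fmt(left + j * cs), .fmt(top), .fmt(left + j * cs),
      .fmt(top + nrow(m) * cs), style$boundary_color))
  for (i in which(diff(row_lab) != 0))
    out <- c(out, sprintf(
      '<line class="cluster-boundary" x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="2"/>',
      .fmt(left), .fmt(top + i * cs), .fmt(left + ncol(m) * cs),
      .fmt(top + i * cs), style$boundary_color))

  out <- c(out,
           vapply(seq_len(nrow(m)), function(i) sprintf(
             '<text class="row-label" x="%s" y="%s" font-size="9" text-anchor="end">%s</text>',
             .fmt(left - 4), .fmt(top + (i - 0.35) * cs),
             .svg_escape(rownames(m)[i])), ""),
           vapply(seq_len(ncol(m)), function(j) sprintf(
             '<text class="col-label" x="%s" y="%s" font-size="9" transform="rotate(-60 %s %s)">%s</text>',
             .fmt(left + (j - 0.5) * cs), .fmt(top - 6),
             .fmt(left + (j - 0.5) * cs), .fmt(top - 6),
             .svg_escape(colnames(m)[j])), ""))

  # legend: 0..1000 gradient strip plus tick labels
  ly <- top + nrow(m) * cs + 18
  steps <- 50L
  for (s in seq_len(steps)) {
    v <- (s - 1) / (steps - 1) * 1000
    out <- c(out, sprintf(
      '<rect class="legend-step" x="%s" y="%s" width="%s" height="12" fill="%s"/>',
      .fmt(left + (s - 1) * 4), .fmt(ly), .fmt(4), score_color(v, style)))
  }
  for (v in c(0, 500, 1000))
    out <- c(out, sprintf(
      '<text class="legend-tick" x="%s" y="%s" font-size="9" text-anchor="middle">%d</text>',
      .fmt(left + v / 1000 * (steps - 1) * 4 + 2), .fmt(ly + 24), v))
  out <- c(out, sprintf(
    '<text class="legend-title" x="%s" y="%s" font-size="10">association score</text>',
    .fmt(left + steps * 4 + 12), .fmt(ly + 11)), "</svg>")

  writeLines(out, file, useBytes = TRUE)
  invisible(file)
}
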