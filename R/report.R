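# Cross-sample normalization, transforms, clustering, and figure rendering.
# Rendering is a pure read of its inputs; files are written atomically.

asAbundanceMatrix <- function(table) {
  if (is(table, "PathwayAbundanceTable")) abundanceMatrix(table)
  else if (is.matrix(table)) table
  else stop("expected a PathwayAbundanceTable or a numeric matrix")
}

#' @rdname normalizeAcrossSamples
#' @aliases normalizeAcrossSamples,matrix-method
setMethod("normalizeAcrossSamples", "matrix", function(table) {
  rs <- rowSums(table)
  out <- table
  nz <- rs > 0
  out[nz, ] <- table[nz, , drop = FALSE] / rs[nz]
  out
})

#' @rdname normalizeAcrossSamples
#' @aliases normalizeAcrossSamples,PathwayAbundanceTable-method
setMethod("normalizeAcrossSamples", "PathwayAbundanceTable",
          function(table) normalizeAcrossSamples(abundanceMatrix(table)))

#' Bubble-plot abundance transform
#'
#' The transform used for bubble plots of pathway relative abundance:
#' multiply by 10^3 and take log10, i.e. `log10(1000 * x)` for `x > 0`.
#' Zeros are masked (returned as `NA`) rather than pseudo-counted, so
#' undetected pathways render as absent. Strictly increasing on `x > 0`.
#'
#' @param x non-negative abundance value(s).
#' @return Transformed values, `NA` where `x == 0`.
#' @examples
#' bubbleTransform(c(0.001, 1, 0))   # 0, 3, NA
#' @export
bubbleTransform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  out <- rep(NA_real_, length(x))
  pos <- !is.na(x) & x > 0
  out[pos] <- log10(1000 * x[pos])
  out
}

#' Hierarchically cluster samples by functional composition
#'
#' Agglomerative clustering of samples on the Bray–Curtis dissimilarity of
#' their pathway abundance vectors (community-ecology defaults; both metric
#' and linkage are configurable). Samples are ordered by id before the
#' distance computation, so the result is independent of input column
#' order, with ties broken by sample id.
#'
#' @param table a [PathwayAbundanceTable-class] or pathways x samples
#'   matrix with at least two samples.
#' @param method dissimilarity passed to [vegan::vegdist()] (default
#'   `"bray"`).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return List with elements `hclust` (the tree) and `order` (sample ids
#'   in dendrogram leaf order).
#' @export
clusterSamples <- function(table, method = "bray", linkage = "average") {
  m <- asAbundanceMatrix(table)
  if (ncol(m) < 2L) stop("clustering needs at least two samples")
  m <- m[, order(colnames(m)), drop = FALSE]
  d <- vegan::vegdist(t(m), method = method)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = colnames(m)[hc$order])
}

openDevice <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    svg = grDevices::svg(path, width = width, height = height),
    png = grDevices::png(path, width = width * 96, height = height * 96,
                         res = 96),
    stop("unsupported figure format '", ext, "' (use .svg or .png)"))
}

#' Render a pathway abundance heatmap
#'
#' Draws a pathways x samples heatmap (via \pkg{pheatmap}) to an SVG or
#' PNG file, chosen by the file extension. Rows/columns are clustered only
#' when there are at least two of each. The input table is not modified.
#'
#' @param table a [PathwayAbundanceTable-class] or numeric matrix.
#' @param path output file ending in `.svg` or `.png`.
#' @param ... passed through to [pheatmap::pheatmap()].
#' @return The path, invisibly.
#' @export
renderHeatmap <- function(table, path, ...) {
  m <- asAbundanceMatrix(table)
  stopifnot(nrow(m) >= 1L, ncol(m) >= 1L)
  extra <- list(...)
  if (is.null(extra$breaks) && length(unique(as.vector(m))) == 1L) {
    # constant matrices need explicit breaks or the colour cut degenerates
    v <- m[1, 1]
    extra$breaks <- seq(v - max(1, abs(v)), v + max(1, abs(v)),
                        length.out = 101)
  }
  p <- do.call(pheatmap::pheatmap,
               c(list(m, cluster_rows = nrow(m) > 1L,
                      cluster_cols = ncol(m) > 1L, silent = TRUE), extra))
  withAtomicFile(path, function(tmp) {
    tmp2 <- fixExt(tmp, path)
    openDevice(tmp2, width = max(5, 1 + 0.6 * ncol(m)),
               height = max(4, 1 + 0.25 * nrow(m)))
    grid::grid.newpage()
    grid::grid.draw(p$gtable)
    grDevices::dev.off()
    file.rename(tmp2, tmp)
  })
}

# devices sniff the file extension, so give the temp file the real one
fixExt <- function(tmp, path) {
  paste0(tmp, ".", tools::file_ext(path))
}

#' Render a cycle sketch (per-pathway, per-sample proportional markers)
#'
#' For every pathway of the selected biogeochemical cycle, draws one marker
#' per sample whose *area* scales linearly with the pathway's cross-sample
#' normalized fraction (see [normalizeAcrossSamples()]): a sample holding
#' twice the fraction gets a marker of twice the area. The marker geometry
#' is returned invisibly so the linear-area rule can be verified without
#' reading pixels.
#'
#' @param normalized matrix of within-pathway fractions from
#'   [normalizeAcrossSamples()].
#' @param cycle which cycle to draw (`"carbon"`, `"nitrogen"`, `"sulfur"`,
#'   `"DMSP"`, `"other"`).
#' @param path output file ending in `.svg` or `.png`.
#' @param definitions pathway definitions supplying the pathway-to-cycle
#'   mapping (default [builtinDefinitions()]).
#' @param maxRadius radius (in user units) of a marker holding fraction 1.
#' @return Invisibly, a data.frame with columns `pathway`, `sample`,
#'   `fraction`, `radius`, `area`.
#' @export
renderCycleSketch <- function(normalized, cycle, path,
                              definitions = builtinDefinitions(),
                              maxRadius = 0.4) {
  stopifnot(is.matrix(normalized))
  cyc <- vapply(definitions, function(d) d@cycle, character(1))
  ids <- vapply(definitions, pathwayId, character(1))
  keep <- intersect(ids[cyc == cycle], rownames(normalized))
  m <- normalized[keep, , drop = FALSE]
  geom <- if (nrow(m)) {
    g <- expand.grid(pathway = rownames(m), sample = colnames(m),
                     stringsAsFactors = FALSE)
    g$fraction <- m[cbind(g$pathway, g$sample)]
    # area = pi r^2 proportional to fraction
    g$radius <- maxRadius * sqrt(g$fraction)
    g$area <- pi * g$radius^2
    g
  } else {
    warning("no pathways of cycle '", cycle, "' in the table; ",
            "writing an empty figure")
    data.frame(pathway = character(), sample = character(),
               fraction = numeric(), radius = numeric(), area = numeric())
  }
  withAtomicFile(path, function(tmp) {
    tmp2 <- fixExt(tmp, path)
    openDevice(tmp2, width = max(4, 1.5 + 0.7 * ncol(m)),
               height = max(3, 1 + 0.5 * max(1L, nrow(m))))
    graphics::par(mar = c(4, 10, 2, 1))
    graphics::plot(NA, xlim = c(0.5, max(1L, ncol(m)) + 0.5),
                   ylim = c(0.5, max(1L, nrow(m)) + 0.5),
                   xlab = "", ylab = "", axes = FALSE, asp = 1,
                   main = paste(cycle, "cycle"))
    if (nrow(m)) {
      xi <- match(geom$sample, colnames(m))
      yi <- match(geom$pathway, rownames(m))
      pos <- geom$radius > 0
      if (any(pos))
        graphics::symbols(xi[pos], yi[pos], circles = geom$radius[pos],
                          inches = FALSE, add = TRUE, bg = "#4A90D9",
                          fg = "grey30")
      graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m),
                     las = 2, cex.axis = 0.8)
      graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m),
                     las = 1, cex.axis = 0.7, tick = FALSE)
    }
    grDevices::dev.off()
    file.rename(tmp2, tmp)
  })
  invisible(geom)
}
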