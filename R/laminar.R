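#' Soma-depth histogram per label source
#'
#' Groups soma depths into contiguous half-open bins `[i*w, (i+1)*w)` of
#' width `bin_width` micrometres from the pia, one count column per label
#' source.
#'
#' @param somas data.frame with columns `depth` (um from pia, >= 0) and
#'   `source` (label-source name).
#' @param bin_width bin width in micrometres (default 25).
#' @param max_depth optional profiled depth; default the deepest soma's bin.
#' @return object of class `depth_profile`: list with `counts` (bins x
#'   sources), `bin_edges` (length bins + 1) and `bin_width`.
#' @export
depth_histogram <- function(somas, bin_width = 25, max_depth = NULL) {
  stopifnot(all(c("depth", "source") %in% names(somas)))
  neg <- which(somas$depth < 0)
  if (length(neg)) stop("negative depth at record ", neg[1])
  if (is.null(max_depth)) max_depth <- max(somas$depth)
  n_bins <- max(1L, ceiling(max_depth / bin_width))
  bin <- pmin(floor(somas$depth / bin_width) + 1L, n_bins)
  sources <- unique(somas$source)
  counts <- vapply(sources, function(s)
    tabulate(bin[somas$source == s], nbins = n_bins), integer(n_bins))
  counts <- matrix(counts, nrow = n_bins,
                   dimnames = list(NULL, sources))
  structure(list(counts = counts,
                 bin_edges = bin_width * (0:n_bins),
                 bin_width = bin_width),
            class = "depth_profile")
}

#' Delineate cortical layers from a depth profile
#'
#' Bins are clustered (Euclidean distance, complete linkage, cut at `k`) on
#' their per-source composition, then layers are the maximal contiguous runs
#' of same-cluster bins, named in depth order. A cluster id recurring at
#' non-adjacent depths therefore yields multiple layers, which is how
#' sublayers (e.g. a superficial/middle/deep split of one cluster) arise.
#'
#' @param profile a [depth_histogram()] result.
#' @param k number of clusters to cut at.
#' @param normalize if TRUE (default) each source's counts are first scaled
#'   to proportions (so abundant sources do not dominate), then each bin's
#'   feature vector is normalized to the source composition at that bin
#'   (so bin-occupancy noise does not swamp the source identity signal).
#'   FALSE clusters raw counts.
#' @return object of class `layer_delineation`: data.frame `layers` (name,
#'   top um, bottom um, cluster) plus `bin_cluster` and `bin_layer` vectors.
#' @export
delineate_layers <- function(profile, k, normalize = TRUE) {
  counts <- profile$counts
  if (k > nrow(counts)) stop("k exceeds number of bins")
  feat <- counts
  if (normalize) {
    cs <- colSums(feat)
    cs[cs == 0] <- 1
    feat <- sweep(feat, 2, cs, "/")
    rs <- rowSums(feat)
    feat[rs > 0, ] <- feat[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  if (k == 1L) {
    cl <- rep(1L, nrow(counts))
  } else {
    hc <- hclust(dist(feat, method = "euclidean"), method = "complete")
    cl <- cutree(hc, k = k)
  }
  runs <- rle(cl)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  layers <- data.frame(
    name = sprintf("L%d", seq_along(runs$values)),
    top = profile$bin_edges[starts],
    bottom = profile$bin_edges[ends + 1L],
    cluster = runs$values,
    stringsAsFactors = FALSE
  )
  bin_layer <- rep(seq_along(runs$values), runs$lengths)
  structure(list(layers = layers, bin_cluster = cl, bin_layer = bin_layer,
                 bin_edges = profile$bin_edges,
                 bin_width = profile$bin_width),
            class = "layer_delineation")
}

#' Map depths to delineated layer names
#' @param delineation a [delineate_layers()] result.
#' @param depth numeric vector of depths (um).
#' @return character vector of layer names.
#' @export
layer_of_depth <- function(delineation, depth) {
  lay <- delineation$layers
  idx <- findInterval(depth, lay$top, rightmost.closed = FALSE)
  idx[depth >= max(lay$bottom)] <- nrow(lay)
  idx[idx < 1L] <- 1L
  lay$name[idx]
}

#' @export
print.layer_delineation <- function(x, ...) {
  cat("layer_delineation:", nrow(x$layers), "layers\n")
  print(x$layers, row.names = FALSE)
  invisible(x)
}
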