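#' Read an SWC morphology file
#'
#' Seven whitespace-separated columns (id, type, x, y, z, radius, parent),
#' '#' comments. The reconstruction must be a single tree: one root
#' (parent -1), no cycles, no node with more than two children off the
#' non-root nodes. Nodes listed before their parents are re-ordered.
#'
#' @param path file path.
#' @return object of class `neuron_morphology`: data.frame `nodes` plus
#'   `total_length` (um, over all parent-child segments).
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty SWC file: ", path)
  fields <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  if (ncol(fields) != 7) stop("SWC must have 7 columns: ", path)
  nodes <- data.frame(
    id = as.integer(fields[, 1]), type = as.integer(fields[, 2]),
    x = as.numeric(fields[, 3]), y = as.numeric(fields[, 4]),
    z = as.numeric(fields[, 5]), radius = as.numeric(fields[, 6]),
    parent = as.integer(fields[, 7])
  )
  neuron_morphology(nodes)
}

#' Validate an SWC node table as a morphology
#' @param nodes data.frame with id, type, x, y, z, radius, parent.
#' @return a `neuron_morphology`.
#' @export
neuron_morphology <- function(nodes) {
  if (anyDuplicated(nodes$id)) stop("duplicate SWC node id")
  roots <- which(nodes$parent == -1)
  if (length(roots) == 0) stop("no root node (breaks)")
  if (length(roots) > 1)
    stop("multiple roots (breaks): nodes ",
         paste(nodes$id[roots], collapse = ", "))
  self <- nodes$id == nodes$parent
  if (any(self)) stop("cycle: node is its own parent: ", nodes$id[self][1])
  unknown <- !(nodes$parent %in% c(-1L, nodes$id))
  if (any(unknown)) stop("parent id not found: ", nodes$parent[unknown][1])
  # cycle detection via parent walk
  idx_of <- setNames(seq_len(nrow(nodes)), nodes$id)
  for (i in seq_len(nrow(nodes))) {
    seen <- logical(nrow(nodes))
    j <- i
    while (nodes$parent[j] != -1L) {
      if (seen[j]) stop("cycle in SWC involving node ", nodes$id[j])
      seen[j] <- TRUE
      j <- idx_of[[as.character(nodes$parent[j])]]
    }
  }
  kids <- table(nodes$parent[nodes$parent != -1L])
  too_many <- names(kids)[kids > 2 &
                          names(kids) != as.character(nodes$id[roots])]
  if (length(too_many))
    stop("more than two branches from node ", too_many[1])
  # topological order: parents before children
  ord <- order(match(nodes$parent, nodes$id, nomatch = 0L))
  nodes <- nodes[ord, ]
  seg <- nodes$parent != -1L
  pidx <- match(nodes$parent[seg], nodes$id)
  seg_len <- sqrt((nodes$x[seg] - nodes$x[pidx])^2 +
                  (nodes$y[seg] - nodes$y[pidx])^2 +
                  (nodes$z[seg] - nodes$z[pidx])^2)
  structure(list(nodes = nodes, total_length = sum(seg_len)),
            class = "neuron_morphology")
}

#' Write a morphology to SWC
#' @param morph a `neuron_morphology` (or bare node data.frame).
#' @param path output path.
#' @export
write_swc <- function(morph, path) {
  nodes <- if (inherits(morph, "neuron_morphology")) morph$nodes else morph
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  writeLines(sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     nodes$id, nodes$type, nodes$x, nodes$y, nodes$z,
                     nodes$radius, nodes$parent), con)
  invisible(path)
}

#' Annotation volume
#'
#' A 3D grid of integer region codes with voxel size and origin in
#' micrometres; code 0 = outside the brain.
#'
#' @param data 3D integer array.
#' @param voxel_size scalar voxel edge, um.
#' @param origin length-3 coordinate of the corner of voxel (1,1,1), um.
#' @param region_ids named integer vector mapping region name -> code.
#' @return an `annotation_volume`.
#' @export
annotation_volume <- function(data, voxel_size, origin = c(0, 0, 0),
                              region_ids) {
  stopifnot(length(dim(data)) == 3, voxel_size > 0, length(origin) == 3)
  structure(list(data = data, voxel_size = voxel_size, origin = origin,
                 region_ids = region_ids),
            class = "annotation_volume")
}

#' Write / read an annotation volume as raw text + JSON header
#'
#' Plain-text serialization: a JSON header (dims, voxel size, origin, region
#' code map) and a whitespace-separated value file in column-major order.
#' @param volume an `annotation_volume`.
#' @param prefix path prefix; writes `<prefix>.json` and `<prefix>.txt`.
#' @export
write_annotation_volume <- function(volume, prefix) {
  hdr <- list(dims = dim(volume$data), voxel_size = volume$voxel_size,
              origin = volume$origin, region_ids = as.list(volume$region_ids))
  jsonlite::write_json(hdr, paste0(prefix, ".json"), auto_unbox = TRUE)
  writeLines(paste(as.vector(volume$data), collapse = " "),
             paste0(prefix, ".txt"))
  invisible(prefix)
}

#' @rdname write_annotation_volume
#' @param prefix path prefix used at write time.
#' @export
read_annotation_volume <- function(prefix) {
  hdr <- jsonlite::fromJSON(paste0(prefix, ".json"))
  vals <- scan(paste0(prefix, ".txt"), what = integer(), quiet = TRUE)
  annotation_volume(array(vals, dim = hdr$dims), hdr$voxel_size, hdr$origin,
                    unlist(hdr$region_ids))
}

# region code at coordinates (matrix n x 3); 0 outside the volume
.lookup_region <- function(volume, xyz) {
  idx <- sweep(xyz, 2, volume$origin, "-") / volume$voxel_size
  idx <- floor(idx) + 1
  dims <- dim(volume$data)
  inside <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
            idx[, 2] >= 1 & idx[, 2] <= dims[2] &
            idx[, 3] >= 1 & idx[, 3] <= dims[3]
  out <- integer(nrow(xyz))
  if (any(inside))
    out[inside] <- volume$data[cbind(idx[inside, 1], idx[inside, 2],
                                     idx[inside, 3])]
  out
}

#' Axon length per region from a morphology and annotation volume
#'
#' Each parent-child axon segment is subdivided into sub-segments of at most
#' `step` micrometres; each sub-segment's length is assigned to the region of
#' its midpoint voxel. Length falling outside the volume (or on code 0) goes
#' to the "unannotated" bucket.
#'
#' @param morph a `neuron_morphology`.
#' @param volume an `annotation_volume`.
#' @param step sub-segment length, um (default 1).
#' @param axon_types SWC type codes counted as axon (default 2; use
#'   `NULL` for all segments).
#' @return named numeric vector of lengths (um) per region name, plus
#'   "unannotated".
#' @export
axon_length_by_region <- function(morph, volume, step = 1, axon_types = 2L) {
  nodes <- morph$nodes
  seg <- which(nodes$parent != -1L)
  if (!is.null(axon_types)) seg <- seg[nodes$type[seg] %in% axon_types]
  code_len <- numeric(0)
  name_of <- setNames(names(volume$region_ids), volume$region_ids)
  acc <- setNames(numeric(length(volume$region_ids) + 1),
                  c(names(volume$region_ids), "unannotated"))
  pidx <- match(nodes$parent[seg], nodes$id)
  for (si in seq_along(seg)) {
    i <- seg[si]; p <- pidx[si]
    a <- c(nodes$x[p], nodes$y[p], nodes$z[p])
    b <- c(nodes$x[i], nodes$y[i], nodes$z[i])
    L <- sqrt(sum((b - a)^2))
    if (L == 0) next
    n_sub <- max(1L, ceiling(L / step))
    # midpoints of n_sub equal sub-segments
    t_mid <- (seq_len(n_sub) - 0.5) / n_sub
    mids <- cbind(a[1] + t_mid * (b[1] - a[1]),
                  a[2] + t_mid * (b[2] - a[2]),
                  a[3] + t_mid * (b[3] - a[3]))
    codes <- .lookup_region(volume, mids)
    sub_len <- L / n_sub
    tab <- table(codes)
    for (cd in names(tab)) {
      nm <- if (cd == "0") "unannotated" else name_of[[cd]]
      acc[nm] <- acc[nm] + sub_len * tab[[cd]]
    }
  }
  if (sum(acc) > 0 && acc["unannotated"] == sum(acc))
    warning("entire axon outside annotation volume")
  acc
}

#' Row-normalized single-cell fraction matrix
#'
#' Sums hemisphere columns of per-neuron per-region lengths (columns named
#' `<region>_ipsi` / `<region>_contra` are combined; already-combined columns
#' pass through), then divides by row totals. Zero-length neurons are
#' excluded with a warning.
#'
#' @param lengths matrix neurons x regions of axon lengths (um).
#' @param drop_unannotated drop an "unannotated" column before normalizing.
#' @return matrix of fractions, rows summing to 1.
#' @export
fraction_matrix <- function(lengths, drop_unannotated = TRUE) {
  m <- as.matrix(lengths)
  if (drop_unannotated && "unannotated" %in% colnames(m))
    m <- m[, colnames(m) != "unannotated", drop = FALSE]
  hemi <- grepl("_(ipsi|contra)$", colnames(m))
  if (any(hemi)) {
    base <- sub("_(ipsi|contra)$", "", colnames(m))
    merged <- vapply(unique(base), function(r)
      rowSums(m[, base == r, drop = FALSE]), numeric(nrow(m)))
    if (nrow(m) == 1L) merged <- t(merged)
    m <- matrix(merged, nrow = nrow(m),
                dimnames = list(rownames(m), unique(base)))
  }
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero)) {
    warning("excluding zero-length neuron(s): ",
            paste(rownames(m)[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
    tot <- tot[!zero]
  }
  m / tot
}
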