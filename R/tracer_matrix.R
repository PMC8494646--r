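#' Construct a connectivity matrix object
#'
#' Thin S3 wrapper around a numeric matrix of row-normalized connection
#' weights (fraction of total labelled signal), experiments/groups in rows,
#' bilateral targets in columns.
#'
#' @param values numeric matrix, rows normalized to 1 (or all-zero).
#' @param kind "output" or "input".
#' @param targets data.frame as returned by [bilateral_targets()].
#' @return a `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, kind = c("output", "input"), targets) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), ncol(values) == nrow(targets))
  if (any(values < 0, na.rm = TRUE)) stop("connectivity weights must be nonnegative")
  rs <- rowSums(values, na.rm = TRUE)
  bad <- which(rs > 0 & abs(rs - 1) > 1e-9)
  if (length(bad))
    stop("rows not normalized: ", paste(rownames(values)[bad], collapse = ", "))
  structure(values, kind = kind, targets = targets,
            class = c("connectivity_matrix", "matrix"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("connectivity_matrix (%s): %d x %d\n", attr(x, "kind"),
              nrow(x), ncol(x)))
  invisible(x)
}

.drop_injection <- function(labels, targets, injection_region) {
  # both hemispheres of the injected structure are excluded
  keep <- targets$region != injection_region
  keep
}

#' Output (anterograde) fraction-of-total connectivity matrix
#'
#' Weight = signal volume per target / total over all targets, excluding both
#' hemispheres of the injection structure, after applying the true-positive
#' mask. Experiments sharing a `group` label are averaged after per-experiment
#' normalization (the mean of member fraction rows).
#'
#' @param signal matrix experiments x bilateral targets of signal volumes.
#' @param ontology a `region_ontology` providing target order.
#' @param mask optional logical/0-1 matrix, same shape as `signal`; FALSE
#'   entries are zeroed before normalization (default all TRUE).
#' @param injection_region region id of the injection site (excluded).
#' @param group optional character vector (length nrow) of group labels;
#'   rows with the same label are averaged into one matrix row.
#' @return a `connectivity_matrix` of kind "output".
#' @export
output_fraction_matrix <- function(signal, ontology, mask = NULL,
                                   injection_region = NULL, group = NULL) {
  bt <- bilateral_targets(ontology)
  stopifnot(ncol(signal) == nrow(bt))
  if (is.null(colnames(signal))) colnames(signal) <- bt$label
  if (!is.null(mask)) {
    stopifnot(all(dim(mask) == dim(signal)))
    signal <- signal * (mask != 0)
  }
  keep <- if (is.null(injection_region)) rep(TRUE, nrow(bt))
          else .drop_injection(colnames(signal), bt, injection_region)
  vals <- matrix(0, nrow(signal), nrow(bt), dimnames = dimnames(signal))
  tot <- rowSums(signal[, keep, drop = FALSE])
  zero <- tot == 0
  if (any(zero))
    warning("all-zero row(s) after masking: ",
            paste(rownames(signal)[zero], collapse = ", "))
  vals[, keep] <- signal[, keep, drop = FALSE] / ifelse(tot == 0, 1, tot)
  if (!is.null(group)) {
    stopifnot(length(group) == nrow(vals))
    glev <- unique(group)
    gvals <- t(vapply(glev, function(g)
      colMeans(vals[group == g, , drop = FALSE]), numeric(ncol(vals))))
    rownames(gvals) <- glev
    # re-normalize group means of rows that included all-zero members
    rs <- rowSums(gvals)
    gvals[rs > 0, ] <- gvals[rs > 0, ] / rs[rs > 0]
    vals <- gvals
  }
  connectivity_matrix(vals, "output", bt)
}

#' Blank-brain false-positive calibration
#'
#' Per-region detection threshold = mean + k * sd over blank brains (sample,
#' n-1, standard deviation), default k = 6.
#'
#' @param blanks matrix blank brains x targets of background signal.
#' @param k SD multiplier (default 6).
#' @return object of class `blank_calibration` with `mean`, `sd`,
#'   `threshold` per region, `n_blanks` and `k`.
#' @export
blank_calibration <- function(blanks, k = 6) {
  if (nrow(blanks) < 2) stop("need at least 2 blank brains")
  m <- colMeans(blanks)
  s <- apply(blanks, 2, sd)
  structure(list(mean = m, sd = s, threshold = m + k * s,
                 n_blanks = nrow(blanks), k = k),
            class = "blank_calibration")
}

#' Input (retrograde) fraction-of-total connectivity matrix
#'
#' Entries below the blank-calibrated per-region threshold are zeroed, the
#' injection structure is excluded, then rows are normalized over the
#' surviving targets.
#'
#' @param signal matrix experiments x bilateral targets of signal volumes.
#' @param ontology a `region_ontology`.
#' @param calibration a [blank_calibration()] (or NULL for no thresholding).
#' @param injection_region region id of the injection site.
#' @param group optional group labels, averaged as in
#'   [output_fraction_matrix()].
#' @return a `connectivity_matrix` of kind "input".
#' @export
input_fraction_matrix <- function(signal, ontology, calibration = NULL,
                                  injection_region = NULL, group = NULL) {
  bt <- bilateral_targets(ontology)
  stopifnot(ncol(signal) == nrow(bt))
  if (is.null(colnames(signal))) colnames(signal) <- bt$label
  if (!is.null(calibration)) {
    thr <- calibration$threshold
    stopifnot(length(thr) == ncol(signal))
    signal <- signal * (sweep(signal, 2, thr, ">") * 1)
  }
  out <- output_fraction_matrix(signal, ontology,
                                injection_region = injection_region,
                                group = group)
  attr(out, "kind") <- "input"
  out
}

#' Summarize a connectivity matrix by major brain division
#'
#' Sums each row's fractions over the targets of each major division; also
#' reports the across-row average. Each summary row sums to 1 (within 1e-9)
#' unless the source row was all-zero.
#'
#' @param matrix a `connectivity_matrix`.
#' @param ontology a `region_ontology`.
#' @return matrix (rows + "average") x divisions of summed fractions.
#' @export
division_summary <- function(matrix, ontology) {
  bt <- attr(matrix, "targets")
  divs <- target_divisions(ontology)
  missing_div <- setdiff(bt$region, names(divs))
  if (length(missing_div))
    stop("target without division: ", missing_div[1])
  col_div <- divs[bt$region]
  present <- intersect(MAJOR_DIVISIONS, unique(col_div))
  out <- vapply(present, function(d)
    rowSums(matrix[, col_div == d, drop = FALSE]), numeric(nrow(matrix)))
  if (nrow(matrix) == 1L) {           # vapply drops to vector
    out <- t(out)
    rownames(out) <- rownames(matrix)
  }
  out <- rbind(out, average = colMeans(out))
  out
}

#' Pairwise injection-site distance statistics
#'
#' Euclidean 3D distances over all unordered experiment pairs; reports mean
#' and sample standard deviation in the coordinate units (micrometres).
#'
#' @param injections data.frame with columns `experiment`, `x`, `y`, `z`;
#'   rows with missing coordinates are excluded with a warning.
#' @return list with `mean`, `sd`, `pairs` (data.frame a, b, distance).
#' @export
injection_distances <- function(injections) {
  ok <- complete.cases(injections[, c("x", "y", "z")])
  if (!all(ok)) {
    warning("excluding experiments with missing coordinates: ",
            paste(injections$experiment[!ok], collapse = ", "))
    injections <- injections[ok, , drop = FALSE]
  }
  if (nrow(injections) < 2) stop("need at least 2 experiments with coordinates")
  d <- dist(as.matrix(injections[, c("x", "y", "z")]))
  idx <- combn(nrow(injections), 2)
  pairs <- data.frame(a = injections$experiment[idx[1, ]],
                      b = injections$experiment[idx[2, ]],
                      distance = as.vector(d), stringsAsFactors = FALSE)
  list(mean = mean(pairs$distance),
       sd = if (nrow(pairs) > 1) sd(pairs$distance) else 0,
       pairs = pairs)
}

#' In-degree: nonzero targets per matrix row
#'
#' Count of strictly positive entries per row of a thresholded connectivity
#' matrix; with a grouping vector also returns group means.
#'
#' @param matrix a `connectivity_matrix` (or plain matrix).
#' @param group optional labels partitioning rows.
#' @return named integer vector, or list(`per_row`, `group_means`) when
#'   `group` is given.
#' @export
in_degree <- function(matrix, group = NULL) {
  deg <- rowSums(matrix > 0)
  if (is.null(group)) return(deg)
  list(per_row = deg,
       group_means = tapply(deg, group, mean))
}
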