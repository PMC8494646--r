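#' Spearman distance between matrix rows
#'
#' Distance = 1 - Spearman rank correlation, with average ranks for ties.
#' Missing values (e.g. masked reciprocal regions in transsynaptic rows) are
#' handled pairwise-complete: each pair is correlated over its mutually
#' observed targets.
#'
#' @param x numeric matrix (rows = samples).
#' @return a `dist` object.
#' @export
spearman_distance <- function(x) {
  const <- apply(x, 1, function(r) {
    r <- r[!is.na(r)]
    length(unique(r)) < 2
  })
  if (any(const))
    stop("constant row (Spearman undefined): ",
         paste(rownames(x)[const], collapse = ", "))
  rho <- cor(t(x), method = "spearman", use = "pairwise.complete.obs")
  as.dist(1 - rho)
}

#' Hierarchical clustering of connectivity rows
#'
#' Agglomerative clustering with Spearman rank-correlation distance and
#' complete linkage, cut at `k` clusters. Cluster labels are renumbered
#' 1..k in order of first appearance down the row order.
#'
#' @param matrix numeric matrix or `connectivity_matrix`.
#' @param k number of clusters.
#' @param exclude optional row names to drop before clustering (e.g.
#'   transsynaptic rows with many masked regions).
#' @return list with `hclust` (the dendrogram), `assignment` (named integer
#'   vector) and `k`.
#' @export
spearman_complete_cluster <- function(matrix, k, exclude = NULL) {
  x <- unclass(matrix)
  if (!is.null(exclude)) x <- x[setdiff(rownames(x), exclude), , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 rows")
  if (k > nrow(x)) stop("k exceeds number of rows")
  hc <- hclust(spearman_distance(x), method = "complete")
  raw <- cutree(hc, k = k)
  relab <- match(raw, unique(raw))
  assignment <- setNames(relab, names(raw))
  list(hclust = hc, assignment = assignment, k = k)
}

#' Export a dendrogram as Newick text
#' @param hc an `hclust` object.
#' @return single Newick string (with branch lengths from merge heights).
#' @export
hclust_to_newick <- function(hc) {
  n <- length(hc$labels)
  node_h <- c(rep(0, n), hc$height)
  build <- function(i) {
    if (i < 0) return(list(str = hc$labels[-i], h = 0))
    a <- build(hc$merge[i, 1]); b <- build(hc$merge[i, 2])
    h <- hc$height[i]
    list(str = sprintf("(%s:%g,%s:%g)", a$str, h - a$h, b$str, h - b$h), h = h)
  }
  paste0(build(nrow(hc$merge))$str, ";")
}

#' Layer enrichment of clusters (Fisher's exact test)
#'
#' For every (cluster, layer) pair, a 2x2 table of membership in/out of the
#' cluster versus in/out of the layer, tested with the two-sided exact test.
#'
#' @param assignment named cluster labels per row.
#' @param layer_of_row named layer labels per row (same names).
#' @return data.frame cluster, layer, counts and two-sided `p`.
#' @export
layer_enrichment <- function(assignment, layer_of_row) {
  stopifnot(all(names(assignment) %in% names(layer_of_row)))
  layer_of_row <- layer_of_row[names(assignment)]
  out <- expand.grid(cluster = unique(assignment),
                     layer = unique(layer_of_row),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(out)), function(i) {
    inc <- assignment == out$cluster[i]
    inl <- layer_of_row == out$layer[i]
    tab <- matrix(c(sum(inc & inl), sum(inc & !inl),
                    sum(!inc & inl), sum(!inc & !inl)), 2, 2)
    c(in_cluster_in_layer = tab[1, 1], in_cluster = sum(inc),
      in_layer = sum(inl), p = fisher.test(tab)$p.value)
  })
  cbind(out, do.call(rbind, res))
}

#' Mean within-cluster pairwise Spearman correlation
#'
#' @param matrix numeric matrix or `connectivity_matrix`.
#' @param assignment named cluster labels for rows of `matrix`.
#' @return named numeric vector per cluster; NA for singleton clusters.
#' @export
within_cluster_similarity <- function(matrix, assignment) {
  x <- unclass(matrix)
  vapply(sort(unique(assignment)), function(cl) {
    rows <- names(assignment)[assignment == cl]
    if (length(rows) < 2) return(NA_real_)
    rho <- cor(t(x[rows, , drop = FALSE]), method = "spearman",
               use = "pairwise.complete.obs")
    mean(rho[lower.tri(rho)])
  }, numeric(1))
}

#' Cluster contrast statistics
#'
#' (a) One-way ANOVA with Tukey HSD on per-row nonzero-target counts across
#' clusters; (b) two-way repeated-measures ANOVA (between factor: cluster;
#' within factor: target area) on the fraction values, reporting the
#' cluster x target interaction.
#'
#' @param matrix numeric matrix or `connectivity_matrix`.
#' @param assignment named cluster labels per row.
#' @return list with `indegree_anova` (F, p, tukey table) and
#'   `interaction_anova` (F, p) — entries are NA when not testable.
#' @export
cluster_contrasts <- function(matrix, assignment) {
  x <- unclass(matrix)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("t%d", seq_len(ncol(x)))
  if (is.null(names(assignment))) names(assignment) <- rownames(x)
  x <- x[names(assignment), , drop = FALSE]
  cl <- factor(assignment)
  sizes <- table(cl)
  if (sum(sizes >= 2) < 2) stop("need >= 2 clusters with >= 2 members")

  deg <- rowSums(x > 0)
  one <- tryCatch({
    if (var(deg) == 0) list(F = 0, p = 1, tukey = NULL)
    else {
      fit <- aov(deg ~ cl)
      s <- summary(fit)[[1]]
      list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
           tukey = TukeyHSD(fit)$cl)
    }
  }, error = function(e) list(F = NA_real_, p = NA_real_, tukey = NULL))

  long <- data.frame(
    value = as.vector(x),
    row = factor(rep(rownames(x), times = ncol(x))),
    target = factor(rep(colnames(x), each = nrow(x))),
    cluster = factor(rep(as.character(assignment), times = ncol(x)))
  )
  two <- tryCatch({
    fit <- aov(value ~ cluster * target + Error(row), data = long)
    within <- summary(fit)[["Error: Within"]][[1]]
    irow <- grep("cluster:target", rownames(within))
    list(F = within[["F value"]][irow], p = within[["Pr(>F)"]][irow])
  }, error = function(e) list(F = NA_real_, p = NA_real_))

  list(indegree_anova = one, interaction_anova = two)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert–Arabie adjustment; 1 for identical partitions, ~0 for independent
#' ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
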