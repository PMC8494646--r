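#' Normalize barcode counts by spike-ins and across brains
#'
#' Step 1: divide each neuron's counts by its spike-in count. Step 2: per
#' projection area, rescale each brain so that the mean over neurons with
#' nonzero counts in that area is equal across brains (anchored to the first
#' brain's mean). Areas with no nonzero neurons in some brain keep factor 1
#' (with a warning). A log copy `log1p(values)` is attached.
#'
#' @param counts integer matrix neurons x areas.
#' @param spikein per-neuron spike-in counts (named or positional).
#' @param brain per-neuron brain ids.
#' @return list with `values`, `log_values`, `binary` (count >= 1), `brain`,
#'   and `dropped` (neurons removed for zero spike-in).
#' @export
normalize_barcodes <- function(counts, spikein, brain) {
  stopifnot(nrow(counts) == length(spikein), nrow(counts) == length(brain))
  drop <- spikein <= 0
  if (any(drop)) {
    warning("dropping ", sum(drop), " neuron(s) with zero spike-in")
    counts <- counts[!drop, , drop = FALSE]
    brain <- brain[!drop]
    spikein <- spikein[!drop]
  }
  vals <- counts / spikein
  brains <- unique(brain)
  if (length(brains) > 1) {
    for (a in seq_len(ncol(vals))) {
      nz <- counts[, a] > 0
      means <- vapply(brains, function(b) {
        sel <- nz & brain == b
        if (any(sel)) mean(vals[sel, a]) else NA_real_
      }, numeric(1))
      if (any(is.na(means))) {
        warning("area ", colnames(vals)[a],
                ": no nonzero neurons in some brain; factor 1 used")
        means[is.na(means)] <- means[which(!is.na(means))[1]]
      }
      ref <- means[1]
      for (bi in seq_along(brains)) {
        f <- if (means[bi] > 0) ref / means[bi] else 1
        vals[brain == brains[bi], a] <- vals[brain == brains[bi], a] * f
      }
    }
  }
  list(values = vals, log_values = log1p(vals), binary = counts >= 1,
       brain = brain, dropped = rownames(counts)[drop])
}

# k-means++ seeding followed by Lloyd iterations, fixed RNG stream
.kmeanspp <- function(x, k, nstart = 10) {
  best <- NULL
  for (s in seq_len(nstart)) {
    cent <- x[sample.int(nrow(x), 1), , drop = FALSE]
    while (nrow(cent) < k) {
      d2 <- apply(x, 1, function(r) min(colSums((t(cent) - r)^2)))
      if (all(d2 == 0)) {
        cent <- rbind(cent, x[sample.int(nrow(x), 1), , drop = FALSE])
      } else {
        cent <- rbind(cent, x[sample.int(nrow(x), 1, prob = d2), , drop = FALSE])
      }
    }
    fit <- tryCatch(kmeans(x, centers = cent, iter.max = 50),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  best
}

#' Major-class clustering by bisecting k-means
#'
#' Divisive ("hierarchical k-means") clustering of log-transformed projection
#' strengths: starting from one cluster, the cluster with the largest total
#' within-ss is repeatedly bisected with (k-means++, 10 restarts) until
#' `n_classes` clusters exist. Classes are annotated post hoc from mean
#' projection strengths: highest mean in medulla/pons areas = "L5 ET"; of the
#' rest, highest thalamus = "CT"; remaining IT clusters split by striatal
#' mean into "IT Str+" / "IT Str-".
#'
#' @param norm a [normalize_barcodes()] result.
#' @param n_classes number of leaf clusters (default 4).
#' @param area_groups named list of area-name vectors for annotation, with
#'   entries `thalamus`, `striatum`, `medulla_pons`. If NULL, labels are
#'   "class1".."classK".
#' @param seed RNG seed for the k-means restarts.
#' @return list with `labels` (named character vector) and `centroids`.
#' @export
major_class_clustering <- function(norm, n_classes = 4, area_groups = NULL,
                                   seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  x <- norm$log_values
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647L)
  cl <- rep(1L, nrow(x))
  wss <- function(idx) {
    xs <- x[idx, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }
  while (length(unique(cl)) < n_classes) {
    sizes <- tapply(seq_along(cl), cl, length)
    cand <- as.integer(names(sizes)[sizes >= 2])
    scores <- vapply(cand, function(g) wss(which(cl == g)), numeric(1))
    target <- cand[which.max(scores)]
    idx <- which(cl == target)
    fit <- .kmeanspp(x[idx, , drop = FALSE], 2)
    if (is.null(fit)) break
    newid <- max(cl) + 1L
    cl[idx[fit$cluster == 2]] <- newid
  }
  cl <- match(cl, unique(cl))
  cent <- t(vapply(seq_len(max(cl)), function(g)
    colMeans(norm$values[cl == g, , drop = FALSE]), numeric(ncol(x))))
  colnames(cent) <- colnames(x)
  labels <- sprintf("class%d", cl)
  if (!is.null(area_groups)) {
    gmean <- function(g, areas) rowMeans(cent[, areas, drop = FALSE])[g]
    ann <- character(max(cl))
    remaining <- seq_len(max(cl))
    et <- remaining[which.max(vapply(remaining, gmean,
                                     numeric(1), area_groups$medulla_pons))]
    ann[et] <- "L5 ET"; remaining <- setdiff(remaining, et)
    ct <- remaining[which.max(vapply(remaining, gmean,
                                     numeric(1), area_groups$thalamus))]
    ann[ct] <- "CT"; remaining <- setdiff(remaining, ct)
    strm <- vapply(remaining, gmean, numeric(1), area_groups$striatum)
    ord <- remaining[order(strm, decreasing = TRUE)]
    half <- ceiling(length(ord) / 2)
    ann[ord[seq_len(half)]] <- "IT Str+"
    ann[setdiff(ord, ord[seq_len(half)])] <- "IT Str-"
    labels <- ann[cl]
  }
  names(labels) <- rownames(x)
  rownames(cent) <- vapply(seq_len(max(cl)), function(g)
    labels[which(cl == g)[1]], character(1))
  list(labels = labels, cluster = cl, centroids = cent)
}

# Shannon entropy (bits) of a count vector
.entropy_bits <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

# Candidate binary patterns over subsets of <= max_areas areas.
# Returns list(membership = logical matrix candidates x neurons, info df).
.split_candidates <- function(binary, max_areas) {
  n_areas <- ncol(binary)
  memb <- list(); info <- list(); ci <- 0L
  for (s in seq_len(min(max_areas, n_areas))) {
    subsets <- combn(n_areas, s)
    for (j in seq_len(ncol(subsets))) {
      areas <- subsets[, j]
      for (bits in 0:(2^s - 1)) {
        want <- as.logical(bitwAnd(bits, 2^(seq_len(s) - 1)))
        m <- rep(TRUE, nrow(binary))
        for (t in seq_len(s))
          m <- m & (binary[, areas[t]] == want[t])
        ci <- ci + 1L
        memb[[ci]] <- m
        info[[ci]] <- list(areas = areas, pattern = want)
      }
    }
  }
  list(membership = do.call(rbind, memb), info = info)
}

# max-dH over all candidates for a given bin one-hot matrix Z (neurons x bins)
.max_entropy_reduction <- function(membM, Z) {
  n <- nrow(Z)
  tot_counts <- colSums(Z)
  H0 <- .entropy_bits(tot_counts)
  c1 <- membM %*% Z                       # candidates x bins
  n1 <- rowSums(c1)
  c0 <- sweep(-c1, 2, tot_counts, "+")
  n0 <- n - n1
  ent <- function(cm, nn) {
    p <- cm / ifelse(nn == 0, 1, nn)
    pl <- ifelse(p > 0, p * log2(p), 0)
    -rowSums(pl)
  }
  dH <- H0 - (n1 * ent(c1, n1) + n0 * ent(c0, n0)) / n
  dH[n1 == 0 | n0 == 0] <- -Inf           # degenerate splits excluded
  dH
}

#' Entropy-reduction recursive binary partitioning
#'
#' At each node, all presence/absence patterns over subsets of at most
#' `max_areas` projection areas are enumerated; each candidate splits the
#' node's neurons into matching/non-matching children. The candidate
#' maximizing the reduction in Shannon entropy (bits) of the laminar depth
#' distribution (over `bin_width`-um bins) is accepted if its permutation
#' p-value is below `alpha`; the null re-maximizes the entropy reduction over
#' all candidates for each of `n_perm` shuffles of depths within the node
#' (max-T construction, which keeps the family-wise type-I rate at alpha
#' despite the exhaustive search). Accepted splits recurse on both children.
#'
#' @param binary logical/0-1 matrix neurons x areas (projection present).
#' @param depths per-neuron soma depths (um).
#' @param max_areas maximum areas per split pattern (default 3).
#' @param alpha significance level (default 0.05, uncorrected across nodes).
#' @param n_perm permutations per node (default 1000).
#' @param min_node minimum node size to attempt a split (default 20).
#' @param bin_width laminar bin width um (default 25).
#' @param seed RNG seed for the permutations.
#' @return object of class `subgroup_tree`: list with recursive `root` node
#'   (fields: neurons, and for internal nodes areas/pattern/delta_h/p_value/
#'   match/nomatch children) and `leaves` (list of neuron-index vectors).
#' @export
entropy_split <- function(binary, depths, max_areas = 3, alpha = 0.05,
                          n_perm = 1000, min_node = 20, bin_width = 25,
                          seed = 1L) {
  binary <- binary != 0
  stopifnot(nrow(binary) == length(depths))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647L)
  n_bins <- max(1L, ceiling((max(depths) + 1e-9) / bin_width))
  bin <- pmin(floor(depths / bin_width) + 1L, n_bins)

  split_node <- function(idx) {
    node <- list(neurons = idx)
    if (length(idx) < min_node) return(node)
    Z <- matrix(0L, length(idx), n_bins)
    Z[cbind(seq_along(idx), bin[idx])] <- 1L
    if (sum(colSums(Z) > 0) < 2) return(node)     # zero entropy, no split
    cand <- .split_candidates(binary[idx, , drop = FALSE], max_areas)
    dH <- .max_entropy_reduction(cand$membership, Z)
    best <- which.max(dH)
    if (!is.finite(dH[best]) || dH[best] <= 0) return(node)
    # permutation null: re-maximize over candidates per shuffle
    exceed <- 0L
    for (p in seq_len(n_perm)) {
      Zp <- Z[sample.int(nrow(Z)), , drop = FALSE]
      if (max(.max_entropy_reduction(cand$membership, Zp)) >= dH[best])
        exceed <- exceed + 1L
    }
    pval <- (exceed + 1) / (n_perm + 1)
    if (pval >= alpha) return(node)
    m <- cand$membership[best, ]
    node$areas <- colnames(binary)[cand$info[[best]]$areas]
    node$pattern <- cand$info[[best]]$pattern
    node$delta_h <- dH[best]
    node$p_value <- pval
    node$match <- split_node(idx[m])
    node$nomatch <- split_node(idx[!m])
    node
  }
  root <- split_node(seq_len(nrow(binary)))
  leaves <- list()
  walk <- function(node) {
    if (is.null(node$match)) leaves[[length(leaves) + 1L]] <<- node$neurons
    else { walk(node$match); walk(node$nomatch) }
  }
  walk(root)
  structure(list(root = root, leaves = leaves, n = nrow(binary),
                 bin_width = bin_width),
            class = "subgroup_tree")
}

#' Leaf labels of a subgroup tree
#' @param tree a `subgroup_tree`.
#' @return integer vector of leaf ids per neuron.
#' @export
subgroup_labels <- function(tree) {
  lab <- integer(tree$n)
  for (i in seq_along(tree$leaves)) lab[tree$leaves[[i]]] <- i
  lab
}

#' Merge entropy-split leaves with similar laminar distributions
#'
#' Builds candidate merges among current groups sharing a major class,
#' ordered by Euclidean distance between group mean projection vectors
#' (closest first). A pair merges iff the rank-sum test on their depths is
#' non-significant after Bonferroni correction over the candidates examined
#' in the pass AND their median depths differ by at most `median_window` um.
#' Passes repeat until no merge applies. Merging never crosses major classes.
#'
#' @param labels integer/character subgroup label per neuron.
#' @param values numeric matrix neurons x areas (projection strengths used
#'   for the merge ordering).
#' @param depths per-neuron soma depths (um).
#' @param major_class per-neuron major class labels (merging stops at this
#'   level); default a single class.
#' @param alpha significance level (default 0.05).
#' @param median_window maximum allowed median depth difference, um
#'   (default 200).
#' @param bonferroni "pass" (denominator = candidates in current pass,
#'   default) or "global" (all candidate tests so far).
#' @return named integer vector: merged group id per neuron.
#' @export
merge_by_laminae <- function(labels, values, depths,
                             major_class = rep("all", length(labels)),
                             alpha = 0.05, median_window = 200,
                             bonferroni = c("pass", "global")) {
  bonferroni <- match.arg(bonferroni)
  stopifnot(length(labels) == nrow(values), length(labels) == length(depths))
  group <- as.integer(factor(labels))
  tests_total <- 0L
  repeat {
    ids <- sort(unique(group))
    if (length(ids) < 2) break
    gclass <- vapply(ids, function(g)
      major_class[which(group == g)[1]], character(1))
    cent <- t(vapply(ids, function(g)
      colMeans(values[group == g, , drop = FALSE]), numeric(ncol(values))))
    cand <- which(outer(gclass, gclass, "==") & upper.tri(diag(length(ids))),
                  arr.ind = TRUE)
    if (!nrow(cand)) break
    d <- sqrt(rowSums((cent[cand[, 1], , drop = FALSE] -
                       cent[cand[, 2], , drop = FALSE])^2))
    ord <- order(d)
    m <- nrow(cand)
    tests_total <- tests_total + m
    denom <- if (bonferroni == "pass") m else tests_total
    merged <- FALSE
    for (ci in ord) {
      g1 <- ids[cand[ci, 1]]; g2 <- ids[cand[ci, 2]]
      d1 <- depths[group == g1]; d2 <- depths[group == g2]
      if (abs(median(d1) - median(d2)) > median_window) next
      p <- suppressWarnings(wilcox.test(d1, d2)$p.value)
      if (is.na(p)) p <- 1
      if (min(1, p * denom) >= alpha) {
        group[group == g2] <- g1
        merged <- TRUE
        break
      }
    }
    if (!merged) break
  }
  match(group, sort(unique(group)))
}

#' Conditional projection probability
#'
#' Within a stratum of neurons, the empirical probability of projecting to
#' `x` conditioned on projecting (or not) to `y`, and the difference.
#'
#' @param binary logical/0-1 matrix neurons x areas.
#' @param x,y area names or column indices.
#' @param stratum logical or integer subset of neurons (default all).
#' @return list `p_x_given_y1`, `p_x_given_y0`, `delta`, plus the counts.
#' @export
conditional_projection_prob <- function(binary, x, y, stratum = NULL) {
  binary <- binary != 0
  if (is.null(stratum)) stratum <- seq_len(nrow(binary))
  b <- binary[stratum, , drop = FALSE]
  if (!nrow(b)) stop("empty stratum")
  xb <- b[, x]; yb <- b[, y]
  n1 <- sum(yb); n0 <- sum(!yb)
  p1 <- if (n1 > 0) sum(xb & yb) / n1 else NA_real_
  p0 <- if (n0 > 0) sum(xb & !yb) / n0 else NA_real_
  list(p_x_given_y1 = p1, p_x_given_y0 = p0, delta = p1 - p0,
       n_y1 = n1, n_y0 = n0)
}

#' Sublayer enrichment of subgroups
#'
#' Enrichment of subgroup g in sublayer s = (fraction of s's neurons in g) /
#' (g's overall fraction); reports the full table and the top two subgroups
#' per sublayer.
#'
#' @param labels subgroup id per neuron.
#' @param sublayer sublayer name per neuron.
#' @return list with `enrichment` (matrix sublayers x subgroups) and `top2`
#'   (data.frame sublayer, first, second).
#' @export
sublayer_enrichment <- function(labels, sublayer) {
  stopifnot(length(labels) == length(sublayer))
  groups <- sort(unique(labels))
  lays <- unique(sublayer)
  overall <- table(factor(labels, levels = groups)) / length(labels)
  enr <- matrix(0, length(lays), length(groups),
                dimnames = list(lays, as.character(groups)))
  for (s in lays) {
    sel <- sublayer == s
    frac <- table(factor(labels[sel], levels = groups)) / sum(sel)
    enr[s, ] <- as.numeric(frac) / as.numeric(overall)
  }
  top1 <- apply(enr, 1, function(r) colnames(enr)[order(-r)[1]])
  top2nd <- if (ncol(enr) > 1)
    apply(enr, 1, function(r) colnames(enr)[order(-r)[2]])
  else rep(NA_character_, nrow(enr))
  top2 <- data.frame(sublayer = lays, first = top1, second = top2nd,
                     stringsAsFactors = FALSE)
  list(enrichment = enr, top2 = top2)
}

#' Cluster homogeneity by bootstrap down-sampling
#'
#' Per cluster and target size, draws `n_boot` with-replacement samples and
#' records the Pearson correlation between the resampled centroid and the
#' full-data centroid.
#'
#' @param values numeric matrix neurons x areas.
#' @param labels cluster label per neuron.
#' @param sizes sample sizes to evaluate.
#' @param n_boot resamples per size (default 1000).
#' @param seed RNG seed.
#' @return data.frame cluster, size, median/q25/q75 of the correlation.
#' @export
cluster_homogeneity <- function(values, labels, sizes, n_boot = 1000,
                                seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647L)
  out <- list()
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    full <- colMeans(values[idx, , drop = FALSE])
    for (sz in sizes) {
      r <- vapply(seq_len(n_boot), function(b) {
        take <- sample(idx, sz, replace = TRUE)
        cent <- colMeans(values[take, , drop = FALSE])
        if (sd(cent) == 0 || sd(full) == 0) return(1)
        cor(cent, full)
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        cluster = cl, size = sz, median = median(r),
        q25 = quantile(r, 0.25), q75 = quantile(r, 0.75))
    }
  }
  do.call(rbind, out)
}
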