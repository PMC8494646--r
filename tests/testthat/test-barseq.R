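test_that("normalization equalizes per-area nonzero means across brains", {
  counts <- rbind(c(4L, 3L), c(2L, 0L), c(8L, 1L), c(8L, 1L))
  colnames(counts) <- c("a1", "a2"); rownames(counts) <- paste0("n", 1:4)
  spike <- c(2, 1, 2, 2)
  brain <- c("b1", "b1", "b2", "b2")
  norm <- normalize_barcodes(counts, spike, brain)
  # brain1 nonzero a1 mean: (2 + 2)/2 = 2; brain2: 4 -> scaled by 0.5
  expect_equal(unname(norm$values[3, "a1"]), 2)
  for (a in colnames(counts)) {
    nz <- counts[, a] > 0
    for (b in unique(brain[nz])) {
      expect_equal(mean(norm$values[nz & brain == "b1", a]),
                   mean(norm$values[nz & brain == b, a]), tolerance = 1e-9)
    }
  }
  expect_equal(norm$log_values, log1p(norm$values))
  # single brain: spike-in division only
  n1 <- normalize_barcodes(counts, spike, rep("b1", 4))
  expect_equal(n1$values, counts / spike, ignore_attr = TRUE)
  # zero spike-in neurons are dropped with a warning
  expect_warning(nd <- normalize_barcodes(counts, c(1, 0, 1, 1), brain),
                 "zero spike-in")
  expect_equal(nrow(nd$values), 3)
  # area all-zero in one brain: factor 1 with warning
  c2 <- counts; c2[3:4, 2] <- 0L; c2[1, 2] <- 3L
  expect_warning(normalize_barcodes(c2, spike, brain), "factor 1")
})

test_that("major classes are recovered from the default synthetic world", {
  groups <- list(thalamus = "Thal_i", striatum = c("Str_i", "Str_c"),
                 medulla_pons = "Med_i")
  aris <- vapply(1:5, function(s) {
    cfg <- synth_config(seed = 300 + s)
    bc <- generate_barcoded_neurons(cfg)
    norm <- normalize_barcodes(bc$counts, bc$spikein, bc$meta$brain)
    mc <- major_class_clustering(norm, 4, area_groups = groups, seed = s)
    expect_setequal(unique(mc$labels), c("CT", "L5 ET", "IT Str+", "IT Str-"))
    adjusted_rand_index(mc$labels, bc$truth$class)
  }, numeric(1))
  expect_true(all(aris >= 0.95))
  expect_error(major_class_clustering(list(log_values = diag(3)), 1),
               "n_classes")
})

test_that("entropy split: closed-form 1-bit split on disjoint halves", {
  pb <- planted_binary(n_per = 20, depths = c(200, 600))
  tree <- entropy_split(pb$binary, pb$depths, n_perm = 99, seed = 1)
  expect_length(tree$leaves, 2)
  expect_equal(tree$root$delta_h, 1)     # mixture entropy of equal halves
  expect_equal(tree$root$areas, "a1")
  expect_lt(tree$root$p_value, 0.05)
  lab <- subgroup_labels(tree)
  expect_equal(adjusted_rand_index(lab, rep(1:2, each = 20)), 1)
})

test_that("entropy split leaves degenerate nodes alone", {
  # all neurons in one depth bin: H = 0, no split possible
  pb <- planted_binary(n_per = 20, depths = c(100, 110))
  tree <- entropy_split(pb$binary, pb$depths, n_perm = 49, seed = 1)
  expect_length(tree$leaves, 1)
  # node below min_node is a leaf
  tree2 <- entropy_split(pb$binary[1:10, ], rep(c(100, 600), 5),
                         min_node = 20, n_perm = 49, seed = 1)
  expect_length(tree2$leaves, 1)
})

test_that("accepted splits have nonnegative entropy reduction (property)", {
  cfg <- synth_config(seed = 31)
  bc <- generate_barcoded_neurons(cfg)
  norm <- normalize_barcodes(bc$counts, bc$spikein, bc$meta$brain)
  tree <- entropy_split(norm$binary, bc$meta$depth, n_perm = 99, seed = 31)
  walk <- function(node) {
    if (is.null(node$match)) return(invisible())
    expect_gte(node$delta_h, 0)
    expect_lte(length(node$areas), 3)    # paper's cap
    expect_equal(sort(c(node$match$neurons, node$nomatch$neurons)),
                 sort(node$neurons))     # children partition the parent
    walk(node$match); walk(node$nomatch)
  }
  walk(tree$root)
})

test_that("laminar merging respects window, class and rank-sum rules", {
  set.seed(6)
  vals <- matrix(runif(60 * 3), 60, 3)
  # identical depth distributions, same class -> merged
  depths <- rep(c(300, 305), 30)
  lab <- rep(1:2, each = 30)
  m1 <- merge_by_laminae(lab, vals, depths)
  expect_length(unique(m1), 1)
  # medians 300 vs 600: window rule blocks the merge regardless of test
  d2 <- c(rep(300, 30), rep(600, 30))
  m2 <- merge_by_laminae(lab, vals, d2)
  expect_length(unique(m2), 2)
  # same depths but different major classes never merge
  m3 <- merge_by_laminae(lab, vals, depths,
                         major_class = rep(c("IT", "CT"), each = 30))
  expect_length(unique(m3), 2)
})

test_that("conditional probabilities: direct count and exact decomposition", {
  b <- rbind(c(1, 1), c(1, 1), c(0, 1), c(1, 0))
  colnames(b) <- c("x", "y")
  cp <- conditional_projection_prob(b, "x", "y")
  expect_equal(cp$p_x_given_y1, 2 / 3)
  expect_equal(cp$p_x_given_y0, 1)
  # law of total probability holds exactly on any finite stratum
  cfg <- synth_config(seed = 8)
  bc <- generate_barcoded_neurons(cfg)
  bin <- bc$counts >= 1
  for (pair in list(c(1, 2), c(3, 5))) {
    cp <- conditional_projection_prob(bin, pair[1], pair[2])
    p_y1 <- cp$n_y1 / (cp$n_y1 + cp$n_y0)
    expect_equal(cp$p_x_given_y1 * p_y1 + cp$p_x_given_y0 * (1 - p_y1),
                 mean(bin[, pair[1]]), tolerance = 1e-12)
  }
  # independence: delta within binomial CI of zero
  set.seed(9)
  bi <- matrix(rbinom(2000, 1, 0.5), 1000, 2,
               dimnames = list(NULL, c("x", "y")))
  cpi <- conditional_projection_prob(bi, "x", "y")
  expect_lt(abs(cpi$delta), 3 * sqrt(0.25 / 500 + 0.25 / 500))
})

test_that("sublayer enrichment ranks subgroups and handles degenerates", {
  lab <- c(rep(1, 30), rep(2, 10))
  sub <- c(rep("L2", 20), rep("L5", 20))
  enr <- sublayer_enrichment(lab, sub)
  # subgroup 2 confined to L5: enrichment = 1/overall fraction, 0 elsewhere
  expect_equal(enr$enrichment["L5", "2"], 1 / (10 / 40) * (10 / 20) / 1)
  expect_equal(enr$enrichment["L2", "2"], 0)
  expect_equal(enr$top2$first[enr$top2$sublayer == "L5"], "2")
  # single subgroup: top-1 everywhere, enrichment exactly 1
  e1 <- sublayer_enrichment(rep(1, 40), sub)
  expect_true(all(e1$enrichment == 1))
})

test_that("cluster homogeneity: perfect clusters and size monotonicity", {
  x <- matrix(rep(c(1, 2, 3, 4), each = 30), 30, 4)
  h <- cluster_homogeneity(x, rep(1, 30), sizes = c(2, 10), n_boot = 50)
  expect_true(all(h$median == 1))
  cfg <- synth_config(seed = 12)
  bc <- generate_barcoded_neurons(cfg)
  norm <- normalize_barcodes(bc$counts, bc$spikein, bc$meta$brain)
  h2 <- cluster_homogeneity(norm$values, bc$truth$class,
                            sizes = c(3, 10, 30, 100), n_boot = 200, seed = 5)
  for (cl in unique(h2$cluster)) {
    med <- h2$median[h2$cluster == cl]
    expect_true(all(diff(med) >= -0.02))  # non-decreasing up to noise
  }
})
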