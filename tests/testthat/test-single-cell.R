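test_that("SWC reading validates tree structure and measures length", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 1 -1", "2 2 3 4 0 0.5 1"), path)
  m <- read_swc(path)
  expect_equal(nrow(m$nodes), 2)
  expect_equal(m$total_length, 5)        # 3-4-5 triangle
  # single node: valid, zero length
  writeLines("1 1 0 0 0 1 -1", path)
  expect_equal(read_swc(path)$total_length, 0)
  # self-parent cycle
  writeLines(c("1 1 0 0 0 1 -1", "2 2 1 0 0 1 2"), path)
  expect_error(read_swc(path), "cycle")
  # two roots = breaks
  writeLines(c("1 1 0 0 0 1 -1", "2 2 1 0 0 1 -1"), path)
  expect_error(read_swc(path), "breaks")
  # trifurcation violates the single-tree contract
  writeLines(c("1 1 0 0 0 1 -1", "2 2 1 0 0 1 1", "3 2 0 1 0 1 2",
               "4 2 1 1 0 1 2", "5 2 2 2 0 1 2"), path)
  expect_error(read_swc(path), "more than two branches")
})

test_that("SWC write-read round trip preserves nodes and cable length", {
  cfg <- synth_config(seed = 14, single_cell = list(n_cells_per_cluster = 1))
  sc <- generate_single_cells(cfg, materialize = TRUE)
  m <- neuron_morphology(sc$swc[[1]])
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_equal(nrow(m2$nodes), nrow(m$nodes))
  expect_equal(m2$total_length, m$total_length, tolerance = 1e-9)
})

test_that("annotation volume text serialization round trips", {
  vol <- annotation_volume(array(rep(1:2, each = 8), c(4, 2, 2)),
                           voxel_size = 10, origin = c(0, 0, 0),
                           region_ids = c(A = 1, B = 2))
  prefix <- tempfile()
  write_annotation_volume(vol, prefix)
  v2 <- read_annotation_volume(prefix)
  expect_equal(v2$data, vol$data)
  expect_equal(v2$region_ids, vol$region_ids)
  unlink(paste0(prefix, c(".json", ".txt")))
})

test_that("segment lengths are assigned by sub-segment midpoint region", {
  # two regions split at x = 40 um; 10-um segment crossing at its 40% point
  vol <- annotation_volume(array(rep(rep(1:2, each = 40), 80), c(80, 80, 1)),
                           voxel_size = 1, origin = c(0, 0, 0),
                           region_ids = c(A = 1, B = 2))
  nodes <- data.frame(id = 1:2, type = 2L, x = c(36, 46), y = 5, z = 0.5,
                      radius = 1, parent = c(-1L, 1L))
  len <- axon_length_by_region(neuron_morphology(nodes), vol, step = 1)
  expect_equal(unname(len["A"]), 4, tolerance = 1)   # +- one step
  expect_equal(unname(len["B"]), 6, tolerance = 1)
  # segment wholly inside one region
  nodes2 <- data.frame(id = 1:2, type = 2L, x = c(1, 21), y = 5, z = 0.5,
                       radius = 1, parent = c(-1L, 1L))
  len2 <- axon_length_by_region(neuron_morphology(nodes2), vol, step = 1)
  expect_equal(unname(len2["A"]), 20)
  expect_equal(unname(len2["B"]), 0)
  # fully outside the volume
  nodes3 <- data.frame(id = 1:2, type = 2L, x = c(-50, -30), y = 5, z = 0.5,
                       radius = 1, parent = c(-1L, 1L))
  expect_warning(len3 <- axon_length_by_region(neuron_morphology(nodes3),
                                               vol, step = 1),
                 "outside")
  expect_equal(unname(len3["unannotated"]), 20)
})

test_that("fraction matrix normalizes rows and sums hemispheres", {
  lengths <- matrix(c(1, 1, 2), 1, 3,
                    dimnames = list("n1", c("r1", "r2", "r3")))
  fm <- fraction_matrix(lengths)
  expect_equal(unname(fm[1, ]), c(0.25, 0.25, 0.5))
  hemi <- matrix(c(2, 3, 5), 1, 3,
                 dimnames = list("n1", c("ca_ipsi", "ca_contra", "cb_ipsi")))
  fm2 <- fraction_matrix(hemi)
  expect_equal(unname(fm2[1, "ca"]), 0.5)  # (2+3)/10
  expect_warning(fraction_matrix(rbind(lengths, n2 = c(0, 0, 0))),
                 "zero-length")
})

test_that("NNLS equals the unconstrained solution when it is feasible", {
  set.seed(3)
  A <- matrix(runif(40), 10, 4)
  x_true <- c(0.5, 0.2, 0.8, 0.1)
  b <- drop(A %*% x_true)
  fit <- nnls_solve(A, b)
  expect_equal(fit$x, x_true, tolerance = 1e-8)
  expect_lt(fit$rss, 1e-16)
})

test_that("NNLS objective matches grid search on 2-column problems", {
  set.seed(7)
  for (rep in 1:5) {
    A <- matrix(runif(12), 6, 2)
    b <- runif(6)
    fit <- nnls_solve(A, b)
    grid <- seq(0, 2, by = 0.005)
    rss_grid <- outer(grid, grid, Vectorize(function(x1, x2)
      sum((A %*% c(x1, x2) - b)^2)))
    expect_lte(fit$rss, min(rss_grid) + 1e-6)
    # never below the unconstrained optimum
    ls <- qr.solve(A, b)
    expect_gte(fit$rss + 1e-12, sum((A %*% ls - b)^2))
  }
})

test_that("composition estimation recovers mixtures; nnls and bvls agree", {
  cfg <- synth_config(seed = 16,
                      single_cell = list(dirichlet_concentration = Inf,
                                         n_cells_per_cluster = 20))
  sc <- generate_single_cells(cfg)
  bulk <- 0.6 * sc$archetypes[1, ] + 0.4 * sc$archetypes[2, ]
  keep <- sc$truth$cluster %in% c("C1", "C2")
  est <- estimate_composition(sc$fractions[keep, ], sc$truth$cluster[keep],
                              bulk)
  expect_equal(unname(est$proportions), c(0.6, 0.4), tolerance = 1e-8)
  expect_lt(est$rss_relative, 1e-10)
  estb <- estimate_composition(sc$fractions[keep, ], sc$truth$cluster[keep],
                               bulk, method = "bvls")
  expect_equal(unname(estb$proportions), c(0.6, 0.4), tolerance = 1e-4)
  expect_lt(max(abs(est$proportions - estb$proportions)), 0.02)
  # bulk equal to one cluster's mean: that cluster ~ 1
  est1 <- estimate_composition(sc$fractions[keep, ], sc$truth$cluster[keep],
                               sc$archetypes[1, ])
  expect_gt(est1$proportions[["C1"]], 0.999)
  # eligibility rules
  expect_equal(formals(estimate_composition)$min_cluster_size, 15)
  expect_error(estimate_composition(sc$fractions[keep, ],
                                    sc$truth$cluster[keep], bulk,
                                    min_cluster_size = 1000),
               "fewer than 2 eligible")
})

test_that("Dirichlet-noised mixtures are recovered within 0.05", {
  for (s in 1:5) {
    cfg <- synth_config(seed = 400 + s,
                        single_cell = list(dirichlet_concentration = 50))
    sc <- generate_single_cells(cfg)
    mix <- c(C1 = 0.5, C2 = 0.3, C3 = 0.2)
    bulk <- drop(mix %*% sc$archetypes)
    est <- estimate_composition(sc$fractions, sc$truth$cluster, bulk)
    expect_lt(max(abs(est$proportions - mix)), 0.05)
  }
})

test_that("XOR distances and fixed-margin shuffles behave as defined", {
  expect_equal(xor_distances(rbind(c(1, 0), c(0, 1))), 2)
  expect_equal(xor_distances(rbind(c(1, 1), c(1, 1))), 0)
  set.seed(10)
  b <- matrix(rbinom(200, 1, 0.3), 20, 10)
  for (rep in 1:5) {
    m <- margin_shuffle(b)
    expect_equal(rowSums(m), rowSums(b))
    expect_equal(colSums(m), colSums(b))
    expect_true(all(m %in% c(0, 1)))
  }
  # identical rows: variance 0, p = 1 by construction
  same <- matrix(rep(c(1, 0, 1, 0), 10), 10, 4, byrow = TRUE)
  xt <- xor_discreteness_test(same, n_shuffles = 5, seed = 1)
  expect_equal(xt$p, 1)
})

test_that("XOR/Levene detects planted two-archetype structure", {
  set.seed(20)
  arch1 <- c(rep(1, 5), rep(0, 15)); arch2 <- c(rep(0, 15), rep(1, 5))
  b <- rbind(t(replicate(50, arch1)), t(replicate(50, arch2)))
  xt <- xor_discreteness_test(b, n_shuffles = 50, seed = 2)
  expect_lt(xt$p, 0.05)
  expect_gt(xt$var_actual, xt$var_shuffled)
})
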