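test_that("output fractions follow the definition, mask and grouping", {
  ont <- toy_ontology(n_iso = 2, n_thal = 1)  # 3 regions, 6 bilateral
  bt <- bilateral_targets(ont)
  sig <- matrix(0, 1, 6, dimnames = list("e1", bt$label))
  sig[1, 1:3] <- c(2, 3, 5)
  m <- output_fraction_matrix(sig, ont)
  expect_equal(unname(m[1, 1:3]), c(0.2, 0.3, 0.5))
  # masking the 0.5 region renormalizes the rest
  mask <- matrix(1, 1, 6); mask[1, 3] <- 0
  m2 <- output_fraction_matrix(sig, ont, mask = mask)
  expect_equal(unname(m2[1, 1:3]), c(0.4, 0.6, 0))
  # mask idempotence
  m3 <- output_fraction_matrix(sig * (mask != 0), ont, mask = mask)
  expect_equal(unclass(m3), unclass(m2), ignore_attr = TRUE)
  # grouping: two experiments averaged after normalization
  sig2 <- rbind(e1 = sig[1, ], e2 = c(0, 10, 0, 0, 0, 0))
  g <- output_fraction_matrix(sig2, ont, group = c("g", "g"))
  expect_equal(nrow(g), 1)
  expect_equal(unname(g[1, 2]), (0.3 + 1) / 2)
})

test_that("injection-site exclusion drops both hemispheres", {
  ont <- toy_ontology(n_iso = 2, n_thal = 1)
  bt <- bilateral_targets(ont)
  sig <- matrix(1, 1, 6, dimnames = list("e1", bt$label))
  m <- output_fraction_matrix(sig, ont, injection_region = "iso1")
  expect_equal(unname(m[1, bt$region == "iso1"]), c(0, 0))
  expect_equal(sum(m), 1)
})

test_that("blank calibration: hand arithmetic, defaults, degenerate cases", {
  blanks <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "r"))
  cal <- blank_calibration(blanks, k = 6)
  expect_equal(unname(cal$threshold), 8)  # mean 2 + 6 * sd 1
  expect_equal(cal$k, 6)
  expect_equal(formals(blank_calibration)$k, 6)  # paper default
  z <- blank_calibration(matrix(0, 5, 2), 6)
  expect_equal(unname(z$threshold), c(0, 0))
  expect_error(blank_calibration(matrix(1, 1, 2)), "at least 2")
})

test_that("input matrix thresholds before normalizing", {
  ont <- toy_ontology(n_iso = 2, n_thal = 1)
  bt <- bilateral_targets(ont)
  sig <- matrix(0, 1, 6, dimnames = list("e1", bt$label))
  sig[1, 1:3] <- c(10, 7, 0)
  cal <- list(threshold = rep(8, 6))
  m <- input_fraction_matrix(sig, ont, cal)
  expect_equal(unname(m[1, 1:3]), c(1, 0, 0))
  expect_equal(attr(m, "kind"), "input")
  # zero thresholds reduce to plain normalization
  m0 <- input_fraction_matrix(sig, ont, list(threshold = rep(0, 6)))
  expect_equal(unname(m0[1, 1:3]), c(10, 7, 0) / 17)
})

test_that("division summary sums fractions within divisions", {
  ont <- toy_ontology(n_iso = 1, n_thal = 1, n_str = 1)
  bt <- bilateral_targets(ont)
  sig <- matrix(0, 1, 6, dimnames = list("e1", bt$label))
  sig[1, bt$region == "str1"] <- c(3, 0)
  m <- output_fraction_matrix(sig, ont)
  dv <- division_summary(m, ont)
  expect_equal(unname(dv["e1", "striatum"]), 1)
  sig[1, ] <- 0
  sig[1, c(1, 2)] <- c(5, 5)  # iso1_ipsi + thal1_ipsi
  dv2 <- division_summary(output_fraction_matrix(sig, ont), ont)
  expect_equal(unname(dv2["e1", c("isocortex", "thalamus")]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(dv2) - 1) < 1e-9))
})

test_that("injection distances: degenerate, hand-enumerated, missing", {
  same <- data.frame(experiment = c("a", "b"), x = 1, y = 2, z = 3)
  d0 <- injection_distances(same)
  expect_equal(c(d0$mean, d0$sd), c(0, 0))
  # collinear points at 0, 3, 4 um: pairs 3, 4, 1 -> mean 8/3
  col3 <- data.frame(experiment = c("a", "b", "c"),
                     x = c(0, 3, 4), y = 0, z = 0)
  d1 <- injection_distances(col3)
  expect_equal(sort(d1$pairs$distance), c(1, 3, 4))
  expect_equal(d1$mean, 8 / 3)
  withmiss <- rbind(col3, data.frame(experiment = "d", x = NA, y = 0, z = 0))
  expect_warning(d2 <- injection_distances(withmiss), "missing")
  expect_equal(d2$mean, d1$mean)
})

test_that("in-degree counts strict positives and group means", {
  m <- rbind(a = c(0, 0.5, 0.5, 0), b = rep(0, 4), c = c(0.25, 0.25, 0.25, 0.25))
  deg <- in_degree(m)
  expect_equal(unname(deg), c(2, 0, 4))
  g <- in_degree(m, group = c("x", "x", "y"))
  expect_equal(unname(g$group_means["x"]), 1)
})

test_that("raising the calibration multiplier never raises in-degree", {
  cfg <- synth_config(seed = 21)
  tr <- generate_tracer_experiments(cfg)
  bl <- generate_blank_brains(cfg, tr$ontology)
  degs <- sapply(c(0, 2, 6, 10), function(k) {
    cal <- blank_calibration(bl, k)
    suppressWarnings(mean(in_degree(input_fraction_matrix(tr$signal,
                                                          tr$ontology, cal))))
  })
  expect_true(all(diff(degs) <= 0))
})

test_that("false-positive survival under k = 6 matches the Gaussian tail", {
  # regions with zero planted signal: survival of pure background past
  # mean + 6 sd should be essentially nil
  n_surv <- 0; n_tot <- 0
  for (s in 1:20) {
    cfg <- synth_config(seed = 100 + s, n_experiments_per_class = 2)
    tr <- generate_tracer_experiments(cfg)
    bl <- generate_blank_brains(cfg, tr$ontology)
    cal <- blank_calibration(bl, 6)
    m <- suppressWarnings(input_fraction_matrix(tr$signal, tr$ontology, cal))
    nosig <- tr$archetypes == 0
    for (i in seq_len(nrow(m))) {
      zero_regions <- which(nosig[tr$truth[i], ])
      n_surv <- n_surv + sum(m[i, zero_regions] > 0)
      n_tot <- n_tot + length(zero_regions)
    }
  }
  expect_lt(n_surv / n_tot, 0.001)
})
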