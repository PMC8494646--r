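#' Synthetic-data configuration
#'
#' Bundles all generator parameters with a seed. Identical `(config, seed)`
#' always produces identical outputs. Defaults state the emulated world:
#' three tracer classes (IT/ET/CT) with 20% multiplicative noise, blank-brain
#' imaging background, two-brain barcode data with planted binary projection
#' subgroups tied to laminar depths, and single cells drawn from cluster
#' archetypes.
#'
#' @param seed integer seed driving every random draw.
#' @param n_regions summary targets in the generated ontology.
#' @param n_experiments_per_class tracer experiments per class.
#' @param class_archetypes optional matrix (classes x bilateral targets) of
#'   mean regional weights, rows nonnegative summing to 1; default built from
#'   the ontology's divisions (IT to cortex/striatum, ET subcortical, CT
#'   thalamic).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   signal noise (unitless).
#' @param blank_background_mean,blank_background_sd background signal-volume
#'   units per region in brains with no tracer.
#' @param n_blank_brains number of blank brains.
#' @param total_signal total labelled signal volume per experiment.
#' @param injection_jitter_sd per-axis s.d. (micrometres) of injection
#'   coordinate jitter around the class centre. 195 um gives a mean pairwise
#'   3D distance of about 440 um between injections, matching a compact
#'   injection grid within one cortical area.
#' @param barcode list: `n_neurons`, `n_areas`, `areas` (labels),
#'   `subgroups` (list with per-subgroup `pattern` digit string over areas —
#'   0 = no projection, 2 = strong (mean `mean_count`), 1 = weak
#'   (`weak_factor * mean_count`); class-defining projections are strong and
#'   subgroup-distinguishing ones weak, mirroring graded projection
#'   strengths — `depth_mean`/`depth_sd` in micrometres, `fraction` mixing
#'   weight summing to 1, `class` major-class label), `mean_count` mean
#'   barcode molecules per strongly projected area, `weak_factor`,
#'   `spikein_mean` mean spike-in count, `n_brains`, `brain_scale_factors`
#'   per-brain library scale, `cortical_depth` truncation bound (um).
#' @param single_cell list: `n_cells_per_cluster`, `cluster_archetypes`
#'   (clusters x regions, rows sum to 1; default planted from the ontology),
#'   `dirichlet_concentration` (larger = less perturbation; `Inf` = exact
#'   archetype copies), `axon_length_scale` total axon length per cell (um).
#' @return object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_regions = 30L,
                         n_experiments_per_class = 5L,
                         class_archetypes = NULL,
                         noise_cv = 0.2,
                         blank_background_mean = 2,
                         blank_background_sd = 1,
                         n_blank_brains = 90L,
                         total_signal = 1e5,
                         injection_jitter_sd = 195,
                         barcode = list(),
                         single_cell = list()) {
  if (noise_cv < 0) stop("noise_cv must be nonnegative")
  if (n_blank_brains < 2) stop("need at least 2 blank brains (sd undefined)")
  barcode_default <- list(
    n_neurons = 1000L,
    areas = c("MOs_i", "MOs_c", "SSp_i", "SSs_i", "Str_i", "Str_c",
              "Thal_i", "Med_i"),
    subgroups = list(
      list(pattern = "00000020", depth_mean = 950, depth_sd = 60,
           fraction = 0.15, class = "CT"),
      list(pattern = "00100022", depth_mean = 650, depth_sd = 60,
           fraction = 0.15, class = "L5 ET"),
      list(pattern = "22002100", depth_mean = 500, depth_sd = 70,
           fraction = 0.20, class = "IT Str+"),
      list(pattern = "22102000", depth_mean = 600, depth_sd = 60,
           fraction = 0.15, class = "IT Str+"),
      list(pattern = "20100000", depth_mean = 250, depth_sd = 60,
           fraction = 0.20, class = "IT Str-"),
      list(pattern = "20010000", depth_mean = 150, depth_sd = 50,
           fraction = 0.15, class = "IT Str-")
    ),
    mean_count = 50,
    weak_factor = 0.1,
    spikein_mean = 100,
    n_brains = 2L,
    brain_scale_factors = c(1, 1.5),
    cortical_depth = 1200
  )
  user_subgroups <- barcode$subgroups   # unnamed list: replace, never merge
  barcode <- modifyList(barcode_default, barcode)
  if (!is.null(user_subgroups)) barcode$subgroups <- user_subgroups
  barcode$n_areas <- length(barcode$areas)
  fr <- vapply(barcode$subgroups, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9) stop("subgroup mixing fractions must sum to 1")
  for (sg in barcode$subgroups)
    if (nchar(sg$pattern) != barcode$n_areas)
      stop("subgroup pattern length != number of areas: ", sg$pattern)
  if (length(barcode$brain_scale_factors) != barcode$n_brains)
    stop("brain_scale_factors length must equal n_brains")

  sc_default <- list(
    n_cells_per_cluster = 40L,
    cluster_archetypes = NULL,
    dirichlet_concentration = 100,
    axon_length_scale = 5e4
  )
  single_cell <- modifyList(sc_default, single_cell)

  structure(list(
    seed = as.integer(seed), n_regions = as.integer(n_regions),
    n_experiments_per_class = as.integer(n_experiments_per_class),
    class_archetypes = class_archetypes, noise_cv = noise_cv,
    blank_background_mean = blank_background_mean,
    blank_background_sd = blank_background_sd,
    n_blank_brains = as.integer(n_blank_brains),
    total_signal = total_signal,
    injection_jitter_sd = injection_jitter_sd,
    barcode = barcode, single_cell = single_cell
  ), class = "synth_config")
}

# deterministic per-purpose seed derived from the config seed (kept < 2^31)
.sub_seed <- function(config, offset) {
  (config$seed * 10007L + offset) %% 2147483647L
}

#' Default tracer class archetypes over an ontology
#'
#' IT: cortex + striatum, bilateral; ET: subcortical (thalamus, midbrain,
#' pons, medulla), ipsi-dominant; CT: thalamus. Within a division, weight is
#' split over that division's targets by a seeded Dirichlet draw so that
#' archetypes are sparse and distinct but reproducible.
#'
#' @param ontology a `region_ontology`.
#' @param seed integer seed.
#' @return matrix 3 x (2 * n summary targets), rows IT/ET/CT, rows sum to 1.
#' @export
default_archetypes <- function(ontology, seed = 1L) {
  bt <- bilateral_targets(ontology)
  divs <- target_divisions(ontology)
  bt$division <- divs[bt$region]
  profiles <- list(
    IT = c(isocortex = 0.55, striatum = 0.35, thalamus = 0.05,
           `cortical subplate` = 0.05),
    ET = c(thalamus = 0.15, midbrain = 0.30, pons = 0.25, medulla = 0.20,
           isocortex = 0.05, striatum = 0.05),
    CT = c(thalamus = 0.90, isocortex = 0.10)
  )
  ipsi_share <- c(IT = 0.7, ET = 0.9, CT = 0.95)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647L)
  arch <- matrix(0, nrow = 3, ncol = nrow(bt),
                 dimnames = list(names(profiles), bt$label))
  for (cl in names(profiles)) {
    for (dv in names(profiles[[cl]])) {
      for (hemi in c("ipsi", "contra")) {
        idx <- which(bt$division == dv & bt$hemisphere == hemi)
        if (!length(idx)) next
        hemi_w <- if (hemi == "ipsi") ipsi_share[[cl]] else 1 - ipsi_share[[cl]]
        # sparse Dirichlet split within the division
        g <- rgamma(length(idx), shape = 0.5)
        arch[cl, idx] <- profiles[[cl]][[dv]] * hemi_w * g / sum(g)
      }
    }
    arch[cl, ] <- arch[cl, ] / sum(arch[cl, ])
  }
  arch
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate synthetic tracer experiments
#'
#' Per experiment, per bilateral target:
#' `signal = archetype_weight * total_signal * lognormal(cv) + background`,
#' with the lognormal noise mean-1 and coefficient of variation `noise_cv`,
#' and Gaussian blank background truncated at zero. Injection coordinates
#' are jittered around a class-specific centre.
#'
#' @param config a [synth_config()].
#' @param ontology ontology over whose bilateral targets archetypes are
#'   defined; default `synthetic_ontology(config$n_regions)`.
#' @return list with `experiments` (long data.frame: experiment, class,
#'   target label, signal), `signal` (matrix experiments x targets),
#'   `injections` (experiment, class, x, y, z um), `archetypes`, `ontology`
#'   and `truth` (per-experiment class labels).
#' @export
generate_tracer_experiments <- function(config,
                                        ontology = synthetic_ontology(config$n_regions)) {
  arch <- config$class_archetypes
  if (is.null(arch)) arch <- default_archetypes(ontology, .sub_seed(config, 1L))
  if (any(arch < 0)) stop("archetype weights must be nonnegative")
  bt <- bilateral_targets(ontology)
  if (ncol(arch) != nrow(bt))
    stop("archetype columns must match bilateral targets")
  classes <- rownames(arch)
  n_exp <- config$n_experiments_per_class
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(config, 2L))

  ids <- character(0); cls <- character(0)
  sig <- matrix(0, nrow = length(classes) * n_exp, ncol = nrow(bt),
                dimnames = list(NULL, bt$label))
  inj <- matrix(0, nrow = length(classes) * n_exp, ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  # class centres 100 um apart along ML within the injected area
  centres <- cbind(x = 5000 + 100 * (seq_along(classes) - 1), y = 3000, z = 800)
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  row <- 0L
  for (ci in seq_along(classes)) {
    for (e in seq_len(n_exp)) {
      row <- row + 1L
      ids[row] <- sprintf("%s_%02d", classes[ci], e)
      cls[row] <- classes[ci]
      noise <- if (cv > 0)
        rlnorm(nrow(bt), meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
      bg <- if (config$blank_background_sd > 0 || config$blank_background_mean > 0)
        pmax(0, rnorm(nrow(bt), config$blank_background_mean,
                      config$blank_background_sd)) else 0
      sig[row, ] <- arch[ci, ] * config$total_signal * noise + bg
      inj[row, ] <- centres[ci, ] + rnorm(3, 0, config$injection_jitter_sd)
    }
  }
  rownames(sig) <- ids; rownames(inj) <- ids
  experiments <- data.frame(
    experiment = rep(ids, each = nrow(bt)),
    class = rep(cls, each = nrow(bt)),
    target = rep(bt$label, times = length(ids)),
    signal = as.vector(t(sig)),
    stringsAsFactors = FALSE
  )
  list(experiments = experiments, signal = sig,
       injections = data.frame(experiment = ids, class = cls, inj,
                               stringsAsFactors = FALSE),
       archetypes = arch, ontology = ontology,
       truth = setNames(cls, ids))
}

#' Generate blank-brain background signal
#'
#' Brains with no tracer, run through the same quantification: per-region
#' draws from a zero-truncated Gaussian with the configured mean/sd.
#'
#' @param config a [synth_config()].
#' @param ontology ontology; default `synthetic_ontology(config$n_regions)`.
#' @return matrix n_blank_brains x bilateral targets.
#' @export
generate_blank_brains <- function(config,
                                  ontology = synthetic_ontology(config$n_regions)) {
  if (config$n_blank_brains < 2) stop("need at least 2 blank brains")
  bt <- bilateral_targets(ontology)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(config, 3L))
  n <- config$n_blank_brains
  m <- matrix(pmax(0, rnorm(n * nrow(bt), config$blank_background_mean,
                            config$blank_background_sd)),
              nrow = n, ncol = nrow(bt),
              dimnames = list(sprintf("blank_%03d", seq_len(n)), bt$label))
  if (config$blank_background_mean == 0 && config$blank_background_sd == 0)
    m[] <- 0
  m
}

#' Generate barcoded single-neuron projection data
#'
#' Each neuron draws a subgroup by mixing fraction; its soma depth is
#' Normal(subgroup mean, sd) truncated to `[0, cortical_depth]`; barcode
#' counts per area are Poisson(mean_count x pattern bit x brain scale);
#' spike-ins are Poisson(spikein_mean x brain scale); brains are assigned
#' round-robin.
#'
#' @param config a [synth_config()].
#' @return list with `counts` (neurons x areas integer matrix), `spikein`,
#'   `meta` (data.frame: neuron, brain, depth um, ml um), `areas`, and
#'   `truth` (subgroup index, class label and true depth per neuron).
#' @export
generate_barcoded_neurons <- function(config) {
  bc <- config$barcode
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(config, 4L))
  n <- bc$n_neurons
  sgs <- bc$subgroups
  fr <- vapply(sgs, `[[`, numeric(1), "fraction")
  sg_idx <- sample.int(length(sgs), n, replace = TRUE, prob = fr)
  brain <- rep_len(seq_len(bc$n_brains), n)
  scale <- bc$brain_scale_factors[brain]
  depth <- numeric(n)
  counts <- matrix(0L, nrow = n, ncol = bc$n_areas,
                   dimnames = list(sprintf("n%05d", seq_len(n)), bc$areas))
  digits <- t(vapply(sgs, function(s)
    as.integer(strsplit(s$pattern, "")[[1]]), integer(bc$n_areas)))
  # digit 0 -> no projection, 1 -> weak, 2 -> strong
  patt <- matrix(c(0, bc$weak_factor, 1)[digits + 1L], nrow = nrow(digits))
  for (i in seq_len(n)) {
    s <- sgs[[sg_idx[i]]]
    d <- rnorm(1, s$depth_mean, s$depth_sd)
    while (d < 0 || d > bc$cortical_depth) d <- rnorm(1, s$depth_mean, s$depth_sd)
    depth[i] <- d
    counts[i, ] <- rpois(bc$n_areas, bc$mean_count * patt[sg_idx[i], ] * scale[i])
  }
  spike <- rpois(n, bc$spikein_mean * scale)
  meta <- data.frame(
    neuron = rownames(counts), brain = sprintf("brain%d", brain),
    depth = depth, ml = runif(n, 0, 2000), stringsAsFactors = FALSE
  )
  truth <- data.frame(
    neuron = rownames(counts), subgroup = sg_idx,
    class = vapply(sgs, `[[`, character(1), "class")[sg_idx],
    depth = depth, stringsAsFactors = FALSE
  )
  list(counts = counts, spikein = setNames(spike, rownames(counts)),
       meta = meta, areas = bc$areas, truth = truth)
}

#' Generate single-cell axon projection data
#'
#' Per-cell region fractions are Dirichlet perturbations of planted cluster
#' archetypes. Optionally materializes each cell as a piecewise-linear SWC
#' axon path through a block annotation volume whose per-region path lengths
#' match the fractions up to voxel quantization.
#'
#' @param config a [synth_config()].
#' @param regions region names; default the first 6 ipsi targets of a small
#'   synthetic ontology.
#' @param materialize if TRUE, also return SWC node tables and an annotation
#'   volume realizing each cell's fractions as geometry.
#' @return list with `fractions` (cells x regions, rows sum to 1), `truth`
#'   (cluster label, soma layer per cell), `archetypes`, and when
#'   materialized `swc` (named list of SWC data.frames) and `volume`
#'   (an `annotation_volume`).
#' @export
generate_single_cells <- function(config, regions = NULL, materialize = FALSE) {
  sc <- config$single_cell
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(.sub_seed(config, 5L))
  arch <- sc$cluster_archetypes
  if (is.null(arch)) {
    if (is.null(regions)) regions <- sprintf("R%02d", 1:6)
    # three planted clusters with distinct dominant regions
    k <- 3L
    arch <- matrix(0.02, nrow = k, ncol = length(regions),
                   dimnames = list(sprintf("C%d", 1:k), regions))
    for (i in seq_len(k)) {
      dom <- ((i - 1) * 2) %% length(regions) + 1
      arch[i, dom] <- 1
      arch[i, (dom %% length(regions)) + 1] <- 0.4
    }
    arch <- arch / rowSums(arch)
  } else {
    if (is.null(regions)) regions <- colnames(arch)
    if (is.null(regions)) stop("regions must be named via archetype columns")
    if (ncol(arch) != length(regions)) stop("archetype dimension mismatch")
    colnames(arch) <- regions
  }
  n_per <- sc$n_cells_per_cluster
  k <- nrow(arch)
  n <- k * n_per
  frac <- matrix(0, nrow = n, ncol = length(regions),
                 dimnames = list(sprintf("cell%04d", seq_len(n)), regions))
  cluster <- rep(rownames(arch), each = n_per)
  conc <- sc$dirichlet_concentration
  soma_layers <- c("L2/3", "L5", "L6")
  for (i in seq_len(n)) {
    a <- arch[cluster[i], ]
    if (is.finite(conc)) {
      g <- rgamma(length(a), shape = conc * pmax(a, 1e-6))
      frac[i, ] <- g / sum(g)
    } else frac[i, ] <- a
  }
  truth <- data.frame(
    cell = rownames(frac), cluster = cluster,
    soma_layer = soma_layers[(match(cluster, rownames(arch)) - 1) %% 3 + 1],
    stringsAsFactors = FALSE
  )
  out <- list(fractions = frac, truth = truth, archetypes = arch)
  if (materialize) {
    mat <- .materialize_cells(frac, sc$axon_length_scale)
    out$swc <- mat$swc
    out$volume <- mat$volume
  }
  out
}

# Build a slab annotation volume (regions stacked along x) and, per cell, a
# single-tree SWC polyline whose in-slab zigzag length matches the target
# per-region lengths up to the slab-crossing overhead.
.materialize_cells <- function(frac, total_length) {
  regions <- colnames(frac)
  nr <- length(regions)
  voxel <- 10                        # um
  slab_vox <- 20L                    # 200 um per region slab
  ny <- 60L; nz <- 4L                # 600 x 40 um cross-section
  nx <- slab_vox * nr
  vol <- array(0L, dim = c(nx, ny, nz))
  for (r in seq_len(nr))
    vol[((r - 1L) * slab_vox + 1L):(r * slab_vox), , ] <- r
  volume <- annotation_volume(vol, voxel_size = voxel, origin = c(0, 0, 0),
                              region_ids = setNames(seq_len(nr), regions))
  stroke <- (ny - 4) * voxel          # length of one y-stroke, inside bounds
  z0 <- nz / 2 * voxel
  swc <- vector("list", nrow(frac))
  names(swc) <- rownames(frac)
  for (ci in seq_len(nrow(frac))) {
    nodes <- list()
    nid <- 0L
    add <- function(x, y, parent) {
      nid <<- nid + 1L
      nodes[[nid]] <<- c(nid, if (nid == 1L) 1 else 2, x, y, z0, 0.5, parent)
      nid
    }
    # the path is monotone in x, so each interior slab contributes exactly
    # its width (slab_w) of horizontal length; vertical zigzag supplies the
    # remainder of the region's target length
    slab_w <- slab_vox * voxel
    margin <- 2 * voxel
    y <- margin
    prev <- add(margin, y, -1L)
    for (r in seq_len(nr)) {
      xs <- (r - 1L) * slab_w + margin
      horiz <- if (r == 1L) slab_w - margin
               else if (r == nr) margin
               else slab_w
      V <- max(0, frac[ci, r] * total_length - horiz)  # vertical budget
      n_strokes <- floor(V / stroke)
      rem <- V - n_strokes * stroke
      xx <- xs
      if (n_strokes > 0) {
        for (s in seq_len(n_strokes)) {
          xx <- xs + s            # 1-um advance per stroke
          prev <- add(xx, y, prev)
          y <- if (y < ny / 2 * voxel) y + stroke else y - stroke
          prev <- add(xx, y, prev)
        }
      }
      if (rem > 1) {
        ynew <- if (y < ny / 2 * voxel) y + rem else y - rem
        prev <- add(xx, ynew, prev)
        y <- ynew
      }
      # cross into next slab
      if (r < nr) prev <- add(r * slab_w + margin, y, prev)
    }
    df <- as.data.frame(do.call(rbind, nodes))
    names(df) <- c("id", "type", "x", "y", "z", "radius", "parent")
    swc[[ci]] <- df
  }
  list(swc = swc, volume = volume)
}
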