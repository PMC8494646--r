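#' @importFrom stats aov as.dist complete.cases cor cutree dist fisher.test
#'   hclust kmeans median optim quantile rbinom rgamma rlnorm rnorm rpois
#'   runif sd setNames t.test var wilcox.test TukeyHSD
#' @importFrom utils combn modifyList write.csv
NULL

#' Major brain divisions
#'
#' The thirteen major divisions used to roll summary targets up for
#' division-level summaries and matrix row ordering.
#' @export
MAJOR_DIVISIONS <- c(
  "isocortex", "olfactory", "hippocampal", "cortical subplate", "striatum",
  "pallidum", "thalamus", "hypothalamus", "midbrain", "pons", "medulla",
  "cerebellum", "spinal cord"
)

#' Build a region ontology from a node table
#'
#' An ontology is a rooted tree of brain regions. Leaf-level regions flagged
#' `is_summary_target` are the quantification units ("summary targets"); each
#' must sit under exactly one major division.
#'
#' @param nodes data.frame with columns `id`, `acronym`, `parent` (NA for the
#'   root), `is_summary_target` (logical), `major_division` (NA or one of
#'   [MAJOR_DIVISIONS]; only required on, and inherited from, division-level
#'   nodes).
#' @return A `region_ontology` object.
#' @export
region_ontology <- function(nodes) {
  stopifnot(is.data.frame(nodes))
  req <- c("id", "acronym", "parent", "is_summary_target", "major_division")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols))
    stop("ontology nodes missing columns: ", paste(missing_cols, collapse = ", "))
  nodes$id <- as.character(nodes$id)
  nodes$parent <- as.character(nodes$parent)
  nodes$acronym <- as.character(nodes$acronym)
  nodes$is_summary_target <- as.logical(nodes$is_summary_target)
  nodes$major_division <- as.character(nodes$major_division)

  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup)) stop("duplicate ontology id: ", dup[1])
  is_root <- is.na(nodes$parent)
  if (sum(is_root) != 1L)
    stop("ontology must have exactly one root, found ", sum(is_root))
  orphan <- setdiff(nodes$parent[!is_root], nodes$id)
  if (length(orphan)) stop("orphan parent reference: ", orphan[1])

  # cycle check: walk each node to the root
  parent_of <- setNames(nodes$parent, nodes$id)
  for (id in nodes$id) {
    seen <- character()
    cur <- id
    while (!is.na(parent_of[[cur]])) {
      if (cur %in% seen) stop("cycle in ontology at node: ", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }

  bad_div <- nodes$major_division[!is.na(nodes$major_division) &
                                  !(nodes$major_division %in% MAJOR_DIVISIONS)]
  if (length(bad_div)) stop("unknown major division: ", bad_div[1])

  ont <- structure(list(nodes = nodes), class = "region_ontology")
  # every summary target must resolve to exactly one division
  for (id in nodes$id[nodes$is_summary_target]) {
    div <- .ancestral_division(ont, id)
    if (is.na(div))
      stop("summary target has no major division on its root path: ", id)
  }
  ont
}

.ancestral_division <- function(ontology, id) {
  nodes <- ontology$nodes
  parent_of <- setNames(nodes$parent, nodes$id)
  div_of <- setNames(nodes$major_division, nodes$id)
  cur <- id
  while (!is.na(cur)) {
    if (!is.na(div_of[[cur]])) return(div_of[[cur]])
    cur <- parent_of[[cur]]
  }
  NA_character_
}

#' Load a region ontology from a JSON file
#'
#' The file holds a flat JSON list, one object per node with fields `id`,
#' `acronym`, `parent` (null for the root), `is_summary_target`,
#' `major_division` (null where inherited). Names that cannot be resolved are
#' reported, never guessed.
#'
#' @param path path to the JSON ontology file.
#' @return A `region_ontology`.
#' @export
load_ontology <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!is.data.frame(raw)) stop("ontology file must be a JSON list of node objects")
  for (col in c("parent", "major_division"))
    if (!col %in% names(raw)) raw[[col]] <- NA_character_
  if (!"is_summary_target" %in% names(raw)) raw$is_summary_target <- FALSE
  raw$parent[vapply(raw$parent, is.null, TRUE)] <- NA_character_
  region_ontology(raw[, c("id", "acronym", "parent", "is_summary_target",
                          "major_division")])
}

#' Write an ontology to JSON
#' @param ontology a `region_ontology`.
#' @param path output path.
#' @export
write_ontology <- function(ontology, path) {
  jsonlite::write_json(ontology$nodes, path, na = "null", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Summary targets of an ontology, in ontology order
#' @param ontology a `region_ontology`.
#' @return character vector of summary-target region ids.
#' @export
summary_targets <- function(ontology) {
  ontology$nodes$id[ontology$nodes$is_summary_target]
}

#' Enumerate bilateral targets
#'
#' Each summary target appears twice: once for the hemisphere ipsilateral to
#' the injection, once contralateral. Order is deterministic: all ipsi targets
#' in ontology order, then all contra targets in the same order.
#'
#' @param ontology a `region_ontology`.
#' @return data.frame with columns `region`, `hemisphere` ("ipsi"/"contra")
#'   and `label` (`<region>_<hemisphere>`).
#' @export
bilateral_targets <- function(ontology) {
  st <- summary_targets(ontology)
  out <- data.frame(
    region = c(st, st),
    hemisphere = rep(c("ipsi", "contra"), each = length(st)),
    stringsAsFactors = FALSE
  )
  out$label <- paste(out$region, out$hemisphere, sep = "_")
  out
}

#' Major division of a target region
#'
#' Walks parent links from the region to the first ancestor (or the region
#' itself) carrying a major-division annotation.
#'
#' @param ontology a `region_ontology`.
#' @param region region id (the `region` field of a bilateral target).
#' @return division label, one of [MAJOR_DIVISIONS].
#' @export
division_of <- function(ontology, region) {
  if (!region %in% ontology$nodes$id) stop("unknown region: ", region)
  div <- .ancestral_division(ontology, region)
  if (is.na(div)) stop("region has no major division: ", region)
  div
}

#' Division of every summary target
#' @param ontology a `region_ontology`.
#' @return named character vector, names = summary target ids.
#' @export
target_divisions <- function(ontology) {
  st <- summary_targets(ontology)
  vapply(st, function(r) division_of(ontology, r), character(1))
}

#' Generate a synthetic stand-in ontology
#'
#' Builds a three-level tree (root, 13 major divisions, leaf summary targets)
#' with `n_targets` leaves spread across divisions roughly in proportion to
#' the size of the real CCFv3 division target lists. This is a synthetic
#' stand-in for an atlas ontology, not real anatomy; acronyms are generated.
#' With the default `n_targets = 314` it exposes 314 summary targets per
#' hemisphere (628 bilateral targets).
#'
#' @param n_targets number of summary targets (default 314).
#' @return A `region_ontology`.
#' @export
synthetic_ontology <- function(n_targets = 314) {
  stopifnot(n_targets >= length(MAJOR_DIVISIONS))
  # rough relative leaf-counts per division in a whole-brain atlas
  w <- c(43, 22, 18, 8, 12, 8, 45, 22, 30, 20, 40, 28, 18)
  counts <- pmax(1L, as.integer(round(n_targets * w / sum(w))))
  # adjust to hit n_targets exactly
  while (sum(counts) != n_targets) {
    i <- which.max(counts)
    counts[i] <- counts[i] + sign(n_targets - sum(counts))
  }
  div_ids <- gsub("[^a-z]", "", MAJOR_DIVISIONS)
  nodes <- data.frame(
    id = "root", acronym = "BRAIN", parent = NA_character_,
    is_summary_target = FALSE, major_division = NA_character_,
    stringsAsFactors = FALSE
  )
  for (d in seq_along(MAJOR_DIVISIONS)) {
    nodes <- rbind(nodes, data.frame(
      id = div_ids[d], acronym = toupper(substr(div_ids[d], 1, 4)),
      parent = "root", is_summary_target = FALSE,
      major_division = MAJOR_DIVISIONS[d], stringsAsFactors = FALSE
    ))
    leaf <- sprintf("%s_%03d", div_ids[d], seq_len(counts[d]))
    nodes <- rbind(nodes, data.frame(
      id = leaf, acronym = toupper(leaf), parent = div_ids[d],
      is_summary_target = TRUE, major_division = NA_character_,
      stringsAsFactors = FALSE
    ))
  }
  region_ontology(nodes)
}

#' @export
print.region_ontology <- function(x, ...) {
  cat("region_ontology:", nrow(x$nodes), "nodes,",
      sum(x$nodes$is_summary_target), "summary targets\n")
  invisible(x)
}
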