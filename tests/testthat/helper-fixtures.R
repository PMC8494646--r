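# Shared fixtures built in code (no binary files).

# minimal ontology: root -> 2 divisions -> leaves
toy_ontology <- function(n_iso = 2, n_thal = 1, n_str = 0) {
  nodes <- data.frame(
    id = "root", acronym = "BRAIN", parent = NA_character_,
    is_summary_target = FALSE, major_division = NA_character_,
    stringsAsFactors = FALSE
  )
  add_div <- function(nodes, div_id, div_name, n_leaf) {
    if (n_leaf == 0) return(nodes)
    nodes <- rbind(nodes, data.frame(
      id = div_id, acronym = toupper(div_id), parent = "root",
      is_summary_target = FALSE, major_division = div_name,
      stringsAsFactors = FALSE))
    if (n_leaf > 0) {
      leaf <- sprintf("%s%d", div_id, seq_len(n_leaf))
      nodes <- rbind(nodes, data.frame(
        id = leaf, acronym = toupper(leaf), parent = div_id,
        is_summary_target = TRUE, major_division = NA_character_,
        stringsAsFactors = FALSE))
    }
    nodes
  }
  nodes <- add_div(nodes, "iso", "isocortex", n_iso)
  nodes <- add_div(nodes, "thal", "thalamus", n_thal)
  nodes <- add_div(nodes, "str", "striatum", n_str)
  region_ontology(nodes)
}

# brute-force complete-linkage agglomeration on a distance matrix:
# returns merge heights (sorted) and the k-cut partition, independent of hclust
brute_complete_linkage <- function(d, k) {
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  cluster_dist <- function(a, b) max(dm[a, b])
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      dd <- cluster_dist(clusters[[i]], clusters[[j]])
      if (dd < best_d) { best_d <- dd; best <- c(j, i) }
    }
    heights <- c(heights, best_d)
    if (length(clusters) == k) {
      part <- integer(nrow(dm))
      for (g in seq_along(clusters)) part[clusters[[g]]] <- g
      attr(heights, "partition_at_k") <- part
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_enumerate <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); kk <- sum(tab[, 1])
  lo <- max(0, kk - n); hi <- min(kk, m)
  probs <- stats::dhyper(lo:hi, m, n, kk)
  p_obs <- stats::dhyper(tab[1, 1], m, n, kk)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# deterministic partition of equal binary-pattern neurons for entropy tests
planted_binary <- function(n_per = 20, depths = c(200, 600)) {
  b <- matrix(0, 2 * n_per, 4, dimnames = list(NULL, paste0("a", 1:4)))
  b[seq_len(n_per), 1] <- 1
  list(binary = b, depths = rep(depths, each = n_per))
}
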