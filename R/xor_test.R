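#' Pairwise XOR distances between binary projection rows
#'
#' XOR distance = number of regions targeted by exactly one neuron of the
#' pair (Hamming distance of the binary rows).
#'
#' @param binary logical/0-1 matrix neurons x regions.
#' @return numeric vector of all unordered pairwise distances.
#' @export
xor_distances <- function(binary) {
  as.vector(dist(binary != 0, method = "manhattan"))
}

#' Fixed-margin shuffle of a binary matrix (checkerboard swaps)
#'
#' Randomizes a binary matrix while preserving every row sum (targets per
#' neuron) and column sum (neurons per target) exactly, by iterated 2x2
#' checkerboard swaps with a burn-in of `n_swaps` attempted swaps
#' (default 10x the number of ones).
#'
#' @param binary logical/0-1 matrix.
#' @param n_swaps attempted swaps (default `10 * sum(binary)`).
#' @return shuffled 0/1 matrix with identical margins.
#' @export
margin_shuffle <- function(binary, n_swaps = NULL) {
  m <- (binary != 0) * 1L
  nr <- nrow(m); nc <- ncol(m)
  if (is.null(n_swaps)) n_swaps <- 10L * sum(m)
  rows <- sample.int(nr, 2L * n_swaps, replace = TRUE)
  cols <- sample.int(nc, 2L * n_swaps, replace = TRUE)
  for (s in seq_len(n_swaps)) {
    r1 <- rows[2L * s - 1L]; r2 <- rows[2L * s]
    c1 <- cols[2L * s - 1L]; c2 <- cols[2L * s]
    if (r1 == r2 || c1 == c2) next
    a <- m[r1, c1]; b <- m[r1, c2]; cc <- m[r2, c1]; d <- m[r2, c2]
    if (a == 1L && d == 1L && b == 0L && cc == 0L) {
      m[r1, c1] <- 0L; m[r2, c2] <- 0L; m[r1, c2] <- 1L; m[r2, c1] <- 1L
    } else if (a == 0L && d == 0L && b == 1L && cc == 1L) {
      m[r1, c1] <- 1L; m[r2, c2] <- 1L; m[r1, c2] <- 0L; m[r2, c1] <- 0L
    }
  }
  dimnames(m) <- dimnames(binary)
  m
}

# classic (mean-centred) Levene test between two samples; one tailed for
# var(x) > var(y). With two groups the Levene W equals the squared t on the
# absolute deviations, so the one-tailed p comes straight from the t test.
.levene_one_tailed <- function(x, y) {
  zx <- abs(x - mean(x)); zy <- abs(y - mean(y))
  if (sd(c(zx, zy)) == 0) return(list(statistic = 0, p = 1))
  tt <- t.test(zx, zy, alternative = "greater", var.equal = TRUE)
  list(statistic = unname(tt$statistic)^2, p = tt$p.value)
}

#' XOR-distance projection discreteness test
#'
#' Compares the spread of observed pairwise XOR distances with the spread
#' under fixed-margin shuffles of the binary projection matrix (the null of
#' continuous targeting consistent with the regional projection pattern).
#' Discrete projection types inflate the variance of the observed
#' distribution; the one-tailed Levene test asks whether the observed
#' variance exceeds the shuffled one.
#'
#' @param binary logical/0-1 matrix neurons x regions.
#' @param n_shuffles shuffled matrices pooled into the null distribution.
#' @param seed RNG seed.
#' @param null "margin" (default, checkerboard fixed-margin) or "bernoulli"
#'   (independent per-region draws at the observed region frequencies).
#' @return list with `actual`, `shuffled` distance vectors, `levene_W`,
#'   `p` (one-tailed) and the variances.
#' @export
xor_discreteness_test <- function(binary, n_shuffles = 100, seed = 1L,
                                  null = c("margin", "bernoulli")) {
  null <- match.arg(null)
  binary <- (binary != 0) * 1L
  if (nrow(binary) < 3) stop("need at least 3 neurons")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed %% 2147483647L)
  actual <- xor_distances(binary)
  shuffled <- unlist(lapply(seq_len(n_shuffles), function(s) {
    mm <- if (null == "margin") margin_shuffle(binary)
          else matrix(rbinom(length(binary), 1, rep(colMeans(binary),
                                                    each = nrow(binary))),
                      nrow = nrow(binary))
    xor_distances(mm)
  }))
  if (var(actual) == 0)
    return(list(actual = actual, shuffled = shuffled, levene_W = 0, p = 1,
                var_actual = 0, var_shuffled = var(shuffled)))
  lev <- .levene_one_tailed(actual, shuffled)
  list(actual = actual, shuffled = shuffled, levene_W = lev$statistic,
       p = lev$p, var_actual = var(actual), var_shuffled = var(shuffled))
}
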