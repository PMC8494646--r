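#' Non-negative least squares (Lawson–Hanson active set)
#'
#' Solves `argmin_x ||A x - b||_2` subject to `x >= 0`.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector (length m).
#' @param tol active-set tolerance.
#' @return list with `x`, `rss` (residual sum of squares) and `iterations`.
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  m <- nrow(A); n <- ncol(A)
  x <- numeric(n)
  P <- logical(n)               # passive (free) set
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 30L * n
  while (any(!P) && any(w[!P] > tol)) {
    iter <- iter + 1L
    if (iter > max_iter) break
    j <- which(!P)[which.max(w[!P])]
    P[j] <- TRUE
    repeat {
      Ap <- A[, P, drop = FALSE]
      z <- numeric(n)
      z[P] <- drop(qr.coef(qr(Ap), b))
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      P[P & x <= tol] <- FALSE
      x[!P] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  r <- b - A %*% x
  list(x = x, rss = sum(r^2), iterations = iter)
}

#' Bounded-variable least squares
#'
#' Solves `argmin_x ||A x - b||_2` subject to `lower <= x <= upper`, as a
#' box-constrained quadratic program via L-BFGS-B with analytic gradient.
#' A deliberately different algorithmic route from [nnls_solve()], so the
#' two can cross-check each other.
#'
#' @param A numeric matrix; @param b numeric vector.
#' @param lower,upper scalar or per-coefficient bounds.
#' @return list with `x` and `rss`.
#' @export
bvls_solve <- function(A, b, lower = 0.01, upper = 1) {
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  fn <- function(x) sum((A %*% x - b)^2)
  gr <- function(x) 2 * (AtA %*% x - Atb)
  x0 <- pmin(pmax(rep(mean(c(lower, upper)), n), lower), upper)
  fit <- optim(x0, fn, gr, method = "L-BFGS-B",
               lower = rep(lower, length.out = n),
               upper = rep(upper, length.out = n),
               control = list(factr = 1e2, maxit = 500))
  list(x = fit$par, rss = fit$value)
}

#' Estimate cluster composition of a bulk projection pattern
#'
#' Columns of A are the mean fraction vectors of eligible single-cell
#' clusters (those with at least `min_cluster_size` members); b is the bulk
#' regional pattern. Solves b ~ A x by NNLS (default) or BVLS with the given
#' bounds; reports raw coefficients, proportions renormalized to sum 1, and
#' the residual sum of squares as a fraction of ||b||^2.
#'
#' @param fractions single-cell fraction matrix (neurons x regions).
#' @param cluster cluster label per neuron.
#' @param bulk named numeric bulk pattern over the same regions.
#' @param min_cluster_size minimum neurons for an eligible cluster
#'   (default 15).
#' @param method "nnls" or "bvls".
#' @param bounds length-2 (lower, upper) for BVLS (default c(0.01, 1)).
#' @return object of class `composition_estimate`: list with `x` (raw),
#'   `proportions`, `rss_relative`, `method`, `clusters`, `A`, `excluded`.
#' @export
estimate_composition <- function(fractions, cluster, bulk,
                                 min_cluster_size = 15,
                                 method = c("nnls", "bvls"),
                                 bounds = c(0.01, 1)) {
  method <- match.arg(method)
  stopifnot(length(cluster) == nrow(fractions))
  sizes <- table(cluster)
  eligible <- names(sizes)[sizes >= min_cluster_size]
  excluded <- setdiff(names(sizes), eligible)
  if (length(eligible) < 2) stop("fewer than 2 eligible clusters")
  if (is.null(names(bulk))) names(bulk) <- colnames(fractions)
  regions <- colnames(fractions)
  stopifnot(all(regions %in% names(bulk)))
  b <- bulk[regions]
  A <- vapply(eligible, function(cl)
    colMeans(fractions[cluster == cl, , drop = FALSE]), numeric(length(regions)))
  if (qr(A)$rank < ncol(A))
    warning("cluster-mean matrix is rank deficient; solution not unique")
  fit <- if (method == "nnls") nnls_solve(A, b)
         else bvls_solve(A, b, bounds[1], bounds[2])
  x <- fit$x
  props <- if (sum(x) > 0) x / sum(x) else x
  structure(list(
    x = setNames(x, eligible), proportions = setNames(props, eligible),
    rss_relative = fit$rss / sum(b^2), method = method,
    clusters = eligible, A = A, excluded = excluded,
    bounds = if (method == "bvls") bounds else NULL
  ), class = "composition_estimate")
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("composition_estimate (", x$method, "), relative RSS ",
      format(x$rss_relative, digits = 3), "\n", sep = "")
  print(round(x$proportions, 4))
  invisible(x)
}
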