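## Square-root velocity representation of composite curves.
##
## A curve P (one column per sample) is parameterized by normalized
## cumulative spatial arc length T in [0,1] and represented by
## q(t) = v(t) / sqrt(||v(t)||) with v = dP/dT, under which the elastic
## metric is the ordinary L2 metric and translation and scale drop out.

#' Normalized arc-length parameterization of a composite curve
#'
#' Cumulative Euclidean distance over the three spatial rows only, divided
#' by the total length. Zero-length spatial segments (duplicate points) are
#' collapsed by dropping the duplicate column from the curve.
#'
#' @param curve An `esa_curve` or a `(3+k) x n` numeric matrix.
#' @return A list of class `esa_param`: `grid` (values in `[0,1]`, first 0,
#'   last 1, strictly increasing), `curve` (possibly deduplicated),
#'   `dropped` (indices of removed columns).
#' @export
arc_length_param <- function(curve) {
  P <- if (inherits(curve, "esa_curve")) curve$values else as.matrix(curve)
  if (ncol(P) < 2L) stop("curve must have at least 2 columns")
  seg <- sqrt(colSums((P[1:3, -1L, drop = FALSE] -
                       P[1:3, -ncol(P), drop = FALSE])^2))
  dropped <- integer(0)
  if (any(seg < 1e-12)) {
    dropped <- which(seg < 1e-12) + 1L
    P <- P[, -dropped, drop = FALSE]
    if (ncol(P) < 2L) stop("degenerate curve: all points coincide")
    seg <- sqrt(colSums((P[1:3, -1L, drop = FALSE] -
                         P[1:3, -ncol(P), drop = FALSE])^2))
    message("dropped ", length(dropped),
            " duplicate point(s) (zero-length spatial segments)")
  }
  total <- sum(seg)
  if (total <= 0) stop("degenerate curve: total spatial length is zero")
  grid <- c(0, cumsum(seg)) / total
  grid[length(grid)] <- 1
  if (inherits(curve, "esa_curve")) curve$values <- P else curve <- P
  structure(list(grid = grid, curve = curve, dropped = dropped),
            class = "esa_param")
}

#' Square-root velocity transform
#'
#' Differentiates the piecewise-linear curve with respect to its parameter
#' grid (three-point nonuniform central differences in the interior,
#' one-sided at the ends) and maps each derivative column `v` to
#' `v / sqrt(||v||)`. Zero-derivative columns map to zero.
#'
#' @param curve An `esa_curve`, matrix, or the `esa_param` result of
#'   [arc_length_param()] (in which case `grid` is taken from it).
#' @param grid Parameter grid matching the curve columns; ignored when
#'   `curve` is an `esa_param`.
#' @return An object of class `esa_srvf`: list with `values`, `grid`, `k`.
#' @export
srvf_transform <- function(curve, grid = NULL) {
  if (inherits(curve, "esa_param")) {
    grid <- curve$grid
    curve <- curve$curve
  }
  P <- if (inherits(curve, "esa_curve")) curve$values else as.matrix(curve)
  if (is.null(grid)) stop("a parameter grid is required")
  n <- ncol(P)
  if (length(grid) != n) stop("grid length does not match curve columns")
  V <- matrix(0, nrow(P), n)
  V[, 1L] <- (P[, 2L] - P[, 1L]) / (grid[2L] - grid[1L])
  V[, n] <- (P[, n] - P[, n - 1L]) / (grid[n] - grid[n - 1L])
  if (n > 2L) {
    i <- 2:(n - 1L)
    h1 <- grid[i] - grid[i - 1L]
    h2 <- grid[i + 1L] - grid[i]
    w_m <- -h2 / (h1 * (h1 + h2))
    w_0 <- (h2 - h1) / (h1 * h2)
    w_p <- h1 / (h2 * (h1 + h2))
    V[, i] <- P[, i - 1L, drop = FALSE] %*% diag(w_m, length(i)) +
      P[, i, drop = FALSE] %*% diag(w_0, length(i)) +
      P[, i + 1L, drop = FALSE] %*% diag(w_p, length(i))
  }
  nv <- sqrt(colSums(V^2))
  scale <- ifelse(nv < 1e-15, 0, 1 / sqrt(nv))
  Q <- V %*% diag(scale, n)
  structure(list(values = Q, grid = grid, k = nrow(P) - 3L),
            class = "esa_srvf")
}

#' Merge two parameter grids
#'
#' Sorted union of the two grids with duplicates removed under a tolerance.
#' The result length `n` satisfies `max(n1, n2) <= n <= n1 + n2 - 2` for
#' grids sharing the endpoints 0 and 1.
#'
#' @param t1,t2 Numeric grids (each from 0 to 1, strictly increasing).
#' @param tol Collapse tolerance (default `1e-12`); of two values closer
#'   than `tol` the first is kept.
#' @return The merged grid.
#' @export
merge_grids <- function(t1, t2, tol = 1e-12) {
  v <- sort(c(t1, t2))
  keep <- c(TRUE, diff(v) > tol)
  out <- v[keep]
  out[1L] <- 0
  out[length(out)] <- 1
  out
}

#' Resample an SRVF onto a new grid
#'
#' Piecewise-linear interpolation of each row onto `t_new`.
#'
#' @param Q An `esa_srvf`.
#' @param t_new Target grid, contained in `[0, 1]`.
#' @return An `esa_srvf` on `t_new`.
#' @export
resample_srvf <- function(Q, t_new) {
  stopifnot(inherits(Q, "esa_srvf"))
  if (min(t_new) < -1e-12 || max(t_new) > 1 + 1e-12)
    stop("target grid outside [0, 1]")
  vals <- t(apply(Q$values, 1L, function(row)
    stats::approx(Q$grid, row, xout = t_new, rule = 2)$y))
  if (length(t_new) == 1L) vals <- matrix(vals, ncol = 1L)
  structure(list(values = vals, grid = t_new, k = Q$k), class = "esa_srvf")
}

## Trapezoidal cell widths: weight of column i in the discrete L2 product.
.grid_weights <- function(grid) {
  n <- length(grid)
  d <- diff(grid)
  c(d[1L] / 2, if (n > 2L) (d[-1L] + d[-(n - 1L)]) / 2, d[n - 1L] / 2)
}

#' Discrete L2 inner product of two SRVFs on a common grid
#'
#' `sum_i <q1(i), q2(i)> w_i` with trapezoidal cell weights `w_i` from the
#' shared grid.
#'
#' @param Q1,Q2 `esa_srvf` objects on identical grids.
#' @return A scalar.
#' @export
srvf_inner_product <- function(Q1, Q2) {
  stopifnot(inherits(Q1, "esa_srvf"), inherits(Q2, "esa_srvf"))
  if (length(Q1$grid) != length(Q2$grid) ||
      max(abs(Q1$grid - Q2$grid)) > 1e-12)
    stop("SRVFs are not on a common grid")
  sum(colSums(Q1$values * Q2$values) * .grid_weights(Q1$grid))
}

#' Normalize an SRVF to unit L2 norm
#'
#' @param Q An `esa_srvf` with positive norm.
#' @return The rescaled `esa_srvf`, with `<Q, Q> = 1`.
#' @export
normalize_srvf <- function(Q) {
  nrm <- srvf_inner_product(Q, Q)
  if (nrm <= 1e-300) stop("cannot normalize a zero-norm SRVF")
  Q$values <- Q$values / sqrt(nrm)
  Q
}

#' @export
print.esa_srvf <- function(x, ...) {
  cat("SRVF: ", nrow(x$values), " x ", ncol(x$values), " on grid of ",
      length(x$grid), " points (k = ", x$k, ")\n", sep = "")
  invisible(x)
}
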