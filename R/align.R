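## Alignment of two SRVFs: optimal rotation (Kabsch/Procrustes via SVD),
## optimal reparameterization (dynamic programming on the matching graph),
## and the geodesic shape distance theta = acos(<Q1, Q2*>).

#' Optimal rotation between two SRVFs (Kabsch / Procrustes)
#'
#' Computes the proper rotation maximizing the grid-weighted inner product
#' of the spatial rows: the cross-covariance
#' `A = Q1_spatial W Q2_spatial^T` (W = trapezoidal cell weights) is
#' decomposed as `A = U S V^T` and the reflection-safe solution
#' `R = U diag(1, 1, det(U V^T)) V^T` returned. Auxiliary rows are left
#' untouched: the full rotation is the block-diagonal `(3+k) x (3+k)`
#' matrix `blockdiag(R, I_k)`.
#'
#' @param Q1,Q2 `esa_srvf` objects on a common grid with equal `k`.
#' @return An object of class `esa_rotation`: list with `spatial` (3 x 3),
#'   `full` ((3+k) x (3+k)) and `k`.
#' @export
optimal_rotation <- function(Q1, Q2) {
  stopifnot(inherits(Q1, "esa_srvf"), inherits(Q2, "esa_srvf"))
  if (Q1$k != Q2$k) stop("auxiliary dimensions differ")
  if (length(Q1$grid) != length(Q2$grid) ||
      max(abs(Q1$grid - Q2$grid)) > 1e-12)
    stop("SRVFs are not on a common grid")
  w <- .grid_weights(Q1$grid)
  A <- Q1$values[1:3, , drop = FALSE] %*%
    (t(Q2$values[1:3, , drop = FALSE]) * w)
  if (qr(A)$rank < 2L)
    warning("near-degenerate cross-covariance (rank < 2); ",
            "rotation may be poorly determined")
  sv <- svd(A)
  d <- det(sv$u %*% t(sv$v))
  R <- sv$u %*% diag(c(1, 1, sign(d))) %*% t(sv$v)
  full <- diag(3L + Q1$k)
  full[1:3, 1:3] <- R
  structure(list(spatial = R, full = full, k = Q1$k),
            class = "esa_rotation")
}

#' Apply an augmented rotation to an SRVF
#'
#' Premultiplies the columns by the full block-diagonal rotation: spatial
#' rows rotate, auxiliary rows pass through. The grid is unchanged.
#'
#' @param Q An `esa_srvf`.
#' @param rotation An `esa_rotation` (or a plain 3 x 3 rotation matrix).
#' @return The rotated `esa_srvf`.
#' @export
apply_rotation <- function(Q, rotation) {
  stopifnot(inherits(Q, "esa_srvf"))
  if (is.matrix(rotation)) {
    if (!all(dim(rotation) == c(3L, 3L)))
      stop("plain rotation must be 3 x 3")
    R <- diag(3L + Q$k)
    R[1:3, 1:3] <- rotation
  } else {
    stopifnot(inherits(rotation, "esa_rotation"))
    if (rotation$k != Q$k) stop("rotation/SRVF dimension mismatch")
    R <- rotation$full
  }
  Q$values <- R %*% Q$values
  Q
}

#' Elastic cost of matching one grid segment against another
#'
#' Squared-L2 cost of matching segment `[T[i], T[ip]]` of `Q1` against
#' `[T[j], T[jp]]` of `Q2` under the linear warp `gamma` between them,
#' with the square-root velocity warp factor:
#' `int ||q1(t) - sqrt(gamma') q2(gamma(t))||^2 dt`, evaluated by
#' trapezoidal quadrature on the union of the grid points in the segment
#' and the preimages of the target-segment grid points.
#'
#' @param Q1,Q2 `esa_srvf` objects on a common grid.
#' @param i,ip Start/end indices (1-based) of the segment on `Q1`; `i < ip`.
#' @param j,jp Likewise on `Q2`; `j < jp`.
#' @return Non-negative scalar cost.
#' @export
matching_cost <- function(Q1, Q2, i, ip, j, jp) {
  stopifnot(inherits(Q1, "esa_srvf"), inherits(Q2, "esa_srvf"))
  if (!(i < ip && j < jp)) stop("segment indices must be strictly increasing")
  esa_edge_cost_cpp(Q1$values, Q2$values, Q1$grid, i, ip, j, jp)
}

#' Optimal monotone matching by dynamic programming
#'
#' Minimum-total-cost strictly monotone path from `(1, 1)` to `(n, n)` on
#' the n x n matching graph with jump window `window` in each direction;
#' edge weights are [matching_cost()] segment costs. The graph is a DAG, so
#' a single topological-order pass finds the all-pairs-shortest-path
#' optimum. Returns the warp `gamma` through the visited vertices and the
#' warped second SRVF `q2*(t) = sqrt(gamma'(t)) q2(gamma(t))` sampled on
#' the common grid.
#'
#' @param Q1,Q2 `esa_srvf` objects on a common grid of length `n >= 2`.
#' @param window Maximum index jump per step (default 5).
#' @return An object of class `esa_matching`: list with `gamma_values` (G),
#'   `change_points` (T_g), `matched_cost`, `warped` (an `esa_srvf`),
#'   `path_i`, `path_j`.
#' @export
optimal_matching <- function(Q1, Q2, window = 5L) {
  stopifnot(inherits(Q1, "esa_srvf"), inherits(Q2, "esa_srvf"))
  Tg <- Q1$grid
  if (length(Tg) < 2L) stop("grid must have at least 2 points")
  if (length(Tg) != length(Q2$grid) || max(abs(Tg - Q2$grid)) > 1e-12)
    stop("SRVFs are not on a common grid")
  res <- esa_dp_match_cpp(Q1$values, Q2$values, Tg, as.integer(window))
  tg <- Tg[res$path_i]
  G <- Tg[res$path_j]
  warped <- .apply_warp(Q2, tg, G)
  structure(list(gamma_values = G, change_points = tg,
                 matched_cost = res$cost, warped = warped,
                 path_i = res$path_i, path_j = res$path_j),
            class = "esa_matching")
}

## Warp an SRVF by the piecewise-linear gamma through (tg, G): sample
## q2*(t) = sqrt(slope) * q2(gamma(t)) on the SRVF's own grid. At interior
## change points the slope of the right-hand segment is used (left-hand for
## the final point); gamma is strictly increasing by construction.
.apply_warp <- function(Q, tg, G) {
  grid <- Q$grid
  seg <- pmin(findInterval(grid, tg), length(tg) - 1L)
  slope <- (G[seg + 1L] - G[seg]) / (tg[seg + 1L] - tg[seg])
  gt <- G[seg] + slope * (grid - tg[seg])
  vals <- t(apply(Q$values, 1L, function(row)
    stats::approx(grid, row, xout = pmin(pmax(gt, 0), 1), rule = 2)$y))
  vals <- vals * rep(sqrt(slope), each = nrow(vals))
  structure(list(values = vals, grid = grid, k = Q$k), class = "esa_srvf")
}

#' Geodesic shape distance between two aligned SRVFs
#'
#' Re-merges the two grids, normalizes both SRVFs to unit L2 norm, computes
#' the grid-weighted inner product `d`, clamps it to `[-1, 1]` and returns
#' `theta = acos(d)` (radians). Clamping in excess of `1e-6` triggers a
#' warning.
#'
#' @param Q1,Q2 `esa_srvf` objects (typically `Q1` and the rotated+warped
#'   second SRVF).
#' @return List of class `esa_geodesic` with `theta`, `cosine`, `grid`.
#' @export
geodesic_distance <- function(Q1, Q2) {
  stopifnot(inherits(Q1, "esa_srvf"), inherits(Q2, "esa_srvf"))
  Tr <- merge_grids(Q1$grid, Q2$grid)
  Q1r <- normalize_srvf(resample_srvf(Q1, Tr))
  Q2r <- normalize_srvf(resample_srvf(Q2, Tr))
  d <- srvf_inner_product(Q1r, Q2r)
  if (abs(d) > 1 + 1e-6)
    warning("inner product ", format(d), " clamped to [-1, 1]")
  d <- min(1, max(-1, d))
  structure(list(theta = acos(d), cosine = d, grid = Tr),
            class = "esa_geodesic")
}

#' Compare two protein structures by elastic shape analysis
#'
#' End-to-end pipeline: build the composite curve for each structure
#' (geometry per `criterion` plus dihedral and property channels),
#' arc-length parameterize, transform to square-root velocity functions,
#' resample both onto the merged grid, optimally rotate the second curve
#' (SVD/Kabsch), optimally reparameterize it (dynamic programming), and
#' score the pair by the geodesic distance
#' `theta = acos(<Q1, Q2*>)` on the unit sphere of normalized SRVFs.
#' `theta = 0` means identical shape (up to translation, scale, rotation
#' and reparameterization); larger values mean greater dissimilarity.
#'
#' @param x,y Each a PDB file path (or raw PDB text), an `esa_structure`,
#'   or an `esa_chain`.
#' @param model,chain Length-2 model numbers / chain ids used when `x`/`y`
#'   need selection (defaults: model 1, first chain).
#' @param criterion `"ESA-CA"` (default), `"ESA-BB"` or `"ESA-MC-BB"`.
#' @param feature_set Property channels, subset of
#'   `c("HP", "POL", "MASS", "GROUP", "SC-ATOMS")` (default: none; the
#'   dihedral channels are always present for ESA-CA / ESA-MC-BB).
#' @param window Dynamic-programming jump window (default 5).
#' @param max_iter Rotation/matching alternation count (default 1, a single
#'   rotation pass followed by a single matching pass).
#' @param tol Convergence tolerance on theta for `max_iter > 1`.
#' @param table,scaling,weights,aux_scale,dihedral_encoding Passed to
#'   [build_curve()].
#' @return An object of class `esa_alignment` with components `theta`,
#'   `cosine`, `rotation`, `matching`, `criterion`, `feature_set`,
#'   `n_res` (residues used per structure), `n_grid`, `timings` (seconds
#'   per stage) and `call`.
#' @examples
#' helix <- make_chain(fixture_spec(30, "helix", seed = 1))
#' strand <- make_chain(fixture_spec(30, "strand", seed = 2))
#' esa_compare(helix, strand)
#' @export
esa_compare <- function(x, y, model = c(1L, 1L), chain = c(NA, NA),
                        criterion = c("ESA-CA", "ESA-BB", "ESA-MC-BB"),
                        feature_set = character(0), window = 5L,
                        max_iter = 1L, tol = 1e-6,
                        table = default_property_table(),
                        scaling = "standardize", weights = NULL,
                        aux_scale = 0.2,
                        dihedral_encoding = c("cossin", "raw")) {
  dihedral_encoding <- match.arg(dihedral_encoding)
  criterion <- match.arg(criterion)
  cl <- match.call()
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- tic() - t0
    out
  }

  ch1 <- stage("structure_io", .as_chain(x, model[1L], chain[1L]))
  ch2 <- stage("structure_io", .as_chain(y, model[2L], chain[2L]))
  P1 <- stage("curve_model",
              build_curve(ch1, criterion, feature_set, table,
                          scaling, weights, aux_scale, dihedral_encoding))
  P2 <- stage("curve_model",
              build_curve(ch2, criterion, feature_set, table,
                          scaling, weights, aux_scale, dihedral_encoding))
  srvf <- stage("srvf", {
    par1 <- arc_length_param(P1)
    par2 <- arc_length_param(P2)
    Tm <- merge_grids(par1$grid, par2$grid)
    ## unit-norm on the common grid: the scale quotient must be taken
    ## before rotation and matching, or the warp absorbs norm mismatch
    list(Q1 = normalize_srvf(resample_srvf(srvf_transform(par1), Tm)),
         Q2 = normalize_srvf(resample_srvf(srvf_transform(par2), Tm)))
  })
  Q1 <- srvf$Q1
  Q2 <- srvf$Q2

  theta_prev <- Inf
  rot <- match_res <- geo <- NULL
  Q2cur <- Q2
  for (it in seq_len(max(1L, max_iter))) {
    rot_it <- stage("rotation", optimal_rotation(Q1, Q2cur))
    Q2R <- apply_rotation(Q2cur, rot_it)
    match_it <- stage("matching", optimal_matching(Q1, Q2R, window))
    geo_it <- stage("distance", geodesic_distance(Q1, match_it$warped))
    rot <- if (is.null(rot)) rot_it else {
      combined <- rot_it
      combined$spatial <- rot_it$spatial %*% rot$spatial
      combined$full <- rot_it$full %*% rot$full
      combined
    }
    match_res <- match_it
    geo <- geo_it
    if (abs(theta_prev - geo_it$theta) < tol) break
    theta_prev <- geo_it$theta
    Q2cur <- match_it$warped
  }

  structure(list(theta = geo$theta, cosine = geo$cosine, rotation = rot,
                 matching = match_res, criterion = criterion,
                 feature_set = feature_set,
                 n_res = c(length(ch1$code3), length(ch2$code3)),
                 ids = c(ch1$pdb_id, ch2$pdb_id),
                 n_grid = length(Q1$grid), timings = timings, call = cl),
            class = "esa_alignment")
}

.as_chain <- function(x, model_id, chain_id) {
  if (inherits(x, "esa_chain")) {
    if (!x$validated) x <- esa_validate_chain(x)
    return(x)
  }
  if (is.character(x)) x <- esa_read_pdb(x)
  if (!inherits(x, "esa_structure"))
    stop("input must be a PDB path/text, esa_structure or esa_chain")
  if (is.na(model_id)) model_id <- 1L
  ch <- esa_select_chain(x, model_id,
                         if (is.na(chain_id)) NULL else chain_id)
  esa_validate_chain(ch)
}

#' @export
print.esa_alignment <- function(x, digits = 4, ...) {
  cat("Elastic shape alignment [", x$criterion,
      if (length(x$feature_set))
        paste0(" + ", paste(x$feature_set, collapse = "+")) else "",
      "]\n", sep = "")
  cat("  structures: ", x$ids[1L], " (", x$n_res[1L], " res) vs ",
      x$ids[2L], " (", x$n_res[2L], " res)\n", sep = "")
  cat("  geodesic distance theta = ", format(x$theta, digits = digits),
      " rad (cos = ", format(x$cosine, digits = digits), ")\n", sep = "")
  invisible(x)
}

#' @export
summary.esa_alignment <- function(object, ...) {
  print(object, ...)
  cat("  merged grid: ", object$n_grid, " points; matched cost = ",
      format(object$matching$matched_cost, digits = 4), "\n", sep = "")
  g <- object$matching
  dev <- max(abs(g$gamma_values - g$change_points))
  cat("  warp: ", length(g$change_points), " change points, max |gamma(t) - t| = ",
      format(dev, digits = 3), "\n", sep = "")
  cat("  timings (s): ",
      paste(names(object$timings),
            sprintf("%.3f", unlist(object$timings)), collapse = ", "),
      "\n", sep = "")
  invisible(object)
}

#' Plot the optimal warp of an alignment
#'
#' Draws the reparameterization function `gamma` against the identity;
#' departures from the diagonal show where one curve is locally stretched
#' or compressed relative to the other.
#'
#' @param x An `esa_alignment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.esa_alignment <- function(x, ...) {
  g <- x$matching
  graphics::plot(g$change_points, g$gamma_values, type = "l",
                 xlab = "t (curve 1)", ylab = "gamma(t) (curve 2)",
                 main = sprintf("Optimal warp (theta = %.4f rad)", x$theta),
                 ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Serialize an alignment result to JSON
#'
#' @param x An `esa_alignment`.
#' @param file Optional output path.
#' @return JSON string, invisibly when written to file.
#' @export
esa_report <- function(x, file = NULL) {
  stopifnot(inherits(x, "esa_alignment"))
  rep <- list(theta = x$theta, cosine = x$cosine,
              criterion = x$criterion,
              feature_set = as.list(x$feature_set),
              n_residues = as.list(stats::setNames(x$n_res, x$ids)),
              n_grid = x$n_grid,
              gamma = list(change_points = x$matching$change_points,
                           values = x$matching$gamma_values),
              matched_cost = x$matching$matched_cost)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
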