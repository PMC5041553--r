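## Deterministic synthetic protein backbones: stylized helix, strand and
## random-coil C-alpha traces with N and C atoms on the local tangent, so
## every pipeline stage is testable without downloading real structures.

#' Specification of a synthetic chain
#'
#' @param n_residues Number of residues (>= 2).
#' @param family `"helix"` (radius 2.3 A, rise 1.5 A/residue, 100
#'   degrees/residue), `"strand"` (3.5 A axial spacing with a +/-1 A
#'   zigzag) or `"coil"` (smoothed random walk with 3.8 A steps).
#' @param sequence Three-letter codes recycled to `n_residues`
#'   (default poly-ALA).
#' @param noise_sigma Gaussian noise added per coordinate, in Angstrom.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A list of class `esa_fixture_spec`.
#' @export
fixture_spec <- function(n_residues, family = c("helix", "strand", "coil"),
                         sequence = "ALA", noise_sigma = 0, seed = 1L) {
  family <- match.arg(family)
  if (n_residues < 2L) stop("n_residues must be >= 2")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_residues = as.integer(n_residues), family = family,
                 sequence = rep_len(toupper(sequence), n_residues),
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "esa_fixture_spec")
}

#' Generate a synthetic chain
#'
#' Builds an ideal C-alpha trace for the requested family, places N and C
#' at -0.75 A and +0.75 A along the local tangent from each C-alpha, then
#' adds independent Gaussian noise per coordinate. The geometry is
#' stylized, not Ramachandran-accurate: the pipeline consumes only
#' coordinates and residue identities.
#'
#' @param spec An `esa_fixture_spec`.
#' @return A validated `esa_chain`.
#' @export
make_chain <- function(spec) {
  stopifnot(inherits(spec, "esa_fixture_spec"))
  m <- spec$n_residues
  old <- .save_seed()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(spec$seed)
  ca <- switch(spec$family,
    helix = {
      i <- seq_len(m) - 1L
      ang <- i * 100 * pi / 180
      cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
    },
    strand = {
      i <- seq_len(m) - 1L
      cbind(3.5 * i, rep_len(c(1, -1), m), 0)
    },
    coil = {
      dirs <- matrix(stats::rnorm(3L * m), m, 3L)
      ## smooth the walk a little so consecutive steps correlate
      for (r in 2:m) dirs[r, ] <- 0.6 * dirs[r - 1L, ] + 0.4 * dirs[r, ]
      dirs <- dirs / sqrt(rowSums(dirs^2))
      apply(3.8 * dirs, 2L, cumsum)
    })
  if (m == 2L && spec$family == "coil") ca <- matrix(ca, 2L, 3L)
  tang <- matrix(0, m, 3L)
  tang[-m, ] <- ca[-1L, , drop = FALSE] - ca[-m, , drop = FALSE]
  tang[m, ] <- tang[m - 1L, ]
  tang <- tang / sqrt(rowSums(tang^2))
  N <- ca - 0.75 * tang
  C <- ca + 0.75 * tang
  if (spec$noise_sigma > 0) {
    N <- N + stats::rnorm(3L * m, sd = spec$noise_sigma)
    ca <- ca + stats::rnorm(3L * m, sd = spec$noise_sigma)
    C <- C + stats::rnorm(3L * m, sd = spec$noise_sigma)
  }
  sc <- default_property_table()[map_residue_code(spec$sequence),
                                 "sidechain_atoms"]
  structure(list(pdb_id = paste0("syn-", spec$family, "-", spec$seed),
                 model_id = 1L, chain_id = "A",
                 code3 = spec$sequence, resno = seq_len(m),
                 n = N, ca = ca, c = C,
                 sidechain_atoms = as.integer(sc), validated = TRUE,
                 dropped = integer(0)),
            class = "esa_chain")
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Apply a rigid motion to a chain
#'
#' @param chain An `esa_chain`.
#' @param rotation 3 x 3 proper rotation matrix (orthogonal, det +1).
#' @param translation 3-vector, Angstrom.
#' @return The transformed `esa_chain` (residue identities unchanged).
#' @export
rigid_motion <- function(chain, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(chain, "esa_chain"))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 ||
      abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be orthogonal with det +1")
  tr <- function(X) sweep(X %*% t(rotation), 2L, -translation)
  chain$n <- tr(chain$n)
  chain$ca <- tr(chain$ca)
  chain$c <- tr(chain$c)
  chain
}

#' Random proper rotation matrix
#'
#' Uniform (Haar) rotation from the QR decomposition of a Gaussian matrix,
#' sign-corrected to det +1.
#'
#' @param seed Optional integer seed.
#' @return A 3 x 3 rotation matrix.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) {
    old <- .save_seed()
    on.exit(.restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

#' Generate a labelled synthetic dataset
#'
#' Produces `per_class` noisy variants of each base specification
#' (variant seeds derived deterministically from `seed`), optionally
#' writing PDB files and a two-column (id, class) labels table.
#'
#' @param base_specs List of `esa_fixture_spec`, one per class; class names
#'   taken from the list names (default family names).
#' @param per_class Variants per class.
#' @param noise_sigma Noise level applied to every variant (overrides the
#'   base specs' value).
#' @param seed Master seed.
#' @param dir Optional output directory for PDB files + `labels.tsv`.
#' @return List with `chains` (named list of `esa_chain`), `labels`
#'   (data frame: id, class) and `files` (paths, or `NULL`).
#' @export
make_dataset <- function(base_specs, per_class = 5L, noise_sigma = 0.05,
                         seed = 1L, dir = NULL) {
  n_classes <- length(base_specs)
  if (!n_classes) stop("at least one base spec required")
  cls_names <- names(base_specs) %||%
    vapply(base_specs, function(s) s$family, character(1))
  chains <- list()
  ids <- classes <- character(0)
  for (ci in seq_len(n_classes)) {
    base <- base_specs[[ci]]
    for (v in seq_len(per_class)) {
      sp <- base
      sp$noise_sigma <- noise_sigma
      sp$seed <- as.integer((seed * 1000L + ci * 100L + v) %% .Machine$integer.max)
      id <- sprintf("%s_%02d", cls_names[ci], v)
      ch <- make_chain(sp)
      ch$pdb_id <- id
      chains[[id]] <- ch
      ids <- c(ids, id)
      classes <- c(classes, cls_names[ci])
    }
  }
  labels <- data.frame(id = ids, class = classes)
  files <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, paste0(ids, ".pdb"))
    for (i in seq_along(ids)) esa_write_pdb(chains[[ids[i]]], files[i])
    utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(chains = chains, labels = labels, files = files)
}
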