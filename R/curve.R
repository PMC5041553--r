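#' Build the composite input curve for a chain
#'
#' Stacks the `3 x n` geometric coordinates selected by `criterion` with
#' auxiliary rows: for `ESA-CA` and `ESA-MC-BB` the backbone dihedral
#' channels (phi, psi, omega) are always included, followed by the
#' requested residue property channels; for `ESA-BB` only the property
#' channels are used, each residue's values repeated across its three atom
#' columns.
#'
#' Dihedrals are angles on a circle; the default `dihedral_encoding =
#' "cossin"` embeds each as a (cos, sin) pair (6 rows), which is continuous
#' across the `+/-pi` cut where trans-peptide omega sits -- a raw-radian
#' row flips by `2 pi` there under tiny coordinate perturbations.
#' `"raw"` stores single rows of radians / pi. Undefined angles (chain
#' termini, degenerate quadruples) are encoded as 0 (the circle centre
#' under `"cossin"`). Dihedral rows have a natural dimensionless scale and
#' are never standardized; they are multiplied by the same amplitude
#' factor as the property rows.
#'
#' Auxiliary rows mix heterogeneous units (radians, Kyte-Doolittle units,
#' Da, counts) with Angstrom coordinates. Under the default
#' `scaling = "standardize"` each auxiliary row is standardized to mean 0,
#' sd 1 (constant rows become 0) and multiplied by
#' `weight * aux_scale * L / n`, where `L` is the total spatial arc length
#' and `n` the number of curve columns. Coupling the amplitude to `L` makes
#' the composite curve homogeneous under coordinate scaling (so the
#' geodesic distance is exactly scale invariant); the `1/n` factor keeps
#' the channel's squared-velocity contribution a fixed fraction of the
#' spatial one (about `aux_scale^2`) independent of chain length, since a
#' standardized channel changes by O(1) per grid step of width `1/n`.
#'
#' @param chain A validated `esa_chain`.
#' @param criterion Curve criterion, see [geometric_coordinates()].
#' @param feature_set Property channels, subset of
#'   `c("HP", "POL", "MASS", "GROUP", "SC-ATOMS")`; may be empty.
#' @param table Property table ([default_property_table()]).
#' @param scaling `"standardize"` (default) or `"none"` (raw values times
#'   weight).
#' @param dihedral_encoding `"cossin"` (default) or `"raw"`, see Details.
#' @param weights Named per-channel weights (names among `phi`, `psi`,
#'   `omega` and the feature codes); unnamed channels get weight 1.
#' @param aux_scale Relative influence of each auxiliary channel against
#'   geometry (default 0.2; roughly the channel's share of velocity norm).
#' @param strict Passed to [residue_properties()].
#' @return An object of class `esa_curve`: list with `values`
#'   (`(3+k) x n` matrix), `row_labels`, `criterion`, `k`, `n_res`.
#' @export
build_curve <- function(chain,
                        criterion = c("ESA-CA", "ESA-BB", "ESA-MC-BB"),
                        feature_set = character(0),
                        table = default_property_table(),
                        scaling = c("standardize", "none"),
                        weights = NULL, aux_scale = 0.2,
                        dihedral_encoding = c("cossin", "raw"),
                        strict = TRUE) {
  criterion <- match.arg(criterion)
  scaling <- match.arg(scaling)
  dihedral_encoding <- match.arg(dihedral_encoding)
  if (length(feature_set))
    feature_set <- match.arg(feature_set, names(.FEATURES), several.ok = TRUE)
  geom <- geometric_coordinates(chain, criterion)
  m <- length(chain$code3)
  aux <- NULL
  labels <- c("x", "y", "z")

  n_dih <- 0L
  if (criterion %in% c("ESA-CA", "ESA-MC-BB")) {
    dih <- compute_dihedrals(chain)
    und <- sum(is.na(dih))
    if (und > 2L * 3L)  # more than the expected terminal sentinels
      message(und, " undefined dihedral value(s) encoded as 0")
    if (dihedral_encoding == "cossin") {
      aux <- rbind(cos(t(dih$phi)), sin(t(dih$phi)),
                   cos(t(dih$psi)), sin(t(dih$psi)),
                   cos(t(dih$omega)), sin(t(dih$omega)))
      labels <- c(labels, "phi_cos", "phi_sin", "psi_cos", "psi_sin",
                  "omega_cos", "omega_sin")
    } else {
      aux <- t(as.matrix(dih)) / pi
      labels <- c(labels, "phi", "psi", "omega")
    }
    aux[is.na(aux)] <- 0
    n_dih <- nrow(aux)
  }
  if (length(feature_set)) {
    prop <- vapply(chain$code3,
                   function(cc) residue_properties(cc, table, feature_set,
                                                   strict = strict),
                   numeric(length(feature_set)))
    prop <- matrix(prop, nrow = length(feature_set))
    if (criterion == "ESA-BB")
      prop <- prop[, rep(seq_len(m), each = 3L), drop = FALSE]
    aux <- rbind(aux, prop)
    labels <- c(labels, feature_set)
  }

  if (!is.null(aux)) {
    L <- sum(sqrt(rowSums(diff(t(geom))^2)))
    w <- rep(1, nrow(aux))
    names(w) <- labels[-(1:3)]
    if (!is.null(weights)) {
      hit <- intersect(names(weights), names(w))
      w[hit] <- weights[hit]
    }
    if (scaling == "standardize") {
      amp <- aux_scale * L / ncol(aux)
      for (r in seq_len(nrow(aux))) {
        if (r <= n_dih) {  # dihedral channels: natural scale, no z-score
          aux[r, ] <- w[r] * amp * aux[r, ]
        } else {
          s <- stats::sd(aux[r, ])
          z <- if (is.na(s) || s < 1e-12) rep(0, ncol(aux))
               else (aux[r, ] - mean(aux[r, ])) / s
          aux[r, ] <- w[r] * amp * z
        }
      }
    } else {
      aux <- aux * w
    }
  }

  values <- rbind(geom, aux)
  if (any(!is.finite(values))) stop("non-finite values in composite curve")
  structure(list(values = values, row_labels = labels, criterion = criterion,
                 k = nrow(values) - 3L, n_res = m,
                 pdb_id = chain$pdb_id, chain_id = chain$chain_id),
            class = "esa_curve")
}

#' @export
print.esa_curve <- function(x, ...) {
  cat("Composite curve [", x$criterion, "]: ", nrow(x$values), " x ",
      ncol(x$values), " (3 spatial + ", x$k, " auxiliary rows, ",
      x$n_res, " residues)\n", sep = "")
  invisible(x)
}
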