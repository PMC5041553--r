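#' Torsion (dihedral) angle of four points
#'
#' Standard right-handed convention:
#' `atan2((n1 x n2) . b2hat, n1 . n2)` with bond vectors `b1, b2, b3` and
#' plane normals `n1 = b1 x b2`, `n2 = b2 x b3`. Returns `NA` when a
#' quadruple is degenerate (zero-length bond or collinear triple).
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors.
#' @return Angle in radians in `[-pi, pi]`, or `NA`.
#' @export
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  nb1 <- sqrt(sum(b1^2)); nb2 <- sqrt(sum(b2^2)); nb3 <- sqrt(sum(b3^2))
  ## degeneracy is judged relative to the bond lengths so the decision is
  ## invariant to rigid motion and uniform scaling
  if (min(nb1, nb2, nb3) < 1e-12 ||
      sqrt(sum(n1^2)) < 1e-7 * nb1 * nb2 ||
      sqrt(sum(n2^2)) < 1e-7 * nb2 * nb3)
    return(NA_real_)
  atan2(sum(.cross3(n1, n2) * b2 / nb2), sum(n1 * n2))
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Backbone dihedral angles of a chain
#'
#' Computes per residue `phi(i) = torsion(C(i-1), N(i), CA(i), C(i))`,
#' `psi(i) = torsion(N(i), CA(i), C(i), N(i+1))` and
#' `omega(i) = torsion(CA(i), C(i), N(i+1), CA(i+1))`. `phi` is undefined
#' (`NA`) for the first residue; `psi` and `omega` for the last. Degenerate
#' quadruples also yield `NA`.
#'
#' @param chain A validated `esa_chain`.
#' @return A data frame with columns `phi`, `psi`, `omega` (radians).
#' @export
compute_dihedrals <- function(chain) {
  stopifnot(inherits(chain, "esa_chain"))
  m <- length(chain$code3)
  phi <- psi <- omega <- rep(NA_real_, m)
  N <- chain$n; CA <- chain$ca; C <- chain$c
  for (i in seq_len(m)) {
    if (i > 1L)
      phi[i] <- torsion_angle(C[i - 1L, ], N[i, ], CA[i, ], C[i, ])
    if (i < m) {
      psi[i] <- torsion_angle(N[i, ], CA[i, ], C[i, ], N[i + 1L, ])
      omega[i] <- torsion_angle(CA[i, ], C[i, ], N[i + 1L, ], CA[i + 1L, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

#' Geometric coordinates of a chain under a curve criterion
#'
#' @param chain A validated `esa_chain`.
#' @param criterion `"ESA-BB"` (N, CA, C interleaved; 3 points per residue),
#'   `"ESA-CA"` (C-alpha trace) or `"ESA-MC-BB"` (per-residue centroid of
#'   N, CA, C).
#' @return A `3 x n` matrix of coordinates in Angstrom.
#' @export
geometric_coordinates <- function(chain,
                                  criterion = c("ESA-CA", "ESA-BB", "ESA-MC-BB")) {
  stopifnot(inherits(chain, "esa_chain"))
  criterion <- match.arg(criterion)
  m <- length(chain$code3)
  switch(criterion,
    "ESA-BB" = {
      out <- matrix(0, 3L, 3L * m)
      out[, seq(1L, 3L * m, by = 3L)] <- t(chain$n)
      out[, seq(2L, 3L * m, by = 3L)] <- t(chain$ca)
      out[, seq(3L, 3L * m, by = 3L)] <- t(chain$c)
      out
    },
    "ESA-CA" = t(chain$ca),
    "ESA-MC-BB" = t((chain$n + chain$ca + chain$c) / 3))
}
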