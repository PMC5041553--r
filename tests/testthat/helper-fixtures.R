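# Shared fixtures and independent oracles, all built in code.

# Hand-written two-residue PDB text (ideal-ish ALA-GLY).
pdb_two_res <- function() {
  paste(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.770  -1.200  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       4.006   2.826   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.504   2.705   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
}

pdb_two_models <- function() {
  body <- function(shift) paste(sprintf(
    "ATOM  %5d  %-3s %s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    1:6, rep(c("N", "CA", "C"), 2), rep(c("ALA", "GLY"), each = 3),
    rep(1:2, each = 3),
    c(0, 1.5, 2.1, 3.8, 4.5, 6.0) + shift, c(0, 0, 1.4, 1.5, 2.8, 2.7),
    rep(0, 6), rep(c("N", "C", "C"), 2)), collapse = "\n")
  paste("MODEL        1", body(0), "ENDMDL",
        "MODEL        2", body(0.5), "ENDMDL", "END", sep = "\n")
}

pdb_altloc <- function() {
  paste(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   9.000   9.000  0.60  0.00           N",
    "ATOM      3  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
    "ATOM      6  CA  ALA A   2       4.006   2.826   0.000  1.00  0.00           C",
    "ATOM      7  C   ALA A   2       5.504   2.705   0.000  1.00  0.00           C",
    "END"), collapse = "\n")
}

# A planar trans-peptide quadruple: omega = +/- pi exactly.
trans_peptide_quad <- function() {
  list(ca1 = c(0, 0, 0), c1 = c(1.5, 0, 0),
       n2 = c(2.2, 1.2, 0), ca2 = c(3.7, 1.2, 0))
}

# Small random SRVF on a random strictly increasing grid.
random_srvf <- function(n, dim = 3L, k = 0L) {
  g <- sort(stats::runif(n))
  g <- (g - g[1L]) / (g[n] - g[1L])
  while (min(diff(g)) < 1e-3) {
    g <- sort(stats::runif(n))
    g <- (g - g[1L]) / (g[n] - g[1L])
  }
  structure(list(values = matrix(stats::rnorm(dim * n), dim), grid = g,
                 k = k), class = "esa_srvf")
}

# Exhaustive minimum over all strictly monotone paths with jumps <= w;
# independent of the DP (same edge costs, brute-force optimization).
enum_matching_cost <- function(Q1, Q2, w) {
  n <- length(Q1$grid)
  best <- Inf
  rec <- function(i, j, acc) {
    if (i == n && j == n) {
      best <<- min(best, acc)
      return(invisible())
    }
    for (a in seq_len(min(w, n - i))) {
      for (b in seq_len(min(w, n - j))) {
        c2 <- acc + matching_cost(Q1, Q2, i, i + a, j, j + b)
        if (c2 < best) rec(i + a, j + b, c2)
      }
    }
  }
  rec(1L, 1L, 0)
  best
}

scale_chain <- function(chain, c) {
  chain$n <- c * chain$n
  chain$ca <- c * chain$ca
  chain$c <- c * chain$c
  chain
}

quiet_compare <- function(...) suppressMessages(esa_compare(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
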