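#' Read a PDB file or raw PDB text
#'
#' Parses a PDB-format input into all of its models and chains. Only `ATOM`
#' records are considered (`HETATM`, waters and ligands are ignored);
#' alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by file order). Parsing is delegated to
#' [bio3d::read.pdb()]; model/chain bookkeeping, altLoc resolution and
#' residue assembly are done here.
#'
#' @param source Path to a PDB file, or a character string containing raw
#'   PDB text (recognised by embedded newlines).
#' @param pdb_id Identifier stored on the returned object; defaults to the
#'   file name (or `"pdb"` for raw text).
#' @return An object of class `esa_structure`: a list with elements
#'   `pdb_id`, `model_ids`, `chain_ids` and `models` (a list, one entry per
#'   model, each a named list of `esa_chain` objects).
#' @seealso [esa_select_chain()], [esa_validate_chain()]
#' @export
esa_read_pdb <- function(source, pdb_id = NULL) {
  if (!is.character(source) || length(source) != 1L)
    stop("`source` must be a single file path or a PDB text string")
  if (grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(source, "\n", fixed = TRUE)[[1L]], path)
    if (is.null(pdb_id)) pdb_id <- "pdb"
  } else {
    path <- source
    if (!file.exists(path)) stop("cannot read PDB input: file not found: ", path)
    if (is.null(pdb_id)) pdb_id <- sub("\\.(pdb|ent)$", "", basename(path))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB input: ", conditionMessage(e))
  )
  atom <- pdb$atom
  keep <- atom$type == "ATOM"
  if (!any(keep)) stop("empty structure: no ATOM records in input")
  n_models <- nrow(pdb$xyz)
  idx_all <- which(keep)
  atom <- atom[keep, , drop = FALSE]
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt[is.na(atom$alt)] <- ""
  atom$o[is.na(atom$o)] <- 1

  ## altLoc: within one (chain, resno, insert, atom-name) group keep the
  ## highest-occupancy record; ties resolved by file order.
  grp <- paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "\r")
  ord <- order(factor(grp, levels = unique(grp)), -atom$o,
               seq_len(nrow(atom)))
  first_of_grp <- !duplicated(grp[ord])
  sel <- sort(ord[first_of_grp])
  atom <- atom[sel, , drop = FALSE]
  idx_all <- idx_all[sel]

  chain_ids <- unique(atom$chain)
  models <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    xyz <- matrix(pdb$xyz[m, ], nrow = 3L)  # 3 x n_atoms, file order
    chains <- list()
    for (ch in chain_ids) {
      in_ch <- atom$chain == ch
      chains[[ch]] <- .build_chain(atom[in_ch, , drop = FALSE],
                                   t(xyz[, idx_all[in_ch], drop = FALSE]),
                                   pdb_id, m, ch)
    }
    models[[m]] <- chains
  }
  structure(list(pdb_id = pdb_id, model_ids = seq_len(n_models),
                 chain_ids = chain_ids, models = models),
            class = "esa_structure")
}

## Assemble an esa_chain from the atom table of a single model+chain.
## Residues keep file order; missing backbone atoms become NA rows and are
## removed later by esa_validate_chain().
.build_chain <- function(atom, coords, pdb_id, model_id, chain_id) {
  res_key <- paste(atom$resno, atom$insert, sep = "\r")
  res_lvl <- unique(res_key)
  nres <- length(res_lvl)
  bb <- c("N", "CA", "C")
  mk <- function() matrix(NA_real_, nres, 3L)
  xyz <- list(N = mk(), CA = mk(), C = mk())
  code3 <- character(nres)
  resno <- integer(nres)
  sc <- integer(nres)
  ridx <- match(res_key, res_lvl)
  is_h <- !is.na(atom$elesy) & atom$elesy %in% c("H", "D")
  for (i in seq_len(nres)) {
    rows <- which(ridx == i)
    code3[i] <- atom$resid[rows[1L]]
    resno[i] <- atom$resno[rows[1L]]
    for (a in bb) {
      hit <- rows[atom$elety[rows] == a]
      if (length(hit)) xyz[[a]][i, ] <- coords[hit[1L], ]
    }
    side <- rows[!(atom$elety[rows] %in% c(bb, "O", "OXT")) & !is_h[rows]]
    sc[i] <- length(side)
  }
  structure(list(pdb_id = pdb_id, model_id = model_id, chain_id = chain_id,
                 code3 = code3, resno = resno,
                 n = xyz$N, ca = xyz$CA, c = xyz$C,
                 sidechain_atoms = sc, validated = FALSE,
                 dropped = integer(0)),
            class = "esa_chain")
}

#' Select one model and chain from a parsed structure
#'
#' @param x An `esa_structure` from [esa_read_pdb()].
#' @param model_id Integer model number (1-based, in file order).
#' @param chain_id Chain identifier. Defaults to the first chain.
#' @return An `esa_chain`.
#' @export
esa_select_chain <- function(x, model_id = 1L, chain_id = NULL) {
  stopifnot(inherits(x, "esa_structure"))
  if (is.null(chain_id)) chain_id <- x$chain_ids[1L]
  if (!(model_id %in% x$model_ids))
    stop("model ", model_id, " not present; available models: ",
         paste(x$model_ids, collapse = ", "))
  if (!(chain_id %in% x$chain_ids))
    stop("chain '", chain_id, "' not present; available chains: ",
         paste(x$chain_ids, collapse = ", "))
  x$models[[model_id]][[chain_id]]
}

#' Validate a chain for curve building
#'
#' Drops residues missing any of the N, C-alpha, C backbone atoms and
#' records their positions. Chain breaks (consecutive C-alpha distance
#' above `break_cutoff`) are reported as warnings; the curve built from the
#' chain remains continuous through them. Idempotent.
#'
#' @param chain An `esa_chain`.
#' @param break_cutoff Chain-break warning threshold in Angstrom.
#' @return The validated `esa_chain`, with `dropped` holding the original
#'   indices of removed residues.
#' @export
esa_validate_chain <- function(chain, break_cutoff = 4.5) {
  stopifnot(inherits(chain, "esa_chain"))
  ok <- stats::complete.cases(chain$n) & stats::complete.cases(chain$ca) &
    stats::complete.cases(chain$c)
  dropped <- which(!ok)
  if (sum(ok) < 2L)
    stop("degenerate chain: fewer than 2 residues with complete ",
         "N/CA/C backbone (", sum(ok), " valid)")
  for (f in c("code3", "resno", "sidechain_atoms"))
    chain[[f]] <- chain[[f]][ok]
  for (f in c("n", "ca", "c"))
    chain[[f]] <- chain[[f]][ok, , drop = FALSE]
  chain$dropped <- union(chain$dropped, dropped)
  chain$validated <- TRUE
  d <- sqrt(rowSums((chain$ca[-1L, , drop = FALSE] -
                     chain$ca[-nrow(chain$ca), , drop = FALSE])^2))
  if (any(d > break_cutoff))
    warning(sum(d > break_cutoff), " chain break(s) (CA-CA > ",
            break_cutoff, " A) in ", chain$pdb_id, " chain ",
            chain$chain_id, "; curve kept continuous")
  chain
}

#' Write a chain as PDB ATOM records
#'
#' Emits wwPDB v3.3 fixed-column `ATOM` records for the N, C-alpha and C
#' atoms of each residue, used mainly to materialize synthetic fixtures.
#'
#' @param chain An `esa_chain`.
#' @param file Output path, or `""` to return the text invisibly only.
#' @return The PDB text, invisibly.
#' @export
esa_write_pdb <- function(chain, file = "") {
  stopifnot(inherits(chain, "esa_chain"))
  m <- length(chain$code3)
  lines <- character(3L * m + 1L)
  serial <- 0L
  names4 <- c(N = " N  ", CA = " CA ", C = " C  ")
  elem <- c(N = "N", CA = "C", C = "C")
  slot <- c(N = "n", CA = "ca", C = "c")
  for (i in seq_len(m)) {
    for (a in c("N", "CA", "C")) {
      serial <- serial + 1L
      p <- chain[[slot[[a]]]][i, ]
      lines[serial] <- sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, names4[[a]], chain$code3[i],
        substr(chain$chain_id, 1L, 1L), chain$resno[i],
        p[1L], p[2L], p[3L], 1, 0, elem[[a]])
    }
  }
  lines[length(lines)] <- "END"
  txt <- paste(lines, collapse = "\n")
  if (!identical(file, "")) writeLines(lines, file)
  invisible(txt)
}

#' @export
print.esa_structure <- function(x, ...) {
  cat("PDB structure '", x$pdb_id, "': ", length(x$model_ids), " model(s), ",
      length(x$chain_ids), " chain(s) [",
      paste(x$chain_ids, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' @export
print.esa_chain <- function(x, ...) {
  cat("Chain ", x$chain_id, " (model ", x$model_id, ") of '", x$pdb_id,
      "': ", length(x$code3), " residues",
      if (x$validated) " [validated]" else "",
      if (length(x$dropped)) paste0(", ", length(x$dropped), " dropped")
      else "", "\n", sep = "")
  invisible(x)
}
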