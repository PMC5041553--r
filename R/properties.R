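## Residue-level molecular property channels.
##
## Default scales: Kyte-Doolittle hydrophobicity, Grantham polarity,
## monoisotopic residue mass (Da), functional-group class coded 1-4
## (1 aliphatic, 2 acyclic [charged/amide side chains], 3 hydroxyl- or
## sulphur-containing, 4 aromatic), and heavy side-chain atom count.
## All overridable via read_property_table().

.FEATURES <- c(HP = "hydrophobicity", POL = "polarity", MASS = "mass",
               GROUP = "group_class", `SC-ATOMS` = "sidechain_atoms")

#' Default residue property table
#'
#' One row per standard residue, columns `hydrophobicity` (Kyte-Doolittle),
#' `polarity` (Grantham), `mass` (monoisotopic residue mass, Da),
#' `group_class` (1 aliphatic, 2 acyclic, 3 hydroxyl/sulphur-containing,
#' 4 aromatic) and `sidechain_atoms` (heavy atoms beyond the backbone;
#' 0 for glycine, whose side chain contributes nothing anywhere).
#'
#' @return A data frame with row names the 20 three-letter codes.
#' @export
default_property_table <- function() {
  tab <- data.frame(
    hydrophobicity = c(
      ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
      GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
      LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
      SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2),
    polarity = c(
      ALA =  8.1, ARG = 10.5, ASN = 11.6, ASP = 13.0, CYS =  5.5,
      GLN = 10.5, GLU = 12.3, GLY =  9.0, HIS = 10.4, ILE =  5.2,
      LEU =  4.9, LYS = 11.3, MET =  5.7, PHE =  5.2, PRO =  8.0,
      SER =  9.2, THR =  8.6, TRP =  5.4, TYR =  6.2, VAL =  5.9),
    mass = c(
      ALA =  71.03711, ARG = 156.10111, ASN = 114.04293, ASP = 115.02694,
      CYS = 103.00919, GLN = 128.05858, GLU = 129.04259, GLY =  57.02146,
      HIS = 137.05891, ILE = 113.08406, LEU = 113.08406, LYS = 128.09496,
      MET = 131.04049, PHE = 147.06841, PRO =  97.05276, SER =  87.03203,
      THR = 101.04768, TRP = 186.07931, TYR = 163.06333, VAL =  99.06841),
    group_class = c(
      ALA = 1, ARG = 2, ASN = 2, ASP = 2, CYS = 3, GLN = 2, GLU = 2,
      GLY = 1, HIS = 4, ILE = 1, LEU = 1, LYS = 2, MET = 3, PHE = 4,
      PRO = 1, SER = 3, THR = 3, TRP = 4, TYR = 4, VAL = 1),
    sidechain_atoms = c(
      ALA = 1, ARG = 7, ASN = 4, ASP = 4, CYS = 2, GLN = 5, GLU = 5,
      GLY = 0, HIS = 6, ILE = 4, LEU = 4, LYS = 5, MET = 4, PHE = 7,
      PRO = 3, SER = 2, THR = 3, TRP = 10, TYR = 8, VAL = 3))
  tab
}

## Nonstandard residue codes mapped to the standard parent used for
## property lookup. Editable through the `extra` argument of
## map_residue_code().
.NONSTANDARD <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", CSO = "CYS",
                  SEP = "SER", TPO = "THR", PTR = "TYR", MLY = "LYS",
                  HYP = "PRO", HSD = "HIS", HSE = "HIS", HSP = "HIS")

#' Map a three-letter residue code to its standard parent
#'
#' @param code3 Character vector of three-letter codes.
#' @param extra Named character vector of additional nonstandard-to-standard
#'   mappings (names = nonstandard codes).
#' @return Character vector of standard codes, `NA` where unmappable.
#' @export
map_residue_code <- function(code3, extra = NULL) {
  code3 <- toupper(code3)
  map <- c(.NONSTANDARD, extra)
  std <- rownames(default_property_table())
  out <- ifelse(code3 %in% std, code3,
                unname(map[code3]))
  out[!(out %in% std)] <- NA_character_
  out
}

#' Read a residue property channel from a delimited file
#'
#' Expects two whitespace- or comma-delimited columns: three-letter code
#' and numeric value. The returned table is the default table with the
#' named channel replaced.
#'
#' @param file Path to the two-column file.
#' @param channel One of `"hydrophobicity"`, `"polarity"`, `"mass"`,
#'   `"group_class"`, `"sidechain_atoms"`.
#' @param table Property table to modify; default [default_property_table()].
#' @return The modified property table.
#' @export
read_property_table <- function(file, channel, table = default_property_table()) {
  channel <- match.arg(channel, unname(.FEATURES))
  raw <- utils::read.table(file, header = FALSE, sep = "",
                           col.names = c("code3", "value"),
                           colClasses = c("character", "numeric"))
  if (!nrow(raw)) stop("empty property file: ", file)
  idx <- match(toupper(raw$code3), rownames(table))
  if (anyNA(idx))
    stop("unknown residue code(s) in ", file, ": ",
         paste(raw$code3[is.na(idx)], collapse = ", "))
  table[[channel]][idx] <- raw$value
  table
}

#' Look up auxiliary property values for one residue
#'
#' Returns the selected channels in the order given by `feature_set`.
#' Glycine behaves like any residue except that its side-chain atom count
#' is 0 (only its backbone atoms ever contribute).
#'
#' @param code3 Three-letter residue code (nonstandard codes are mapped to
#'   their standard parent first).
#' @param table Property table, see [default_property_table()].
#' @param feature_set Character vector drawn from
#'   `c("HP", "POL", "MASS", "GROUP", "SC-ATOMS")`.
#' @param strict If `TRUE` (default) an unmappable code is an error;
#'   otherwise `neutral` is returned for every channel, with a warning.
#' @param neutral Fallback value in non-strict mode.
#' @return Numeric vector of length `length(feature_set)`.
#' @export
residue_properties <- function(code3, table = default_property_table(),
                               feature_set = names(.FEATURES),
                               strict = TRUE, neutral = 0) {
  feature_set <- match.arg(feature_set, names(.FEATURES), several.ok = TRUE)
  std <- map_residue_code(code3)
  if (is.na(std)) {
    if (strict) stop("property lookup failed: unmapped residue code '",
                     code3, "'")
    warning("unmapped residue code '", code3, "'; using neutral value ",
            neutral)
    return(stats::setNames(rep(neutral, length(feature_set)), feature_set))
  }
  vals <- vapply(feature_set,
                 function(f) table[std, .FEATURES[[f]]], numeric(1))
  stats::setNames(vals, feature_set)
}
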