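#' @keywords internal
"_PACKAGE"

# Canonical residue codes, alphabetical by 3-letter code. This order fixes
# the identity blocks of every descriptor group.
AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
         "F", "P", "S", "T", "W", "Y", "V")
names(AA1) <- AA3

# Numeric property columns used in descriptor sums/means, in descriptor
# order, mapped to their human-readable descriptor labels.
AA_PROPERTIES <- c(
  "Volume"            = "volume",
  "Flexibility"       = "flexibility",
  "Hydrophobicity"    = "hydrophobicity",
  "Steric hindrance"  = "steric_hindrance",
  "Polarity index"    = "polarity_index",
  "Isoelectric point" = "isoelectric_point",
  "Helix propensity"  = "helix_propensity",
  "Sheet propensity"  = "sheet_propensity")

AA_CLASSES <- c("polar", "apolar", "hydrophobic", "charged", "positive",
                "negative", "aromatic", "small", "hbond_donor",
                "hbond_acceptor")

.aa_env <- new.env(parent = emptyenv())

#' Amino-acid physicochemical property table
#'
#' Returns the bundled per-residue property table used by every counting and
#' summing descriptor: residue volume (\eqn{\mathrm{\AA}^3}, Zamyatnin),
#' average flexibility (Bhaskaran–Ponnuswamy), Kyte–Doolittle
#' hydrophobicity, Charton steric parameter, Grantham polarity, free
#' amino-acid isoelectric point, Chou–Fasman helix/sheet propensities,
#' side-chain heavy-atom element counts (N, O, C, S), side-chain H-bond
#' donor/acceptor atom counts, and binary class memberships (polar, apolar,
#' hydrophobic, charged, positive, negative, aromatic, small, H-bond
#' donor/acceptor). The table is immutable at run time; an alternative
#' table with the same schema can be supplied via `path` to swap scales.
#'
#' @param path Optional path to a TSV file with the same schema as the
#'   bundled table (see `inst/extdata/aa_properties.tsv`).
#' @return A data frame with 20 rows (one per canonical residue, rownames =
#'   3-letter codes) and the documented columns.
#' @export
#' @examples
#' tab <- aa_property_table()
#' tab["ARG", "n_N"]   # 3 nitrogen atoms in the guanidinium side chain
aa_property_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.aa_env$table)) return(.aa_env$table)
    path <- system.file("extdata", "aa_properties.tsv", package = "flavoqspr")
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, setequal(tab$res3, AA3))
  rownames(tab) <- tab$res3
  tab <- tab[AA3, , drop = FALSE]
  if (cache) .aa_env$table <- tab
  tab
}

#' Look up one physicochemical property of one residue
#'
#' @param residue_name 3-letter canonical residue code (e.g. `"GLN"`).
#' @param property Column name of [aa_property_table()] (e.g. `"n_N"`,
#'   `"volume"`, `"hydrophobicity"`).
#' @param table Property table; defaults to the bundled one.
#' @return The scalar table value.
#' @export
property_value <- function(residue_name, property, table = aa_property_table()) {
  if (!residue_name %in% AA3)
    stop("non-canonical residue code: ", residue_name, call. = FALSE)
  if (!property %in% colnames(table))
    stop("unknown property: ", property, call. = FALSE)
  table[residue_name, property]
}

#' Residue class membership
#'
#' Returns the set of 3-letter residue codes belonging to a physicochemical
#' class. `polar` and `apolar` partition the 20 canonical residues;
#' `charged` = \{ASP, GLU, LYS, ARG, HIS\}; `positive` = \{LYS, ARG, HIS\}
#' (histidine is treated as protonatable); classes may otherwise overlap
#' (e.g. HIS is both positive and aromatic).
#'
#' @param class_name One of `r paste(AA_CLASSES, collapse = ", ")`.
#' @param table Property table; defaults to the bundled one.
#' @return Character vector of residue codes.
#' @export
class_members <- function(class_name, table = aa_property_table()) {
  if (!class_name %in% AA_CLASSES)
    stop("unknown residue class: ", class_name, call. = FALSE)
  table$res3[table[[class_name]] == 1L]
}

#' Map 3-letter residue codes to one-letter codes
#' @param res3 Character vector of 3-letter codes.
#' @return One-letter codes; `NA` for non-canonical input.
#' @export
aa_three_to_one <- function(res3) {
  unname(AA1[res3])
}
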