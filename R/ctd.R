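# Three-class residue attribute partitions (Dubchak-style CTD scheme).
# Each attribute splits the 20 canonical residues into classes 1/2/3.
CTD_ATTRIBUTES <- list(
  hydrophobicity = list(
    "1" = c("R", "K", "E", "D", "Q", "N"),            # polar
    "2" = c("G", "A", "S", "T", "P", "H", "Y"),       # neutral
    "3" = c("C", "L", "V", "I", "M", "F", "W")),      # hydrophobic
  secondary_structure = list(
    "1" = c("E", "A", "L", "M", "Q", "K", "R", "H"),  # helix formers
    "2" = c("V", "I", "Y", "C", "W", "F", "T"),       # strand formers
    "3" = c("G", "N", "P", "S", "D")),                # coil formers
  solvent_accessibility = list(
    "1" = c("A", "L", "F", "C", "G", "I", "V", "W"),  # buried
    "2" = c("R", "K", "Q", "E", "N", "D"),            # exposed
    "3" = c("M", "P", "S", "T", "H", "Y")))           # intermediate

#' Names of the 21 CTD descriptors
#' @return Character vector: 3 composition, 3 transition, 15 distribution
#'   names.
#' @export
ctd_feature_names <- function() {
  c(paste0("CTD.Composition.", 1:3),
    c("CTD.Transition.1.2", "CTD.Transition.1.3", "CTD.Transition.2.3"),
    as.vector(t(outer(1:3, c(0, 25, 50, 75, 100),
                      function(c, q) paste0("CTD.Distribution.", c, ".", q)))))
}

#' Encode a protein sequence into attribute classes
#'
#' Maps each residue of a one-letter sequence to its class (1/2/3) under a
#' three-class attribute partition. Non-canonical letters are skipped with
#' a warning.
#'
#' @param sequence One-letter amino-acid string (or character vector of
#'   letters).
#' @param attribute One of `"hydrophobicity"` (default partition:
#'   polar/neutral/hydrophobic), `"secondary_structure"`,
#'   `"solvent_accessibility"`.
#' @return Integer vector over \{1, 2, 3\}, one entry per usable residue.
#' @export
encode_sequence <- function(sequence, attribute = "hydrophobicity") {
  part <- CTD_ATTRIBUTES[[match.arg(attribute, names(CTD_ATTRIBUTES))]]
  letters1 <- if (length(sequence) == 1L)
    strsplit(toupper(sequence), "")[[1]] else toupper(sequence)
  cls <- rep(NA_integer_, length(letters1))
  for (k in 1:3) cls[letters1 %in% part[[k]]] <- k
  if (anyNA(cls)) {
    warning("skipping non-canonical letter(s): ",
            paste(unique(letters1[is.na(cls)]), collapse = ", "),
            call. = FALSE)
    cls <- cls[!is.na(cls)]
  }
  if (length(cls) == 0L)
    stop("no usable residues in sequence", call. = FALSE)
  cls
}

#' CTD features from an already-encoded class sequence
#'
#' Composition: fraction of each class. Transition: for each unordered
#' class pair, the number of adjacent positions switching between the two
#' classes divided by (L − 1). Distribution: for each class, the 1-based
#' sequence positions of its first, ceil(25%)-th, ceil(50%)-th,
#' ceil(75%)-th and last occurrence, as a percentage of the sequence
#' length; a class absent from the sequence contributes five zeros.
#'
#' @param encoded Integer (or digit-character) vector/string over
#'   \{1, 2, 3\}.
#' @return Named numeric vector of length 21 ([ctd_feature_names()]).
#' @export
ctd_from_encoded <- function(encoded) {
  if (is.character(encoded) && length(encoded) == 1L)
    encoded <- as.integer(strsplit(encoded, "")[[1]])
  encoded <- as.integer(encoded)
  stopifnot(all(encoded %in% 1:3))
  L <- length(encoded)
  comp <- tabulate(encoded, nbins = 3L) / L
  if (L < 2L) {
    warning("sequence too short for transition features; set to 0",
            call. = FALSE)
    trans <- c(0, 0, 0)
  } else {
    a <- encoded[-L]; b <- encoded[-1]
    pair <- function(c1, c2) sum((a == c1 & b == c2) | (a == c2 & b == c1))
    trans <- c(pair(1, 2), pair(1, 3), pair(2, 3)) / (L - 1)
  }
  distr <- numeric(0)
  for (cl in 1:3) {
    pos <- which(encoded == cl)
    m <- length(pos)
    if (m == 0L) {
      distr <- c(distr, rep(0, 5))
    } else {
      idx <- c(1L, ceiling(c(0.25, 0.5, 0.75) * m), m)
      distr <- c(distr, pos[idx] / L * 100)
    }
  }
  out <- c(comp, trans, distr)
  names(out) <- ctd_feature_names()
  out
}

#' Composition/transition/distribution features of a sequence
#'
#' Encodes a one-letter sequence under a three-class residue attribute and
#' computes the 21 CTD descriptors (see [ctd_from_encoded()] for the exact
#' definitions).
#'
#' @inheritParams encode_sequence
#' @return Named numeric vector of length 21.
#' @export
ctd_features <- function(sequence, attribute = "hydrophobicity") {
  ctd_from_encoded(encode_sequence(sequence, attribute))
}

#' One-letter sequence of a structure's chain
#'
#' Standard amino-acid residues of one chain in author (file) order,
#' mapped to one-letter codes.
#'
#' @param structure A [parse_structure()] result.
#' @param chain Chain identifier; defaults to the first chain.
#' @return One-letter character string.
#' @export
structure_sequence <- function(structure, chain = structure$chain_order[1]) {
  a <- .protein_heavy_atoms(structure)
  res <- .residue_table(a[a$chain == chain, , drop = FALSE])
  paste(aa_three_to_one(res$resid), collapse = "")
}
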