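# --- descriptor name contracts ------------------------------------------

#' Names of the 55 per-region descriptors
#'
#' The region descriptor block computed at each spatial scope: 20
#' residue-type counts, 11 class counts, 8 physicochemical property sums,
#' the 8 corresponding means, 4 side-chain element-count sums and 4 derived
#' counts. Prefixed `"Protein."`, `"Bar."` or `"Ring."` in assembled
#' feature vectors.
#'
#' @return Character vector of length 55.
#' @export
region_descriptor_names <- function() {
  c(AA3,
    c("ResTotal", "ResPolar", "ResApolar", "ResCharged", "ResPositive",
      "ResNegative", "ResHydrophobic", "ResAromatic", "ResSmall",
      "ResHBondDonor", "ResHBondAcceptor"),
    names(AA_PROPERTIES),
    paste(names(AA_PROPERTIES), "mean"),
    c("nNats in side chain", "nOats in side chain", "nCats in side chain",
      "nSats in side chain"),
    c("Net charge", "Aromatic atoms", "HBond donor atoms",
      "HBond acceptor atoms"))
}

#' Names of the 28 N5-environment descriptors
#'
#' One residue-identity block (20) plus the 8 physicochemical properties.
#' Used for both N5 variants: `N5_nearest_<X>` (single nearest residue,
#' identity indicator + property values) and `Around_N5.<X>` (nearest
#' residue plus its two sequence neighbours, identity counts + property
#' sums).
#'
#' @return Character vector of length 28.
#' @export
n5_descriptor_names <- function() {
  c(AA3, names(AA_PROPERTIES))
}

# --- region membership ---------------------------------------------------

.residue_table <- function(atoms) {
  # unique residues in file order
  r <- atoms[!duplicated(atoms$key),
             c("key", "chain", "resno", "insert", "resid"), drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Standard residues with any heavy atom inside a sphere
#'
#' Returns the set of standard amino-acid residues of a structure having at
#' least one non-hydrogen atom within `radius` (Angstrom, Euclidean) of
#' `center`. Hetero groups (cofactor, waters) never contribute.
#'
#' @param structure A [parse_structure()] result.
#' @param center Numeric 3-vector, Angstrom.
#' @param radius Sphere radius, Angstrom (`>= 0`).
#' @return Data frame of residues (columns key, chain, resno, insert,
#'   resid) in file order.
#' @export
residues_in_sphere <- function(structure, center, radius) {
  stopifnot(radius >= 0, length(center) == 3)
  a <- .protein_heavy_atoms(structure)
  d2 <- (a$x - center[1])^2 + (a$y - center[2])^2 + (a$z - center[3])^2
  .residue_table(a[d2 <= radius^2, , drop = FALSE])
}

# squared distance of each atom row to its nearest ring atom
.min_d2_to_ring <- function(atoms, ring) {
  n <- nrow(atoms)
  if (n == 0L) return(numeric(0))
  m <- matrix(Inf, n, nrow(ring))
  for (j in seq_len(nrow(ring)))
    m[, j] <- (atoms$x - ring[j, 1])^2 + (atoms$y - ring[j, 2])^2 +
      (atoms$z - ring[j, 3])^2
  apply(m, 1, min)
}

#' Residues within r2 of any isoalloxazine ring atom
#'
#' Union over the ring atoms of [residues_in_sphere()] with radius `r2`.
#'
#' @inheritParams residues_in_sphere
#' @param site A `FlavinSite`.
#' @param r2 Per-ring-atom sphere radius, Angstrom.
#' @return Data frame of residues as in [residues_in_sphere()].
#' @export
ring_union_region <- function(structure, site, r2) {
  stopifnot(r2 >= 0)
  a <- .protein_heavy_atoms(structure)
  d2 <- .min_d2_to_ring(a, site$ring_atoms)
  .residue_table(a[d2 <= r2^2, , drop = FALSE])
}

#' Protein N/O/C atom counts near the isoalloxazine ring
#'
#' Counts the protein nitrogen, oxygen and carbon atoms (non-hydrogen,
#' cofactor excluded) lying within `r2` of any ring atom; an atom close to
#' several ring atoms is counted once.
#'
#' @inheritParams ring_union_region
#' @return Named numeric vector `c(Nitrogen_Around, Oxygen_Around,
#'   Carbon_Around)`.
#' @export
ring_atom_counts <- function(structure, site, r2) {
  stopifnot(r2 >= 0)
  a <- .protein_heavy_atoms(structure)
  sel <- .min_d2_to_ring(a, site$ring_atoms) <= r2^2
  el <- a$element[sel]
  c(Nitrogen_Around = sum(el == "N"),
    Oxygen_Around = sum(el == "O"),
    Carbon_Around = sum(el == "C"))
}

# --- region descriptor computation ---------------------------------------

#' Compute the 55 region descriptors for a residue set
#'
#' Pure bookkeeping over residue identities: residue-type counts, class
#' counts, property sums and means, side-chain element-count sums and the
#' derived counts (net formal charge = positives − negatives;
#' aromatic-residue side-chain atom count; H-bond donor/acceptor atom
#' counts, all taken from the bundled chemistry table). The empty region
#' yields all zeros (means included).
#'
#' @param residues Character vector of 3-letter residue codes (one entry
#'   per region residue), or a data frame with a `resid` column as returned
#'   by [residues_in_sphere()].
#' @param table Property table from [aa_property_table()].
#' @return Named numeric vector of length 55 (names =
#'   [region_descriptor_names()]).
#' @export
region_descriptors <- function(residues, table = aa_property_table()) {
  if (is.data.frame(residues)) residues <- residues$resid
  bad <- !(residues %in% AA3)
  if (any(bad)) {
    warning("skipping non-canonical residue(s): ",
            paste(unique(residues[bad]), collapse = ", "), call. = FALSE)
    residues <- residues[!bad]
  }
  n <- length(residues)
  type_counts <- tabulate(factor(residues, levels = AA3), nbins = 20L)
  sub <- table[residues, , drop = FALSE]
  # class order must mirror the descriptor-name contract
  cls <- c("polar", "apolar", "charged", "positive", "negative",
           "hydrophobic", "aromatic", "small", "hbond_donor",
           "hbond_acceptor")
  class_counts <- vapply(cls, function(cl) sum(sub[[cl]]), numeric(1))
  sums <- vapply(AA_PROPERTIES, function(col) sum(sub[[col]]), numeric(1))
  means <- if (n > 0) sums / n else rep(0, length(sums))
  elem <- vapply(c("n_N", "n_O", "n_C", "n_S"),
                 function(col) sum(sub[[col]]), numeric(1))
  derived <- c(
    sum(sub$positive) - sum(sub$negative),
    sum(sub$n_atoms[sub$aromatic == 1L]),
    sum(sub$n_hbd),
    sum(sub$n_hba))
  out <- c(type_counts, n, class_counts, sums, means, elem, derived)
  names(out) <- region_descriptor_names()
  out
}

# --- N5 environment ------------------------------------------------------

#' Residue nearest to the flavin N5 atom
#'
#' The standard residue minimising the minimum heavy-atom distance to the
#' N5 position; ties are broken by chain order in the file, then by lower
#' author sequence number.
#'
#' @inheritParams ring_union_region
#' @return One-row data frame (key, chain, resno, insert, resid).
#' @export
n5_nearest_residue <- function(structure, site) {
  a <- .protein_heavy_atoms(structure)
  stopifnot(nrow(a) > 0)
  n5 <- site$n5_coord
  d2 <- (a$x - n5[1])^2 + (a$y - n5[2])^2 + (a$z - n5[3])^2
  res <- .residue_table(a)
  res$d2 <- as.numeric(tapply(d2, factor(a$key, levels = res$key), min))
  res <- res[order(res$d2,
                   match(res$chain, structure$chain_order),
                   res$resno), , drop = FALSE]
  res[1, c("key", "chain", "resno", "insert", "resid"), drop = FALSE]
}

#' N5-environment descriptor pair
#'
#' Computes the two 28-value N5 descriptor blocks: `N5_nearest_<X>` — the
#' residue-identity indicator plus the 8 property values of the residue
#' nearest to N5 — and `Around_N5.<X>` — identity counts and property sums
#' over that residue and its two neighbours in the owning chain's sequence
#' (a terminal nearest residue contributes only the existing neighbours).
#'
#' @inheritParams ring_union_region
#' @param table Property table.
#' @return List with numeric vectors `n5_nearest` and `around_n5`, each of
#'   length 28 (names = [n5_descriptor_names()]).
#' @export
n5_descriptors <- function(structure, site, table = aa_property_table()) {
  nearest <- n5_nearest_residue(structure, site)
  chain_res <- .residue_table(
    .protein_heavy_atoms(structure)[
      .protein_heavy_atoms(structure)$chain == nearest$chain, , drop = FALSE])
  i <- match(nearest$key, chain_res$key)
  trio <- chain_res$resid[max(1L, i - 1L):min(nrow(chain_res), i + 1L)]

  block <- function(resids) {
    ident <- tabulate(factor(resids, levels = AA3), nbins = 20L)
    props <- vapply(AA_PROPERTIES,
                    function(col) sum(table[resids, col]), numeric(1))
    out <- c(ident, props)
    names(out) <- n5_descriptor_names()
    out
  }
  list(n5_nearest = block(nearest$resid), around_n5 = block(trio))
}
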