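# Canonical atom-name set of the isoalloxazine ring system (tricyclic core
# plus its methyls C7M/C8M and carbonyl oxygens O2/O4). FAD entries in the
# PDB chemical dictionary may alias C4A/C5A as C4X/C5X.
ISOALLOXAZINE_ATOMS <- c("N1", "C2", "O2", "N3", "C4", "O4", "C4A", "N5",
                         "C5A", "C6", "C7", "C7M", "C8", "C8M", "C9", "C9A",
                         "N10")
FAD_RING_ALIASES <- c(C4X = "C4A", C5X = "C5A")
FLAVIN_RESIDUES <- c("FMN", "FAD")

.residue_key <- function(chain, resno, insert, resid) {
  paste(chain, resno, insert, resid, sep = "|")
}

.guess_element <- function(elety) {
  # fall back on the atom-name convention when columns 77-78 are absent
  nm <- gsub("[^A-Za-z]", "", elety)
  two <- toupper(substr(nm, 1, 2))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "SE"),
         two, toupper(substr(nm, 1, 1)))
}

#' Parse a PDB file into a protein structure model
#'
#' Reads ATOM/HETATM coordinate records (first model only) into an internal
#' structure model: standard amino-acid residues grouped per chain in file
#' order, and hetero groups (cofactors, waters, ...) kept separately. For
#' atoms with alternate locations, only the highest-occupancy altloc is
#' retained (ties broken in favour of altloc `"A"`). Hydrogens are retained
#' in the model but flagged, and are excluded from all downstream distance
#' computations. ATOM records with non-canonical residue names are kept with
#' `is_standard = FALSE` and reported in a warning.
#'
#' @param pdb_text A single string (or character vector of lines) holding
#'   the PDB file content, or the path to a PDB file.
#' @param source_id Optional label stored with the structure.
#' @return An object of class `ProteinStructure`: a list with `atoms`
#'   (data frame of polymer ATOM records with chain, resno, insert, resid,
#'   elety, element, x, y, z, occupancy, is_standard, is_h, key), `hetero`
#'   (same layout for HETATM groups), `chain_order` and `source_id`.
#' @export
parse_structure <- function(pdb_text, source_id = "structure") {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    path <- pdb_text
    if (identical(source_id, "structure"))
      source_id <- tools::file_path_sans_ext(basename(path))
  } else {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb_text) == 1L)
      strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text, path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("no parseable coordinate records: ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L)
    stop("no parseable coordinate records in input", call. = FALSE)

  df <- data.frame(
    record   = at$type,
    chain    = ifelse(is.na(at$chain), "", at$chain),
    resno    = at$resno,
    insert   = ifelse(is.na(at$insert), "", at$insert),
    resid    = at$resid,
    elety    = at$elety,
    altloc   = ifelse(is.na(at$alt), "", at$alt),
    element  = ifelse(is.na(at$elesy) | at$elesy == "",
                      .guess_element(at$elety), toupper(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)
  df$key <- .residue_key(df$chain, df$resno, df$insert, df$resid)

  # altloc resolution: per (residue, atom name) keep highest occupancy,
  # ties prefer 'A', then alphabetical
  if (any(df$altloc != "")) {
    df$.ord <- seq_len(nrow(df))
    pref <- ifelse(df$altloc %in% c("", "A"), 0L, 1L)
    o <- order(df$key, df$elety, -df$occupancy, pref, df$altloc)
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(paste(df$key, df$elety)), , drop = FALSE]
    df <- df[order(df$.ord), , drop = FALSE]
    df$.ord <- NULL
  }
  rownames(df) <- NULL

  df$is_h <- df$element %in% c("H", "D")
  is_atom <- df$record == "ATOM"
  prot <- df[is_atom, , drop = FALSE]
  het <- df[!is_atom, , drop = FALSE]
  prot$is_standard <- prot$resid %in% AA3
  if (nrow(prot) > 0 && any(!prot$is_standard)) {
    warning("non-standard polymer residue name(s) kept with is_standard = FALSE: ",
            paste(unique(prot$resid[!prot$is_standard]), collapse = ", "),
            call. = FALSE)
  }
  if (nrow(prot) == 0L || !any(prot$is_standard))
    stop("structure contains no standard amino-acid residues", call. = FALSE)

  structure(list(atoms = prot, hetero = het,
                 chain_order = unique(prot$chain),
                 source_id = source_id),
            class = "ProteinStructure")
}

#' @export
print.ProteinStructure <- function(x, ...) {
  res <- unique(x$atoms$key[x$atoms$is_standard])
  cat("ProteinStructure <", x$source_id, ">: ",
      length(res), " standard residues in ", length(x$chain_order),
      " chain(s); ", length(unique(x$hetero$key)), " hetero group(s)\n",
      sep = "")
  invisible(x)
}

# non-hydrogen polymer atoms of standard residues, as a coordinate matrix
# with the residue bookkeeping alongside
.protein_heavy_atoms <- function(structure) {
  a <- structure$atoms
  a[a$is_standard & !a$is_h, , drop = FALSE]
}

#' Locate flavin cofactors and their isoalloxazine ring geometry
#'
#' Finds every FMN/FAD hetero group in a parsed structure and returns, for
#' each, the isoalloxazine ring-atom coordinates, their barycenter, the N5
#' position and the owning protein chain (the chain whose residues come
#' closest to the ring barycenter, any non-hydrogen atom).
#'
#' @param structure A [parse_structure()] result.
#' @return A list of `FlavinSite` objects, each with fields
#'   `cofactor_kind` (`"FMN"` or `"FAD"`), `ring_atoms` (17 x 3 coordinate
#'   matrix, canonical atom names as rownames), `barycenter`, `n5_coord`,
#'   `chain_id` and `group_key`. Empty list when no flavin is present.
#' @export
locate_flavin_sites <- function(structure) {
  het <- structure$hetero
  flav <- het[het$resid %in% FLAVIN_RESIDUES, , drop = FALSE]
  if (nrow(flav) == 0L) return(list())
  sites <- list()
  for (key in unique(flav$key)) {
    grp <- flav[flav$key == key, , drop = FALSE]
    kind <- grp$resid[1]
    nm <- grp$elety
    if (kind == "FAD") {
      ali <- nm %in% names(FAD_RING_ALIASES)
      nm[ali] <- FAD_RING_ALIASES[nm[ali]]
    }
    idx <- match(ISOALLOXAZINE_ATOMS, nm)
    if (anyNA(idx))
      stop("cofactor ", key, " is missing isoalloxazine atom(s): ",
           paste(ISOALLOXAZINE_ATOMS[is.na(idx)], collapse = ", "),
           call. = FALSE)
    ring <- as.matrix(grp[idx, c("x", "y", "z")])
    rownames(ring) <- ISOALLOXAZINE_ATOMS
    bc <- colMeans(ring)
    prot <- .protein_heavy_atoms(structure)
    d2 <- (prot$x - bc[1])^2 + (prot$y - bc[2])^2 + (prot$z - bc[3])^2
    chain_min <- tapply(d2, factor(prot$chain, levels = structure$chain_order),
                        min)
    chain_id <- structure$chain_order[which.min(chain_min)]
    sites[[length(sites) + 1L]] <- structure(
      list(cofactor_kind = kind, ring_atoms = ring, barycenter = bc,
           n5_coord = ring["N5", ], chain_id = chain_id, group_key = key),
      class = "FlavinSite")
  }
  sites
}

#' Barycenter of the isoalloxazine ring
#'
#' Unweighted arithmetic mean of the ring-atom coordinates of a flavin site.
#'
#' @param site A `FlavinSite` from [locate_flavin_sites()].
#' @return Numeric 3-vector (x, y, z) in Angstrom.
#' @export
ring_barycenter <- function(site) {
  stopifnot(inherits(site, "FlavinSite"), nrow(site$ring_atoms) > 0)
  colMeans(site$ring_atoms)
}

#' @export
print.FlavinSite <- function(x, ...) {
  cat("FlavinSite ", x$cofactor_kind, " [", x$group_key, "] chain ",
      x$chain_id, "; barycenter (",
      paste(sprintf("%.2f", x$barycenter), collapse = ", "), ") A\n",
      sep = "")
  invisible(x)
}
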