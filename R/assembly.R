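# --- the 246-descriptor naming contract ----------------------------------

#' Names of the full 246-descriptor vector
#'
#' Fixed order: 55 region descriptors at each of the three scopes
#' (`Protein.<X>`, `Bar.<X>`, `Ring.<X>`), the 3 ring-proximity atom counts
#' (`Nitrogen_Around`, `Oxygen_Around`, `Carbon_Around`), the 28
#' `N5_nearest_<X>` and 28 `Around_N5.<X>` descriptors, the 21 CTD
#' descriptors, and `pH`.
#'
#' @return Character vector of length 246.
#' @export
feature_vector_names <- function() {
  reg <- region_descriptor_names()
  n5 <- n5_descriptor_names()
  c(paste0("Protein.", reg), paste0("Bar.", reg), paste0("Ring.", reg),
    c("Nitrogen_Around", "Oxygen_Around", "Carbon_Around"),
    paste0("N5_nearest_", n5), paste0("Around_N5.", n5),
    ctd_feature_names(), "pH")
}

# descriptors of one flavin site against its structure
.site_feature_vector <- function(structure, site, r1, r2,
                                 ctd_attribute = "hydrophobicity",
                                 table = aa_property_table()) {
  a <- .protein_heavy_atoms(structure)
  own <- .residue_table(a[a$chain == site$chain_id, , drop = FALSE])
  prot_block <- region_descriptors(own$resid, table)
  bar_block <- region_descriptors(
    residues_in_sphere(structure, site$barycenter, r1), table)
  ring_block <- region_descriptors(
    ring_union_region(structure, site, r2), table)
  counts <- ring_atom_counts(structure, site, r2)
  n5 <- n5_descriptors(structure, site, table)
  ctd <- ctd_features(structure_sequence(structure, site$chain_id),
                      ctd_attribute)
  reg <- region_descriptor_names()
  out <- c(stats::setNames(prot_block, paste0("Protein.", reg)),
           stats::setNames(bar_block, paste0("Bar.", reg)),
           stats::setNames(ring_block, paste0("Ring.", reg)),
           counts,
           stats::setNames(n5$n5_nearest,
                           paste0("N5_nearest_", n5_descriptor_names())),
           stats::setNames(n5$around_n5,
                           paste0("Around_N5.", n5_descriptor_names())),
           ctd)
  out
}

#' Build the named 246-descriptor vector for one structure
#'
#' Locates every flavin site, computes the full descriptor vector per site
#' at radii (`r1`, `r2`), averages element-wise over sites when the
#' structure carries several flavins, and appends the assay pH (may be
#' `NA`; imputed later from training data).
#'
#' @param structure A [parse_structure()] result with at least one FMN/FAD.
#' @param pH Assay pH of the record, or `NA` when unknown.
#' @param r1 Barycenter-sphere radius, Angstrom (study grid: 8–16).
#' @param r2 Per-ring-atom sphere radius, Angstrom (study grid: 3–6).
#' @param ctd_attribute Attribute used for the CTD block.
#' @param table Property table.
#' @return Named numeric vector of length 246 ([feature_vector_names()]).
#' @export
build_feature_vector <- function(structure, pH = NA_real_, r1, r2,
                                 ctd_attribute = "hydrophobicity",
                                 table = aa_property_table()) {
  sites <- locate_flavin_sites(structure)
  if (length(sites) == 0L)
    stop("no FMN/FAD cofactor found in structure ", structure$source_id,
         call. = FALSE)
  vecs <- lapply(sites, function(s)
    .site_feature_vector(structure, s, r1, r2, ctd_attribute, table))
  out <- c(aggregate_multi_cofactor(vecs), pH = as.numeric(pH))
  stopifnot(identical(names(out), feature_vector_names()))
  out
}

#' Average descriptor vectors over multiple flavin sites
#'
#' Element-wise arithmetic mean of per-site descriptor vectors, yielding
#' one vector per record for structures with several flavin cofactors.
#' A single vector is returned unchanged.
#'
#' @param per_site_vectors List of identically named numeric vectors.
#' @return Named numeric vector.
#' @export
aggregate_multi_cofactor <- function(per_site_vectors) {
  stopifnot(length(per_site_vectors) >= 1L)
  nm <- names(per_site_vectors[[1]])
  for (v in per_site_vectors)
    if (!identical(names(v), nm))
      stop("inconsistent descriptor naming across sites", call. = FALSE)
  if (length(per_site_vectors) == 1L) return(per_site_vectors[[1]])
  rowMeans(do.call(cbind, per_site_vectors))
}

#' The (r1, r2) radius grid of the study
#'
#' Full Cartesian grid r1 = 8, 9, ..., 16 Angstrom by r2 = 3, 4, 5, 6
#' Angstrom (36 configurations), ordered r1 ascending then r2 ascending.
#'
#' @param r1 Vector of barycenter-sphere radii.
#' @param r2 Vector of ring-atom sphere radii.
#' @return Data frame with columns `r1`, `r2`.
#' @export
radius_grid <- function(r1 = 8:16, r2 = 3:6) {
  g <- expand.grid(r2 = r2, r1 = r1)[, c("r1", "r2")]
  rownames(g) <- NULL
  g
}

#' Assemble a design matrix at one radius configuration
#'
#' Builds one row per study record: the 246 descriptors of the record's
#' structure at (`r1`, `r2`) plus the measured `E_m` label (247 columns).
#' Records sharing a structure at different pH yield distinct rows with
#' identical structural descriptors. Structures are parsed once per unique
#' file.
#'
#' @param records Data frame with columns `structure_id`, `pdb_path`,
#'   `E_m_mV` and optionally `pH`.
#' @param r1,r2 Radii, Angstrom.
#' @param skip_failures If `TRUE`, records whose structure cannot be
#'   processed are dropped with a warning instead of failing the build.
#' @param ctd_attribute,table Passed to [build_feature_vector()].
#' @return Data frame (class `DesignMatrix`) of dimension
#'   n_records x 247 with attributes `r1`, `r2` and rownames from
#'   `structure_id` (made unique).
#' @export
build_design_matrix <- function(records, r1, r2, skip_failures = FALSE,
                                ctd_attribute = "hydrophobicity",
                                table = aa_property_table()) {
  stopifnot(all(c("structure_id", "pdb_path", "E_m_mV") %in% names(records)))
  if (!"pH" %in% names(records)) records$pH <- NA_real_
  cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(records))
  ok <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    res <- tryCatch({
      key <- rec$pdb_path
      if (!exists(key, envir = cache, inherits = FALSE))
        assign(key, parse_structure(rec$pdb_path,
                                    source_id = rec$structure_id),
               envir = cache)
      build_feature_vector(get(key, envir = cache), pH = rec$pH,
                           r1 = r1, r2 = r2,
                           ctd_attribute = ctd_attribute, table = table)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (!skip_failures)
        stop("record ", rec$structure_id, " failed: ",
             conditionMessage(res), call. = FALSE)
      warning("skipping record ", rec$structure_id, ": ",
              conditionMessage(res), call. = FALSE)
      ok[i] <- FALSE
    } else rows[[i]] <- res
  }
  rows <- rows[ok]
  mat <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  mat$E_m <- records$E_m_mV[ok]
  rownames(mat) <- make.unique(as.character(records$structure_id[ok]))
  attr(mat, "r1") <- r1
  attr(mat, "r2") <- r2
  class(mat) <- c("DesignMatrix", "data.frame")
  mat
}

#' Write / read a design matrix as CSV with exact round-trip
#'
#' Values are written with the `%.17g` format so that re-reading restores
#' every double bit-exactly; the header carries the descriptor naming
#' contract verbatim.
#'
#' @param mat A [build_design_matrix()] result (or any numeric data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(mat, path) {
  fm <- as.data.frame(lapply(mat, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col))),
    check.names = FALSE)
  utils::write.csv(cbind(structure_id = rownames(mat), fm), path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_design_matrix
#' @export
read_design_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  rn <- df$structure_id
  df$structure_id <- NULL
  df[] <- lapply(df, as.numeric)
  rownames(df) <- rn
  class(df) <- c("DesignMatrix", "data.frame")
  df
}
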