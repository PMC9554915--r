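gen <- fixture_structure(seed = 21, n_decoys = 8)
st <- parse_structure(gen$pdb_text)
site <- locate_flavin_sites(st)[[1]]

test_that("sphere membership matches an exhaustive atom scan and nests", {
  expect_equal(nrow(residues_in_sphere(st, site$barycenter, 0)), 0L)
  for (r in c(5, 9, 30)) {
    got <- residues_in_sphere(st, site$barycenter, r)$key
    expect_setequal(got, oracle_sphere_keys(st, site$barycenter, r))
  }
  # ball nesting
  r_small <- residues_in_sphere(st, site$barycenter, 6)$key
  r_big <- residues_in_sphere(st, site$barycenter, 12)$key
  expect_true(all(r_small %in% r_big))
})

test_that("ring-union region equals the brute-force union of per-atom scans", {
  expect_equal(nrow(ring_union_region(st, site, 0)), 0L)
  for (r2 in c(3, 4.5, 8)) {
    got <- ring_union_region(st, site, r2)$key
    expect_setequal(got, oracle_ring_union_keys(st, site, r2))
  }
  # degenerate union: one-atom "ring" equals a plain sphere
  site1 <- site
  site1$ring_atoms <- site$ring_atoms["N5", , drop = FALSE]
  expect_setequal(ring_union_region(st, site1, 7)$key,
                  residues_in_sphere(st, site$n5_coord, 7)$key)
})

test_that("region descriptors equal the recount oracle and handle edge cases", {
  empty <- region_descriptors(character(0))
  expect_length(empty, 55L)
  expect_true(all(empty == 0))  # empty-region convention, means included

  one <- region_descriptors("GLN")
  expect_equal(one[["GLN"]], 1)
  expect_equal(one[["ResTotal"]], 1)
  expect_equal(one[["nNats in side chain"]], 1)
  expect_equal(one[["ResPolar"]], 1)

  for (s in 1:20) {
    resids <- random_resids(30, seed = 100 + s)
    expect_equal(region_descriptors(resids),
                 oracle_region_descriptors(resids), tolerance = 1e-12)
  }
  expect_warning(region_descriptors(c("ALA", "MSE")), "MSE")
})

test_that("ring atom counts match the oracle and are monotone in r2", {
  expect_equal(ring_atom_counts(st, site, 0),
               c(Nitrogen_Around = 0, Oxygen_Around = 0, Carbon_Around = 0))
  prev <- c(0, 0, 0)
  for (r2 in c(3, 4, 5, 6)) {
    got <- ring_atom_counts(st, site, r2)
    expect_equal(got, oracle_ring_atom_counts(st, site, r2))
    expect_true(all(got >= prev))
    prev <- got
  }
  # a residue planted right against N5 brings its backbone N inside r2 = 4
  pl <- data.frame(resid = c("GLY", "ALA"), dmin = c(3, 18),
                   dmax = c(5, 26), ref = c("N5", "barycenter"),
                   chain = "A", resno = 1:2)
  gn <- generate_structure(pl, seed = 9)
  stn <- parse_structure(gn$pdb_text)
  siten <- locate_flavin_sites(stn)[[1]]
  cnt <- ring_atom_counts(stn, siten, 6)
  expect_gte(cnt[["Nitrogen_Around"]], 1)
  expect_equal(cnt, oracle_ring_atom_counts(stn, siten, 6))
})

test_that("N5-nearest residue follows generator placement and the tie rule", {
  pl <- data.frame(resid = c("TRP", "ALA", "GLY"), dmin = c(3, 18, 18),
                   dmax = c(5, 26, 26), ref = c("N5", "barycenter",
                                                "barycenter"),
                   chain = "A", resno = 1:3)
  gn <- generate_structure(pl, seed = 17)
  stn <- parse_structure(gn$pdb_text)
  siten <- locate_flavin_sites(stn)[[1]]
  expect_equal(n5_nearest_residue(stn, siten)$resid, "TRP")
  # rigid rotation leaves the answer unchanged
  rot <- rotate_structure(stn)
  site_rot <- locate_flavin_sites(rot)[[1]]
  expect_equal(n5_nearest_residue(rot, site_rot)$resno,
               n5_nearest_residue(stn, siten)$resno)

  # exact tie: two CA-only residues mirrored about N5; lower resno wins
  txt <- paste(
    "ATOM      1  CA  ALA A   5       5.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2      -5.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  st_tie <- parse_structure(txt)
  site_tie <- site
  site_tie$n5_coord <- c(0, 0, 0)
  expect_equal(n5_nearest_residue(st_tie, site_tie)$resno, 2L)
})

test_that("N5 descriptor blocks follow the nearest-plus-neighbours contract", {
  # chain ALA-GLY-ALA with the middle GLY nearest to N5
  pl <- data.frame(resid = c("ALA", "GLY", "ALA"),
                   dmin = c(8, 3, 8), dmax = c(11, 5, 11),
                   ref = "N5", chain = "A", resno = 1:3)
  gn <- generate_structure(pl, seed = 23)
  stn <- parse_structure(gn$pdb_text)
  siten <- locate_flavin_sites(stn)[[1]]
  d <- n5_descriptors(stn, siten)
  expect_length(d$n5_nearest, 28L)
  expect_length(d$around_n5, 28L)
  ident <- d$n5_nearest[flavoqspr:::AA3]
  expect_equal(sum(ident), 1)
  expect_equal(unname(d$n5_nearest[["GLY"]]), 1)
  h <- function(r) property_value(r, "hydrophobicity")
  expect_equal(unname(d$around_n5[["Hydrophobicity"]]),
               2 * h("ALA") + h("GLY"))
  expect_equal(sum(d$around_n5[flavoqspr:::AA3]), 3)

  # terminal nearest residue: only two residues contribute
  pl2 <- data.frame(resid = c("GLY", "ALA", "ALA"),
                    dmin = c(3, 8, 12), dmax = c(5, 11, 15),
                    ref = "N5", chain = "A", resno = 1:3)
  gn2 <- generate_structure(pl2, seed = 29)
  st2 <- parse_structure(gn2$pdb_text)
  d2 <- n5_descriptors(st2, locate_flavin_sites(st2)[[1]])
  expect_equal(sum(d2$around_n5[flavoqspr:::AA3]), 2)
})

test_that("all geometric descriptors are invariant under rigid motion", {
  rot <- rotate_structure(st)
  site_rot <- locate_flavin_sites(rot)[[1]]
  for (r in list(c(8, 3), c(12, 5))) {
    a <- region_descriptors(residues_in_sphere(st, site$barycenter, r[1]))
    b <- region_descriptors(residues_in_sphere(rot, site_rot$barycenter,
                                               r[1]))
    expect_equal(a, b, tolerance = 1e-9)
    expect_equal(ring_atom_counts(st, site, r[2]),
                 ring_atom_counts(rot, site_rot, r[2]))
    expect_equal(region_descriptors(ring_union_region(st, site, r[2])),
                 region_descriptors(ring_union_region(rot, site_rot, r[2])),
                 tolerance = 1e-9)
  }
})

test_that("whole-protein scope is the large-radius limit of the sphere scope", {
  whole <- region_descriptors(
    flavoqspr:::.residue_table(flavoqspr:::.protein_heavy_atoms(st)))
  limit <- region_descriptors(residues_in_sphere(st, site$barycenter, 1e6))
  expect_equal(whole, limit)
})
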