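test_that("minimal PDB text parses into chains and residues", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  st <- parse_structure(txt, source_id = "toy")
  expect_s3_class(st, "ProteinStructure")
  expect_equal(st$chain_order, "A")
  expect_equal(unique(st$atoms$resid), c("ALA", "GLY"))
  expect_equal(nrow(st$atoms), 2L)

  expect_error(parse_structure("REMARK nothing here\nEND"),
               "no parseable")
})

test_that("altloc resolution keeps the highest occupancy, ties prefer A", {
  mk <- function(occ_a, occ_b) paste(
    sprintf("ATOM      1  CA AALA A   1       1.000   0.000   0.000%6.2f  0.00           C", occ_a),
    sprintf("ATOM      2  CA BALA A   1       2.000   0.000   0.000%6.2f  0.00           C", occ_b),
    "ATOM      3  CA  GLY A   2       9.000   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  st <- parse_structure(mk(0.6, 0.4))
  expect_equal(nrow(st$atoms[st$atoms$resid == "ALA", ]), 1L)
  expect_equal(st$atoms$x[st$atoms$resid == "ALA"], 1.0)
  # B has the higher occupancy
  st2 <- parse_structure(mk(0.3, 0.7))
  expect_equal(st2$atoms$x[st2$atoms$resid == "ALA"], 2.0)
  # tie goes to A
  st3 <- parse_structure(mk(0.5, 0.5))
  expect_equal(st3$atoms$x[st3$atoms$resid == "ALA"], 1.0)
})

test_that("non-standard polymer residues are kept but flagged with a warning", {
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  XYZ A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_warning(st <- parse_structure(txt), "XYZ")
  expect_false(all(st$atoms$is_standard))
  expect_equal(sum(st$atoms$is_standard), 1L)
})

test_that("parsing round-trips generator bookkeeping and is idempotent", {
  gen <- fixture_structure(seed = 11)
  expect_silent(st <- parse_structure(gen$pdb_text))
  n_parsed <- nrow(st$atoms) + nrow(st$hetero)
  expect_identical(n_parsed, as.integer(attr(gen$ground_truth, "n_atoms")))
  # per-residue element counts match the generator's declaration
  gt <- gen$ground_truth
  for (i in seq_len(nrow(gt))) {
    sel <- st$atoms$chain == gt$chain[i] & st$atoms$resno == gt$resno[i]
    expect_equal(sum(st$atoms$element[sel] == "N"), gt$n_N[i])
    expect_equal(sum(st$atoms$element[sel] == "S"), gt$n_S[i])
    expect_equal(sum(sel), gt$n_atoms[i])
  }
  # re-serialise retained atoms and re-parse: identical coordinates
  relines <- vapply(seq_len(nrow(st$atoms)), function(i)
    flavoqspr:::.pdb_atom_line("ATOM", i, st$atoms$elety[i],
                               st$atoms$resid[i], st$atoms$chain[i],
                               st$atoms$resno[i],
                               c(st$atoms$x[i], st$atoms$y[i], st$atoms$z[i]),
                               st$atoms$element[i]), character(1))
  st2 <- parse_structure(paste(c(relines, "END"), collapse = "\n"))
  expect_equal(st2$atoms[, c("x", "y", "z")], st$atoms[, c("x", "y", "z")])
})

test_that("flavin sites are located with the canonical ring-atom set", {
  gen <- fixture_structure(seed = 3)
  st <- parse_structure(gen$pdb_text)
  sites <- locate_flavin_sites(st)
  expect_length(sites, 1L)
  expect_equal(sites[[1]]$cofactor_kind, "FMN")
  expect_equal(nrow(sites[[1]]$ring_atoms), 17L)
  expect_true("N5" %in% rownames(sites[[1]]$ring_atoms))
  expect_equal(sites[[1]]$chain_id, "A")

  # two FAD groups on two chains -> two sites with distinct owners
  pl <- data.frame(resid = c("ALA", "GLY"), dmin = 4, dmax = 7,
                   ref = "barycenter", chain = c("A", "B"), resno = 1:2)
  cof <- data.frame(kind = "FAD", chain = c("A", "B"), resno = c(901L, 902L),
                    x = c(0, 40), y = 0, z = 0)
  gen2 <- generate_structure(pl, cofactors = cof, seed = 5)
  st2 <- parse_structure(gen2$pdb_text)
  sites2 <- locate_flavin_sites(st2)
  expect_length(sites2, 2L)
  expect_setequal(vapply(sites2, function(s) s$cofactor_kind, ""), "FAD")
  # FAD aliases C4X/C5X resolve to the canonical names
  expect_true(all(c("C4A", "C5A") %in% rownames(sites2[[1]]$ring_atoms)))

  # structure with no flavin -> empty list
  txt <- paste(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_length(locate_flavin_sites(parse_structure(txt)), 0L)
})

test_that("a cofactor missing ring atoms fails naming the missing atom", {
  gen <- fixture_structure(seed = 3)
  lines <- strsplit(gen$pdb_text, "\n")[[1]]
  lines <- lines[!grepl("^HETATM.* N5 ", lines)]
  st <- parse_structure(paste(lines, collapse = "\n"))
  expect_error(locate_flavin_sites(st), "N5")
})

test_that("ring barycenter is the coordinate mean, equivariant and order-free", {
  mk_site <- function(coords) {
    structure(list(cofactor_kind = "FMN", ring_atoms = coords,
                   barycenter = colMeans(coords),
                   n5_coord = coords[1, ], chain_id = "A",
                   group_key = "x"), class = "FlavinSite")
  }
  two <- rbind(N5 = c(0, 0, 0), C4A = c(2, 0, 0))
  expect_equal(ring_barycenter(mk_site(two)), c(1, 0, 0),
               ignore_attr = TRUE)
  set.seed(42)
  ring <- matrix(rnorm(51), 17, 3,
                 dimnames = list(flavoqspr:::ISOALLOXAZINE_ATOMS, NULL))
  bc <- ring_barycenter(mk_site(ring))
  # brute-force mean oracle
  expect_equal(bc, apply(ring, 2, function(col) sum(col) / 17))
  # translation equivariance and permutation invariance
  t <- c(5, -3, 2)
  expect_equal(ring_barycenter(mk_site(sweep(ring, 2, -t))), bc + t)
  perm <- sample(17)
  expect_equal(ring_barycenter(mk_site(ring[perm, ])), bc)
})
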