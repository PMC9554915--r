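# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use plain loops and from-definition formulas, not the
# package's vectorised code paths.

aa3 <- flavoqspr:::AA3

# --- oracles -------------------------------------------------------------

oracle_region_descriptors <- function(resids, tab = aa_property_table()) {
  out <- stats::setNames(numeric(55), region_descriptor_names())
  for (aa in aa3) out[aa] <- sum(resids == aa)
  out["ResTotal"] <- length(resids)
  cls_map <- c(ResPolar = "polar", ResApolar = "apolar",
               ResCharged = "charged", ResPositive = "positive",
               ResNegative = "negative", ResHydrophobic = "hydrophobic",
               ResAromatic = "aromatic", ResSmall = "small",
               ResHBondDonor = "hbond_donor",
               ResHBondAcceptor = "hbond_acceptor")
  for (nm in names(cls_map)) {
    k <- 0
    for (r in resids) if (tab[r, cls_map[nm]] == 1) k <- k + 1
    out[nm] <- k
  }
  props <- flavoqspr:::AA_PROPERTIES
  for (lab in names(props)) {
    s <- 0
    for (r in resids) s <- s + tab[r, props[lab]]
    out[lab] <- s
    out[paste(lab, "mean")] <- if (length(resids)) s / length(resids) else 0
  }
  el_map <- c("nNats in side chain" = "n_N", "nOats in side chain" = "n_O",
              "nCats in side chain" = "n_C", "nSats in side chain" = "n_S")
  for (nm in names(el_map)) {
    s <- 0
    for (r in resids) s <- s + tab[r, el_map[nm]]
    out[nm] <- s
  }
  pos <- neg <- arom_at <- hbd <- hba <- 0
  for (r in resids) {
    pos <- pos + tab[r, "positive"]; neg <- neg + tab[r, "negative"]
    if (tab[r, "aromatic"] == 1) arom_at <- arom_at + tab[r, "n_atoms"]
    hbd <- hbd + tab[r, "n_hbd"]; hba <- hba + tab[r, "n_hba"]
  }
  out["Net charge"] <- pos - neg
  out["Aromatic atoms"] <- arom_at
  out["HBond donor atoms"] <- hbd
  out["HBond acceptor atoms"] <- hba
  out
}

# exhaustive atom scan for sphere membership (residue keys)
oracle_sphere_keys <- function(structure, center, radius) {
  a <- structure$atoms
  keys <- character(0)
  for (i in seq_len(nrow(a))) {
    if (!a$is_standard[i] || a$is_h[i]) next
    d <- sqrt((a$x[i] - center[1])^2 + (a$y[i] - center[2])^2 +
                (a$z[i] - center[3])^2)
    if (d <= radius) keys <- c(keys, a$key[i])
  }
  unique(keys)
}

oracle_ring_union_keys <- function(structure, site, r2) {
  keys <- character(0)
  for (j in seq_len(nrow(site$ring_atoms)))
    keys <- c(keys, oracle_sphere_keys(structure, site$ring_atoms[j, ], r2))
  unique(keys)
}

oracle_ring_atom_counts <- function(structure, site, r2) {
  a <- structure$atoms
  n <- o <- ca <- 0
  for (i in seq_len(nrow(a))) {
    if (!a$is_standard[i] || a$is_h[i]) next
    within <- FALSE
    for (j in seq_len(nrow(site$ring_atoms))) {
      d <- sqrt(sum((c(a$x[i], a$y[i], a$z[i]) - site$ring_atoms[j, ])^2))
      if (d <= r2) { within <- TRUE; break }
    }
    if (within) {
      if (a$element[i] == "N") n <- n + 1
      else if (a$element[i] == "O") o <- o + 1
      else if (a$element[i] == "C") ca <- ca + 1
    }
  }
  c(Nitrogen_Around = n, Oxygen_Around = o, Carbon_Around = ca)
}

oracle_ctd <- function(encoded) {
  L <- length(encoded)
  out <- numeric(0)
  for (cl in 1:3) out <- c(out, sum(encoded == cl) / L)
  for (pr in list(c(1, 2), c(1, 3), c(2, 3))) {
    k <- 0
    for (i in 1:(L - 1)) {
      pair <- sort(c(encoded[i], encoded[i + 1]))
      if (pair[1] == pr[1] && pair[2] == pr[2]) k <- k + 1
    }
    out <- c(out, k / (L - 1))
  }
  for (cl in 1:3) {
    pos <- which(encoded == cl)
    if (length(pos) == 0) { out <- c(out, rep(0, 5)); next }
    m <- length(pos)
    for (q in c(0, 0.25, 0.5, 0.75, 1)) {
      idx <- if (q == 0) 1 else ceiling(q * m)
      out <- c(out, pos[idx] / L * 100)
    }
  }
  stats::setNames(out, ctd_feature_names())
}

oracle_metrics <- function(y, yhat) {
  n <- length(y)
  mae <- sum(abs(y - yhat)) / n
  rmse <- sqrt(sum((y - yhat)^2) / n)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  sc <- stats::cor(rank(y), rank(yhat))
  c(MAE = mae, RMSE = rmse, R2 = r2, SC = sc)
}

# two-sided Mann-Whitney U p-value, normal approximation with tie
# correction, no continuity correction
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  u <- 0
  for (xi in x) for (yj in y)
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  N <- n1 + n2
  sig <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
  z <- (u - mu) / sig
  2 * stats::pnorm(-abs(z))
}

# --- fixture builders ----------------------------------------------------

# standard fixture: 3 residues near the barycenter, a few decoys far out
fixture_structure <- function(seed = 1, inner = c("ARG", "GLN", "HIS"),
                              n_decoys = 5, dmin = 4, dmax = 7) {
  pl <- data.frame(resid = inner, dmin = dmin, dmax = dmax,
                   ref = "barycenter", chain = "A",
                   resno = seq_along(inner))
  generate_structure(pl, n_decoys = n_decoys, seed = seed)
}

rotate_structure <- function(structure, angle = 0.7,
                             axis = c(1, 1, 1) / sqrt(3), shift = c(3, -2, 5)) {
  # Rodrigues rotation applied to every coordinate
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rot <- function(df) {
    xyz <- t(R %*% t(as.matrix(df[, c("x", "y", "z")]))) +
      rep(shift, each = nrow(df))
    df[, c("x", "y", "z")] <- xyz
    df
  }
  structure$atoms <- rot(structure$atoms)
  if (nrow(structure$hetero)) structure$hetero <- rot(structure$hetero)
  structure
}

random_resids <- function(n, seed) {
  set.seed(seed)
  sample(aa3, n, replace = TRUE)
}
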