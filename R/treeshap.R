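# Exact path-dependent Shapley attributions for gradient-boosted trees,
# computed in double precision from the dumped trees. xgboost's built-in
# contribution predictor works in single precision, whose round-off at mV
# scale exceeds the package's local-accuracy contract (1e-4 mV); this
# implementation trades speed for exactness. Attributions are additive
# across trees; per tree the classic polynomial-time path algorithm is
# used, with split covers defining the background weighting.

# round doubles through IEEE single precision; split comparisons must be
# made on float32 values to replicate the booster's branching exactly
.f32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), what = "numeric",
          size = 4L, n = length(x))
}

# parse a booster into per-tree node tables with feature indices resolved
# against the training feature names
.xgb_tree_tables <- function(booster, feature_names) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = booster))
  trees <- split(dump, dump$Tree)
  lapply(trees, function(tr) {
    tr <- tr[order(tr$Node), , drop = FALSE]
    id2idx <- stats::setNames(seq_len(nrow(tr)), tr$ID)
    is_leaf <- tr$Feature == "Leaf"
    list(feature = ifelse(is_leaf, NA_integer_,
                          match(tr$Feature, feature_names)),
         split = .f32(tr$Split),
         yes = ifelse(is_leaf, NA_integer_, id2idx[tr$Yes]),
         no = ifelse(is_leaf, NA_integer_, id2idx[tr$No]),
         value = ifelse(is_leaf, tr$Gain, NA_real_),
         cover = tr$Cover,
         is_leaf = is_leaf)
  })
}

.xgb_base_score <- function(booster) {
  cfg <- xgboost::xgb.config(booster)
  as.numeric(cfg$learner$learner_model_param$base_score)
}

# cover-weighted expectation of one tree
.tree_expectation <- function(tree) {
  rec <- function(j) {
    if (tree$is_leaf[j]) return(tree$value[j])
    (tree$cover[tree$yes[j]] * rec(tree$yes[j]) +
       tree$cover[tree$no[j]] * rec(tree$no[j])) / tree$cover[j]
  }
  rec(1L)
}

# double-precision ensemble prediction
.xgb_predict_double <- function(trees, X, base_score) {
  X <- matrix(.f32(X), nrow(X), ncol(X), dimnames = dimnames(X))
  out <- rep(base_score, nrow(X))
  for (tree in trees) {
    for (i in seq_len(nrow(X))) {
      j <- 1L
      while (!tree$is_leaf[j])
        j <- if (X[i, tree$feature[j]] < tree$split[j]) tree$yes[j]
             else tree$no[j]
      out[i] <- out[i] + tree$value[j]
    }
  }
  out
}

# --- the path algorithm --------------------------------------------------
# A path is a set of parallel vectors (d = feature, z = zero fraction,
# o = one fraction, w = permutation weight), 1-based with a dummy first
# element. R's copy-on-modify gives each recursion branch its own copy.

.path_extend <- function(p, pz, po, pi) {
  l <- p$len + 1L
  p$d[l] <- pi; p$z[l] <- pz; p$o[l] <- po
  p$w[l] <- if (l == 1L) 1 else 0
  if (l >= 2L) for (i in (l - 1L):1L) {
    p$w[i + 1L] <- p$w[i + 1L] + po * p$w[i] * i / l
    p$w[i] <- pz * p$w[i] * (l - i) / l
  }
  p$len <- l
  p
}

.path_unwind <- function(p, i) {
  l <- p$len
  one <- p$o[i]; zero <- p$z[i]
  n <- p$w[l]
  if (l >= 2L) for (j in (l - 1L):1L) {
    if (one != 0) {
      tmp <- p$w[j]
      p$w[j] <- n * l / (j * one)
      n <- tmp - p$w[j] * zero * (l - j) / l
    } else {
      p$w[j] <- p$w[j] * l / (zero * (l - j))
    }
  }
  if (i <= l - 1L) for (j in i:(l - 1L)) {
    p$d[j] <- p$d[j + 1L]; p$z[j] <- p$z[j + 1L]; p$o[j] <- p$o[j + 1L]
  }
  p$len <- l - 1L
  p
}

.path_unwound_sum <- function(p, i) {
  l <- p$len
  one <- p$o[i]; zero <- p$z[i]
  total <- 0
  n <- p$w[l]
  if (l >= 2L) for (j in (l - 1L):1L) {
    if (one != 0) {
      t <- n * l / (j * one)
      total <- total + t
      n <- p$w[j] - t * zero * (l - j) / l
    } else {
      total <- total + p$w[j] * l / (zero * (l - j))
    }
  }
  total
}

.treeshap_one <- function(tree, x, phi) {
  recurse <- function(j, p, pz, po, pi) {
    p <- .path_extend(p, pz, po, pi)
    if (tree$is_leaf[j]) {
      if (p$len >= 2L) for (i in 2L:p$len) {
        w <- .path_unwound_sum(p, i)
        phi[p$d[i]] <<- phi[p$d[i]] +
          w * (p$o[i] - p$z[i]) * tree$value[j]
      }
      return(invisible(NULL))
    }
    d <- tree$feature[j]
    hot <- if (x[d] < tree$split[j]) tree$yes[j] else tree$no[j]
    cold <- if (hot == tree$yes[j]) tree$no[j] else tree$yes[j]
    iz <- 1; io <- 1
    k <- if (p$len >= 2L) {
      hits <- which(p$d[2:p$len] == d) + 1L
      if (length(hits)) hits[1] else 0L
    } else 0L
    if (k > 0L) {
      iz <- p$z[k]; io <- p$o[k]
      p <- .path_unwind(p, k)
    }
    recurse(hot, p, tree$cover[hot] / tree$cover[j] * iz, io, d)
    recurse(cold, p, tree$cover[cold] / tree$cover[j] * iz, 0, d)
    invisible(NULL)
  }
  recurse(1L, list(d = integer(0), z = numeric(0), o = numeric(0),
                   w = numeric(0), len = 0L),
          1, 1, 0L)
  phi
}

# exact attributions for every row of X; returns phi (n x p) and the base
# value (cover-weighted ensemble expectation)
.xgb_treeshap <- function(booster, X) {
  feats <- colnames(X)
  trees <- .xgb_tree_tables(booster, feats)
  base <- .xgb_base_score(booster) +
    sum(vapply(trees, .tree_expectation, numeric(1)))
  phi <- matrix(0, nrow(X), ncol(X), dimnames = list(NULL, feats))
  X32 <- matrix(.f32(X), nrow(X), ncol(X))
  for (tree in trees) {
    if (tree$is_leaf[1L]) next  # stump with no splits contributes only to base
    for (i in seq_len(nrow(X)))
      phi[i, ] <- .treeshap_one(tree, X32[i, ], phi[i, ])
  }
  list(phi = phi, base = base,
       predictions = .xgb_predict_double(trees, X,
                                         .xgb_base_score(booster)))
}
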