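# shared fixtures: everything built in code at test time

# a simple rigid pharmacophore: 4 distinct-type features on a tetrahedron
fixture_pharmacophore <- function(tolerance = 1.5, types = c("H", "HBA", "HBD", "AR")) {
  xyz <- rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3.5, 0), c(2, 1.2, 3))
  feats <- feature_points(types, xyz[seq_along(types), , drop = FALSE],
                          tolerance = tolerance)
  pharmacophore("fix", "SB", "rX", "agonist", feats)
}

# feature set realizing a pharmacophore's enabled features exactly, with
# optional jitter, dropped rows, extra decoy features, under a rigid motion
fixture_ligand_features <- function(p, id = "lig", jitter = 0, drop = integer(0),
                                    extra = 0L, rotate = FALSE, seed = 1L) {
  set.seed(seed)
  en <- p$features[!p$features$disabled, , drop = FALSE]
  keep <- setdiff(seq_len(nrow(en)), drop)
  df <- data.frame(type = en$type[keep],
                   x = en$x[keep], y = en$y[keep], z = en$z[keep])
  if (jitter > 0) {
    df$x <- df$x + rnorm(nrow(df), 0, jitter)
    df$y <- df$y + rnorm(nrow(df), 0, jitter)
    df$z <- df$z + rnorm(nrow(df), 0, jitter)
  }
  if (extra > 0L) {
    df <- rbind(df, data.frame(
      type = sample(c("H", "HBA", "HBD", "AR", "PI", "NI", "MB"), extra,
                    replace = TRUE),
      x = runif(extra, 8, 14), y = runif(extra, 8, 14),
      z = runif(extra, 8, 14)))
  }
  if (rotate) {
    rot <- rotation_matrix(c(1, 1, 0), pi / 3)
    m <- as.matrix(df[, c("x", "y", "z")]) %*% t(rot)
    m <- sweep(m, 2L, c(3, -2, 5), "+")
    df$x <- m[, 1L]; df$y <- m[, 2L]; df$z <- m[, 3L]
  }
  feature_set(id, 1L, df)
}

# tiny planted dataset: n ligands realizing archetype `a`
fixture_dataset <- function(a, n, cls = a$activity_class, jitter = 0.2,
                            seed = 1L, drop_for = integer(0), drop = integer(0)) {
  recs <- lapply(seq_len(n), function(i) {
    generate_ligand(a, sprintf("%s_%s_%02d", a$receptor_id, substr(cls, 1, 3), i),
                    jitter_sigma = jitter,
                    drop = if (i %in% drop_for) drop else integer(0),
                    seed = seed * 1000L + i)
  })
  recs <- lapply(recs, function(r) { r$activity_class <- cls; r })
  ligand_dataset(a$receptor_id, cls, recs)
}

# hand-rolled adjusted Rand index (independent of any clustering package)
fixture_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- sum_a * sum_b / n
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
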