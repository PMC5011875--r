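#' Synthetic benchmark generation
#'
#' Generates receptor-shaped benchmarks with known ground truth: for every
#' pseudo-receptor, an agonist and an antagonist pharmacophoric archetype
#' (typed feature points in a 12 A box), ligand sets whose members realise
#' their class archetype as pseudo-atom probe groups (with positional
#' jitter, peripheral distractor features, occasional drops of features
#' planted as non-essential, and optional steric-clash atoms), and
#' pseudo-complexes whose receptor anchor atoms sit at the midpoint of each
#' interaction-rule window, geometrically complementary to the archetype.
#' A manifest records the provenance of every generated entity, so expected
#' screening outcomes are decidable without running the pipeline.
#'
#' Probe chemistry per feature type (atoms typed to trigger exactly the
#' intended perception rules): hydroxyl O-H for HBD (also perceived as an
#' acceptor, as real hydroxyls are), carbonyl C=O for HBA, a three-carbon
#' chain for H, a benzene ring for AR, an ammonium nitrogen for PI, a
#' carboxylate for NI and a thiol for MB. Distractor features are placed
#' peripherally (>= 17 A from every archetype atom): outside the RDF-code
#' distance window and far outside any exclusion-shell band, so that intact
#' actives always remain recoverable by their class models.
#'
#' @name synthetic
NULL

#' Default feature-type sampling weights
#'
#' Hydrophobic and acceptor features dominate nuclear-receptor pharmacophore
#' compositions (about 39.3 and 32.5 percent of all features), followed by
#' aromatic rings (14.0) and donors (9.2); ionizable and metal-binding
#' features are rare and share the remainder here.
#'
#' @return named probability vector over feature types.
#' @export
default_type_weights <- function() {
  c(H = 0.393, HBA = 0.325, AR = 0.140, HBD = 0.092,
    NI = 0.022, PI = 0.018, MB = 0.010)
}

#' Sample a pharmacophoric archetype
#'
#' `k` typed feature points with positions uniform in a 12 A box, subject to
#' pairwise distance >= 2.5 A and non-collinearity; deterministic given the
#' seed. One or more features can be planted as "spurious" (non-essential):
#' ligand generation may drop them, so the refinement protocol has something
#' real to discover. A designated clash site on the exclusion shell (2.5 A
#' outward from the first feature's anchor atom) is stored for steric-clash
#' decoys.
#'
#' @param k number of features (>= 3).
#' @param type_weights sampling weights over feature types.
#' @param seed RNG seed.
#' @param receptor_id,activity_class annotation.
#' @param n_spurious features marked as plausibly non-essential (default 1).
#' @param box box edge (A, default 12).
#' @param min_dist minimum pairwise feature distance (A, default 2.5).
#' @param max_tries bounded retries for the geometric constraints.
#' @return object of class `pharm_archetype`: feature table (`type`, `x`,
#'   `y`, `z`, `nx`, `ny`, `nz`, `u*` outward probe direction),
#'   `spurious_indices`, `clash_site`, annotation and seed.
#' @export
sample_archetype <- function(k, type_weights = default_type_weights(),
                             seed = 1L, receptor_id = "r1",
                             activity_class = "agonist", n_spurious = 1L,
                             box = 12, min_dist = 2.5, max_tries = 2000L) {
  if (k < 3L) stop("an archetype needs at least 3 independent features")
  with_seed(seed, {
    pos <- NULL
    tries <- 0L
    while (is.null(pos)) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("could not satisfy archetype geometric constraints")
      }
      cand <- matrix(stats::runif(3L * k, 0, box), k, 3L)
      if (k >= 2L && min(stats::dist(cand)) < min_dist) next
      if (points_collinear(cand, tol = 0.5)) next
      pos <- cand
    }
    types <- sample(names(type_weights), k, replace = TRUE,
                    prob = type_weights)
    ctr <- colMeans(pos)
    u <- t(apply(pos, 1L, function(p1) {
      d <- p1 - ctr
      if (sqrt(sum(d^2)) < 1e-6) d <- c(0, 0, 1)
      unitize(d)
    }))
    normals <- t(vapply(seq_len(k), function(i) {
      v <- stats::rnorm(3L)
      unitize(v)
    }, numeric(3L)))
    feats <- data.frame(type = types, x = pos[, 1L], y = pos[, 2L],
                        z = pos[, 3L],
                        nx = ifelse(types == "AR", normals[, 1L], NA_real_),
                        ny = ifelse(types == "AR", normals[, 2L], NA_real_),
                        nz = ifelse(types == "AR", normals[, 3L], NA_real_),
                        ux = u[, 1L], uy = u[, 2L], uz = u[, 3L])
    spurious <- sort(sample.int(k, min(n_spurious, k - 3L)))
    a <- structure(list(receptor_id = receptor_id,
                        activity_class = activity_class,
                        features = feats,
                        spurious_indices = spurious,
                        seed = seed),
                   class = "pharm_archetype")
    atoms <- realize_archetype(a)
    actr <- colMeans(atoms$xyz)
    a$clash_site <- atoms$xyz[1L, ] +
      2.5 * unitize(atoms$xyz[1L, ] - actr)
    a
  })
}

#' @export
print.pharm_archetype <- function(x, ...) {
  cat(sprintf("<archetype %s/%s: %d features (%s), spurious: %s>\n",
              x$receptor_id, x$activity_class, nrow(x$features),
              paste(x$features$type, collapse = ","),
              paste(x$spurious_indices, collapse = ",")))
  invisible(x)
}

# probe-group realization of a feature table: returns atoms (element, charge),
# bonds, xyz, and the feature index each atom realizes
realize_archetype <- function(a, feature_rows = seq_len(nrow(a$features))) {
  elements <- character(0); charges <- integer(0)
  bonds <- NULL; xyz <- NULL; owner <- integer(0)
  add_atoms <- function(el, ch, co, bd, frow) {
    base <- length(elements)
    elements <<- c(elements, el)
    charges <<- c(charges, ch)
    xyz <<- rbind(xyz, co)
    owner <<- c(owner, rep(frow, length(el)))
    if (!is.null(bd)) {
      bonds <<- rbind(bonds, data.frame(i = bd[, 1L] + base,
                                        j = bd[, 2L] + base,
                                        order = bd[, 3L]))
    }
  }
  for (fi in feature_rows) {
    f <- a$features[fi, ]
    p <- c(f$x, f$y, f$z)
    u <- c(f$ux, f$uy, f$uz)
    v <- .perp_vector(u)
    switch(as.character(f$type),
      HBD = add_atoms(c("O", "H"), c(0L, 0L),
                      rbind(p, p + 0.97 * u),
                      cbind(1L, 2L, 1L), fi),
      HBA = add_atoms(c("O", "C"), c(0L, 0L),
                      rbind(p, p - 1.23 * u),
                      cbind(1L, 2L, 2L), fi),
      H = add_atoms(c("C", "C", "C"), c(0L, 0L, 0L),
                    rbind(p - 1.4 * v, p, p + 1.4 * v),
                    rbind(c(1L, 2L, 1L), c(2L, 3L, 1L)), fi),
      AR = {
        n <- unitize(c(f$nx, f$ny, f$nz))
        w1 <- .perp_vector(n); w2 <- unitize(.cross3(n, w1))
        ring <- t(vapply(0:5, function(s) {
          ang <- s * pi / 3
          p + 1.39 * (cos(ang) * w1 + sin(ang) * w2)
        }, numeric(3L)))
        add_atoms(rep("C", 6L), rep(0L, 6L), ring,
                  cbind(1:6, c(2:6, 1L), 4L), fi)
      },
      PI = add_atoms("N", 1L, rbind(p), NULL, fi),
      NI = {
        c_pos <- p - 0.42 * u
        w1 <- unitize(rotation_matrix(.cross3(u, v), pi / 3) %*% u)
        w2 <- unitize(rotation_matrix(.cross3(u, v), -pi / 3) %*% u)
        add_atoms(c("C", "O", "O"), c(0L, -1L, 0L),
                  rbind(c_pos, c_pos + 1.26 * as.numeric(w1),
                        c_pos + 1.26 * as.numeric(w2)),
                  rbind(c(1L, 2L, 1L), c(1L, 3L, 2L)), fi)
      },
      MB = add_atoms(c("S", "H"), c(0L, 0L),
                     rbind(p, p + 1.34 * u),
                     cbind(1L, 2L, 1L), fi))
  }
  rownames(xyz) <- NULL
  list(elements = elements, charges = charges, bonds = bonds, xyz = xyz,
       owner = owner)
}

.perp_vector <- function(u) {
  v <- if (abs(u[1L]) < 0.9) .cross3(u, c(1, 0, 0)) else .cross3(u, c(0, 1, 0))
  unitize(v)
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Generate a pseudo-ligand realizing an archetype
#'
#' Every non-dropped archetype feature is realized as a probe group at its
#' (jittered) position; `n_extra` distractor features of random type are
#' added at peripheral positions (>= 17 A from every archetype atom, so they
#' can never collide with a class model's exclusion shell nor enter the
#' RDF-code distance window); with
#' `clash = TRUE` an extra isolated carbon is placed at the archetype's
#' designated clash site. Conformer 1 carries these coordinates; conformer 2
#' is a random rigid rotation + translation of conformer 1 (for
#' alignment-invariance checks).
#'
#' @param a a [sample_archetype()] result.
#' @param id molecule id.
#' @param jitter_sigma isotropic Gaussian positional jitter per feature (A);
#'   must stay below the feature tolerance.
#' @param n_extra number of distractor features.
#' @param drop integer indices of archetype features to omit.
#' @param clash add the steric-clash atom?
#' @param seed RNG seed.
#' @return a [ligand_record()] with provenance attributes (`archetype`,
#'   `jitter_sigma`, `n_extra`, `drop`, `clash`).
#' @export
generate_ligand <- function(a, id, jitter_sigma = 0.3, n_extra = 0L,
                            drop = integer(0), clash = FALSE, seed = 1L) {
  stopifnot(inherits(a, "pharm_archetype"))
  with_seed(seed, {
    aj <- a
    keep <- setdiff(seq_len(nrow(a$features)), drop)
    aj$features <- aj$features[keep, , drop = FALSE]
    if (jitter_sigma > 0) {
      aj$features$x <- aj$features$x + stats::rnorm(length(keep), 0, jitter_sigma)
      aj$features$y <- aj$features$y + stats::rnorm(length(keep), 0, jitter_sigma)
      aj$features$z <- aj$features$z + stats::rnorm(length(keep), 0, jitter_sigma)
    }
    arch_atoms <- realize_archetype(a)$xyz
    ctr <- colMeans(arch_atoms)
    if (n_extra > 0L) {
      extra <- NULL
      tries <- 0L
      while (NROW(extra) < n_extra && tries < 500L) {
        tries <- tries + 1L
        dir <- unitize(stats::rnorm(3L))
        pos <- ctr + dir * stats::runif(1L, 18.5, 21)
        if (min(cross_dist(rbind(pos), arch_atoms)) < 17) next
        if (!is.null(extra) &&
            min(cross_dist(rbind(pos), extra[, c("x", "y", "z"), drop = FALSE])) < 2) next
        typ <- sample(names(default_type_weights()), 1L,
                      prob = default_type_weights())
        nrm <- unitize(stats::rnorm(3L))
        extra <- rbind(extra, data.frame(
          type = typ, x = pos[1L], y = pos[2L], z = pos[3L],
          nx = if (typ == "AR") nrm[1L] else NA_real_,
          ny = if (typ == "AR") nrm[2L] else NA_real_,
          nz = if (typ == "AR") nrm[3L] else NA_real_,
          ux = dir[1L], uy = dir[2L], uz = dir[3L]))
      }
      aj$features <- rbind(aj$features, extra)
    }
    real <- realize_archetype(aj)
    elements <- real$elements; charges <- real$charges
    bonds <- real$bonds; xyz <- real$xyz
    if (clash) {
      elements <- c(elements, "C")
      charges <- c(charges, 0L)
      xyz <- rbind(xyz, a$clash_site)
    }
    conf1 <- unname(as.matrix(xyz))
    rot <- random_rotation()
    shift <- stats::runif(3L, -5, 5)
    conf2 <- sweep(conf1 %*% t(rot), 2L, shift, "+")
    mol <- molecule(id, data.frame(element = elements, charge = charges),
                    bonds, conformers = list(conf1, conf2))
    rec <- ligand_record(mol, a$activity_class, a$receptor_id)
    attr(rec, "archetype") <- sprintf("%s_%s", a$receptor_id, a$activity_class)
    attr(rec, "jitter_sigma") <- jitter_sigma
    attr(rec, "n_extra") <- n_extra
    attr(rec, "drop") <- drop
    attr(rec, "clash") <- clash
    rec
  })
}

# anchor placement distances: midpoint of each interaction-rule window
.ANCHOR <- list(HBD = list(el = "O", ch = 0L, d = 3.15),
                HBA = list(el = "N", ch = 0L, d = 3.15),
                H = list(el = "C", ch = 0L, d = 4.0),
                AR = list(el = "C", ch = 0L, d = 4.5),
                PI = list(el = "O", ch = -1L, d = 4.0),
                NI = list(el = "N", ch = 1L, d = 4.0),
                MB = list(el = "Zn", ch = 0L, d = 2.5))

#' Generate a pseudo-complex complementary to an archetype
#'
#' The ligand is the exact archetype realization; the receptor consists of
#' one anchor atom per feature, placed along the feature's outward direction
#' at the midpoint of the corresponding interaction-rule window (e.g. an
#' acceptor oxygen 3.15 A from each donor), plus apolar carbon shell atoms
#' around the ligand for exclusion-volume derivation and one carbon at the
#' archetype's designated clash site.
#'
#' @param a a [sample_archetype()] result.
#' @param seed RNG seed (shell placement only).
#' @param with_anchors place the interaction anchors? (`FALSE` gives an
#'   interaction-free pocket).
#' @return a [complex_structure()] with `bound_class = a$activity_class`.
#' @export
generate_complex <- function(a, seed = 1L, with_anchors = TRUE) {
  stopifnot(inherits(a, "pharm_archetype"))
  real <- realize_archetype(a)
  mol <- molecule(sprintf("%s_%s_ref", a$receptor_id, a$activity_class),
                  data.frame(element = real$elements, charge = real$charges),
                  real$bonds, conformers = list(unname(as.matrix(real$xyz))))
  el <- character(0); ch <- integer(0); xyz <- NULL; tag <- character(0)
  if (with_anchors) {
    for (fi in seq_len(nrow(a$features))) {
      f <- a$features[fi, ]
      spec <- .ANCHOR[[as.character(f$type)]]
      pos <- c(f$x, f$y, f$z) + spec$d * c(f$ux, f$uy, f$uz)
      el <- c(el, spec$el); ch <- c(ch, spec$ch)
      xyz <- rbind(xyz, pos)
      tag <- c(tag, sprintf("ANC %d", fi))
    }
  }
  # apolar shell atoms around the ligand body
  lig_xyz <- unname(as.matrix(real$xyz))
  ctr <- colMeans(lig_xyz)
  shell <- NULL
  for (k in seq_len(nrow(lig_xyz))) {
    dirs <- rbind(.SHELL_DIRS, unitize(lig_xyz[k, ] - ctr))
    pts <- sweep(dirs * 4.5, 2L, lig_xyz[k, ], "+")
    shell <- rbind(shell, pts)
  }
  dmin <- apply(cross_dist(shell, lig_xyz), 1L, min)
  shell <- shell[dmin >= 3.5 & dmin <= 5.5, , drop = FALSE]
  if (!is.null(xyz) && nrow(shell)) {
    dair <- apply(cross_dist(shell, xyz), 1L, min)
    shell <- shell[dair >= 2.0, , drop = FALSE]
  }
  # deduplicate
  if (nrow(shell)) {
    sel <- integer(0)
    for (k in seq_len(nrow(shell))) {
      if (!length(sel) ||
          min(cross_dist(shell[k, , drop = FALSE],
                         shell[sel, , drop = FALSE])) > 1.5) {
        sel <- c(sel, k)
      }
    }
    shell <- shell[sel, , drop = FALSE]
  }
  el <- c(el, rep("C", nrow(shell)), "C")
  ch <- c(ch, rep(0L, nrow(shell)), 0L)
  xyz <- rbind(xyz, shell, a$clash_site)
  tag <- c(tag, rep("SHL 1", nrow(shell)), "CLS 1")
  rec <- receptor_atoms(el, xyz, charge = ch, residue_tag = tag)
  complex_structure(sprintf("%s_%s_cx", a$receptor_id, a$activity_class),
                    rec, mol, a$activity_class)
}

#' Generate a full synthetic benchmark
#'
#' Per receptor: an agonist and an antagonist archetype (forced to differ in
#' at least one feature type or by >= 2 A in some position), one
#' pseudo-complex per class, and ligand datasets. Actives realise their
#' class archetype with jitter and occasional distractors; a fraction drop
#' one planted spurious feature; optionally (`clash_rate > 0`) a fraction
#' are steric-clash decoys built from the *opposite* class's archetype plus
#' a clash atom (they map that class's features but should be rejected by
#' its exclusion volumes).
#' Receptors named in `overlap_pairs` share their agonist archetype,
#' emulating isoform cross-reactivity.
#'
#' @param n_receptors number of receptors (default 6).
#' @param n_agonists,n_antagonists ligands per class (defaults 20 / 10;
#'   agonist sets larger, as in real nuclear-receptor collections).
#' @param overlap_pairs list of 2-vectors of receptor indices sharing the
#'   agonist archetype.
#' @param jitter_sigma positional jitter (A, default 0.3).
#' @param n_extra_max distractor features per ligand drawn uniformly from
#'   `0:n_extra_max` (default 2).
#' @param spurious_rate fraction of actives dropping one spurious feature
#'   (default 0.25; set 0 to disable drops).
#' @param clash_rate fraction of each dataset made of opposite-archetype
#'   steric-clash decoys (default 0; targeted exclusion-volume studies
#'   only -- such decoys can evade their clash sphere through alternative
#'   feature correspondences and then invalidate every model of a class).
#' @param k_range archetype sizes sampled uniformly (default 4:6).
#' @param seed master seed; all sub-seeds derive from it.
#' @param out_dir optional directory: writes per-dataset SDF files,
#'   per-complex PDB files, `manifest.csv` and `archetypes.csv`.
#' @return object of class `pharm_benchmark`: `receptors` (per receptor:
#'   `agonist`/`antagonist` archetypes, `complexes`, `datasets`),
#'   `manifest` data.frame, `params`.
#' @export
generate_benchmark <- function(n_receptors = 6L, n_agonists = 20L,
                               n_antagonists = 10L, overlap_pairs = list(),
                               jitter_sigma = 0.3, n_extra_max = 2L,
                               spurious_rate = 0.25, clash_rate = 0,
                               k_range = 4:6, seed = 1L, out_dir = NULL) {
  stopifnot(n_agonists >= 2L, n_antagonists >= 2L)
  with_seed(seed, {
    sub_seed <- function() sample.int(.Machine$integer.max - 1L, 1L)
    rec_ids <- sprintf("r%d", seq_len(n_receptors))
    receptors <- list()
    manifest <- list()
    for (ri in seq_len(n_receptors)) {
      rid <- rec_ids[ri]
      arch <- list()
      shared_from <- NULL
      for (pair in overlap_pairs) {
        if (length(pair) == 2L && pair[2L] == ri) shared_from <- pair[1L]
      }
      if (!is.null(shared_from)) {
        arch$agonist <- receptors[[rec_ids[shared_from]]]$agonist
        arch$agonist$receptor_id <- rid
      } else {
        arch$agonist <- sample_archetype(sample(k_range, 1L),
                                         seed = sub_seed(), receptor_id = rid,
                                         activity_class = "agonist")
      }
      repeat {
        arch$antagonist <- sample_archetype(sample(k_range, 1L),
                                            seed = sub_seed(),
                                            receptor_id = rid,
                                            activity_class = "antagonist")
        if (.archetypes_differ(arch$agonist, arch$antagonist)) break
      }
      cx <- list(agonist = generate_complex(arch$agonist, seed = sub_seed()),
                 antagonist = generate_complex(arch$antagonist,
                                               seed = sub_seed()))
      datasets <- list()
      for (cls in c("agonist", "antagonist")) {
        n <- if (cls == "agonist") n_agonists else n_antagonists
        n_clash <- floor(clash_rate * n)
        own <- arch[[cls]]
        opp <- arch[[setdiff(c("agonist", "antagonist"), cls)]]
        recs <- list()
        for (li in seq_len(n)) {
          mid <- sprintf("%s_%s_%03d", rid, substr(cls, 1L, 3L), li)
          is_clash <- li > n - n_clash
          if (is_clash) {
            r <- generate_ligand(opp, mid, jitter_sigma = jitter_sigma,
                                 n_extra = 0L, clash = TRUE,
                                 seed = sub_seed())
            r$activity_class <- cls   # decoy-shaped, but labelled by dataset
            r$receptor_id <- rid
            drop <- integer(0)
            src <- sprintf("%s_%s", opp$receptor_id, opp$activity_class)
            nx <- 0L
          } else {
            nx <- sample(0:n_extra_max, 1L)
            drop <- if (length(own$spurious_indices) &&
                          stats::runif(1L) < spurious_rate) {
              sample(own$spurious_indices, 1L)
            } else integer(0)
            r <- generate_ligand(own, mid, jitter_sigma = jitter_sigma,
                                 n_extra = nx, drop = drop,
                                 seed = sub_seed())
            src <- sprintf("%s_%s", rid, cls)
          }
          recs[[length(recs) + 1L]] <- r
          manifest[[length(manifest) + 1L]] <- data.frame(
            receptor_id = rid, activity_class = cls, molecule_id = mid,
            source_archetype = src, jitter_sigma = jitter_sigma,
            n_extra = nx,
            dropped = paste(drop, collapse = ";"),
            clash = is_clash)
        }
        datasets[[cls]] <- ligand_dataset(rid, cls, recs)
      }
      receptors[[rid]] <- list(agonist = arch$agonist,
                               antagonist = arch$antagonist,
                               complexes = cx, datasets = datasets)
    }
    manifest <- do.call(rbind, manifest)
    bench <- structure(list(receptors = receptors, manifest = manifest,
                            params = list(n_receptors = n_receptors,
                                          n_agonists = n_agonists,
                                          n_antagonists = n_antagonists,
                                          jitter_sigma = jitter_sigma,
                                          n_extra_max = n_extra_max,
                                          spurious_rate = spurious_rate,
                                          clash_rate = clash_rate,
                                          seed = seed)),
                       class = "pharm_benchmark")
    if (!is.null(out_dir)) write_benchmark(bench, out_dir)
    bench
  })
}

.archetypes_differ <- function(a, b) {
  fa <- a$features; fb <- b$features
  if (nrow(fa) != nrow(fb)) return(TRUE)
  if (!identical(sort(fa$type), sort(fb$type))) return(TRUE)
  any(sqrt(rowSums((as.matrix(fa[, c("x", "y", "z")]) -
                      as.matrix(fb[, c("x", "y", "z")]))^2)) >= 2)
}

#' Write a benchmark to disk
#'
#' Emits one SDF per dataset, one PDB per pseudo-complex, `manifest.csv` and
#' `archetypes.csv` (ground-truth feature tables).
#'
#' @param bench a [generate_benchmark()] result.
#' @param out_dir output directory (created).
#' @return `out_dir`, invisibly.
#' @export
write_benchmark <- function(bench, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  arch_rows <- list()
  for (rid in names(bench$receptors)) {
    r <- bench$receptors[[rid]]
    for (cls in c("agonist", "antagonist")) {
      ds <- r$datasets[[cls]]
      write_sdf(lapply(ds$ligands, `[[`, "molecule"),
                file.path(out_dir, sprintf("%s_%s.sdf", rid, cls)))
      write_pdb_complex(r$complexes[[cls]],
                        file.path(out_dir, sprintf("%s_%s.pdb", rid, cls)))
      af <- r[[cls]]$features
      arch_rows[[length(arch_rows) + 1L]] <- data.frame(
        receptor_id = rid, activity_class = cls,
        feature = seq_len(nrow(af)), type = af$type,
        x = round(af$x, 4L), y = round(af$y, 4L), z = round(af$z, 4L),
        spurious = seq_len(nrow(af)) %in% r[[cls]]$spurious_indices)
    }
  }
  utils::write.csv(bench$manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, arch_rows),
                   file.path(out_dir, "archetypes.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
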