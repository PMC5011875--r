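test_that("archetype sampling is deterministic, constrained and refuses k < 3", {
  a1 <- sample_archetype(5, seed = 301L)
  a2 <- sample_archetype(5, seed = 301L)
  expect_identical(a1$features, a2$features)
  expect_identical(a1$spurious_indices, a2$spurious_indices)
  expect_error(sample_archetype(2, seed = 1L), "at least 3")
  for (s in 1:10) {
    a <- sample_archetype(sample(3:7, 1L), seed = 300L + s)
    xyz <- as.matrix(a$features[, c("x", "y", "z")])
    expect_gte(min(dist(xyz)), 2.5)
    expect_false(points_collinear(xyz, tol = 0.5))
  }
})

test_that("exact realizations match their archetype model with negligible RMSD", {
  a <- sample_archetype(5, seed = 311L)
  p <- pharmacophore("arch", "SB", a$receptor_id, "agonist",
                     feature_points(a$features$type,
                                    as.matrix(a$features[, c("x", "y", "z")])))
  rec <- prepare_ligand(generate_ligand(a, "exact", jitter_sigma = 0, seed = 1))
  m <- match_conformer(p, rec$features[[1L]], rec$heavy[[1L]], 0L)
  expect_false(is.null(m))
  expect_lt(m$rmsd, 1e-6)
})

test_that("dropped features and clash atoms behave as planted", {
  a <- sample_archetype(5, seed = 313L)
  p <- pharmacophore("arch", "SB", a$receptor_id, "agonist",
                     feature_points(a$features$type,
                                    as.matrix(a$features[, c("x", "y", "z")])))
  dropped <- prepare_ligand(generate_ligand(a, "drop2", jitter_sigma = 0.1,
                                            drop = 2L, seed = 2))
  expect_null(match_conformer(p, dropped$features[[1L]], dropped$heavy[[1L]], 0L))
  expect_false(is.null(match_conformer(p, dropped$features[[1L]],
                                       dropped$heavy[[1L]], 1L)))

  # clash ligand maps the features of a shell-equipped model but is rejected
  cx <- generate_complex(a)
  sb <- build_sb_pharmacophore(cx, receptor_id = a$receptor_id)
  clashy <- prepare_ligand(generate_ligand(a, "clash", jitter_sigma = 0,
                                           clash = TRUE, seed = 3))
  no_shell <- sb
  no_shell$exclusions <- exclusion_spheres(matrix(numeric(), 0L, 3L))
  expect_false(is.null(match_conformer(no_shell, clashy$features[[1L]],
                                       clashy$heavy[[1L]], 0L)))
  expect_null(match_conformer(sb, clashy$features[[1L]], clashy$heavy[[1L]], 0L))
})

test_that("pseudo-complexes are complementary and self-consistent", {
  for (s in 1:5) {
    a <- sample_archetype(sample(3:6, 1L), seed = 320L + s)
    cx <- generate_complex(a)
    sb <- build_sb_pharmacophore(cx, receptor_id = a$receptor_id)
    rec <- prepare_ligand(ligand_record(cx$ligand, a$activity_class,
                                        a$receptor_id))
    expect_false(is.null(match_conformer(sb, rec$features[[1L]],
                                         rec$heavy[[1L]], 0L)))
  }
})

test_that("benchmark generation is reproducible down to the written manifest", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- generate_benchmark(n_receptors = 2L, n_agonists = 4L,
                           n_antagonists = 3L, seed = 331L, out_dir = d1)
  b2 <- generate_benchmark(n_receptors = 2L, n_agonists = 4L,
                           n_antagonists = 3L, seed = 331L, out_dir = d2)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, "archetypes.csv")),
                   readLines(file.path(d2, "archetypes.csv")))
  expect_identical(b1$manifest, b2$manifest)
  # manifest is complete: one row per generated ligand, all traceable
  expect_equal(nrow(b1$manifest), 2L * (4L + 3L))
  expect_true(all(b1$manifest$source_archetype %in%
                    c(paste0("r", 1:2, "_agonist"),
                      paste0("r", 1:2, "_antagonist"))))
  # per-receptor class archetypes differ
  for (rid in names(b1$receptors)) {
    r <- b1$receptors[[rid]]
    expect_true(!identical(r$agonist$features[, c("type", "x", "y", "z")],
                           r$antagonist$features[, c("type", "x", "y", "z")]))
  }
})

test_that("the manifest is a decidable oracle for hit status at zero omissions", {
  bench <- generate_benchmark(n_receptors = 2L, n_agonists = 6L,
                              n_antagonists = 4L, n_extra_max = 2L,
                              spurious_rate = 0.5, seed = 337L)
  for (rid in names(bench$receptors)) {
    r <- bench$receptors[[rid]]
    a <- r$agonist
    p <- pharmacophore("truth", "SB", rid, "agonist",
                       feature_points(a$features$type,
                                      as.matrix(a$features[, c("x", "y", "z")])))
    ds <- prepare_dataset(r$datasets$agonist)
    man <- bench$manifest[bench$manifest$receptor_id == rid &
                            bench$manifest$activity_class == "agonist", ]
    for (i in seq_len(nrow(man))) {
      rec <- ds$ligands[[man$molecule_id[i]]]
      hit <- !is.null(match_conformer(p, rec$features[[1L]], rec$heavy[[1L]], 0L))
      expect_identical(hit, !nzchar(man$dropped[i]) && !man$clash[i],
                       info = man$molecule_id[i])
    }
  }
})
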