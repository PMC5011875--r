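test_that("planted positives match; missing features need the omitted allowance", {
  p <- fixture_pharmacophore()
  p$features <- feature_points(c("H", "HBA", "HBD", "AR", "PI"),
                               rbind(c(0, 0, 0), c(4, 0, 0), c(2, 3.5, 0),
                                     c(2, 1.2, 3), c(-2, 2, 1)))
  exact <- fixture_ligand_features(p, "exact")
  m <- match_conformer(p, exact, NULL, 0L)
  expect_false(is.null(m))
  expect_length(m$omitted, 0L)
  expect_lt(m$rmsd, 1e-8)

  # ligand missing 1 of 5 required features: rejected at 0, hit at 1
  short <- fixture_ligand_features(p, "short", drop = 2L)
  expect_null(match_conformer(p, short, NULL, 0L))
  m1 <- match_conformer(p, short, NULL, 1L)
  expect_false(is.null(m1))
  expect_length(m1$omitted, 1L)
  expect_identical(p$features$type[m1$omitted], "HBA")
})

test_that("an atom strictly inside an exclusion sphere rejects an otherwise perfect match", {
  p <- fixture_pharmacophore()
  p$exclusions <- exclusion_spheres(matrix(c(2, 1.5, 1), 1L), radius = 1.0)
  fs <- fixture_ligand_features(p, "clash")
  heavy_clean <- feature_xyz(fs)
  expect_false(is.null(match_conformer(p, fs, heavy_clean, 0L)))
  heavy_clash <- rbind(heavy_clean, c(2, 1.5, 1.4))   # 0.4 A inside the sphere
  expect_null(match_conformer(p, fs, heavy_clash, 0L))
  heavy_surface <- rbind(heavy_clean, c(2, 1.5, 2.0))  # exactly on the surface
  expect_false(is.null(match_conformer(p, fs, heavy_surface, 0L)))
})

test_that("matching is invariant under rigid motion of the conformer", {
  for (seed in 1:25) {
    p <- fixture_pharmacophore()
    fs <- fixture_ligand_features(p, "l", jitter = 0.4, extra = 2L, seed = seed)
    fs_rot <- fixture_ligand_features(p, "l", jitter = 0.4, extra = 2L,
                                      rotate = TRUE, seed = seed)
    m1 <- match_conformer(p, fs, NULL, 0L)
    m2 <- match_conformer(p, fs_rot, NULL, 0L)
    expect_identical(is.null(m1), is.null(m2))
    if (!is.null(m1)) expect_equal(m1$rmsd, m2$rmsd, tolerance = 1e-6)
  }
})

test_that("optional features are matched when possible but never reject", {
  p <- fixture_pharmacophore(types = c("H", "HBA", "HBD", "AR"))
  p$features <- rbind(p$features,
                      feature_points("NI", matrix(c(-2, -2, 0), 1L),
                                     optional = TRUE))
  # ligand without the optional feature still hits
  fs <- fixture_ligand_features(p, "no_opt", drop = 5L)
  m <- match_conformer(p, fs, NULL, 0L)
  expect_false(is.null(m))
  expect_true(is.na(m$correspondence[5L]))
  # ligand with it gets the optional matched
  fs2 <- fixture_ligand_features(p, "with_opt")
  m2 <- match_conformer(p, fs2, NULL, 0L)
  expect_false(is.na(m2$correspondence[5L]))
})

test_that("non-screenable queries error; empty ligand features never match", {
  two <- pharmacophore("p2", "LB", "r", "agonist",
                       feature_points(c("H", "HBA"),
                                      rbind(c(0, 0, 0), c(3, 0, 0))))
  fs <- feature_set("l", 1L, data.frame(type = "H", x = 0, y = 0, z = 0))
  expect_error(match_conformer(two, fs, NULL, 0L), "not screenable")
  p <- fixture_pharmacophore()
  empty <- feature_set("l", 1L,
                       data.frame(type = character(), x = numeric(),
                                  y = numeric(), z = numeric()))
  expect_null(match_conformer(p, empty, NULL, 0L))
  expect_null(brute_force_match(p, empty, NULL, 0L))
})

test_that("dataset screening keeps the best hit per molecule and stays deterministic", {
  a <- sample_archetype(5, seed = 31)
  p <- pharmacophore("pa", "SB", a$receptor_id, "agonist",
                     feature_points(a$features$type,
                                    as.matrix(a$features[, c("x", "y", "z")])))
  ds <- fixture_dataset(a, 6L, jitter = 0.2, seed = 8)
  sr1 <- screen(p, ds, 0L)
  sr2 <- screen(p, ds, 0L)
  expect_identical(sr1$hits, sr2$hits)
  expect_equal(nrow(sr1$hits), 6L)
  expect_lte(max(table(sr1$hits$molecule_id)), 1L)
  # empty dataset
  sr0 <- screen(p, list(), 0L)
  expect_equal(nrow(sr0$hits), 0L)
})

test_that("ensemble screening is a union, idempotent, and degenerates to screen", {
  a1 <- sample_archetype(4, seed = 41, receptor_id = "rA")
  a2 <- sample_archetype(4, seed = 43, receptor_id = "rA")
  mk <- function(a, id) pharmacophore(id, "SB", "rA", "agonist",
                                      feature_points(a$features$type,
                                                     as.matrix(a$features[, c("x", "y", "z")])))
  p1 <- mk(a1, "p1"); p2 <- mk(a2, "p2")
  ds1 <- fixture_dataset(a1, 3L, seed = 1)
  ds2 <- fixture_dataset(a2, 4L, seed = 2)
  # rename to avoid id collisions, then screen the pooled records
  pool <- c(gather_ligands(ds1), lapply(gather_ligands(ds2), function(r) {
    r$molecule$id <- paste0(r$molecule$id, "_b"); r
  }))
  hits1 <- screen_ensemble(list(p1), pool)$hits
  expect_identical(sort(hits1$molecule_id),
                   sort(screen(p1, pool)$hits$molecule_id))
  both <- screen_ensemble(list(p1, p2), pool)$hits
  expect_equal(nrow(both), 7L)
  dup <- screen_ensemble(list(p1, p2, p1), pool)$hits
  expect_setequal(dup$molecule_id, both$molecule_id)
})
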