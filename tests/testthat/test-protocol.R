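# small planted worlds for the protocol: archetype-true actives, opposite
# archetype decoys
protocol_world <- function(seed = 101L, k = 5L, n_act = 6L, n_dec = 4L,
                           drop_for = integer(0)) {
  a_act <- sample_archetype(k, seed = seed, receptor_id = "rp",
                            activity_class = "agonist")
  a_dec <- sample_archetype(k, seed = seed + 1L, receptor_id = "rp",
                            activity_class = "antagonist")
  sp <- if (length(a_act$spurious_indices)) a_act$spurious_indices[1L] else integer(0)
  actives <- prepare_dataset(fixture_dataset(a_act, n_act, jitter = 0.2,
                                             seed = seed,
                                             drop_for = drop_for, drop = sp))
  decoys <- prepare_dataset(fixture_dataset(a_dec, n_dec, cls = "antagonist",
                                            jitter = 0.2, seed = seed + 50L))
  p <- pharmacophore("base", "SB", "rp", "agonist",
                     feature_points(a_act$features$type,
                                    as.matrix(a_act$features[, c("x", "y", "z")])))
  list(a = a_act, p = p, actives = actives, decoys = decoys, spurious = sp)
}

test_that("validation demands at least one active and zero decoys", {
  w <- protocol_world()
  expect_true(validate_pharmacophore(w$p, w$actives, w$decoys))

  # a model that also retrieves decoys is rejected: screen actives with the
  # decoy model's own archetype
  wd <- protocol_world(seed = 131L)
  mixed <- wd$p
  # decoy-archetype model screened with decoys as "actives": hits only the
  # opposite class
  dec_arch <- sample_archetype(5, seed = 132L, receptor_id = "rp")
  pd <- pharmacophore("dec", "SB", "rp", "agonist",
                      feature_points(dec_arch$features$type,
                                     as.matrix(dec_arch$features[, c("x", "y", "z")])))
  # pd hits nothing: zero-hit models are not validated
  expect_false(validate_pharmacophore(pd, wd$actives, wd$decoys))

  # a model matching the decoy archetype is not validated either
  a_dec <- sample_archetype(5, seed = 131L + 1L, receptor_id = "rp",
                            activity_class = "antagonist")
  p_dec <- pharmacophore("pdec", "SB", "rp", "agonist",
                         feature_points(a_dec$features$type,
                                        as.matrix(a_dec$features[, c("x", "y", "z")])))
  expect_false(validate_pharmacophore(p_dec, wd$actives, wd$decoys))
})

test_that("non-essential features are those whose omission gains actives but no decoys", {
  w <- protocol_world(seed = 141L, n_act = 8L, drop_for = c(2L, 5L, 7L))
  skip_if(length(w$spurious) == 0L)
  cand <- find_nonessential_features(w$p, w$actives, w$decoys)
  expect_true(w$spurious %in% cand)
  # the spurious feature is ranked first (it gains the dropper ligands)
  expect_identical(cand[1L], w$spurious)

  # with no droppers there is nothing to gain
  w0 <- protocol_world(seed = 151L, n_act = 6L)
  expect_length(find_nonessential_features(w0$p, w0$actives, w0$decoys), 0L)
})

test_that("a feature whose omission would admit decoys is never reported", {
  # actives and decoys share all features except one discriminating feature
  a <- sample_archetype(4, seed = 161L, receptor_id = "rp")
  a$features$type <- c("AR", "HBA", "PI", "NI")
  a$features[1L, c("nx", "ny", "nz")] <- c(0, 0, 1)
  a_sub <- a
  a_sub$features <- a$features[-4L, , drop = FALSE]   # decoys miss feature 4
  a_sub$activity_class <- "antagonist"
  actives <- prepare_dataset(fixture_dataset(a, 5L, jitter = 0.15, seed = 7))
  decoys <- prepare_dataset(fixture_dataset(a_sub, 4L, cls = "antagonist",
                                            jitter = 0.15, seed = 8))
  p <- pharmacophore("disc", "SB", "rp", "agonist",
                     feature_points(a$features$type,
                                    as.matrix(a$features[, c("x", "y", "z")])))
  expect_true(validate_pharmacophore(p, actives, decoys))
  cand <- find_nonessential_features(p, actives, decoys)
  expect_false(4L %in% cand)   # dropping it would retrieve every decoy
})

test_that("refinement validates, explores disabled variants and stops at three features", {
  w <- protocol_world(seed = 171L, n_act = 8L, drop_for = c(1L, 4L))
  skip_if(length(w$spurious) == 0L)
  out <- refine(w$p, w$actives, w$decoys)
  expect_gte(length(out), 2L)
  n_enabled <- vapply(out, function(q) sum(!q$features$disabled), integer(1L))
  expect_true(all(n_enabled >= 3L))
  # the variant without the spurious feature retrieves at least as many actives
  recall_of <- function(q) {
    nrow(screen(q, w$actives)$hits) / length(w$actives$ligands)
  }
  r_full <- recall_of(out[[1L]])
  slim <- Filter(function(q) q$features$disabled[w$spurious], out)
  expect_gte(length(slim), 1L)
  expect_gte(recall_of(slim[[1L]]), r_full)

  # an unvalidated model refines to nothing
  a_dec <- sample_archetype(5, seed = 172L, receptor_id = "rp",
                            activity_class = "antagonist")
  p_dec <- pharmacophore("pdec", "SB", "rp", "agonist",
                         feature_points(a_dec$features$type,
                                        as.matrix(a_dec$features[, c("x", "y", "z")])))
  expect_length(refine(p_dec, w$actives, w$decoys), 0L)

  # a validated three-feature model is returned as itself
  w3 <- protocol_world(seed = 181L, k = 3L)
  out3 <- refine(w3$p, w3$actives, w3$decoys)
  expect_length(out3, 1L)
  expect_identical(out3[[1L]]$id, w3$p$id)
})

test_that("greedy redundancy removal keeps union recall and drops covered models", {
  # A hits {l1, l2}, B hits {l2}, C hits {l3}: B removed, A and C kept
  aX <- sample_archetype(4, seed = 191L, receptor_id = "rr")
  aY <- sample_archetype(4, seed = 193L, receptor_id = "rr")
  aZ <- sample_archetype(4, seed = 197L, receptor_id = "rr")
  # l2 realizes X and Y simultaneously (Y shifted far away stays a separate
  # probe cluster of the same molecule)
  aY_shift <- aY
  aY_shift$features[, c("x", "y", "z")] <- aY$features[, c("x", "y", "z")] + 40
  combo <- aX
  combo$features <- rbind(aX$features, aY_shift$features)
  l1 <- generate_ligand(aX, "l1", jitter_sigma = 0.05, seed = 1)
  l2 <- generate_ligand(combo, "l2", jitter_sigma = 0.05, seed = 2)
  l3 <- generate_ligand(aZ, "l3", jitter_sigma = 0.05, seed = 3)
  ds <- prepare_dataset(ligand_dataset("rr", "agonist", list(l1, l2, l3)))
  mk <- function(a, id, shift = 0) {
    f <- a$features
    pharmacophore(id, "SB", "rr", "agonist",
                  feature_points(f$type,
                                 as.matrix(f[, c("x", "y", "z")]) + shift))
  }
  A <- mk(aX, "A"); B <- mk(aY, "B", shift = 40); C <- mk(aZ, "C")
  hits <- function(p) sort(screen(p, ds)$hits$molecule_id)
  expect_identical(hits(A), c("l1", "l2"))
  expect_identical(hits(B), "l2")
  expect_identical(hits(C), "l3")
  kept <- remove_redundant(list(A, B, C), ds)
  expect_setequal(vapply(kept, `[[`, character(1L), "id"), c("A", "C"))
  # identical duplicates collapse to one
  kept2 <- remove_redundant(list(A, mk(aX, "A2")), ds)
  expect_length(kept2, 1L)
  # single candidate survives
  expect_length(remove_redundant(list(C), ds), 1L)
})

test_that("ensembles unite SB and LB coverage without redundancy", {
  w <- protocol_world(seed = 201L)
  p <- w$p
  # sb empty, lb single model
  ens <- suppressWarnings(build_ensembles(list(), list(p), w$actives, "rp",
                                          "agonist"))
  expect_length(ens$SBLB$members, 1L)
  expect_identical(ens$SBLB$members[[1L]]$id, p$id)
  expect_length(ens$SB$members, 0L)
  # both empty warns
  expect_warning(build_ensembles(list(), list(), w$actives, "rp", "agonist"),
                 "empty ensemble")
  # SBLB recall >= max(SB, LB) on the generating dataset
  sb <- refine(p, w$actives, w$decoys)
  ens2 <- build_ensembles(sb, list(p), w$actives, "rp", "agonist")
  r <- vapply(c("SB", "LB", "SBLB"), function(l) {
    ensemble_recall(ens2[[l]], w$actives)
  }, numeric(1L))
  expect_gte(r["SBLB"], max(r["SB"], r["LB"]))
})

test_that("cross-screening separates disjoint receptors and exposes shared archetypes", {
  set.seed(1)
  bench <- generate_benchmark(n_receptors = 3L, n_agonists = 5L,
                              n_antagonists = 4L, n_extra_max = 0L,
                              spurious_rate = 0, overlap_pairs = list(c(1L, 3L)),
                              seed = 211L)
  mk_ens <- function(rid, cls) {
    a <- bench$receptors[[rid]][[cls]]
    p <- pharmacophore(sprintf("%s_%s", rid, cls), "SB", rid, cls,
                       feature_points(a$features$type,
                                      as.matrix(a$features[, c("x", "y", "z")])))
    pharmacophore_ensemble(rid, cls, list(p), "SBLB")
  }
  enss <- list(mk_ens("r1", "agonist"), mk_ens("r2", "agonist"))
  dss <- list(prepare_dataset(bench$receptors$r1$datasets$agonist),
              prepare_dataset(bench$receptors$r2$datasets$agonist),
              prepare_dataset(bench$receptors$r3$datasets$agonist))
  m <- cross_screen(enss, dss)
  expect_equal(dim(m), c(2L, 3L))
  # diagonal: own-dataset recall is full for intact planted actives
  expect_equal(m["r1_agonist_SBLB", "r1_agonist"], 1.0)
  expect_equal(m["r2_agonist_SBLB", "r2_agonist"], 1.0)
  # disjoint receptors do not cross-react
  expect_equal(m["r1_agonist_SBLB", "r2_agonist"], 0.0)
  expect_equal(m["r2_agonist_SBLB", "r1_agonist"], 0.0)
  # r3 shares r1's agonist archetype: elevated cross-recall
  expect_gt(m["r1_agonist_SBLB", "r3_agonist"], 0.9)
})
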