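test_that("RDF codes: no pairs give zero, identity gives distance zero, mass sits at the pair distance", {
  single <- feature_set("s", 1L, data.frame(type = "H", x = 0, y = 0, z = 0))
  expect_true(all(rdf_code(single) == 0))

  a <- sample_archetype(5, seed = 51)
  lig <- generate_ligand(a, "l", jitter_sigma = 0, seed = 1)
  fs <- prepare_ligand(lig)$features[[1L]]
  expect_equal(rdf_code(fs), rdf_code(fs))
  expect_equal(sqrt(sum((rdf_code(fs) - rdf_code(fs))^2)), 0)

  pair <- feature_set("p", 1L,
                      data.frame(type = c("H", "HBA"),
                                 x = c(0, 4), y = 0, z = 0))
  code <- matrix(rdf_code(pair), 32L,
                 dimnames = list(NULL, NULL))
  block_names <- apply(expand.grid(a = c("AR", "H", "HBA", "HBD", "PI", "NI", "MB"),
                                   b = c("AR", "H", "HBA", "HBD", "PI", "NI", "MB"),
                                   stringsAsFactors = FALSE), 1L,
                       function(r) if (r[1] <= r[2]) paste(r[1], r[2], sep = ":") else NA)
  block_names <- block_names[!is.na(block_names)]
  colnames(code) <- block_names
  centers <- (1:32 - 0.5) * 16 / 32
  hot <- code[, "H:HBA"]
  expect_true(all(code[, setdiff(block_names, "H:HBA")] == 0))
  # direct kernel evaluation: mass peaks in the bin nearest 4 A
  expected <- exp(-(centers - 4)^2 / 2)
  expected <- expected / sqrt(sum(expected^2))
  expect_equal(hot, expected, tolerance = 1e-12)
  expect_equal(which.max(hot), which.min(abs(centers - 4)))
})

test_that("clustering recovers planted chemotypes and respects configuration", {
  # 10 near-copies of one ligand: one cluster
  a <- sample_archetype(5, seed = 53)
  ds <- fixture_dataset(a, 10L, jitter = 0.05, seed = 3)
  cl <- cluster_ligands(ds, 0.4)
  expect_length(cl, 1L)
  expect_length(cl[[1L]]$member_ids, 10L)

  # three well-separated archetypes: adjusted Rand index 1 vs the labels
  arch <- lapply(c(61, 67, 71), function(s) sample_archetype(5, seed = s))
  recs <- list(); truth <- integer(0)
  for (g in seq_along(arch)) {
    for (i in 1:4) {
      recs[[length(recs) + 1L]] <- generate_ligand(
        arch[[g]], sprintf("g%d_l%d", g, i), jitter_sigma = 0.1,
        seed = g * 100L + i)
      truth <- c(truth, g)
    }
  }
  recs <- lapply(recs, function(r) { r$receptor_id <- "rX"; r })
  names(truth) <- vapply(recs, function(r) r$molecule$id, character(1L))
  ds3 <- ligand_dataset("rX", "agonist", recs)
  cl3 <- cluster_ligands(ds3, 0.4)
  got <- integer(0)
  for (ci in seq_along(cl3)) got[cl3[[ci]]$member_ids] <- ci
  expect_equal(fixture_ari(truth[names(got)], got), 1.0)

  # thresholds 0.4 / 0.3 / 0.2 are accepted configuration
  for (thr in c(0.4, 0.3, 0.2)) {
    expect_no_error(cluster_ligands(ds, thr))
  }
  expect_error(cluster_ligands(ligand_dataset("rX", "agonist", recs[1])[
    c("receptor_id", "activity_class")], 0.4))
})

test_that("clustering is invariant under permutation of the input ligands", {
  a1 <- sample_archetype(4, seed = 73)
  a2 <- sample_archetype(4, seed = 79)
  recs <- c(lapply(1:3, function(i) generate_ligand(a1, sprintf("a%d", i),
                                                    seed = i)),
            lapply(1:3, function(i) generate_ligand(a2, sprintf("b%d", i),
                                                    seed = 10L + i)))
  recs <- lapply(recs, function(r) { r$receptor_id <- "rP"; r })
  set.seed(5)
  base <- NULL
  for (k in 1:4) {
    ds <- ligand_dataset("rP", "agonist", sample(recs))
    cl <- cluster_ligands(ds, 0.4)
    part <- lapply(cl, `[[`, "member_ids")
    part <- part[order(vapply(part, `[[`, character(1L), 1L))]
    if (is.null(base)) base <- part else expect_identical(part, base)
  }
})

test_that("cluster alignment recovers rigid motions and excludes degenerate members", {
  a <- sample_archetype(5, seed = 83)
  ref <- prepare_ligand(generate_ligand(a, "ref", jitter_sigma = 0,
                                        seed = 1))$features[[1L]]
  rot <- rotation_matrix(c(0, 0, 1), pi / 2)
  moved <- ref
  m <- as.matrix(moved$features[, c("x", "y", "z")]) %*% t(rot)
  m <- sweep(m, 2L, c(2, -1, 4), "+")
  moved$features$x <- m[, 1L]; moved$features$y <- m[, 2L]
  moved$features$z <- m[, 3L]
  # equal feature counts: reference is the lexicographically first id
  aln <- align_cluster(list(a_ref = ref, b_moved = moved))
  expect_identical(aln$reference_id, "a_ref")
  tr <- aln$transforms$b_moved
  back <- apply_transform(m, tr$rotation, tr$translation)
  expect_lt(rmsd(back, as.matrix(ref$features[, c("x", "y", "z")])), 1e-6)

  tiny <- feature_set("tiny", 1L,
                      data.frame(type = c("H", "HBA"), x = c(0, 3), y = 0, z = 0))
  expect_warning(aln2 <- align_cluster(list(a_ref = ref, tiny = tiny)),
                 "fewer than 3")
  expect_identical(aln2$excluded, "tiny")

  # jittered copies align within 1 A
  members <- lapply(1:5, function(i) {
    prepare_ligand(generate_ligand(a, sprintf("j%d", i), jitter_sigma = 0.3,
                                   seed = 200L + i))$features[[1L]]
  })
  names(members) <- sprintf("j%d", 1:5)
  aln3 <- align_cluster(members)
  ref3 <- members[[aln3$reference_id]]
  for (id in setdiff(names(members), aln3$reference_id)) {
    if (id %in% aln3$excluded) next
    tr <- aln3$transforms[[id]]
    moved <- apply_transform(feature_xyz(members[[id]]), tr$rotation,
                             tr$translation)
    # compare planted (non-extra) features in archetype order
    expect_lt(rmsd(moved[seq_len(nrow(a$features)), , drop = FALSE],
                   feature_xyz(ref3)[seq_len(nrow(a$features)), , drop = FALSE]),
              1.0)
  }
})

test_that("merged-feature models follow the presence rules", {
  a <- sample_archetype(5, seed = 89)
  mk_fs <- function(id, drop = integer(0)) {
    prepare_ligand(generate_ligand(a, id, jitter_sigma = 0, drop = drop,
                                   seed = 1))$features[[1L]]
  }
  # four identical members: the common feature set, all required
  members <- lapply(sprintf("m%d", 1:4), mk_fs)
  names(members) <- sprintf("m%d", 1:4)
  aln <- align_cluster(members)
  p <- build_lb_pharmacophore(members, aln, "lb1", "rX", "agonist")
  expect_equal(nrow(p$features), nrow(members[[1L]]$features))
  expect_false(any(p$features$optional))

  # a feature present in 1 of 8 members (12.5% >= 10%) becomes optional
  members8 <- lapply(sprintf("n%d", 1:8), function(id) mk_fs(id, drop = 2L))
  names(members8) <- sprintf("n%d", 1:8)
  members8$n1 <- mk_fs("n1")   # only n1 keeps feature 2
  aln8 <- align_cluster(members8)
  p8 <- build_lb_pharmacophore(members8, aln8, "lb8", "rX", "agonist")
  dropped_type <- a$features$type[2L]
  d <- sqrt((p8$features$x - a$features$x[2L])^2 +
              (p8$features$y - a$features$y[2L])^2 +
              (p8$features$z - a$features$z[2L])^2)
  rare <- which(d < 0.5 & p8$features$type == dropped_type)
  expect_length(rare, 1L)
  expect_true(p8$features$optional[rare])

  # a member missing too many required merged features fails generation:
  # six distinct-type features, far apart; one member offset on five of them
  # so they merge (within merge_radius) but drift outside tolerance of the
  # merged centroid for that member only
  types6 <- c("AR", "H", "HBA", "HBD", "PI", "NI")
  pos6 <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0, 0, 0, 10, 10, 10, 0, 10, 0, 10),
                 6L, 3L, byrow = TRUE)
  mkfs6 <- function(id, off = 0) {
    p <- pos6
    p[1:5, 1L] <- p[1:5, 1L] + off
    feature_set(id, 1L, data.frame(type = types6, x = p[, 1L], y = p[, 2L],
                                   z = p[, 3L]))
  }
  idt <- list(rotation = diag(3), translation = c(0, 0, 0))
  trio <- list(b1 = mkfs6("b1"), b2 = mkfs6("b2"), b3 = mkfs6("b3", off = 2.2))
  aln_id <- list(reference_id = "b1",
                 transforms = list(b1 = idt, b2 = idt, b3 = idt))
  expect_error(
    build_lb_pharmacophore(trio, aln_id, "lberr", "rX", "agonist",
                           omitted_max = 4L, merge_radius = 3.0,
                           tolerance = 1.0),
    "b3")
  # with a higher allowance the same trio builds fine
  expect_no_error(
    build_lb_pharmacophore(trio, aln_id, "lbok", "rX", "agonist",
                           omitted_max = 5L, merge_radius = 3.0,
                           tolerance = 1.0))
})

test_that("exclusion shells keep training members matchable and manual spheres kill clash decoys", {
  a <- sample_archetype(4, seed = 97)
  members <- lapply(sprintf("t%d", 1:3), function(id) {
    prepare_ligand(generate_ligand(a, id, jitter_sigma = 0.15,
                                   seed = match(id, sprintf("t%d", 1:3))))
  })
  names(members) <- sprintf("t%d", 1:3)
  fsets <- lapply(members, function(r) r$features[[1L]])
  aln <- align_cluster(fsets)
  p <- build_lb_pharmacophore(fsets, aln, "lbx", "rX", "agonist")
  member_xyz <- lapply(names(aln$transforms), function(id) {
    tr <- aln$transforms[[id]]
    apply_transform(members[[id]]$heavy[[1L]], tr$rotation, tr$translation)
  })
  p_shell <- add_exclusion_shell(p, member_xyz)
  expect_gt(nrow(p_shell$exclusions), 0L)
  for (id in names(members)) {
    expect_false(is.null(match_conformer(p_shell, members[[id]]$features[[1L]],
                                         members[[id]]$heavy[[1L]], 0L)))
  }
  # empty manual list leaves only automatic spheres
  expect_false(any(p_shell$exclusions$manual))

  # manual sphere on a decoy-only substituent position
  decoy <- members[[1L]]
  site <- a$clash_site
  decoy$molecule$atoms <- rbind(decoy$molecule$atoms,
                                data.frame(element = "C", charge = 0L))
  decoy$molecule$conformers <- list(rbind(decoy$molecule$conformers[[1L]], site))
  decoy$features <- NULL
  decoy <- prepare_ligand(decoy)
  p_man <- add_exclusion_shell(p, member_xyz,
                               manual = data.frame(x = site[1L], y = site[2L],
                                                   z = site[3L]))
  expect_true(any(p_man$exclusions$manual))
  expect_null(match_conformer(p_man, decoy$features[[1L]], decoy$heavy[[1L]], 0L))
  for (id in names(members)) {
    expect_false(is.null(match_conformer(p_man, members[[id]]$features[[1L]],
                                         members[[id]]$heavy[[1L]], 0L)))
  }
})
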