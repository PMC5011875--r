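#' Ligand-based pharmacophore generation
#'
#' Clusters a ligand set by pharmacophore RDF-code similarity, rigidly aligns
#' each cluster on its feature-richest member, merges features shared across
#' the aligned members into a single "merged feature" pharmacophore, and
#' wraps the alignment in an exclusion-volume shell.
#'
#' The RDF code of a feature set is a Gaussian-smoothed radial distribution
#' of inter-feature distances, one block per unordered feature-type pair
#' (including same-type pairs: 28 blocks), L2-normalised as a whole so that
#' distances between codes live on a fixed 0..sqrt(2) scale commensurate
#' with the conventional 0.4 cluster cut. Clustering is complete-linkage hierarchical clustering on the
#' Euclidean distance between codes, cut at a per-dataset distance threshold
#' (0.4 by default, lowered stepwise to 0.3/0.2 to balance clusters);
#' singletons are reassigned to the nearest cluster by average linkage
#' whenever a multi-member cluster exists.
#'
#' @name lb_builder
NULL

RDF_TYPE_PAIRS <- {
  tp <- expand.grid(a = FEATURE_TYPES, b = FEATURE_TYPES,
                    stringsAsFactors = FALSE)
  tp <- tp[tp$a <= tp$b, ]
  paste(tp$a, tp$b, sep = ":")
}

#' Pharmacophore RDF code of a feature set
#'
#' @param fs a [feature_set()] with at least one feature.
#' @param n_bins radial bins per type-pair block (default 32).
#' @param r_max maximum distance covered (A, default 16).
#' @param sigma Gaussian smoothing width (A, default 1.0, commensurate with
#'   the 1.5 A feature tolerance so one chemotype stays within the 0.4 cut
#'   under sub-Angstrom coordinate noise).
#' @return numeric vector of length `28 * n_bins` (unordered type pairs x
#'   bins); all zero for a single-feature set.
#' @export
rdf_code <- function(fs, n_bins = 32L, r_max = 16, sigma = 1.0) {
  stopifnot(inherits(fs, "pharm_features"), nrow(fs$features) >= 1L)
  centers <- (seq_len(n_bins) - 0.5) * r_max / n_bins
  code <- matrix(0, n_bins, length(RDF_TYPE_PAIRS),
                 dimnames = list(NULL, RDF_TYPE_PAIRS))
  n <- nrow(fs$features)
  if (n >= 2L) {
    xyz <- feature_xyz(fs)
    typ <- fs$features$type
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      key <- paste(sort(c(typ[i], typ[j])), collapse = ":")
      code[, key] <- code[, key] + exp(-(centers - d)^2 / (2 * sigma^2))
    }
    nrm <- sqrt(sum(code^2))
    if (nrm > 0) code <- code / nrm
  }
  as.numeric(code)
}

#' Cluster a ligand set by RDF-code similarity
#'
#' @param ds a [ligand_dataset()].
#' @param distance_threshold cut height for complete-linkage clustering on
#'   Euclidean RDF-code distance (unitless; 0.4 / 0.3 / 0.2 in decreasing
#'   granularity).
#' @param auto_threshold when `TRUE`, start at `distance_threshold` and step
#'   down through 0.3 and 0.2 while the largest cluster still holds more
#'   than half of the ligands (the "balanced clusters" adjustment).
#' @param rules feature-perception rules.
#' @return list of clusters: each a list with `id`, `member_ids` (sorted),
#'   `distance_threshold` and `singleton` flag (`TRUE` when the cluster
#'   could not be merged into any other).
#' @export
cluster_ligands <- function(ds, distance_threshold = 0.4,
                            auto_threshold = FALSE, rules = feature_rules()) {
  stopifnot(inherits(ds, "ligand_dataset"))
  if (length(ds$ligands) == 0L) stop("empty dataset")
  ids <- sort(names(ds$ligands))   # stable order: lexicographic molecule id
  codes <- t(vapply(ids, function(id) {
    rec <- prepare_ligand(ds$ligands[[id]], rules)
    rdf_code(rec$features[[1L]])
  }, numeric(length(RDF_TYPE_PAIRS) * 32L)))
  if (length(ids) == 1L) {
    return(list(list(id = "c1", member_ids = ids,
                     distance_threshold = distance_threshold,
                     singleton = TRUE)))
  }
  d <- stats::dist(codes)
  hc <- stats::hclust(d, method = "complete")
  thresholds <- if (auto_threshold) {
    unique(c(distance_threshold, 0.3, 0.2))
  } else distance_threshold
  dm <- as.matrix(d)
  for (thr in thresholds) {
    cut <- stats::cutree(hc, h = thr)
    used <- thr
    if (max(table(cut)) <= length(ids) / 2) break
  }
  # singleton reassignment: attach to the nearest multi-member cluster by
  # average linkage, whenever one exists
  sizes <- table(cut)
  multi <- as.integer(names(sizes)[sizes >= 2L])
  singles <- which(cut %in% as.integer(names(sizes)[sizes == 1L]))
  flagged <- integer(0)
  if (length(multi)) {
    for (s in singles) {
      avg <- vapply(multi, function(cl) mean(dm[s, cut == cl & seq_along(cut) != s]),
                    numeric(1L))
      cut[s] <- multi[which.min(avg)]
    }
  } else {
    flagged <- singles
  }
  out <- list()
  for (cl in sort(unique(cut))) {
    members <- ids[cut == cl]
    out[[length(out) + 1L]] <- list(
      id = sprintf("c%d", length(out) + 1L),
      member_ids = sort(members),
      distance_threshold = used,
      singleton = length(members) == 1L)
  }
  out
}

#' Align the members of a cluster on a reference member
#'
#' The reference is the member with the most features (ties broken by
#' lexicographic molecule id); every other member is aligned by the best
#' type-compatible feature correspondence minimising RMSD (least-squares
#' superposition over a correspondence search, as in the screening matcher).
#' Members with fewer than three features, or with no feasible
#' correspondence, are left unaligned with a warning and excluded.
#'
#' @param members named list of [feature_set()]s (names = molecule ids).
#' @param align_tol correspondence tolerance during alignment (A).
#' @return list with `reference_id`, `transforms` (named list of
#'   `rotation`/`translation` per aligned member; identity for the
#'   reference) and `excluded` (character vector of member ids).
#' @export
align_cluster <- function(members, align_tol = 1.5) {
  stopifnot(length(members) >= 2L, !is.null(names(members)))
  nfeat <- vapply(members, function(fs) nrow(fs$features), integer(1L))
  ord <- order(-nfeat, names(members))
  ref_id <- names(members)[ord[1L]]
  ref <- members[[ref_id]]
  ref_p <- pharmacophore(id = paste0("align_", ref_id), provenance = "LB",
                         receptor_id = "align", activity_class = "agonist",
                         features = feature_points(
                           ref$features$type, feature_xyz(ref),
                           tolerance = align_tol))
  transforms <- list()
  transforms[[ref_id]] <- list(rotation = diag(3L), translation = c(0, 0, 0))
  excluded <- character(0)
  for (id in setdiff(names(members), ref_id)) {
    fs <- members[[id]]
    if (nrow(fs$features) < 3L) {
      warning(sprintf("cluster member %s has fewer than 3 features; excluded from alignment",
                      id), call. = FALSE)
      excluded <- c(excluded, id)
      next
    }
    mo <- max(0L, nrow(ref_p$features) - 3L)
    m <- tryCatch(match_conformer(ref_p, fs, heavy_xyz = NULL, max_omitted = mo),
                  error = function(e) NULL)
    if (is.null(m)) {
      warning(sprintf("cluster member %s could not be aligned; excluded", id),
              call. = FALSE)
      excluded <- c(excluded, id)
      next
    }
    transforms[[id]] <- m$transform
  }
  list(reference_id = ref_id, transforms = transforms, excluded = excluded)
}

#' Build a merged-feature ligand-based pharmacophore
#'
#' Features of the same type lying within the merge radius across aligned
#' members are merged into one feature at their centroid. Merged features
#' present in every member become required; features present in at least
#' `partial_threshold` of the members become optional partially-matching
#' features; rarer features are dropped. Generation fails when any training
#' member misses more than `omitted_max` required merged features (presence
#' re-measured at the feature tolerance around the merged centroid).
#'
#' @param members named list of [feature_set()]s (cluster members).
#' @param alignment result of [align_cluster()] on these members.
#' @param id model id.
#' @param receptor_id,activity_class model annotation.
#' @param omitted_max maximum missing required merged features per training
#'   member (default 4).
#' @param partial_threshold minimum presence fraction for an optional
#'   feature (default 0.10).
#' @param merge_radius feature merge distance (A, default 1.5).
#' @param tolerance tolerance radius of the merged features (A).
#' @param source free-text provenance (cluster id).
#' @return a [pharmacophore()] with provenance `"LB"`.
#' @export
build_lb_pharmacophore <- function(members, alignment, id, receptor_id,
                                   activity_class, omitted_max = 4L,
                                   partial_threshold = 0.10,
                                   merge_radius = 1.5, tolerance = 1.5,
                                   source = "") {
  aligned_ids <- names(alignment$transforms)
  stopifnot(length(aligned_ids) >= 2L)
  rows <- list()
  for (mid in aligned_ids) {
    fs <- members[[mid]]
    tr <- alignment$transforms[[mid]]
    xyz <- apply_transform(feature_xyz(fs), tr$rotation, tr$translation)
    if (nrow(fs$features)) {
      rows[[length(rows) + 1L]] <- data.frame(
        member = mid, type = fs$features$type,
        x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
        nx = fs$features$nx, ny = fs$features$ny, nz = fs$features$nz)
    }
  }
  all_f <- do.call(rbind, rows)
  n_members <- length(aligned_ids)
  # single-linkage merge of same-type features within the merge radius
  grp <- seq_len(nrow(all_f))
  find <- function(a) { while (grp[a] != a) { grp[a] <<- grp[grp[a]]; a <- grp[a] }; a }
  for (i in seq_len(nrow(all_f) - 1L)) for (j in (i + 1L):nrow(all_f)) {
    if (all_f$type[i] == all_f$type[j] &&
        sqrt(sum((unlist(all_f[i, c("x", "y", "z")]) -
                    unlist(all_f[j, c("x", "y", "z")]))^2)) <= merge_radius) {
      grp[find(i)] <- find(j)
    }
  }
  gids <- vapply(seq_len(nrow(all_f)), find, integer(1L))
  merged <- list()
  for (g in unique(gids)) {
    sel <- all_f[gids == g, , drop = FALSE]
    pres <- length(unique(sel$member)) / n_members
    if (pres < partial_threshold) next
    nrm <- .merge_normals(as.matrix(sel[, c("nx", "ny", "nz")]))
    merged[[length(merged) + 1L]] <- data.frame(
      type = sel$type[1L],
      x = mean(sel$x), y = mean(sel$y), z = mean(sel$z),
      nx = nrm[1L], ny = nrm[2L], nz = nrm[3L],
      presence = pres)
  }
  merged <- do.call(rbind, merged)
  if (is.null(merged) || nrow(merged) == 0L) {
    stop("no shared features across cluster members")
  }
  required <- merged$presence >= 1 - 1e-9
  feats <- feature_points(merged$type,
                          as.matrix(merged[, c("x", "y", "z")]),
                          tolerance = tolerance,
                          normal = as.matrix(merged[, c("nx", "ny", "nz")]),
                          optional = !required)
  # omitted-features constraint: every member must realise all but at most
  # omitted_max of the required merged features, within tolerance
  req <- feats[!feats$optional, , drop = FALSE]
  for (mid in aligned_ids) {
    sel <- all_f[all_f$member == mid, , drop = FALSE]
    missing <- 0L
    for (k in seq_len(nrow(req))) {
      same <- sel[sel$type == req$type[k], , drop = FALSE]
      d <- if (nrow(same)) min(cross_dist(
        as.matrix(same[, c("x", "y", "z")]),
        matrix(unlist(req[k, c("x", "y", "z")]), 1L))) else Inf
      if (d > req$tolerance[k]) missing <- missing + 1L
    }
    if (missing > omitted_max) {
      stop(sprintf("training member %s misses %d required merged features (allowed: %d)",
                   mid, missing, omitted_max))
    }
  }
  pharmacophore(id = id, provenance = "LB", receptor_id = receptor_id,
                activity_class = activity_class, features = feats,
                source = source)
}

.merge_normals <- function(nrm) {
  ok <- rowSums(is.na(nrm)) == 0L
  if (!any(ok)) return(c(NA_real_, NA_real_, NA_real_))
  nrm <- nrm[ok, , drop = FALSE]
  ref <- nrm[1L, ]
  for (k in seq_len(nrow(nrm))) {
    if (sum(nrm[k, ] * ref) < 0) nrm[k, ] <- -nrm[k, ]
  }
  unitize(colMeans(nrm))
}

# 13 probe directions: centroid-outward direction is added by the caller
.SHELL_DIRS <- {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  v / sqrt(rowSums(v^2))
}

#' Add an exclusion-volume shell around an aligned ligand set
#'
#' Sphere centers are probe points placed around every aligned heavy atom
#' and kept when they lie 2.0-3.0 A away from the union of aligned heavy
#' atoms; spheres that any training member's atoms would penetrate (with a
#' safety margin) are dropped, so every training member still matches after
#' shell addition. Extra manual spheres (placed by hand to reject decoys
#' whose inactivity stems from steric clashes with the binding site) can be
#' supplied as a data.frame with columns `x`, `y`, `z` and optionally
#' `radius`.
#'
#' @param p a [pharmacophore()].
#' @param member_xyz list of heavy-atom coordinate matrices of the aligned
#'   training members (already in the pharmacophore frame).
#' @param manual optional manual sphere table.
#' @param band distance band from the atom union (A).
#' @param radius sphere radius (A, default 1.0).
#' @param probe_dist probe placement distance from each atom (A).
#' @param margin safety margin kept clear around training atoms (A).
#' @param core_dist spheres are only kept this close (A) to the model's
#'   enabled features, so the shell limits the pharmacophore core rather
#'   than tracing distant substituents.
#' @param max_spheres cap on automatic spheres (evenly subsampled).
#' @return the pharmacophore with spheres appended.
#' @export
add_exclusion_shell <- function(p, member_xyz, manual = NULL,
                                band = c(2.0, 3.0), radius = 1.0,
                                probe_dist = 2.5, margin = 0.3,
                                core_dist = 6.0, max_spheres = 60L) {
  stopifnot(inherits(p, "pharmacophore"))
  union_xyz <- do.call(rbind, lapply(member_xyz, as.matrix))
  ctr <- colMeans(union_xyz)
  cands <- NULL
  for (k in seq_len(nrow(union_xyz))) {
    a <- union_xyz[k, ]
    dirs <- rbind(.SHELL_DIRS, unitize(a - ctr))
    cands <- rbind(cands, sweep(dirs * probe_dist, 2L, a, "+"))
  }
  dmin <- apply(cross_dist(cands, union_xyz), 1L, min)
  cands <- cands[dmin >= band[1L] & dmin <= band[2L], , drop = FALSE]
  if (nrow(cands)) {
    feat_xyz <- as.matrix(p$features[!p$features$disabled, c("x", "y", "z"),
                                     drop = FALSE])
    dcore <- apply(cross_dist(cands, feat_xyz), 1L, min)
    cands <- cands[dcore <= core_dist, , drop = FALSE]
  }
  keep <- rep(TRUE, nrow(cands))
  if (nrow(cands)) {
    # keep training members clear
    dmin <- apply(cross_dist(cands, union_xyz), 1L, min)
    keep <- dmin >= radius + margin
    cands <- cands[keep, , drop = FALSE]
  }
  # deduplicate within one radius
  if (nrow(cands)) {
    sel <- integer(0)
    for (k in seq_len(nrow(cands))) {
      if (!length(sel) ||
          min(cross_dist(cands[k, , drop = FALSE],
                         cands[sel, , drop = FALSE])) > radius) {
        sel <- c(sel, k)
      }
    }
    cands <- cands[sel, , drop = FALSE]
  }
  if (nrow(cands) > max_spheres) {
    cands <- cands[round(seq(1L, nrow(cands), length.out = max_spheres)), ,
                   drop = FALSE]
  }
  auto <- exclusion_spheres(cands, radius = radius, manual = FALSE)
  man <- if (!is.null(manual) && NROW(manual) > 0L) {
    manual <- as.data.frame(manual)
    if (is.null(manual$radius)) manual$radius <- radius
    exclusion_spheres(as.matrix(manual[, c("x", "y", "z")]),
                      radius = manual$radius, manual = TRUE)
  } else {
    exclusion_spheres(matrix(numeric(), 0L, 3L))
  }
  p$exclusions <- rbind(p$exclusions, auto, man)
  p
}
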