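#' Pharmacophore screening
#'
#' Matches ligand conformers against a pharmacophore query. A conformer is a
#' hit when an injective, type-compatible correspondence maps every enabled
#' required feature (except at most `max_omitted` of them) onto a ligand
#' feature such that some rigid transform places each matched ligand feature
#' inside the query feature's tolerance sphere, and no ligand heavy atom
#' falls strictly inside an exclusion sphere. Optional features are matched
#' when possible but never cause rejection.
#'
#' The search enumerates correspondences depth-first with a distance-geometry
#' pruning rule (`|d_query - d_ligand| <= tol_a + tol_b` for every assigned
#' pair -- a necessary condition for any rigid placement), and tests each
#' complete correspondence against a fixed family of candidate transforms:
#' the full least-squares superposition, every 3-pair (triplet-seeded)
#' superposition, and -- when none of those is feasible -- a short
#' iteratively reweighted fit that pushes violated features inside their
#' tolerance spheres. Per-feature tolerance is tested under each candidate,
#' not an aggregate RMSD, matching per-sphere screening semantics.
#' [brute_force_match()] enumerates correspondences exhaustively without
#' pruning and applies the same accept/reject contract; it is the oracle the
#' production matcher is validated against.
#'
#' @name screening
NULL

# ---- internal geometry of one correspondence --------------------------------

# Candidate transforms for a correspondence: full LS fit + all triplet seeds.
# Returns list(ok, rotation, translation, rmsd) for the best passing
# candidate (lowest RMSD over the matched pairs), or ok = FALSE.
.assess_correspondence <- function(q_pos, q_tol, l_pos, heavy_xyz, exclusions) {
  m <- nrow(q_pos)
  # the full least-squares fit minimises the pairwise RMSD over all rigid
  # transforms, so when it passes it is also the best-RMSD candidate
  cands <- list(seq_len(m))
  if (m > 3L) {
    cands <- c(cands, utils::combn(m, 3L, simplify = FALSE))
  }
  best <- NULL
  consider <- function(rotation, translation) {
    moved <- apply_transform(l_pos, rotation, translation)
    dev <- sqrt(rowSums((moved - q_pos)^2))
    if (any(dev > q_tol)) return(FALSE)
    if (.clashes(heavy_xyz, rotation, translation, exclusions)) return(FALSE)
    r <- sqrt(mean(dev^2))
    if (is.null(best) || r < best$rmsd) {
      best <<- list(ok = TRUE, rotation = rotation, translation = translation,
                    rmsd = r)
    }
    TRUE
  }
  for (idx in cands) {
    k <- tryCatch(kabsch(l_pos[idx, , drop = FALSE], q_pos[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(k)) next
    ok <- consider(k$rotation, k$translation)
    if (ok && identical(idx, seq_len(m))) break  # full fit passed: optimal RMSD
  }
  if (is.null(best)) {
    # feasibility fallbacks, attempted only when the least-squares start is
    # already close to feasible (distant misses cannot be rescued by a
    # bounded local search)
    k0 <- tryCatch(kabsch(l_pos, q_pos), error = function(e) NULL)
    start_ratio <- Inf
    if (!is.null(k0)) {
      moved <- apply_transform(l_pos, k0$rotation, k0$translation)
      start_ratio <- max(sqrt(rowSums((moved - q_pos)^2)) / q_tol)
    }
    if (start_ratio > 1 && start_ratio < 1.8) {
      # 1: iteratively reweighted fits pushing violated features inside
      # their tolerance spheres
      w <- rep(1, m)
      for (iter in seq_len(10L)) {
        k <- tryCatch(kabsch(l_pos, q_pos, w = w), error = function(e) NULL)
        if (is.null(k)) break
        if (consider(k$rotation, k$translation)) break
        moved <- apply_transform(l_pos, k$rotation, k$translation)
        dev <- sqrt(rowSums((moved - q_pos)^2))
        w <- w + 2 * pmax(0, dev / q_tol - 1)
      }
    }
    if (is.null(best) && start_ratio > 1 && start_ratio < 1.8) {
      # 2: deterministic minimax (Chebyshev) registration from the
      # least-squares start
      obj <- function(par) {
        rot <- .axis_angle_rotation(par[1:3]) %*% k0$rotation
        tr <- k0$translation + par[4:6]
        mv <- apply_transform(l_pos, rot, tr)
        max(sqrt(rowSums((mv - q_pos)^2)) / q_tol)
      }
      o <- stats::optim(rep(0, 6L), obj, method = "Nelder-Mead",
                        control = list(maxit = 150L, reltol = 1e-6))
      if (o$value <= 1) {
        consider(.axis_angle_rotation(o$par[1:3]) %*% k0$rotation,
                 k0$translation + o$par[4:6])
      }
    }
  }
  if (is.null(best)) list(ok = FALSE) else best
}

.axis_angle_rotation <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) diag(3L) else rotation_matrix(v / th, th)
}

# TRUE when any transformed ligand heavy atom lies strictly inside a sphere
.clashes <- function(heavy_xyz, rotation, translation, exclusions) {
  if (is.null(exclusions) || nrow(exclusions) == 0L || is.null(heavy_xyz) ||
      nrow(heavy_xyz) == 0L) {
    return(FALSE)
  }
  moved <- apply_transform(heavy_xyz, rotation, translation)
  d <- cross_dist(moved, as.matrix(exclusions[, c("x", "y", "z")]))
  any(sweep(d, 2L, exclusions$radius, "<"))
}

# ---- production matcher -----------------------------------------------------

#' Match one conformer against a pharmacophore
#'
#' @param p a screenable [pharmacophore()].
#' @param fs a [feature_set()] of the conformer.
#' @param heavy_xyz heavy-atom coordinates of the conformer (n x 3), used for
#'   exclusion-volume clash testing; `NULL` disables clash testing.
#' @param max_omitted maximum number of enabled required features a hit may
#'   fail to map (default 0).
#' @return a match (list with `molecule_id`, `conformer_index`,
#'   `correspondence` -- row index into `p$features` mapped to ligand feature
#'   row or `NA`, `omitted` -- feature rows left unmapped, `rmsd`,
#'   `transform`), or `NULL` when the conformer is not a hit.
#' @export
match_conformer <- function(p, fs, heavy_xyz = NULL, max_omitted = 0L) {
  stopifnot(inherits(p, "pharmacophore"), inherits(fs, "pharm_features"))
  if (!is_screenable(p)) stop(sprintf("pharmacophore %s is not screenable", p$id))
  req_rows <- which(!p$features$disabled & !p$features$optional)
  opt_rows <- which(!p$features$disabled & p$features$optional)
  lf <- fs$features
  l_pos <- feature_xyz(fs)
  q_pos_all <- as.matrix(p$features[, c("x", "y", "z")])
  q_tol_all <- p$features$tolerance
  if (!is.null(heavy_xyz)) heavy_xyz <- as.matrix(heavy_xyz)
  n_req <- length(req_rows)
  max_omitted <- min(max_omitted, n_req)
  for (omit_k in 0:max_omitted) {
    omit_sets <- if (omit_k == 0L) list(integer(0)) else
      utils::combn(n_req, omit_k, simplify = FALSE)
    best <- NULL
    for (omit in omit_sets) {
      keep <- setdiff(seq_len(n_req), omit)
      rows <- req_rows[keep]
      if (length(rows) < 3L) next
      q_pos <- q_pos_all[rows, , drop = FALSE]
      if (points_collinear(unique(round(q_pos, 6L)))) next
      res <- .dfs_match(lf$type, l_pos, p$features$type[rows], q_pos,
                        q_tol_all[rows], heavy_xyz, p$exclusions)
      if (!is.null(res)) {
        res$rows <- rows
        res$omit_rows <- req_rows[omit]
        if (is.null(best) || res$rmsd < best$rmsd) best <- res
      }
    }
    if (!is.null(best)) {
      return(.finalize_match(p, fs, l_pos, best, opt_rows))
    }
  }
  NULL
}

# depth-first correspondence search with distance-geometry pruning
.dfs_match <- function(l_type, l_pos, q_type, q_pos, q_tol, heavy_xyz,
                       exclusions) {
  m <- length(q_type)
  cand <- lapply(seq_len(m), function(i) which(l_type == q_type[i]))
  if (any(vapply(cand, length, integer(1L)) == 0L)) return(NULL)
  ord <- order(vapply(cand, length, integer(1L)))
  dq <- as.matrix(stats::dist(q_pos))
  dl <- if (nrow(l_pos) >= 2L) as.matrix(stats::dist(l_pos)) else
    matrix(0, nrow(l_pos), nrow(l_pos))
  assign_l <- integer(m)   # ligand feature chosen for ordered slot k
  best <- NULL
  recurse <- function(k) {
    if (k > m) {
      perm <- integer(m)
      perm[ord] <- assign_l[seq_len(m)]
      a <- .assess_correspondence(q_pos, q_tol, l_pos[perm, , drop = FALSE],
                                  heavy_xyz, exclusions)
      if (a$ok && (is.null(best) || a$rmsd < best$rmsd)) {
        best <<- c(a, list(ligand_rows = perm))
      }
      return()
    }
    qi <- ord[k]
    for (lj in cand[[qi]]) {
      if (k > 1L && lj %in% assign_l[seq_len(k - 1L)]) next
      ok <- TRUE
      for (prev in seq_len(k - 1L)) {
        qp <- ord[prev]
        if (abs(dq[qi, qp] - dl[lj, assign_l[prev]]) >
            q_tol[qi] + q_tol[qp]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_l[k] <<- lj
      recurse(k + 1L)
    }
  }
  recurse(1L)
  best
}

.finalize_match <- function(p, fs, l_pos, res, opt_rows) {
  correspondence <- rep(NA_integer_, nrow(p$features))
  correspondence[res$rows] <- res$ligand_rows
  # optional features: matched when an unused compatible ligand feature sits
  # inside tolerance under the accepted transform; never cause rejection
  if (length(opt_rows)) {
    moved <- apply_transform(l_pos, res$rotation, res$translation)
    used <- res$ligand_rows
    for (r in opt_rows) {
      cand <- setdiff(which(fs$features$type == p$features$type[r]), used)
      if (!length(cand)) next
      d <- sqrt(rowSums((moved[cand, , drop = FALSE] -
                           matrix(unlist(p$features[r, c("x", "y", "z")]),
                                  length(cand), 3L, byrow = TRUE))^2))
      hit <- cand[which.min(d)]
      if (min(d) <= p$features$tolerance[r]) {
        correspondence[r] <- hit
        used <- c(used, hit)
      }
    }
  }
  list(molecule_id = fs$molecule_id, conformer_index = fs$conformer_index,
       correspondence = correspondence, omitted = res$omit_rows,
       rmsd = res$rmsd,
       transform = list(rotation = res$rotation,
                        translation = res$translation))
}

# ---- exhaustive oracle ------------------------------------------------------

#' Exhaustive matching oracle
#'
#' Enumerates every injective type-compatible correspondence (no pruning) and
#' every omission subset, testing each against the full least-squares and all
#' triplet-seeded superpositions with the identical accept/reject contract as
#' [match_conformer()]. Intended as a test oracle on small instances.
#'
#' @inheritParams match_conformer
#' @return a match list (as [match_conformer()]) or `NULL`.
#' @export
brute_force_match <- function(p, fs, heavy_xyz = NULL, max_omitted = 0L) {
  stopifnot(inherits(p, "pharmacophore"), inherits(fs, "pharm_features"))
  if (!is_screenable(p)) stop(sprintf("pharmacophore %s is not screenable", p$id))
  req_rows <- which(!p$features$disabled & !p$features$optional)
  if (length(req_rows) > 8L) stop("oracle limit: more than 8 enabled features")
  if (nrow(fs$features) > 20L) stop("oracle limit: more than 20 ligand features")
  l_pos <- feature_xyz(fs)
  if (!is.null(heavy_xyz)) heavy_xyz <- as.matrix(heavy_xyz)
  n_req <- length(req_rows)
  max_omitted <- min(max_omitted, n_req)
  for (omit_k in 0:max_omitted) {
    omit_sets <- if (omit_k == 0L) list(integer(0)) else
      utils::combn(n_req, omit_k, simplify = FALSE)
    best <- NULL
    for (omit in omit_sets) {
      rows <- req_rows[setdiff(seq_len(n_req), omit)]
      if (length(rows) < 3L) next
      q_pos <- as.matrix(p$features[rows, c("x", "y", "z")])
      if (points_collinear(unique(round(q_pos, 6L)))) next
      q_tol <- p$features$tolerance[rows]
      q_type <- p$features$type[rows]
      for (perm in .all_injective(q_type, fs$features$type)) {
        a <- .assess_correspondence(q_pos, q_tol, l_pos[perm, , drop = FALSE],
                                    heavy_xyz, p$exclusions)
        if (a$ok && (is.null(best) || a$rmsd < best$rmsd)) {
          best <- c(a, list(ligand_rows = perm, rows = rows,
                            omit_rows = req_rows[omit]))
        }
      }
    }
    if (!is.null(best)) {
      return(.finalize_match(p, fs, l_pos,
                             best,
                             which(!p$features$disabled & p$features$optional)))
    }
  }
  NULL
}

# all injective assignments slot i -> ligand index with matching type
.all_injective <- function(q_type, l_type) {
  out <- list(integer(0))
  for (i in seq_along(q_type)) {
    cand <- which(l_type == q_type[i])
    nxt <- list()
    for (partial in out) {
      for (c1 in setdiff(cand, partial)) {
        nxt[[length(nxt) + 1L]] <- c(partial, c1)
      }
    }
    out <- nxt
    if (!length(out)) return(list())
  }
  out
}

# ---- dataset screening ------------------------------------------------------

#' Screen a ligand set against a pharmacophore
#'
#' Returns at most one hit per molecule: the best match over its conformers,
#' ranked by (number of omitted features, RMSD, conformer index).
#'
#' @param p a screenable [pharmacophore()].
#' @param ligands a [ligand_dataset()], a list of datasets, or a list of
#'   ligand records.
#' @param max_omitted omitted-features allowance (default 0).
#' @return list with `pharmacophore_id`, `hits` (data.frame: molecule_id,
#'   activity_class, conformer_index, n_omitted, rmsd), `matches` (named list
#'   of match objects) and `parameters`.
#' @export
screen <- function(p, ligands, max_omitted = 0L) {
  recs <- gather_ligands(ligands)
  hits <- list(); matches <- list()
  for (rec in recs) {
    rec <- prepare_ligand(rec)
    best <- NULL
    for (ci in seq_along(rec$features)) {
      m <- match_conformer(p, rec$features[[ci]], rec$heavy[[ci]], max_omitted)
      if (!is.null(m) &&
          (is.null(best) || length(m$omitted) < length(best$omitted) ||
             (length(m$omitted) == length(best$omitted) && m$rmsd < best$rmsd))) {
        best <- m
      }
    }
    if (!is.null(best)) {
      hits[[length(hits) + 1L]] <- data.frame(
        molecule_id = rec$molecule$id, activity_class = rec$activity_class,
        conformer_index = best$conformer_index,
        n_omitted = length(best$omitted), rmsd = best$rmsd)
      matches[[rec$molecule$id]] <- best
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(molecule_id = character(), activity_class = character(),
               conformer_index = integer(), n_omitted = integer(),
               rmsd = numeric())
  list(pharmacophore_id = p$id, hits = hits, matches = matches,
       parameters = list(max_omitted = max_omitted))
}

#' Screen a ligand set against a pharmacophore ensemble
#'
#' A molecule is a hit when at least one ensemble member matches it at
#' `max_omitted = 0`; hits are the union over members.
#'
#' @param ens non-empty list of [pharmacophore()] objects.
#' @param ligands as in [screen()].
#' @param max_omitted omitted-features allowance (default 0, the ensemble
#'   screening semantics).
#' @return list with `hits` data.frame (molecule_id, activity_class,
#'   pharmacophore_id of the first member, in ensemble order, that hit).
#' @export
screen_ensemble <- function(ens, ligands, max_omitted = 0L) {
  stopifnot(length(ens) >= 1L)
  recs <- gather_ligands(ligands)
  rows <- list()
  for (rec in recs) {
    rec <- prepare_ligand(rec)
    hit_by <- NA_character_
    for (p in ens) {
      for (ci in seq_along(rec$features)) {
        m <- match_conformer(p, rec$features[[ci]], rec$heavy[[ci]],
                             max_omitted)
        if (!is.null(m)) { hit_by <- p$id; break }
      }
      if (!is.na(hit_by)) break
    }
    if (!is.na(hit_by)) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = rec$molecule$id, activity_class = rec$activity_class,
        pharmacophore_id = hit_by)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(), activity_class = character(),
               pharmacophore_id = character())
  list(hits = hits)
}
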