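#' Pharmacophoric feature perception
#'
#' Tags a 3D conformer with typed feature points: aromatic rings (AR),
#' hydrophobic areas (H), hydrogen-bond acceptors and donors (HBA/HBD),
#' negative and positive ionizable groups (NI/PI) and metal-binding
#' locations (MB). The chemistry is rule-based and configurable through
#' [feature_rules()]; the defaults are deliberately conventional:
#'
#' * HBD: neutral O-H or N-H (explicit or implicit hydrogens).
#' * HBA: neutral O with a lone pair, or neutral N that is neither an amide
#'   nitrogen nor an aromatic N-H.
#' * AR: aromatic rings (all-aromatic bond orders, or 5/6-rings of C/N/O/S
#'   with >= 2 ring double bonds); placed at the ring centroid with the ring
#'   plane normal stored.
#' * H: connected groups of >= 3 non-aromatic carbons/halogens with no polar
#'   or charged neighbours, placed at the group centroid; centroids closer
#'   than 2 A are merged.
#' * PI: positively charged nitrogen, or neutral amidine/guanidine group
#'   (group centroid) - protonatable at assay pH.
#' * NI: carboxylate (centroid of C and both oxygens), sulfonate/phosphate
#'   (centroid), or other negatively charged O/P atoms.
#' * MB: thiol/thiolate sulfur.
#'
#' Feature positions always lie on atoms or group centroids of the conformer.
#' Output rows are sorted by type and position, so perception is invariant
#' under atom reordering of the input record.
#'
#' @name features
NULL

FEATURE_TYPES <- c("AR", "H", "HBA", "HBD", "PI", "NI", "MB")

#' Default feature-perception rule settings
#'
#' @param hydrophobic_min_atoms minimum contiguous apolar atoms per H group.
#' @param hydrophobic_merge merge distance (A) for H centroids.
#' @return named list of rule parameters.
#' @export
feature_rules <- function(hydrophobic_min_atoms = 3L, hydrophobic_merge = 2.0) {
  list(hydrophobic_min_atoms = hydrophobic_min_atoms,
       hydrophobic_merge = hydrophobic_merge)
}

#' Construct a feature set
#'
#' @param molecule_id molecule identifier.
#' @param conformer_index conformer the features were perceived on.
#' @param features data.frame with columns `type`, `x`, `y`, `z` and
#'   optionally `nx`, `ny`, `nz` (ring normal, AR only).
#' @return object of class `pharm_features`.
#' @export
feature_set <- function(molecule_id, conformer_index, features) {
  features <- as.data.frame(features)
  if (nrow(features)) {
    stopifnot(all(features$type %in% FEATURE_TYPES),
              all(is.finite(features$x)), all(is.finite(features$y)),
              all(is.finite(features$z)))
  }
  for (cn in c("nx", "ny", "nz")) {
    if (is.null(features[[cn]])) features[[cn]] <- rep(NA_real_, nrow(features))
  }
  structure(list(molecule_id = molecule_id,
                 conformer_index = as.integer(conformer_index),
                 features = features[, c("type", "x", "y", "z",
                                         "nx", "ny", "nz")]),
            class = "pharm_features")
}

#' @export
print.pharm_features <- function(x, ...) {
  tab <- table(factor(x$features$type, levels = FEATURE_TYPES))
  cat(sprintf("<features of %s (conformer %d): %s>\n", x$molecule_id,
              x$conformer_index,
              paste(sprintf("%s=%d", names(tab)[tab > 0], tab[tab > 0]),
                    collapse = " ")))
  invisible(x)
}

#' Feature coordinates as a matrix
#' @param fs a [feature_set()].
#' @return n x 3 matrix.
#' @export
feature_xyz <- function(fs) {
  as.matrix(fs$features[, c("x", "y", "z")])
}

#' Perceive pharmacophoric features of a conformer
#'
#' @param mol a [molecule()].
#' @param conformer_index conformer to perceive on (default 1).
#' @param rules rule settings from [feature_rules()].
#' @return a [feature_set()]; empty when nothing matches.
#' @export
perceive_features <- function(mol, conformer_index = 1L, rules = feature_rules()) {
  stopifnot(inherits(mol, "pharm_mol"),
            conformer_index >= 1L, conformer_index <= length(mol$conformers))
  xyz <- conformer_xyz(mol, conformer_index)
  elem <- mol$atoms$element
  charge <- mol$atoms$charge
  n <- n_atoms(mol)
  adj <- mol_adjacency(mol)
  nh <- total_h(mol)
  rings <- .find_rings(mol)
  arom <- .aromatic_atoms(mol, rings)
  consumed <- logical(n)   # atoms claimed by an ionizable/MB group
  feats <- list()
  add <- function(type, pos, normal = c(NA_real_, NA_real_, NA_real_)) {
    feats[[length(feats) + 1L]] <<- data.frame(
      type = type, x = pos[1L], y = pos[2L], z = pos[3L],
      nx = normal[1L], ny = normal[2L], nz = normal[3L])
  }

  ## -- negative ionizable groups (claim their atoms first) ------------------
  for (c_idx in which(elem == "C")) {
    nb <- adj[[c_idx]]
    o_nb <- nb[elem[nb] == "O"]
    if (length(o_nb) == 2L) {
      ords <- vapply(o_nb, function(o) .bond_order(mol, c_idx, o), integer(1L))
      if ((any(ords == 2L) && any(charge[o_nb] < 0L)) ||
          all(charge[o_nb] < 0L)) {
        grp <- c(c_idx, o_nb)
        add("NI", colMeans(xyz[grp, , drop = FALSE]))
        consumed[grp] <- TRUE
      }
    }
  }
  for (s_idx in which(elem %in% c("S", "P"))) {
    if (consumed[s_idx]) next
    o_nb <- adj[[s_idx]][elem[adj[[s_idx]]] == "O"]
    if (length(o_nb) >= 3L && any(charge[o_nb] < 0L)) {
      grp <- c(s_idx, o_nb)
      add("NI", colMeans(xyz[grp, , drop = FALSE]))
      consumed[grp] <- TRUE
    }
  }
  for (a in which(charge < 0L & elem %in% c("O", "P"))) {
    if (!consumed[a]) { add("NI", xyz[a, ]); consumed[a] <- TRUE }
  }

  ## -- positive ionizable ---------------------------------------------------
  for (a in which(charge > 0L & elem == "N")) {
    add("PI", xyz[a, ]); consumed[a] <- TRUE
  }
  # neutral amidine/guanidine: C doubly bonded to N with >= 2 N neighbours
  for (c_idx in which(elem == "C")) {
    nb <- adj[[c_idx]]
    n_nb <- nb[elem[nb] == "N" & !consumed[nb] & !arom[nb]]
    if (length(n_nb) >= 2L &&
        any(vapply(n_nb, function(x) .bond_order(mol, c_idx, x), integer(1L)) == 2L)) {
      grp <- c(c_idx, n_nb)
      add("PI", colMeans(xyz[grp, , drop = FALSE]))
      consumed[grp] <- TRUE
    }
  }

  ## -- metal binding ---------------------------------------------------------
  for (a in which(elem == "S")) {
    if (consumed[a]) next
    heavy_nb <- adj[[a]][elem[adj[[a]]] != "H"]
    if (nh[a] >= 1L || charge[a] < 0L) {   # thiol / thiolate
      add("MB", xyz[a, ]); consumed[a] <- TRUE
    } else if (length(heavy_nb) <= 1L) {
      consumed[a] <- TRUE                  # terminal S (e.g. C=S): inert here
    }
  }

  ## -- hydrogen-bond donors and acceptors ------------------------------------
  amide_n <- .amide_nitrogens(mol, adj)
  for (a in seq_len(n)) {
    if (consumed[a] || charge[a] != 0L) next
    if (elem[a] == "O") {
      if (nh[a] >= 1L) add("HBD", xyz[a, ])
      add("HBA", xyz[a, ])
    } else if (elem[a] == "N") {
      if (nh[a] >= 1L) add("HBD", xyz[a, ])
      # acceptors: not amide N, not pyrrole-type aromatic N-H
      if (!(a %in% amide_n) && !(arom[a] && nh[a] >= 1L)) add("HBA", xyz[a, ])
    }
  }

  ## -- aromatic rings ---------------------------------------------------------
  for (ring in rings) {
    if (!.ring_is_aromatic(mol, ring)) next
    pos <- colMeans(xyz[ring, , drop = FALSE])
    add("AR", pos, .plane_normal(xyz[ring, , drop = FALSE]))
  }

  ## -- hydrophobic groups ------------------------------------------------------
  polar <- elem %in% c("N", "O", "S", "P") | charge != 0L
  cand <- which((elem == "C" | elem %in% c("F", "Cl", "Br", "I")) &
                  !arom & charge == 0L &
                  !vapply(seq_len(n), function(a) any(polar[adj[[a]]]), logical(1L)))
  if (length(cand) >= rules$hydrophobic_min_atoms) {
    sub_edges <- mol$bonds[mol$bonds$i %in% cand & mol$bonds$j %in% cand, ,
                           drop = FALSE]
    gid <- .components(cand, sub_edges)
    cent <- NULL
    for (g in unique(gid)) {
      grp <- cand[gid == g]
      if (length(grp) >= rules$hydrophobic_min_atoms) {
        cent <- rbind(cent, colMeans(xyz[grp, , drop = FALSE]))
      }
    }
    for (pos in .merge_points(cent, rules$hydrophobic_merge)) add("H", pos)
  }

  out <- if (length(feats)) do.call(rbind, feats) else
    data.frame(type = character(), x = numeric(), y = numeric(), z = numeric(),
               nx = numeric(), ny = numeric(), nz = numeric())
  ord <- order(out$type, round(out$x, 4L), round(out$y, 4L), round(out$z, 4L))
  feature_set(mol$id, conformer_index, out[ord, , drop = FALSE])
}

.bond_order <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$i == i & b$j == j) | (b$i == j & b$j == i)
  if (!any(hit)) 0L else as.integer(b$order[which(hit)[1L]])
}

# connected components of a vertex subset; returns group id per element of `cand`
.components <- function(cand, edges) {
  idx <- match(seq_len(max(c(cand, 1L))), cand)
  parent <- seq_along(cand)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (k in seq_len(NROW(edges))) {
    a <- idx[edges$i[k]]; b <- idx[edges$j[k]]
    if (!is.na(a) && !is.na(b)) parent[find(a)] <- find(b)
  }
  vapply(seq_along(cand), find, integer(1L))
}

.merge_points <- function(pts, radius) {
  if (is.null(pts) || nrow(pts) == 0L) return(list())
  merged <- list()
  used <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (used[i]) next
    grp <- i
    repeat {
      d <- cross_dist(pts[grp, , drop = FALSE], pts)
      near <- which(!used & apply(d, 2L, min) <= radius)
      if (setequal(near, grp)) break
      grp <- near
    }
    used[grp] <- TRUE
    merged[[length(merged) + 1L]] <- colMeans(pts[grp, , drop = FALSE])
  }
  merged
}

# simple rings (size 3..8) via DFS on the bond graph, deduplicated by atom set
.find_rings <- function(mol, max_size = 8L) {
  adj <- mol_adjacency(mol)
  rings <- list()
  seen <- character(0)
  n <- n_atoms(mol)
  for (start in seq_len(n)) {
    stack <- list(c(start))
    while (length(stack)) {
      path <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- path[length(path)]
      for (nb in adj[[last]]) {
        if (nb == start && length(path) >= 3L) {
          key <- paste(sort(path), collapse = "-")
          if (!(key %in% seen)) {
            # keep only chordless cycles (every non-adjacent ring pair unbonded)
            if (.is_chordless(path, adj)) {
              seen <- c(seen, key)
              rings[[length(rings) + 1L]] <- path
            }
          }
        } else if (!(nb %in% path) && nb > start && length(path) < max_size) {
          stack[[length(stack) + 1L]] <- c(path, nb)
        }
      }
    }
  }
  rings
}

.is_chordless <- function(ring, adj) {
  k <- length(ring)
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b > a + 1L && !(a == 1L && b == k)) {
      if (ring[b] %in% adj[[ring[a]]]) return(FALSE)
    }
  }
  TRUE
}

.ring_is_aromatic <- function(mol, ring) {
  k <- length(ring)
  if (k < 5L || k > 6L) return(FALSE)
  if (!all(mol$atoms$element[ring] %in% c("C", "N", "O", "S"))) return(FALSE)
  ords <- vapply(seq_len(k), function(a) {
    .bond_order(mol, ring[a], ring[if (a == k) 1L else a + 1L])
  }, integer(1L))
  all(ords == 4L) || sum(ords == 2L) >= 2L
}

.aromatic_atoms <- function(mol, rings) {
  arom <- logical(n_atoms(mol))
  for (ring in rings) if (.ring_is_aromatic(mol, ring)) arom[ring] <- TRUE
  arom
}

.amide_nitrogens <- function(mol, adj) {
  out <- integer(0)
  for (a in which(mol$atoms$element == "N")) {
    for (c_idx in adj[[a]][mol$atoms$element[adj[[a]]] == "C"]) {
      o_nb <- adj[[c_idx]][mol$atoms$element[adj[[c_idx]]] == "O"]
      if (any(vapply(o_nb, function(o) .bond_order(mol, c_idx, o), integer(1L)) == 2L)) {
        out <- c(out, a); break
      }
    }
  }
  out
}

.plane_normal <- function(pts) {
  ctr <- sweep(pts, 2L, colMeans(pts))
  sv <- svd(ctr, nu = 0L, nv = 3L)
  unitize(sv$v[, 3L])
}
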