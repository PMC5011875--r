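#' Pharmacophore data model
#'
#' A pharmacophore is a set of typed feature points (position, tolerance
#' radius, optional ring normal, disabled/optional flags) plus exclusion
#' volume spheres, carrying provenance (structure-based or ligand-based),
#' the receptor and pharmacological class it was built for, and a free-text
#' source (PDB code or cluster id). It is the geometric query object of
#' screening. Feature-count statistics never include exclusion spheres.
#'
#' @name pharmacophore-model
NULL

#' Construct a feature-point table
#'
#' @param type character vector in `AR, H, HBA, HBD, PI, NI, MB`.
#' @param xyz n x 3 matrix of positions (A).
#' @param tolerance tolerance radii (A), recycled; default 1.5 A.
#' @param normal optional n x 3 matrix of unit ring normals (AR rows only).
#' @param disabled,optional logical flags, recycled.
#' @return data.frame of feature points.
#' @export
feature_points <- function(type, xyz, tolerance = 1.5, normal = NULL,
                           disabled = FALSE, optional = FALSE) {
  xyz <- as.matrix(xyz)
  n <- length(type)
  stopifnot(all(type %in% FEATURE_TYPES), nrow(xyz) == n, ncol(xyz) == 3L,
            all(is.finite(xyz)), all(tolerance > 0))
  if (is.null(normal)) normal <- matrix(NA_real_, n, 3L)
  data.frame(type = type, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             tolerance = rep_len(tolerance, n),
             nx = normal[, 1L], ny = normal[, 2L], nz = normal[, 3L],
             disabled = rep_len(as.logical(disabled), n),
             optional = rep_len(as.logical(optional), n))
}

#' Construct an exclusion-sphere table
#'
#' @param xyz n x 3 matrix of sphere centers (A).
#' @param radius sphere radii (A), recycled.
#' @param manual logical: placed by hand (`TRUE`) or generated (`FALSE`).
#' @return data.frame of exclusion spheres.
#' @export
exclusion_spheres <- function(xyz, radius = 1.0, manual = FALSE) {
  xyz <- as.matrix(xyz)
  if (nrow(xyz) == 0L) {
    return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                      radius = numeric(), manual = logical()))
  }
  stopifnot(ncol(xyz) == 3L, all(is.finite(xyz)), all(radius > 0))
  data.frame(x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             radius = rep_len(radius, nrow(xyz)),
             manual = rep_len(as.logical(manual), nrow(xyz)))
}

#' Construct a pharmacophore
#'
#' @param id model identifier.
#' @param provenance `"SB"` (structure-based) or `"LB"` (ligand-based).
#' @param receptor_id receptor the model was built for.
#' @param activity_class `"agonist"` or `"antagonist"`.
#' @param features data.frame from [feature_points()]; at least one row.
#' @param exclusions data.frame from [exclusion_spheres()].
#' @param source free text: PDB code or cluster id.
#' @return object of class `pharmacophore`.
#' @export
pharmacophore <- function(id, provenance = c("SB", "LB"), receptor_id,
                          activity_class = c("agonist", "antagonist"),
                          features, exclusions = exclusion_spheres(matrix(numeric(), 0L, 3L)),
                          source = "") {
  provenance <- match.arg(provenance)
  activity_class <- match.arg(activity_class)
  features <- as.data.frame(features)
  stopifnot(nrow(features) >= 1L, all(features$type %in% FEATURE_TYPES),
            all(features$tolerance > 0))
  nrm <- as.matrix(features[, c("nx", "ny", "nz")])
  has_n <- rowSums(is.na(nrm)) == 0L
  if (any(has_n)) {
    stopifnot(all(abs(sqrt(rowSums(nrm[has_n, , drop = FALSE]^2)) - 1) < 1e-6))
  }
  structure(list(id = id, provenance = provenance, receptor_id = receptor_id,
                 activity_class = activity_class, features = features,
                 exclusions = as.data.frame(exclusions), source = source),
            class = "pharmacophore")
}

#' @export
print.pharmacophore <- function(x, ...) {
  en <- enabled_required_features(x)
  cat(sprintf("<pharmacophore %s [%s/%s %s]: %d features (%d enabled required, %d optional), %d exclusion spheres>\n",
              x$id, x$provenance, x$receptor_id, x$activity_class,
              nrow(x$features), nrow(en), sum(x$features$optional),
              nrow(x$exclusions)))
  invisible(x)
}

#' Enabled required features of a pharmacophore
#'
#' Features that are neither disabled nor optional, in their original order.
#' These are the features a hit must map (up to the omitted-features
#' allowance); optional features are handled separately during matching.
#'
#' @param p a [pharmacophore()].
#' @return data.frame of feature points (possibly zero rows).
#' @export
enabled_required_features <- function(p) {
  p$features[!p$features$disabled & !p$features$optional, , drop = FALSE]
}

#' Enabled optional features of a pharmacophore
#' @param p a [pharmacophore()].
#' @return data.frame of feature points.
#' @export
enabled_optional_features <- function(p) {
  p$features[!p$features$disabled & p$features$optional, , drop = FALSE]
}

#' Can a pharmacophore be used as a screening query?
#'
#' A model is screenable only with at least three *independent* enabled
#' required features: pairwise-distinct, non-collinear points, since a rigid
#' alignment is undefined for fewer than three non-collinear anchors.
#' Optional features do not count towards the minimum.
#'
#' @param p a [pharmacophore()].
#' @param tol geometric degeneracy tolerance (A).
#' @return logical.
#' @export
is_screenable <- function(p, tol = 1e-6) {
  en <- enabled_required_features(p)
  if (nrow(en) < 3L) return(FALSE)
  pts <- as.matrix(en[, c("x", "y", "z")])
  if (any(stats::dist(pts) <= tol)) {
    # coincident points do not count as independent anchors; recheck on
    # the distinct positions
    pts <- unique(round(pts, 6L))
    if (nrow(pts) < 3L) return(FALSE)
  }
  !points_collinear(pts, tol)
}

#' Serialize a pharmacophore to JSON
#'
#' Lossless, schema-versioned (`pharmselect/1`) serialization. The schema is
#' documented in `docs/pharmacophore.schema.json` at the repository root.
#'
#' @param p a [pharmacophore()].
#' @return JSON text (single string).
#' @export
pharmacophore_to_json <- function(p) {
  stopifnot(inherits(p, "pharmacophore"))
  obj <- list(schema = "pharmselect/1", id = p$id, provenance = p$provenance,
              receptor_id = p$receptor_id, activity_class = p$activity_class,
              source = p$source, features = p$features,
              exclusions = p$exclusions)
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Deserialize a pharmacophore from JSON
#'
#' @param txt JSON text produced by [pharmacophore_to_json()].
#' @return a [pharmacophore()].
#' @export
pharmacophore_from_json <- function(txt) {
  obj <- jsonlite::fromJSON(txt)
  if (is.null(obj$schema) || obj$schema != "pharmselect/1") {
    stop("unknown or missing schema tag (expected \"pharmselect/1\")")
  }
  for (fld in c("id", "provenance", "receptor_id", "activity_class",
                "features")) {
    if (is.null(obj[[fld]])) stop(sprintf("missing field \"%s\"", fld))
  }
  ft <- as.data.frame(obj$features)
  for (cn in c("type", "x", "y", "z", "tolerance", "disabled", "optional")) {
    if (is.null(ft[[cn]])) stop(sprintf("missing field \"features.%s\"", cn))
  }
  if (!all(ft$type %in% FEATURE_TYPES)) {
    stop(sprintf("unknown feature type \"%s\"",
                 setdiff(ft$type, FEATURE_TYPES)[1L]))
  }
  if (any(!is.finite(ft$tolerance)) || any(ft$tolerance <= 0)) {
    stop("invalid field \"features.tolerance\"")
  }
  for (cn in c("nx", "ny", "nz")) {
    ft[[cn]] <- if (is.null(ft[[cn]])) rep(NA_real_, nrow(ft)) else
      as.numeric(ft[[cn]])
  }
  ex <- if (is.null(obj$exclusions) || NROW(obj$exclusions) == 0L) {
    exclusion_spheres(matrix(numeric(), 0L, 3L))
  } else {
    as.data.frame(obj$exclusions)
  }
  pharmacophore(obj$id, obj$provenance, obj$receptor_id, obj$activity_class,
                ft, ex, source = if (is.null(obj$source)) "" else obj$source)
}
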