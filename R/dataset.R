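#' Ligand records and datasets
#'
#' A ligand record pairs a 3D molecule with its pharmacological class and
#' receptor; a dataset is a receptor's agonist or antagonist ligand set.
#' Records cache perceived feature sets and heavy-atom coordinates per
#' conformer so repeated screening does not re-perceive chemistry.
#'
#' @name dataset
NULL

#' Construct a ligand record
#'
#' @param molecule a [molecule()] with at least one conformer (required
#'   before screening).
#' @param activity_class `"agonist"` or `"antagonist"`.
#' @param receptor_id receptor identifier.
#' @return object of class `ligand_record`.
#' @export
ligand_record <- function(molecule, activity_class = c("agonist", "antagonist"),
                          receptor_id) {
  activity_class <- match.arg(activity_class)
  stopifnot(inherits(molecule, "pharm_mol"))
  structure(list(molecule = molecule, activity_class = activity_class,
                 receptor_id = receptor_id, features = NULL, heavy = NULL),
            class = "ligand_record")
}

#' Cache features and heavy-atom coordinates of a ligand record
#'
#' @param rec a [ligand_record()].
#' @param rules feature-perception rules.
#' @return the record with `features` and `heavy` caches filled.
#' @export
prepare_ligand <- function(rec, rules = feature_rules()) {
  stopifnot(inherits(rec, "ligand_record"))
  if (!is.null(rec$features)) return(rec)
  stopifnot(length(rec$molecule$conformers) >= 1L)
  rec$features <- lapply(seq_along(rec$molecule$conformers), function(ci) {
    perceive_features(rec$molecule, ci, rules)
  })
  rec$heavy <- lapply(seq_along(rec$molecule$conformers), function(ci) {
    conformer_xyz(rec$molecule, ci, heavy_only = TRUE)
  })
  rec
}

#' Construct a dataset (one receptor, one pharmacological class)
#'
#' @param receptor_id receptor identifier.
#' @param activity_class `"agonist"` or `"antagonist"`.
#' @param ligands list of [ligand_record()]s sharing receptor and class.
#' @return object of class `ligand_dataset`.
#' @export
ligand_dataset <- function(receptor_id,
                           activity_class = c("agonist", "antagonist"),
                           ligands) {
  activity_class <- match.arg(activity_class)
  stopifnot(length(ligands) >= 1L,
            all(vapply(ligands, inherits, logical(1L), "ligand_record")),
            all(vapply(ligands, function(l) l$activity_class, character(1L)) ==
                  activity_class),
            all(vapply(ligands, function(l) l$receptor_id, character(1L)) ==
                  receptor_id))
  names(ligands) <- vapply(ligands, function(l) l$molecule$id, character(1L))
  stopifnot(!anyDuplicated(names(ligands)))
  structure(list(receptor_id = receptor_id, activity_class = activity_class,
                 ligands = ligands),
            class = "ligand_dataset")
}

#' @export
print.ligand_dataset <- function(x, ...) {
  cat(sprintf("<dataset %s/%s: %d ligands>\n", x$receptor_id,
              x$activity_class, length(x$ligands)))
  invisible(x)
}

#' Flatten datasets / record lists into one list of ligand records
#' @param ligands a `ligand_dataset`, a `ligand_record`, or a list of either.
#' @return list of `ligand_record`s.
#' @export
gather_ligands <- function(ligands) {
  if (inherits(ligands, "ligand_dataset")) return(unname(ligands$ligands))
  if (inherits(ligands, "ligand_record")) return(list(ligands))
  out <- list()
  for (el in ligands) {
    out <- c(out, gather_ligands(el))
  }
  out
}

#' Molecule ids of a dataset or record list
#' @param ligands as in [gather_ligands()].
#' @return character vector.
#' @export
ligand_ids <- function(ligands) {
  vapply(gather_ligands(ligands), function(r) r$molecule$id, character(1L))
}
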