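#' Selectivity refinement, redundancy removal and ensembles
#'
#' The model optimization protocol: a pharmacophore built for one
#' pharmacological class is screened against its own class (actives) and the
#' opposite class (decoys: agonists for antagonist models and reciprocally).
#'
#' 1. Screening 1 (omitted features = 0): the model is validated only when
#'    it retrieves at least one active and no decoy.
#' 2. Screening 2 (omitted features = 1): identifies non-essential features,
#'    i.e. features whose omission retrieves additional actives but no decoy.
#' 3. Screening 3: each candidate feature is disabled and the model
#'    re-screened at omitted features = 0; the disabled variant is kept only
#'    when it still retrieves only actives.
#'
#' The loop recurses on accepted variants until three enabled features
#' remain or no non-essential feature can be identified. Validated models
#' are then ranked by hit count and pruned greedily: starting from the model
#' with the fewest hits, a model is dismissed whenever its removal leaves
#' the union recall unchanged. Finally the structure-based and ligand-based
#' survivors are gathered into SB, LB and combined SBLB ensembles.
#'
#' Every model emitted here retrieves zero decoys at omitted features = 0,
#' so ensemble false positives are always 0 and specificity is always 1.
#'
#' @name protocol
NULL

.hit_ids <- function(p, ligands, max_omitted = 0L) {
  screen(p, ligands, max_omitted = max_omitted)$hits$molecule_id
}

#' Validate a pharmacophore for class selectivity (screening 1)
#'
#' @param p a screenable [pharmacophore()].
#' @param actives [ligand_dataset()] of the model's own class.
#' @param decoys [ligand_dataset()] of the opposite class.
#' @return `TRUE` iff the model retrieves at least one active and zero
#'   decoys at omitted features = 0. A model with no hits at all is not
#'   validated (it would contribute nothing to an ensemble).
#' @export
validate_pharmacophore <- function(p, actives, decoys) {
  ids <- .hit_ids(p, list(actives, decoys))
  act <- ligand_ids(actives)
  length(intersect(ids, act)) >= 1L &&
    length(setdiff(ids, act)) == 0L
}

#' Identify non-essential features (screening 2)
#'
#' For each enabled required feature, computes the extra hits gained when
#' that feature is the omitted one in omitted-features = 1 matches
#' (equivalently, hits of the model with the feature disabled, screened at
#' omitted features = 0, beyond the baseline hits). Features gaining at
#' least one extra active and no extra decoy are non-essential.
#'
#' @inheritParams validate_pharmacophore
#' @return integer vector of feature row indices into `p$features`, sorted
#'   by (extra actives descending, feature index ascending).
#' @export
find_nonessential_features <- function(p, actives, decoys) {
  both <- list(actives, decoys)
  act <- ligand_ids(actives)
  base <- .hit_ids(p, both)
  req_rows <- which(!p$features$disabled & !p$features$optional)
  gains <- integer(0)
  for (f in req_rows) {
    v <- p
    v$features$disabled[f] <- TRUE
    if (!is_screenable(v)) next
    ids <- .hit_ids(v, both)
    extra <- setdiff(ids, base)
    extra_act <- length(intersect(extra, act))
    extra_dec <- length(setdiff(extra, act))
    if (extra_act >= 1L && extra_dec == 0L) gains[as.character(f)] <- extra_act
  }
  if (!length(gains)) return(integer(0))
  idx <- as.integer(names(gains))
  idx[order(-gains, idx)]
}

#' Iterative selectivity refinement (the three-screening loop)
#'
#' Runs screenings 1-3 breadth-first: validates the input model, repeatedly
#' disables non-essential features, validates each disabled variant, and
#' recurses on the accepted ones until three enabled features remain or no
#' non-essential feature exists. Variants are deduplicated by their
#' enabled-feature set.
#'
#' @inheritParams validate_pharmacophore
#' @return list of validated pharmacophores (the input, when validated,
#'   plus accepted variants); empty when the input does not validate.
#' @export
refine <- function(p, actives, decoys) {
  if (!is_screenable(p) || !validate_pharmacophore(p, actives, decoys)) {
    return(list())
  }
  act <- ligand_ids(actives)
  key_of <- function(q) paste(which(!q$features$disabled), collapse = ",")
  seen <- key_of(p)
  out <- list(p)
  queue <- list(p)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    n_enabled <- sum(!cur$features$disabled & !cur$features$optional)
    if (n_enabled <= 3L) next   # stop: three features retained
    for (f in find_nonessential_features(cur, actives, decoys)) {
      v <- cur
      v$features$disabled[f] <- TRUE
      v$id <- sprintf("%s-d%d", cur$id, f)
      key <- key_of(v)
      if (key %in% seen || !is_screenable(v)) next
      seen <- c(seen, key)
      # screening 3: the disabled variant must still retrieve only actives
      ids <- .hit_ids(v, list(actives, decoys))
      if (length(intersect(ids, act)) >= 1L &&
          length(setdiff(ids, act)) == 0L) {
        out[[length(out) + 1L]] <- v
        queue[[length(queue) + 1L]] <- v
      }
    }
  }
  out
}

#' Greedy removal of redundant pharmacophores
#'
#' Candidates are ranked by the number of hits they retrieve on the actives
#' (ascending, ties broken by id). Walking that order, each candidate is
#' removed whenever the union recall of the remaining models is unchanged;
#' the surviving set has the same union recall as the input.
#'
#' @param candidates list of validated [pharmacophore()]s.
#' @param actives the generating [ligand_dataset()].
#' @return pruned list of pharmacophores.
#' @export
remove_redundant <- function(candidates, actives) {
  if (length(candidates) <= 1L) return(candidates)
  hit_sets <- lapply(candidates, .hit_ids, ligands = actives)
  ids <- vapply(candidates, `[[`, character(1L), "id")
  ord <- order(lengths(hit_sets), ids)
  alive <- rep(TRUE, length(candidates))
  total <- length(unique(unlist(hit_sets)))
  for (k in ord) {
    rest <- unique(unlist(hit_sets[alive & seq_along(alive) != k]))
    if (length(rest) == total) alive[k] <- FALSE
  }
  candidates[alive]
}

#' Pharmacophore ensemble container
#'
#' @param receptor_id,activity_class annotation shared by the members.
#' @param members list of [pharmacophore()]s (possibly empty).
#' @param label `"SB"`, `"LB"` or `"SBLB"`.
#' @return object of class `pharm_ensemble`.
#' @export
pharmacophore_ensemble <- function(receptor_id, activity_class, members,
                                   label = c("SB", "LB", "SBLB")) {
  label <- match.arg(label)
  structure(list(receptor_id = receptor_id, activity_class = activity_class,
                 members = members, label = label,
                 id = sprintf("%s_%s_%s", receptor_id, activity_class, label)),
            class = "pharm_ensemble")
}

#' @export
print.pharm_ensemble <- function(x, ...) {
  cat(sprintf("<ensemble %s: %d members>\n", x$id, length(x$members)))
  invisible(x)
}

#' Gather validated models into SB, LB and combined ensembles
#'
#' Each ensemble is pruned with [remove_redundant()]; the combined SBLB
#' ensemble unites both inputs, so its recall on the generating dataset is
#' at least the larger of the SB and LB recalls.
#'
#' @param sb,lb lists of validated pharmacophores (either may be empty).
#' @param actives the generating [ligand_dataset()].
#' @param receptor_id,activity_class ensemble annotation.
#' @return named list of three [pharmacophore_ensemble()]s: `SB`, `LB`,
#'   `SBLB`. Both inputs empty yields empty ensembles with a warning
#'   (no selective model could be produced for this dataset).
#' @export
build_ensembles <- function(sb, lb, actives, receptor_id, activity_class) {
  if (!length(sb) && !length(lb)) {
    warning(sprintf("no validated pharmacophore for %s/%s: empty ensemble",
                    receptor_id, activity_class), call. = FALSE)
  }
  list(SB = pharmacophore_ensemble(receptor_id, activity_class,
                                   remove_redundant(sb, actives), "SB"),
       LB = pharmacophore_ensemble(receptor_id, activity_class,
                                   remove_redundant(lb, actives), "LB"),
       SBLB = pharmacophore_ensemble(receptor_id, activity_class,
                                     remove_redundant(c(sb, lb), actives),
                                     "SBLB"))
}

#' Ensemble recall on a dataset
#' @param ens a [pharmacophore_ensemble()].
#' @param ds a [ligand_dataset()].
#' @return fraction of the dataset retrieved (0 for an empty ensemble).
#' @export
ensemble_recall <- function(ens, ds) {
  if (!length(ens$members)) return(0)
  nrow(screen_ensemble(ens$members, ds)$hits) / length(ds$ligands)
}

#' Cross-screening selectivity matrix
#'
#' Screens every ensemble against every dataset and reports the recall
#' fraction; the diagonal (own receptor and class) equals each ensemble's
#' own-dataset recall.
#'
#' @param ensembles list of [pharmacophore_ensemble()]s.
#' @param datasets list of [ligand_dataset()]s.
#' @return numeric matrix, rows = ensemble ids, cols = dataset ids
#'   (`receptor_activityclass`), values in `[0, 1]`.
#' @export
cross_screen <- function(ensembles, datasets) {
  ds_ids <- vapply(datasets, function(d) {
    sprintf("%s_%s", d$receptor_id, d$activity_class)
  }, character(1L))
  m <- matrix(0, length(ensembles), length(datasets),
              dimnames = list(vapply(ensembles, `[[`, character(1L), "id"),
                              ds_ids))
  for (i in seq_along(ensembles)) {
    for (j in seq_along(datasets)) {
      m[i, j] <- ensemble_recall(ensembles[[i]], datasets[[j]])
    }
  }
  m
}
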