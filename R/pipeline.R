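#' End-to-end selective-pharmacophore pipeline
#'
#' Convenience drivers running the full study design on one receptor and
#' class of a benchmark: structure-based derivation from the class's
#' pseudo-complex, ligand-based generation (clustering, alignment, merged
#' features, exclusion shell), the three-screening refinement loop with the
#' opposite class as decoys, redundancy removal and ensemble assembly.
#'
#' @name pipeline
NULL

#' Pre-perceive features of every ligand of a dataset
#' @param ds a [ligand_dataset()].
#' @param rules feature-perception rules.
#' @return the dataset with cached ligand records.
#' @export
prepare_dataset <- function(ds, rules = feature_rules()) {
  ds$ligands <- lapply(ds$ligands, prepare_ligand, rules = rules)
  ds
}

#' Build and refine all models for one receptor and class
#'
#' @param bench a [generate_benchmark()] result.
#' @param receptor_id receptor to process.
#' @param activity_class class to process (`"agonist"` or `"antagonist"`);
#'   the opposite class is used as the decoy set throughout.
#' @param cluster_threshold starting ligand-cluster distance (default 0.4,
#'   auto-lowered to 0.3/0.2 for balance).
#' @param manual_exclusions optional manual exclusion spheres (data.frame
#'   `x`, `y`, `z`[, `radius`]) added to every ligand-based model.
#' @param verbose print progress messages?
#' @return list with `ensembles` (`SB`, `LB`, `SBLB`
#'   [pharmacophore_ensemble()]s), `sb`, `lb` (validated model lists),
#'   `actives`, `decoys` (prepared datasets) and `clusters`.
#' @export
run_class_pipeline <- function(bench, receptor_id,
                               activity_class = c("agonist", "antagonist"),
                               cluster_threshold = 0.4,
                               manual_exclusions = NULL, verbose = FALSE) {
  activity_class <- match.arg(activity_class)
  say <- function(...) if (verbose) message(sprintf(...))
  r <- bench$receptors[[receptor_id]]
  stopifnot(!is.null(r))
  opposite <- setdiff(c("agonist", "antagonist"), activity_class)
  actives <- prepare_dataset(r$datasets[[activity_class]])
  decoys <- prepare_dataset(r$datasets[[opposite]])

  ## structure-based branch
  sb <- list()
  cx <- r$complexes[[activity_class]]
  if (!is.null(cx)) {
    p <- tryCatch(build_sb_pharmacophore(cx, receptor_id = receptor_id),
                  error = function(e) { say("SB build failed: %s",
                                            conditionMessage(e)); NULL })
    if (!is.null(p) && is_screenable(p)) {
      sb <- refine(p, actives, decoys)
      say("SB: %d validated model(s) from %s", length(sb), cx$pdb_id)
    }
  }

  ## ligand-based branch
  lb <- list()
  clusters <- cluster_ligands(actives, cluster_threshold,
                              auto_threshold = TRUE)
  for (cl in clusters) {
    if (length(cl$member_ids) < 2L) next
    members <- lapply(cl$member_ids, function(id) {
      actives$ligands[[id]]$features[[1L]]
    })
    names(members) <- cl$member_ids
    aln <- withCallingHandlers(
      tryCatch(align_cluster(members), error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(aln) || length(aln$transforms) < 2L) next
    p <- tryCatch(
      build_lb_pharmacophore(members, aln,
                             id = sprintf("LB_%s_%s_%s", receptor_id,
                                          activity_class, cl$id),
                             receptor_id = receptor_id,
                             activity_class = activity_class,
                             source = cl$id),
      error = function(e) { say("LB build failed for %s: %s", cl$id,
                                conditionMessage(e)); NULL })
    if (is.null(p) || !is_screenable(p)) next
    member_xyz <- lapply(names(aln$transforms), function(id) {
      tr <- aln$transforms[[id]]
      apply_transform(actives$ligands[[id]]$heavy[[1L]], tr$rotation,
                      tr$translation)
    })
    p <- add_exclusion_shell(p, member_xyz, manual = manual_exclusions)
    lb <- c(lb, refine(p, actives, decoys))
  }
  say("LB: %d validated model(s) from %d cluster(s)", length(lb),
      length(clusters))

  ens <- suppressWarnings(
    build_ensembles(sb, lb, actives, receptor_id, activity_class))
  list(ensembles = ens, sb = sb, lb = lb, actives = actives, decoys = decoys,
       clusters = clusters)
}

#' Run the pipeline on every receptor and class of a benchmark
#'
#' @param bench a [generate_benchmark()] result.
#' @param verbose print progress messages?
#' @return named list (`<receptor>_<class>`) of [run_class_pipeline()]
#'   results.
#' @export
run_benchmark_pipeline <- function(bench, verbose = FALSE) {
  out <- list()
  for (rid in names(bench$receptors)) {
    for (cls in c("agonist", "antagonist")) {
      key <- sprintf("%s_%s", rid, cls)
      if (verbose) message("== ", key)
      out[[key]] <- run_class_pipeline(bench, rid, cls, verbose = verbose)
    }
  }
  out
}

#' Performance table of pipeline results
#'
#' One row per receptor, class and approach, with recall, specificity and
#' MCC of the corresponding ensemble measured on its own receptor's actives
#' with the opposite class as decoys.
#'
#' @param results a [run_benchmark_pipeline()] result.
#' @return data.frame with columns dataset, approach, R, Sp, MCC (`"ND"`
#'   when not determined).
#' @export
performance_table <- function(results) {
  rows <- list()
  for (key in names(results)) {
    res <- results[[key]]
    act_ids <- ligand_ids(res$actives)
    dec_ids <- ligand_ids(res$decoys)
    for (lab in c("SB", "LB", "SBLB")) {
      ens <- res$ensembles[[lab]]
      hits <- if (length(ens$members)) {
        screen_ensemble(ens$members, list(res$actives, res$decoys))$hits$molecule_id
      } else character(0)
      m <- compute_metrics(confusion(hits, act_ids, dec_ids))
      rows[[length(rows) + 1L]] <- metrics_report_row(key, lab, m)
    }
  }
  do.call(rbind, rows)
}
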