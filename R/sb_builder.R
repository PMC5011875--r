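#' Structure-based pharmacophore derivation
#'
#' Perceives ligand-receptor interactions in a bound complex and turns the
#' interacting ligand features into a pharmacophore, completed by an
#' exclusion-volume shell representing the shape of the binding site.
#'
#' Interaction rules (geometric windows, configurable via
#' [interaction_rules()]):
#' * hydrogen bond: donor-acceptor heavy-atom distance 2.5-3.8 A, and
#'   D-H...A angle >= 120 degrees when an explicit hydrogen is present on the
#'   ligand donor; receptor nitrogens act as donors, receptor oxygens as
#'   acceptors.
#' * hydrophobic: ligand H centroid within 4.5 A of >= 1 receptor apolar
#'   carbon.
#' * aromatic: ring centroid within 5.5 A of a receptor carbon.
#' * ionic: ligand PI/NI feature within 5.5 A of an oppositely charged
#'   receptor atom.
#' * metal binding: ligand MB feature within 2.8 A of a receptor metal ion.
#'
#' @name sb_builder
NULL

#' Interaction-rule parameters
#' @return named list of distance/angle windows (Angstrom, degrees).
#' @export
interaction_rules <- function() {
  list(hbond_min = 2.5, hbond_max = 3.8, hbond_angle_min = 120,
       hydrophobic_max = 4.5, aromatic_max = 5.5, ionic_max = 5.5,
       metal_max = 2.8,
       shell_dist = 6.0, shell_radius = 1.2)
}

METAL_ELEMENTS <- c("Zn", "Mg", "Ca", "Fe", "Mn", "Ni", "Cu", "Co", "K", "Na")

#' Detect ligand-receptor interactions in a complex
#'
#' @param cx a [complex_structure()].
#' @param rules parameters from [interaction_rules()].
#' @param feat_rules feature-perception rules for the ligand.
#' @return data.frame with one row per interaction: `kind`, ligand feature
#'   position (`x`, `y`, `z`, `nx`, `ny`, `nz`), `receptor_atom` (row index
#'   into `cx$receptor`), `distance` and `angle` (degrees, H-bonds only,
#'   otherwise `NA`). Zero rows when nothing interacts.
#' @export
detect_interactions <- function(cx, rules = interaction_rules(),
                                feat_rules = feature_rules()) {
  stopifnot(inherits(cx, "pharm_complex"))
  fs <- perceive_features(cx$ligand, 1L, feat_rules)
  rec <- cx$receptor
  rxyz <- as.matrix(rec[, c("x", "y", "z")])
  lig_xyz <- conformer_xyz(cx$ligand, 1L)
  out <- list()
  add <- function(kind, frow, ratom, distance, angle = NA_real_) {
    out[[length(out) + 1L]] <<- cbind(
      data.frame(kind = kind), fs$features[frow, , drop = FALSE],
      data.frame(receptor_atom = ratom, distance = distance, angle = angle))
  }
  if (nrow(fs$features) == 0L || nrow(rec) == 0L) {
    return(.empty_interactions())
  }
  fxyz <- feature_xyz(fs)
  d <- cross_dist(fxyz, rxyz)
  rec_metal <- rec$element %in% METAL_ELEMENTS
  rec_apolar_c <- rec$element == "C" & rec$charge == 0L
  for (k in seq_len(nrow(fs$features))) {
    typ <- fs$features$type[k]
    pos <- fxyz[k, ]
    if (typ == "HBD") {
      cand <- which(rec$element == "O" &
                      d[k, ] >= rules$hbond_min & d[k, ] <= rules$hbond_max)
      for (a in cand) {
        ang <- .donor_angle(cx$ligand, lig_xyz, pos, rxyz[a, ])
        if (is.na(ang) || ang >= rules$hbond_angle_min) {
          add("HBD", k, a, d[k, a], ang)
        }
      }
    } else if (typ == "HBA") {
      cand <- which(rec$element == "N" &
                      d[k, ] >= rules$hbond_min & d[k, ] <= rules$hbond_max)
      for (a in cand) add("HBA", k, a, d[k, a])
    } else if (typ == "H") {
      cand <- which(rec_apolar_c & d[k, ] <= rules$hydrophobic_max)
      if (length(cand)) {
        a <- cand[which.min(d[k, cand])]
        add("H", k, a, d[k, a])
      }
    } else if (typ == "AR") {
      cand <- which(rec$element == "C" & d[k, ] <= rules$aromatic_max)
      if (length(cand)) {
        a <- cand[which.min(d[k, cand])]
        add("AR", k, a, d[k, a])
      }
    } else if (typ %in% c("PI", "NI")) {
      want <- if (typ == "PI") rec$charge < 0L else rec$charge > 0L
      cand <- which(want & d[k, ] <= rules$ionic_max)
      if (length(cand)) {
        a <- cand[which.min(d[k, cand])]
        add(typ, k, a, d[k, a])
      }
    } else if (typ == "MB") {
      cand <- which(rec_metal & d[k, ] <= rules$metal_max)
      if (length(cand)) {
        a <- cand[which.min(d[k, cand])]
        add("MB", k, a, d[k, a])
      }
    }
  }
  if (!length(out)) return(.empty_interactions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.empty_interactions <- function() {
  data.frame(kind = character(), type = character(), x = numeric(),
             y = numeric(), z = numeric(), nx = numeric(), ny = numeric(),
             nz = numeric(), receptor_atom = integer(), distance = numeric(),
             angle = numeric())
}

# D-H...A angle at the hydrogen, using the explicit H on the donor closest to
# the acceptor; NA when the donor carries no explicit hydrogen
.donor_angle <- function(mol, lig_xyz, donor_pos, acceptor_pos) {
  donor_idx <- which.min(rowSums(sweep(lig_xyz, 2L, donor_pos)^2))
  adj <- mol_adjacency(mol)[[donor_idx]]
  h_idx <- adj[mol$atoms$element[adj] == "H"]
  if (!length(h_idx)) return(NA_real_)
  hb <- h_idx[which.min(cross_dist(lig_xyz[h_idx, , drop = FALSE],
                                   matrix(acceptor_pos, 1L)))]
  angle_deg(donor_pos, lig_xyz[hb, ], acceptor_pos)
}

#' Build a structure-based pharmacophore from a complex
#'
#' One feature point per detected interaction, deduplicated within 1 A per
#' type; exclusion spheres on every receptor heavy atom within the shell
#' distance of the ligand, minus spheres that would clash with the source
#' pose itself (the generating pose must pass its own screen).
#'
#' @param cx a [complex_structure()].
#' @param id model id (defaults to the PDB id).
#' @param receptor_id receptor identifier (defaults to the PDB id up to the
#'   first underscore).
#' @param tolerance feature tolerance radius (A).
#' @param rules interaction-rule parameters.
#' @param feat_rules feature-perception rules.
#' @return a [pharmacophore()] with provenance `"SB"`. When the bound class
#'   is `"other"` the model is built with `activity_class = "agonist"` and
#'   flagged non-assignable via attribute `assignable = FALSE`.
#' @export
build_sb_pharmacophore <- function(cx, id = NULL, receptor_id = NULL,
                                   tolerance = 1.5,
                                   rules = interaction_rules(),
                                   feat_rules = feature_rules()) {
  inter <- detect_interactions(cx, rules, feat_rules)
  if (nrow(inter) == 0L) {
    stop(sprintf("no interaction features in complex %s", cx$pdb_id))
  }
  # deduplicate per type within 1 A
  keep <- rep(TRUE, nrow(inter))
  for (i in seq_len(nrow(inter))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(inter))) {
      if (j <= i || !keep[j]) next
      if (inter$kind[i] == inter$kind[j] &&
          sqrt(sum((unlist(inter[i, c("x", "y", "z")]) -
                      unlist(inter[j, c("x", "y", "z")]))^2)) < 1.0) {
        keep[j] <- FALSE
      }
    }
  }
  inter <- inter[keep, , drop = FALSE]
  feats <- feature_points(inter$kind,
                          as.matrix(inter[, c("x", "y", "z")]),
                          tolerance = tolerance,
                          normal = as.matrix(inter[, c("nx", "ny", "nz")]))
  # exclusion shell: receptor heavy atoms near the ligand
  lig_heavy <- conformer_xyz(cx$ligand, 1L, heavy_only = TRUE)
  rxyz <- as.matrix(cx$receptor[, c("x", "y", "z")])
  heavy_rec <- cx$receptor$element != "H"
  near <- heavy_rec &
    apply(cross_dist(rxyz, lig_heavy), 1L, min) <= rules$shell_dist
  centers <- rxyz[near, , drop = FALSE]
  if (nrow(centers)) {
    # self-clash check: drop spheres the source pose would violate
    dmin <- apply(cross_dist(centers, lig_heavy), 1L, min)
    centers <- centers[dmin >= rules$shell_radius, , drop = FALSE]
  }
  excl <- exclusion_spheres(centers, radius = rules$shell_radius)
  cls <- if (cx$bound_class == "other") "agonist" else cx$bound_class
  p <- pharmacophore(id = if (is.null(id)) paste0("SB_", cx$pdb_id) else id,
                     provenance = "SB",
                     receptor_id = if (is.null(receptor_id))
                       sub("_.*$", "", cx$pdb_id) else receptor_id,
                     activity_class = cls,
                     features = feats, exclusions = excl,
                     source = cx$pdb_id)
  attr(p, "assignable") <- cx$bound_class != "other"
  p
}
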