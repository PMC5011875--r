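#' Molecule and atom containers
#'
#' Light containers for small molecules and receptor atoms. A molecule holds
#' an atom table, a bond table and zero or more conformers (coordinate sets).
#' Atom indices are 1-based internally; file writers emit the 1-based indices
#' required by the formats.
#'
#' @name molecule
NULL

STANDARD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L, B = 3L, H = 1L)

#' Construct a molecule
#'
#' @param id molecule identifier.
#' @param atoms data.frame with columns `element` (character) and optionally
#'   `charge` (integer formal charge, default 0).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3, or 4 for aromatic); may have zero rows.
#' @param conformers list of n_atoms x 3 numeric matrices (Angstrom).
#' @return object of class `pharm_mol`.
#' @export
molecule <- function(id, atoms, bonds = NULL, conformers = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  atoms <- as.data.frame(atoms)
  stopifnot("element" %in% names(atoms), all(nzchar(atoms$element)))
  if (is.null(atoms$charge)) atoms$charge <- 0L
  atoms$charge <- as.integer(atoms$charge)
  n <- nrow(atoms)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)[, c("i", "j", "order")]
    stopifnot(all(bonds$i >= 1L), all(bonds$j >= 1L),
              all(bonds$i <= n), all(bonds$j <= n), all(bonds$i != bonds$j))
  }
  conformers <- lapply(conformers, function(xyz) {
    xyz <- as.matrix(xyz)
    stopifnot(nrow(xyz) == n, ncol(xyz) == 3L, all(is.finite(xyz)))
    dimnames(xyz) <- NULL
    xyz
  })
  structure(list(id = id, atoms = atoms, bonds = bonds,
                 conformers = conformers),
            class = "pharm_mol")
}

#' @export
print.pharm_mol <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms (%d heavy), %d bonds, %d conformer(s)>\n",
              x$id, n_atoms(x), sum(is_heavy(x)), nrow(x$bonds),
              length(x$conformers)))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `pharm_mol`.
#' @return integer.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Heavy-atom indicator
#' @param mol a `pharm_mol`.
#' @return logical vector over atoms (`TRUE` unless hydrogen).
#' @export
is_heavy <- function(mol) mol$atoms$element != "H"

#' Coordinates of one conformer
#' @param mol a `pharm_mol`.
#' @param conformer_index 1-based conformer index.
#' @param heavy_only drop hydrogens?
#' @return n x 3 matrix.
#' @export
conformer_xyz <- function(mol, conformer_index = 1L, heavy_only = FALSE) {
  stopifnot(conformer_index >= 1L, conformer_index <= length(mol$conformers))
  xyz <- mol$conformers[[conformer_index]]
  if (heavy_only) xyz <- xyz[is_heavy(mol), , drop = FALSE]
  xyz
}

# adjacency list over all atoms (list of integer vectors)
mol_adjacency <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# implicit hydrogen count per atom from standard valences; never negative
implicit_h <- function(mol) {
  n <- n_atoms(mol)
  bsum <- numeric(n)
  for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    o <- if (o == 4L) 1.5 else o   # aromatic bonds count 1.5
    bsum[mol$bonds$i[k]] <- bsum[mol$bonds$i[k]] + o
    bsum[mol$bonds$j[k]] <- bsum[mol$bonds$j[k]] + o
  }
  val <- STANDARD_VALENCE[mol$atoms$element]
  val[is.na(val)] <- 0L
  # a positive charge on N adds a bonding site, a negative charge on O/S removes one
  adj <- ifelse(mol$atoms$element %in% c("N", "P"), pmax(mol$atoms$charge, 0),
                ifelse(mol$atoms$element %in% c("O", "S"), pmin(mol$atoms$charge, 0), 0))
  pmax(0L, as.integer(round(val + adj - bsum)))
}

# total attached hydrogens (explicit atoms + implicit)
total_h <- function(mol) {
  adj <- mol_adjacency(mol)
  expl <- vapply(seq_len(n_atoms(mol)), function(i) {
    sum(mol$atoms$element[adj[[i]]] == "H")
  }, integer(1L))
  ih <- implicit_h(mol)
  ih[expl > 0L] <- 0L  # explicit hydrogens present: trust them
  expl + ih
}

#' Receptor atom table constructor
#'
#' @param element character vector of element symbols.
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param charge integer formal charges (default 0).
#' @param residue_tag optional residue name/number labels.
#' @return data.frame with columns element, x, y, z, charge, residue_tag.
#' @export
receptor_atoms <- function(element, xyz, charge = 0L, residue_tag = NA_character_) {
  xyz <- as.matrix(xyz)
  stopifnot(length(element) == nrow(xyz), ncol(xyz) == 3L, all(is.finite(xyz)))
  data.frame(element = element, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             charge = as.integer(charge),
             residue_tag = as.character(residue_tag))
}

#' Receptor-ligand complex
#'
#' @param pdb_id structure identifier.
#' @param receptor data.frame from [receptor_atoms()].
#' @param ligand a `pharm_mol` with exactly one conformer.
#' @param bound_class `"agonist"`, `"antagonist"` or `"other"`.
#' @return object of class `pharm_complex`.
#' @export
complex_structure <- function(pdb_id, receptor, ligand,
                              bound_class = c("agonist", "antagonist", "other")) {
  bound_class <- match.arg(bound_class)
  stopifnot(inherits(ligand, "pharm_mol"), length(ligand$conformers) == 1L)
  structure(list(pdb_id = pdb_id, receptor = receptor, ligand = ligand,
                 bound_class = bound_class),
            class = "pharm_complex")
}

#' @export
print.pharm_complex <- function(x, ...) {
  cat(sprintf("<complex %s: %d receptor atoms, ligand %s (%d atoms), bound: %s>\n",
              x$pdb_id, nrow(x$receptor), x$ligand$id, n_atoms(x$ligand),
              x$bound_class))
  invisible(x)
}
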