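#' Molecular file input/output and conformer generation
#'
#' SDF (V2000) reading goes through ChemmineR; formal charges are recovered
#' from the raw `M  CHG` lines, which ChemmineR does not apply. SDF output is
#' written directly so that charges survive a round trip. PDB complexes are
#' read and written through bio3d. SMILES input and initial 3D embedding use
#' Open Babel through ChemmineOB.
#'
#' @name mol_io
NULL

# parse "M  CHG" lines of one raw SDF record -> named integer vector (atom -> charge)
.sdf_charges <- function(lines) {
  out <- integer(0)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    tok <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
    n <- tok[1L]
    for (k in seq_len(n)) {
      out[as.character(tok[2L * k])] <- tok[2L * k + 1L]
    }
  }
  out
}

#' Read molecules from an SDF file
#'
#' Reads a multi-record V2000 SDF. Unparseable records are skipped with a
#' warning; 3D coordinates become conformer 1; the record title becomes the
#' molecule id (falling back to `mol_<k>` when blank).
#'
#' @param path SDF file path.
#' @return list of [molecule()] objects.
#' @export
read_sdf <- function(path) {
  stopifnot(file.exists(path))
  txt <- readLines(path, warn = FALSE)
  if (length(trimws(txt)) == 0L || all(!nzchar(trimws(txt)))) return(list())
  # split into records on $$$$
  ends <- grep("^\\${4}", txt)
  if (length(ends) == 0L) ends <- length(txt)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  mols <- list()
  for (k in seq_along(starts)) {
    rec <- txt[starts[k]:ends[k]]
    if (all(!nzchar(trimws(rec)))) next
    m <- tryCatch(.parse_sdf_record(rec, fallback_id = sprintf("mol_%d", k)),
                  error = function(e) {
                    warning(sprintf("skipping unparseable SDF record %d: %s",
                                    k, conditionMessage(e)), call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) mols[[length(mols) + 1L]] <- m
  }
  mols
}

.parse_sdf_record <- function(rec, fallback_id = "mol") {
  # delegate the connection-table parse to ChemmineR, then graft charges back on
  rec <- rec[!grepl("^\\${4}", rec)]
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c(rec, "$$$$"), tmp)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp, skipErrors = FALSE))
  if (length(sdfset) != 1L) stop("expected one record")
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  if (nrow(ab) == 0L) stop("empty atom block")
  elem <- sub("_.*$", "", rownames(ab))
  xyz <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  charge <- integer(nrow(ab))
  chg <- .sdf_charges(rec)
  if (length(chg)) charge[as.integer(names(chg))] <- unname(chg)
  bonds <- if (NROW(bb)) {
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = as.integer(bb[, 3L]))
  } else NULL
  id <- trimws(rec[1L])
  if (!nzchar(id)) id <- fallback_id
  molecule(id, data.frame(element = elem, charge = charge), bonds,
           conformers = list(xyz))
}

#' Write molecules to an SDF file (V2000)
#'
#' Writes conformer `conformer_index` of each molecule as one record,
#' including `M  CHG` lines for non-zero formal charges so that ionizable
#' groups survive a round trip.
#'
#' @param mols list of [molecule()] objects (or a single one).
#' @param path output file path.
#' @param conformer_index conformer written per molecule (default 1).
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path, conformer_index = 1L) {
  if (inherits(mols, "pharm_mol")) mols <- list(mols)
  out <- character(0)
  for (mol in mols) {
    stopifnot(inherits(mol, "pharm_mol"))
    xyz <- if (length(mol$conformers)) conformer_xyz(mol, conformer_index)
           else matrix(0, n_atoms(mol), 3L)
    na <- n_atoms(mol); nb <- nrow(mol$bonds)
    rec <- c(mol$id, "  pharmselect", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    rec <- c(rec, vapply(seq_len(na), function(i) {
      sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
              xyz[i, 1L], xyz[i, 2L], xyz[i, 3L], mol$atoms$element[i])
    }, character(1L)))
    if (nb) rec <- c(rec, vapply(seq_len(nb), function(k) {
      sprintf("%3d%3d%3d  0  0  0  0", mol$bonds$i[k], mol$bonds$j[k],
              mol$bonds$order[k])
    }, character(1L)))
    chg_idx <- which(mol$atoms$charge != 0L)
    while (length(chg_idx)) {
      take <- utils::head(chg_idx, 8L)
      chg_idx <- chg_idx[-seq_along(take)]
      rec <- c(rec, paste0("M  CHG", sprintf("%3d", length(take)),
                           paste0(sprintf("%4d%4d", take,
                                          mol$atoms$charge[take]),
                                  collapse = "")))
    }
    out <- c(out, rec, "M  END", "$$$$")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read molecules from a SMILES file
#'
#' One molecule per line: `SMILES [id]`. Molecules come back with zero
#' conformers; call [generate_conformers()] before feature perception.
#' Invalid SMILES are skipped with a warning. Requires ChemmineOB.
#'
#' @param path SMILES file path.
#' @return list of [molecule()] objects.
#' @export
read_smiles <- function(path) {
  stopifnot(file.exists(path))
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("read_smiles requires the ChemmineOB package")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  mols <- list()
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1L]]
    smi <- tok[1L]
    id <- if (length(tok) > 1L) tok[2L] else sprintf("smi_%d", k)
    m <- tryCatch(.smiles_to_mol(smi, id),
                  error = function(e) {
                    warning(sprintf("skipping invalid SMILES on line %d: %s",
                                    k, smi), call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) mols[[length(mols) + 1L]] <- m
  }
  mols
}

.smiles_to_mol <- function(smi, id) {
  sdf_txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, "\n"))
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_txt, tmp)
  mols <- read_sdf(tmp)
  if (length(mols) != 1L || n_atoms(mols[[1L]]) == 0L) stop("conversion failed")
  m <- mols[[1L]]
  m$id <- id
  m$conformers <- list()   # 2D placeholder coordinates are not conformers
  m
}

# run a block with a private RNG seed, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  force(code)
}

#' Generate 3D conformers for a molecule
#'
#' The first conformer comes from a deterministic distance-geometry build:
#' standard bond lengths define a shortest-path distance matrix, classical
#' multidimensional scaling embeds it in 3D, and a short gradient refinement
#' enforces bond lengths and relieves nonbonded clashes. Additional
#' conformers are produced by seeded random torsion driving around acyclic
#' rotatable bonds with a steric clash filter. Deterministic for a given
#' seed. Molecules that already carry conformers keep conformer 1 as the
#' base geometry.
#'
#' @param mol a [molecule()].
#' @param n_max maximum number of conformers to return (default 25).
#' @param seed RNG seed for torsion sampling (default 42).
#' @return the molecule with 1..n_max conformers.
#' @export
generate_conformers <- function(mol, n_max = 25L, seed = 42L) {
  stopifnot(inherits(mol, "pharm_mol"), n_max >= 1L)
  if (length(mol$conformers) == 0L) {
    mol$conformers <- list(.embed_3d(mol))
  }
  base <- mol$conformers[[1L]]
  rot <- .rotatable_bonds(mol)
  confs <- list(base)
  if (nrow(rot) > 0L && n_max > 1L) {
    with_seed(seed, {
      tries <- 0L
      while (length(confs) < n_max && tries < 20L * n_max) {
        tries <- tries + 1L
        xyz <- base
        for (k in seq_len(nrow(rot))) {
          ang <- sample(c(-120, -60, 60, 120, 180), 1L) * pi / 180
          xyz <- .rotate_about_bond(xyz, rot$i[k], rot$j[k], rot$side[[k]], ang)
        }
        if (.no_clash(mol, xyz)) confs[[length(confs) + 1L]] <- xyz
      }
    })
  }
  mol$conformers <- confs
  mol
}

# deterministic distance-geometry embedding: shortest-path bond-length
# distances -> classical MDS -> restraint refinement
.embed_3d <- function(mol) {
  n <- n_atoms(mol)
  if (n == 0L) stop(sprintf("3D embedding failed for molecule %s", mol$id))
  if (n == 1L) return(matrix(0, 1L, 3L))
  r <- COVALENT_RADIUS[mol$atoms$element]
  r[is.na(r)] <- 0.77
  blen <- function(i, j) r[i] + r[j]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds)) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
    igraph::E(g)$weight <- blen(mol$bonds$i, mol$bonds$j)
  }
  d <- igraph::distances(g)
  if (any(is.infinite(d))) {
    # disconnected fragments: separate them along x
    comp <- igraph::components(g)$membership
    off <- (comp - 1L) * (2 * max(d[is.finite(d)], 1) + 5)
    d[is.infinite(d)] <- 0
    d <- d + abs(outer(off, off, "-"))
  }
  # classical MDS into 3D (deterministic up to sign; fix signs explicitly)
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (d^2) %*% j
  eg <- eigen(b, symmetric = TRUE)
  lam <- pmax(eg$values[1:3], 0)
  xyz <- eg$vectors[, 1:3, drop = FALSE] %*% diag(sqrt(lam), 3L)
  for (k in 1:3) {
    nz <- which(abs(xyz[, k]) > 1e-9)
    if (length(nz) && xyz[nz[1L], k] < 0) xyz[, k] <- -xyz[, k]
  }
  # deterministic symmetry-breaking (keeps chains from staying collinear)
  xyz <- xyz + 0.05 * matrix(sin(seq_len(3L * n)), n, 3L)
  # refinement: bond lengths, 1-3 (angle) distances, nonbonded contacts
  if (nrow(mol$bonds)) {
    bonded <- matrix(FALSE, n, n)
    bonded[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
    bonded <- bonded | t(bonded)
    adj <- mol_adjacency(mol)
    onethree <- NULL
    for (jmid in seq_len(n)) {
      nb <- adj[[jmid]]
      if (length(nb) >= 2L) {
        prs <- utils::combn(nb, 2L)
        onethree <- rbind(onethree,
                          cbind(t(prs),
                                1.634 * (blen(prs[1L, ], jmid) +
                                           blen(prs[2L, ], jmid)) / 2))
      }
    }
    for (iter in seq_len(150L)) {
      grad <- matrix(0, n, 3L)
      for (k in seq_len(nrow(mol$bonds))) {
        i <- mol$bonds$i[k]; jj <- mol$bonds$j[k]
        v <- xyz[i, ] - xyz[jj, ]
        dist_ij <- sqrt(sum(v^2))
        if (dist_ij < 1e-9) next
        f <- (dist_ij - blen(i, jj)) * v / dist_ij
        grad[i, ] <- grad[i, ] - f
        grad[jj, ] <- grad[jj, ] + f
      }
      for (k in seq_len(NROW(onethree))) {
        i <- onethree[k, 1L]; jj <- onethree[k, 2L]
        v <- xyz[i, ] - xyz[jj, ]
        dist_ij <- sqrt(sum(v^2))
        if (dist_ij < 1e-9) next
        f <- 0.3 * (dist_ij - onethree[k, 3L]) * v / dist_ij
        grad[i, ] <- grad[i, ] - f
        grad[jj, ] <- grad[jj, ] + f
      }
      dm <- as.matrix(stats::dist(xyz))
      close_pairs <- which(dm < 2.0 & !bonded & upper.tri(dm), arr.ind = TRUE)
      for (q in seq_len(nrow(close_pairs))) {
        i <- close_pairs[q, 1L]; jj <- close_pairs[q, 2L]
        v <- xyz[i, ] - xyz[jj, ]
        dist_ij <- sqrt(sum(v^2))
        if (dist_ij < 1e-9) v <- c(1, 0, 0) * (dist_ij <- 1e-3)
        f <- (2.0 - dist_ij) * v / max(dist_ij, 1e-3)
        grad[i, ] <- grad[i, ] + 0.5 * f
        grad[jj, ] <- grad[jj, ] - 0.5 * f
      }
      xyz <- xyz + 0.3 * grad
    }
  }
  unname(xyz)
}

# acyclic single bonds between two non-terminal heavy atoms
.rotatable_bonds <- function(mol) {
  g <- igraph::graph_from_edgelist(as.matrix(mol$bonds[, c("i", "j")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < n_atoms(mol)) {
    g <- igraph::add_vertices(g, n_atoms(mol) - igraph::vcount(g))
  }
  deg <- igraph::degree(g)
  out <- list()
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$bonds$order[k] != 1L) next
    if (deg[i] < 2L || deg[j] < 2L) next
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    comp <- igraph::components(g2)$membership
    if (comp[i] == comp[j]) next  # in a ring
    side <- which(comp == comp[j])
    out[[length(out) + 1L]] <- list(i = i, j = j, side = side)
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), side = I(list())))
  }
  data.frame(i = vapply(out, `[[`, integer(1L), "i"),
             j = vapply(out, `[[`, integer(1L), "j"),
             side = I(lapply(out, `[[`, "side")))
}

.rotate_about_bond <- function(xyz, i, j, side, angle) {
  axis <- xyz[j, ] - xyz[i, ]
  rotm <- rotation_matrix(axis, angle)
  side <- setdiff(side, c(i, j))
  xyz[side, ] <- sweep(sweep(xyz[side, , drop = FALSE], 2L, xyz[j, ]) %*% t(rotm),
                       2L, xyz[j, ], "+")
  xyz
}

.no_clash <- function(mol, xyz, min_dist = 1.0) {
  heavy <- which(is_heavy(mol))
  if (length(heavy) < 2L) return(TRUE)
  bonded <- matrix(FALSE, n_atoms(mol), n_atoms(mol))
  bonded[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
  bonded <- bonded | t(bonded)
  d <- as.matrix(stats::dist(xyz[heavy, , drop = FALSE]))
  for (a in seq_along(heavy)) for (b in seq_along(heavy)) {
    if (a < b && !bonded[heavy[a], heavy[b]] && d[a, b] < min_dist) return(FALSE)
  }
  TRUE
}

#' Read a receptor-ligand complex from a PDB file
#'
#' Polymer (`ATOM`) records become the receptor; the named `HETATM` residue
#' becomes the ligand, with bonds perceived from interatomic distances
#' (covalent radius sum x 1.25). When several copies of the residue are
#' present the first by chain/residue order is used (logged). An absent
#' residue raises a "no bound ligand" error, mirroring the exclusion of apo
#' structures from structure-based model building.
#'
#' @param path PDB file path.
#' @param ligand_resname HETATM residue name of the bound ligand.
#' @param bound_class pharmacological class of the bound ligand
#'   (`"agonist"`, `"antagonist"`, `"other"`).
#' @return a [complex_structure()].
#' @export
read_pdb_complex <- function(path, ligand_resname,
                             bound_class = c("agonist", "antagonist", "other")) {
  bound_class <- match.arg(bound_class)
  stopifnot(file.exists(path))
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  rec <- at[at$type == "ATOM", , drop = FALSE]
  lig <- at[at$type == "HETATM" & at$resid == ligand_resname, , drop = FALSE]
  if (nrow(lig) == 0L) {
    stop(sprintf("no bound ligand: residue %s absent from %s",
                 ligand_resname, path))
  }
  copies <- unique(lig[, c("chain", "resno")])
  if (nrow(copies) > 1L) {
    message(sprintf("%d copies of %s found; using chain %s resno %d",
                    nrow(copies), ligand_resname, copies$chain[1L],
                    copies$resno[1L]))
    lig <- lig[lig$chain %in% copies$chain[1L] & lig$resno == copies$resno[1L], ,
               drop = FALSE]
  }
  elem_of <- function(df) {
    e <- df$elesy
    if (is.null(e) || all(is.na(e)) || all(!nzchar(trimws(e)))) {
      e <- sub("^([A-Za-z]+).*$", "\\1", trimws(df$elety))
      e <- paste0(toupper(substr(e, 1L, 1L)), tolower(substr(e, 2L, 2L)))
      e <- sub("[a-z]*[0-9]*$", "", e)
    }
    trimws(e)
  }
  receptor <- receptor_atoms(
    element = .normalize_element(elem_of(rec)),
    xyz = as.matrix(rec[, c("x", "y", "z")]),
    residue_tag = paste(rec$resid, rec$resno))
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  lelem <- .normalize_element(elem_of(lig))
  ligand <- molecule(ligand_resname,
                     data.frame(element = lelem, charge = 0L),
                     .perceive_bonds(lelem, lxyz),
                     conformers = list(lxyz))
  complex_structure(basename(path), receptor, ligand, bound_class)
}

.normalize_element <- function(e) {
  e <- trimws(e)
  paste0(toupper(substr(e, 1L, 1L)), tolower(substring(e, 2L)))
}

COVALENT_RADIUS <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05,
                     P = 1.07, F = 0.57, Cl = 1.02, Br = 1.20, I = 1.39,
                     Zn = 1.22, Mg = 1.41, Ca = 1.76, Fe = 1.32, B = 0.84)

# distance-based bond perception; all orders 1 except short C-O/C-N contacts
.perceive_bonds <- function(elem, xyz) {
  n <- length(elem)
  if (n < 2L) return(NULL)
  r <- COVALENT_RADIUS[elem]
  r[is.na(r)] <- 0.77
  d <- as.matrix(stats::dist(xyz))
  bonds <- NULL
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (d[i, j] <= 1.25 * (r[i] + r[j]) && d[i, j] > 0.4) {
      ord <- 1L
      pair <- sort(c(elem[i], elem[j]))
      if (identical(pair, c("C", "O")) && d[i, j] < 1.28) ord <- 2L
      bonds <- rbind(bonds, data.frame(i = i, j = j, order = ord))
    }
  }
  bonds
}

#' Write a receptor-ligand complex to a PDB file
#'
#' Receptor atoms as `ATOM` records, the ligand as a `HETATM` residue
#' (`LIG`, chain `L`). Used by the synthetic benchmark generator.
#'
#' @param cx a [complex_structure()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_pdb_complex <- function(cx, path) {
  stopifnot(inherits(cx, "pharm_complex"))
  nr <- nrow(cx$receptor)
  nl <- n_atoms(cx$ligand)
  lxyz <- conformer_xyz(cx$ligand, 1L)
  xyz <- rbind(as.matrix(cx$receptor[, c("x", "y", "z")]), lxyz)
  rtag <- cx$receptor$residue_tag
  rres <- ifelse(is.na(rtag), "SIT", sub(" .*$", "", rtag))
  rno <- suppressWarnings(as.integer(sub("^\\S+ ", "", rtag)))
  rno[is.na(rno)] <- seq_len(nr)[is.na(rno)]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   type = c(rep("ATOM", nr), rep("HETATM", nl)),
                   resno = c(rno, rep(1L, nl)),
                   resid = c(rres, rep("LIG", nl)),
                   eleno = seq_len(nr + nl),
                   elety = c(cx$receptor$element,
                             paste0(cx$ligand$atoms$element,
                                    seq_len(nl))),
                   chain = c(rep("A", nr), rep("L", nl)),
                   elesy = c(cx$receptor$element, cx$ligand$atoms$element))
  invisible(path)
}
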