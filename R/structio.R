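#' @name structio
#' @title Structure input/output and receptor preparation
#'
#' @description
#' Reading of PDB structures into a flat heavy-atom table, receptor
#' preparation (strip ligands, keep cofactors, drop waters) and location of
#' the bound ligand. Biological-assembly expansion is not performed: feed
#' pre-expanded assemblies when the asymmetric unit is not the functional
#' unit. Hydrogens are dropped throughout; all geometry is heavy-atom.
NULL

new_structure <- function(atoms, title = "", source_path = "") {
  stopifnot(is.data.frame(atoms))
  structure(list(atoms = atoms, title = title, source_path = source_path),
            class = "enz_structure")
}

#' @export
print.enz_structure <- function(x, ...) {
  cat(sprintf("<enz_structure> %d atoms (%d hetero), %d residues\n",
              nrow(x$atoms), sum(x$atoms$is_hetero),
              nrow(unique(x$atoms[, c("chain_id", "residue_number", "residue_name")]))))
  invisible(x)
}

.infer_element <- function(elety) {
  two <- c("CL", "BR", "FE", "ZN", "MG", "MN", "CU", "NA", "SE",
           "NI", "CO", "MO", "CA")
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  out <- substr(nm, 1, 1)
  # two-letter element only when the full stripped name IS that element
  hit <- nm %in% two
  out[hit] <- nm[hit]
  out
}

.atoms_from_bio3d <- function(at, vdw_table) {
  elem <- toupper(trimws(at$elesy))
  miss <- is.na(elem) | elem == ""
  if (any(miss)) elem[miss] <- .infer_element(at$elety[miss])
  occ <- suppressWarnings(as.numeric(at$o)); occ[is.na(occ)] <- 1
  bf <- suppressWarnings(as.numeric(at$b)); bf[is.na(bf)] <- 0
  df <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = elem,
    x = at$x, y = at$y, z = at$z,
    vdw_radius = .assign_vdw(elem, vdw_table),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_number = as.integer(at$resno),
    residue_name = toupper(trimws(at$resid)),
    is_hetero = at$type == "HETATM",
    occupancy = occ,
    b_factor = bf,
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE
  )
  # altloc: keep highest occupancy per (chain, residue, atom name); tie -> 'A'
  key <- paste(df$chain_id, df$residue_number, df$residue_name, df$name)
  if (anyDuplicated(key)) {
    ord <- order(key, -df$occupancy, df$alt != "A", df$alt)
    df <- df[ord, , drop = FALSE]
    key <- paste(df$chain_id, df$residue_number, df$residue_name, df$name)
    df <- df[!duplicated(key), , drop = FALSE]
    df <- df[order(df$serial), , drop = FALSE]
  }
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records (via \pkg{bio3d}), drops hydrogens, resolves
#' alternate locations by highest occupancy (tie broken towards altloc `A`)
#' and assigns van der Waals radii from a configurable table.
#'
#' @param path PDB file path.
#' @param model_policy `"first-model"` (default) keeps only the first MODEL
#'   block; `"all-models"` concatenates all models (atoms get a `model`
#'   column and unique serials).
#' @param vdw_table named radius table, see [vdw_radii()].
#' @return an `enz_structure`: list with `atoms` (data frame), `title`,
#'   `source_path`.
#' @export
read_structure <- function(path, model_policy = c("first-model", "all-models"),
                           vdw_table = vdw_radii()) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop_enzport("enzport_parse_error",
                                       paste0("file not found: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = (model_policy == "all-models"),
                                     rm.alt = FALSE, verbose = FALSE)),
    error = function(e) stop_enzport(
      "enzport_parse_error",
      sprintf("unreadable PDB '%s': %s", path, conditionMessage(e)))
  )
  atoms <- .atoms_from_bio3d(pdb$atom, vdw_table)
  if (model_policy == "all-models" && !is.null(pdb$xyz) &&
      is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1) {
    # bio3d stores per-model coordinates row-wise in xyz for the same atom set
    keep_serial <- atoms$serial
    idx <- match(keep_serial, as.integer(pdb$atom$eleno))
    per_model <- lapply(seq_len(nrow(pdb$xyz)), function(m) {
      a <- atoms
      xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
      a$x <- xyz[idx, 1]; a$y <- xyz[idx, 2]; a$z <- xyz[idx, 3]
      a$model <- m
      a$serial <- a$serial + (m - 1L) * (max(atoms$serial) + 1L)
      a
    })
    atoms <- do.call(rbind, per_model)
  } else {
    atoms$model <- 1L
  }
  if (nrow(atoms) == 0)
    stop_enzport("enzport_empty_structure",
                 paste0("no heavy atoms parsed from ", path))
  new_structure(atoms, title = basename(path), source_path = path)
}

#' Write a structure to a PDB file
#'
#' @param structure an `enz_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  a <- structure$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$residue_number, resid = a$residue_name,
    eleno = a$serial, elety = a$name, chain = a$chain_id,
    o = a$occupancy, b = a$b_factor, elesy = a$element
  )
  invisible(path)
}

new_ligand_instance <- function(het_code, atoms) {
  stopifnot(nrow(atoms) >= 1)
  structure(list(
    het_code = toupper(het_code),
    atoms = atoms,
    centroid = colMeans(as.matrix(atoms[, c("x", "y", "z")]))
  ), class = "enz_ligand")
}

#' @export
print.enz_ligand <- function(x, ...) {
  cat(sprintf("<enz_ligand> %s: %d heavy atoms, centroid (%.1f, %.1f, %.1f)\n",
              x$het_code, nrow(x$atoms), x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Prepare a receptor: strip ligands, keep cofactors
#'
#' Hetero residues whose het code is on the keep-list stay in the receptor;
#' waters are removed when `strip_waters`; every other hetero residue is
#' returned as a candidate ligand instance (one per residue copy).
#'
#' @param structure an `enz_structure`.
#' @param cofactor_keep_list character vector of het codes to keep
#'   (default: shipped cofactor list).
#' @param strip_waters drop HOH/WAT/DOD residues (default TRUE).
#' @return list with `receptor` (`enz_structure`), `ligands` (list of
#'   `enz_ligand`) and `n_water_atoms_removed`.
#' @export
prepare_receptor <- function(structure,
                             cofactor_keep_list = default_cofactors(),
                             strip_waters = TRUE) {
  a <- structure$atoms
  if (nrow(a) == 0) stop_enzport("enzport_empty_structure", "empty structure")
  keep <- toupper(cofactor_keep_list)
  water <- a$is_hetero & a$residue_name %in% c("HOH", "WAT", "DOD")
  is_lig <- a$is_hetero & !water & !(a$residue_name %in% keep)
  n_water <- if (strip_waters) sum(water) else 0L
  rec_rows <- !is_lig & !(strip_waters & water)
  receptor <- new_structure(a[rec_rows, , drop = FALSE],
                            title = structure$title,
                            source_path = structure$source_path)
  lig_atoms <- a[is_lig, , drop = FALSE]
  ligands <- list()
  if (nrow(lig_atoms) > 0) {
    grp <- paste(lig_atoms$chain_id, lig_atoms$residue_number,
                 lig_atoms$residue_name)
    ligands <- lapply(split(lig_atoms, factor(grp, levels = unique(grp))),
                      function(g) new_ligand_instance(g$residue_name[1], g))
    names(ligands) <- NULL
  }
  list(receptor = receptor, ligands = ligands,
       n_water_atoms_removed = as.integer(n_water))
}

#' Locate the bound ligand among stripped hetero residues
#'
#' When several copies of the same het code are present, the copy nearest to
#' the receptor centroid is returned (the disambiguation convention of this
#' package; configurable via `prefer`).
#'
#' @param ligands list of `enz_ligand` from [prepare_receptor()].
#' @param het_code uppercase three-letter code of the target ligand.
#' @param receptor optional `enz_structure` used for the nearest-to-centroid
#'   rule (required when several copies exist and `prefer` is
#'   `"nearest-centroid"`).
#' @param prefer `"nearest-centroid"` (default) or `"first"`.
#' @return the selected `enz_ligand`.
#' @export
locate_ligand <- function(ligands, het_code, receptor = NULL,
                          prefer = c("nearest-centroid", "first")) {
  prefer <- match.arg(prefer)
  het_code <- toupper(het_code)
  hits <- Filter(function(l) l$het_code == het_code, ligands)
  if (length(hits) == 0)
    stop_enzport("enzport_ligand_not_present",
                 paste0("ligand not present in PDB: ", het_code))
  if (length(hits) == 1 || prefer == "first") return(hits[[1]])
  if (is.null(receptor))
    stop_enzport("enzport_config_error",
                 "multiple ligand copies: receptor needed for nearest-centroid rule")
  cen <- colMeans(as.matrix(receptor$atoms[, c("x", "y", "z")]))
  d <- vapply(hits, function(l) sqrt(sum((l$centroid - cen)^2)), numeric(1))
  hits[[which.min(d)]]
}

.coords <- function(structure) as.matrix(structure$atoms[, c("x", "y", "z")])
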