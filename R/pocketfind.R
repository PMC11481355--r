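#' @name pocketfind
#' @title Alpha-sphere pocket detection and descriptors
#'
#' @description
#' Pockets are detected geometrically: every Delaunay tetrahedron of the
#' heavy-atom centers defines a candidate sphere tangent to its four atoms
#' (van der Waals weighted). Spheres with tangent radius inside
#' \code{[r_min, r_max]} and an interior free of all other atoms are kept as
#' alpha spheres; single-linkage clustering of their centers yields pockets,
#' each described by a fixed 20-descriptor feature vector.
NULL

#' Detect alpha spheres
#'
#' @param structure an `enz_structure` with at least 4 heavy atoms.
#' @param r_min,r_max radius window in angstroms (defaults 3.0 and 6.0,
#'   the customary alpha-sphere window for ligand-scale cavities).
#' @return data frame with columns `x, y, z` (center), `radius`,
#'   `a1..a4` (row indices of the four contact atoms in `structure$atoms`),
#'   `apolar` (TRUE when at least 3 contact atoms are C or S). The number of
#'   degenerate (coplanar) tetrahedra skipped is attached as attribute
#'   `n_degenerate`.
#' @export
detect_alpha_spheres <- function(structure, r_min = 3.0, r_max = 6.0) {
  a <- structure$atoms
  if (nrow(a) < 4)
    stop_enzport("enzport_degenerate_input",
                 "alpha-sphere detection needs at least 4 heavy atoms")
  stopifnot(r_min < r_max, r_min > 0)
  pts <- .coords(structure)
  dt <- delaunay3d_cpp(pts)
  res <- tangent_spheres_cpp(pts, a$vdw_radius, dt$tets, r_min, r_max)
  if (res$n_degenerate > 0)
    message(sprintf("detect_alpha_spheres: skipped %d degenerate tetrahedra",
                    res$n_degenerate))
  quad <- dt$tets[res$quad, , drop = FALSE]
  apolar_atom <- a$element %in% .APOLAR_ELEMENTS
  n_apolar <- matrix(apolar_atom[quad], ncol = 4)
  out <- data.frame(
    x = res$center[, 1], y = res$center[, 2], z = res$center[, 3],
    radius = res$radius,
    a1 = quad[, 1], a2 = quad[, 2], a3 = quad[, 3], a4 = quad[, 4],
    apolar = rowSums(n_apolar) >= 3
  )
  attr(out, "n_degenerate") <- res$n_degenerate
  out
}

new_pocket <- function(pocket_id, spheres, lining, features = NULL) {
  structure(list(pocket_id = pocket_id, spheres = spheres,
                 lining_residues = lining, features = features),
            class = "enz_pocket")
}

#' @export
print.enz_pocket <- function(x, ...) {
  cat(sprintf("<enz_pocket> id %d: %d alpha spheres, %d lining residues\n",
              x$pocket_id, nrow(x$spheres), nrow(x$lining_residues)))
  invisible(x)
}

.pocket_lining <- function(spheres, atoms) {
  idx <- unique(c(spheres$a1, spheres$a2, spheres$a3, spheres$a4))
  lin <- unique(atoms[idx, c("chain_id", "residue_number")])
  rownames(lin) <- NULL
  lin
}

.pocket_contact_atoms <- function(pocket) {
  unique(c(pocket$spheres$a1, pocket$spheres$a2,
           pocket$spheres$a3, pocket$spheres$a4))
}

#' Cluster alpha spheres into ranked pockets
#'
#' Single-linkage clustering of sphere centers at `linkage_cutoff`; clusters
#' smaller than `min_spheres` are dropped. Pockets are ranked by decreasing
#' `fpocket_score` and `pocket_id` is assigned 0-based in rank order.
#'
#' @param spheres output of [detect_alpha_spheres()].
#' @param structure the `enz_structure` the spheres came from.
#' @param linkage_cutoff single-linkage distance cutoff in angstroms
#'   (default 4.5).
#' @param min_spheres minimum cluster size (default 15).
#' @param compute compute the 20-feature vector per pocket (default TRUE;
#'   FALSE skips feature/SASA work when only geometry is needed).
#' @return list of `enz_pocket`.
#' @export
cluster_pockets <- function(spheres, structure, linkage_cutoff = 4.5,
                            min_spheres = 15, compute = TRUE) {
  stopifnot(linkage_cutoff > 0)
  if (is.null(spheres) || nrow(spheres) == 0) return(list())
  cen <- as.matrix(spheres[, c("x", "y", "z")])
  if (nrow(cen) == 1) {
    grp <- 1L
  } else {
    hc <- stats::hclust(stats::dist(cen), method = "single")
    grp <- stats::cutree(hc, h = linkage_cutoff)
  }
  keep <- names(which(table(grp) >= max(1L, min_spheres)))
  pockets <- lapply(keep, function(g) {
    s <- spheres[grp == as.integer(g), , drop = FALSE]
    rownames(s) <- NULL
    new_pocket(NA_integer_, s, .pocket_lining(s, structure$atoms))
  })
  if (length(pockets) == 0) return(list())
  if (compute) {
    sasa <- structure_sasa(structure)
    pockets <- lapply(pockets, function(p) {
      p$features <- compute_features(p, structure, sasa = sasa)
      p
    })
    score <- vapply(pockets, function(p) p$features[["fpocket_score"]], numeric(1))
  } else {
    score <- vapply(pockets, function(p) nrow(p$spheres), numeric(1))
  }
  ord <- order(-score)
  pockets <- pockets[ord]
  for (i in seq_along(pockets)) pockets[[i]]$pocket_id <- i - 1L
  pockets
}

#' Per-atom and per-residue solvent-accessible surface area
#'
#' Shrake-Rupley SASA with a 1.4 A probe over a deterministic golden-spiral
#' point set. Relative per-residue SASA is normalized by the SASA of the
#' same residue computed in isolation (context-free), which makes the
#' normalization self-consistent for non-standard residues.
#'
#' @param structure an `enz_structure`.
#' @param probe probe radius in angstroms (default 1.4).
#' @param n_points sample points per atom (default 256).
#' @return list with `atom_area` (per atom, A^2) and `residues` (data frame:
#'   chain_id, residue_number, area, ref_area, rel_sasa).
#' @export
structure_sasa <- function(structure, probe = 1.4, n_points = 256) {
  a <- structure$atoms
  pts <- .coords(structure)
  area <- shrake_rupley_cpp(pts, a$vdw_radius, probe, n_points)
  key <- paste(a$chain_id, a$residue_number)
  res_area <- tapply(area, key, sum)
  # reference: residue alone
  ref <- vapply(names(res_area), function(k) {
    idx <- which(key == k)
    sum(shrake_rupley_cpp(pts[idx, , drop = FALSE], a$vdw_radius[idx],
                          probe, n_points))
  }, numeric(1))
  parts <- do.call(rbind, strsplit(names(res_area), " ", fixed = TRUE))
  residues <- data.frame(
    chain_id = parts[, 1],
    residue_number = as.integer(parts[, 2]),
    area = as.numeric(res_area),
    ref_area = as.numeric(ref),
    rel_sasa = as.numeric(res_area) / pmax(as.numeric(ref), 1e-9)
  )
  rownames(residues) <- NULL
  list(atom_area = area, residues = residues, probe = probe)
}

#' Fraction of solvent-exposed pocket-lining residues
#'
#' The "exposed ratio" descriptor: the fraction of pocket-lining residues
#' whose relative SASA (residue SASA in context over the SASA of the residue
#' in isolation) exceeds `rel_sasa_threshold`. A fraction rather than a raw
#' count so the descriptor is independent of pocket size.
#'
#' @param pocket an `enz_pocket`.
#' @param structure the parent `enz_structure`.
#' @param rel_sasa_threshold relative-SASA cutoff in (0,1), default 0.2.
#' @param sasa optional precomputed [structure_sasa()] result.
#' @return fraction in [0,1].
#' @export
exposed_ratio <- function(pocket, structure, rel_sasa_threshold = 0.2,
                          sasa = NULL) {
  stopifnot(rel_sasa_threshold > 0, rel_sasa_threshold < 1)
  if (is.null(sasa)) sasa <- structure_sasa(structure)
  lin <- pocket$lining_residues
  m <- merge(lin, sasa$residues, by = c("chain_id", "residue_number"))
  if (nrow(m) == 0) return(0)
  mean(m$rel_sasa > rel_sasa_threshold)
}

.grid_union_volume <- function(spheres, spacing = 0.5) {
  cen <- as.matrix(spheres[, c("x", "y", "z")])
  r <- spheres$radius
  lo <- apply(cen - r, 2, min); hi <- apply(cen + r, 2, max)
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  nn <- RANN::nn2(cen, pts, k = min(25L, nrow(cen)))
  inside <- rowSums(nn$nn.dists <= matrix(r[nn$nn.idx], nrow = nrow(pts))) > 0
  sum(inside) * spacing^3
}

# fixed min-max normalization ranges used by the composite scores
.nm <- function(x, lo, hi) min(1, max(0, (x - lo) / (hi - lo)))

#' Pocket druggability score
#'
#' Logistic composite of the normalized local hydrophobic density, the
#' lining-residue hydrophobicity and the lining-residue polarity, in the
#' spirit of published alpha-sphere druggability models. Coefficients are
#' configurable; the defaults are this package's documented calibration
#' (hydrophobic pockets with low polarity score high).
#'
#' @param features a 20-descriptor vector from [compute_features()].
#' @param coefficients numeric: intercept and weights for the three
#'   normalized inputs (hydrophobic density / 60, (hydropathy + 4.5) / 9,
#'   polarity fraction).
#' @return score in [0,1].
#' @export
druggability_score <- function(features,
                               coefficients = c(intercept = -3, hyd_density = 3.5,
                                                hydrophobicity = 2.5, polarity = -1)) {
  h1 <- .nm(features[["mean_local_hydrophobic_density"]], 0, 60)
  h2 <- .nm(features[["hydrophobicity_score"]], -4.5, 4.5)
  h3 <- .nm(features[["polarity_score"]], 0, 1)
  z <- coefficients[[1]] + coefficients[[2]] * h1 + coefficients[[3]] * h2 +
    coefficients[[4]] * h3
  unname(1 / (1 + exp(-z)))
}

.FEATURE_NAMES <- c(
  "fpocket_score", "druggability_score", "n_alpha_spheres", "total_sasa",
  "polar_sasa", "apolar_sasa", "volume", "mean_local_hydrophobic_density",
  "mean_alpha_sphere_radius", "mean_alpha_sphere_solvent_access",
  "apolar_sphere_proportion", "hydrophobicity_score", "volume_score",
  "polarity_score", "charge_score", "proportion_polar_atoms",
  "alpha_sphere_density", "com_max_distance", "flexibility", "exposed_ratio"
)

#' Names of the 20 pocket descriptors
#' @return character vector of the fixed feature schema.
#' @export
pocket_feature_names <- function() .FEATURE_NAMES

#' Compute the 20-descriptor feature vector of a pocket
#'
#' Descriptor definitions (documented per field in the source) follow the
#' alpha-sphere pocket-descriptor tradition: counts, radii and polarity of
#' the spheres, SASA of the contact atoms, lining-residue physicochemistry
#' (Kyte-Doolittle hydropathy, Zamyatnin volumes, polarity and formal
#' charge), sphere-cloud shape statistics, B-factor flexibility, and the
#' exposed ratio. Deterministic for fixed input.
#'
#' @param pocket an `enz_pocket`.
#' @param structure parent `enz_structure`.
#' @param sasa optional precomputed [structure_sasa()] result.
#' @return named numeric vector, names per [pocket_feature_names()].
#' @export
compute_features <- function(pocket, structure, sasa = NULL) {
  s <- pocket$spheres
  stopifnot(nrow(s) >= 1)
  a <- structure$atoms
  if (is.null(sasa)) sasa <- structure_sasa(structure)
  cen <- as.matrix(s[, c("x", "y", "z")])
  contacts <- .pocket_contact_atoms(pocket)
  celem <- a$element[contacts]

  # sphere-cloud shape
  com <- colMeans(cen)
  dcom <- sqrt(rowSums((cen - matrix(com, nrow(cen), 3, byrow = TRUE))^2))
  pd <- if (nrow(cen) > 1) as.numeric(stats::dist(cen)) else 0

  # local hydrophobic density: apolar spheres touching other apolar spheres
  ap <- which(s$apolar)
  mlhd <- 0
  if (length(ap) > 1) {
    apc <- cen[ap, , drop = FALSE]
    dm <- as.matrix(stats::dist(apc))
    lim <- outer(s$radius[ap], s$radius[ap], "+")
    mlhd <- mean(rowSums(dm <= lim) - 1)
  }

  # SASA split by contact-atom polarity
  atom_area <- sasa$atom_area[contacts]
  polar_atoms <- celem %in% .POLAR_ELEMENTS
  apolar_atoms <- celem %in% .APOLAR_ELEMENTS

  # alpha-sphere solvent access: mean relative atomic SASA of contact atoms
  sphere_access <- vapply(seq_len(nrow(s)), function(i) {
    idx <- c(s$a1[i], s$a2[i], s$a3[i], s$a4[i])
    mean(sasa$atom_area[idx] / (4 * pi * (a$vdw_radius[idx] + sasa$probe)^2))
  }, numeric(1))

  # lining-residue physicochemistry
  lin <- pocket$lining_residues
  lin_key <- paste(a$chain_id, a$residue_number)
  res_names <- vapply(seq_len(nrow(lin)), function(i) {
    a$residue_name[match(paste(lin$chain_id[i], lin$residue_number[i]), lin_key)]
  }, character(1))
  hyd <- .HYDROPATHY[res_names]; hyd[is.na(hyd)] <- 0
  vol <- .RES_VOLUME[res_names]; vol[is.na(vol)] <- mean(.RES_VOLUME)
  chg <- .RES_CHARGE[res_names]; chg[is.na(chg)] <- 0

  bf <- a$b_factor
  brange <- diff(range(bf))
  flex <- if (brange > 0) mean((bf[contacts] - min(bf)) / brange) else 0

  f <- c(
    fpocket_score = NA_real_, druggability_score = NA_real_,
    n_alpha_spheres = nrow(s),
    total_sasa = sum(atom_area),
    polar_sasa = sum(atom_area[polar_atoms]),
    apolar_sasa = sum(atom_area[apolar_atoms]),
    volume = .grid_union_volume(s),
    mean_local_hydrophobic_density = mlhd,
    mean_alpha_sphere_radius = mean(s$radius),
    mean_alpha_sphere_solvent_access = mean(sphere_access),
    apolar_sphere_proportion = mean(s$apolar),
    hydrophobicity_score = mean(hyd),
    volume_score = mean(vol),
    polarity_score = mean(res_names %in% .POLAR_RESIDUES),
    charge_score = mean(chg),
    proportion_polar_atoms = mean(polar_atoms),
    alpha_sphere_density = mean(pd),
    com_max_distance = max(dcom),
    flexibility = flex,
    exposed_ratio = 0
  )
  f[["exposed_ratio"]] <- exposed_ratio(pocket, structure, sasa = sasa)
  # composite pocket score: larger, denser, more hydrophobic and more buried
  # pockets rank higher (fixed documented normalization ranges)
  f[["fpocket_score"]] <-
    0.4 * .nm(f[["n_alpha_spheres"]], 0, 300) +
    0.3 * .nm(f[["mean_local_hydrophobic_density"]], 0, 60) +
    0.2 * f[["apolar_sphere_proportion"]] +
    0.1 * (1 - .nm(f[["mean_alpha_sphere_solvent_access"]], 0, 1))
  f[["druggability_score"]] <- druggability_score(f)
  f[.FEATURE_NAMES]
}

#' Write pockets to a TSV feature table
#'
#' One row per pocket, fixed versioned header (`pocket_id` + the 20 feature
#' columns).
#'
#' @param pockets list of `enz_pocket` with computed features.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pocket_table <- function(pockets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#enzport pocket feature table v1", con)
  df <- do.call(rbind, lapply(pockets, function(p)
    data.frame(pocket_id = p$pocket_id, t(p$features))))
  if (is.null(df)) df <- data.frame(matrix(nrow = 0, ncol = 21,
      dimnames = list(NULL, c("pocket_id", .FEATURE_NAMES))))
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write alpha-sphere centers as a pseudo-atom PDB for visualization
#'
#' @param spheres alpha-sphere data frame (or an `enz_pocket`).
#' @param path output PDB path. Sphere radius goes to the B-factor column.
#' @return `path`, invisibly.
#' @export
write_alpha_spheres_pdb <- function(spheres, path) {
  if (inherits(spheres, "enz_pocket")) spheres <- spheres$spheres
  n <- nrow(spheres)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(spheres[, c("x", "y", "z")]))),
    type = rep("HETATM", n), resno = seq_len(n),
    resid = rep("APS", n), eleno = seq_len(n),
    elety = rep("C", n), chain = rep("S", n),
    o = rep(1, n), b = spheres$radius, elesy = rep("C", n)
  )
  invisible(path)
}
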