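#' @name synthdata
#' @title Synthetic structures, feature tables and energy profiles
#'
#' @description
#' Ground-truth generators used to exercise every pipeline stage without
#' external data: sphere-packed protein shells with carved tubes and
#' cavities, class-conditional Gaussian pocket-feature tables with a
#' computable Bayes-optimal accuracy, and piecewise-smooth energy profiles
#' with prescribed bound/maximum/surface energies. All generators are pure
#' functions of their specification and seed. These fixtures are geometric
#' and statistical stand-ins, not physically realistic proteins.
NULL

#' Specification of a synthetic shell protein
#'
#' A hollow spherical shell of pseudo-carbon atoms (vdW 1.7 A) on a
#' jittered cubic lattice, with an empty central cavity and optional
#' radial tubes of prescribed bottleneck radius and an optional surface
#' cleft.
#'
#' @param inner_radius cavity radius in angstroms (default 6).
#' @param shell_thickness shell wall thickness in angstroms (default 6).
#' @param atom_spacing lattice constant in angstroms (default 1.6; small
#'   enough that lattice granularity is well below the tunnel-radius
#'   tolerances, and the un-carved wall is sealed for a 0.9 A probe).
#' @param tubes list of `list(direction = unit 3-vector, bottleneck = A)`.
#' @param surface_cleft optional `list(direction = unit 3-vector,
#'   depth = A)` carving a surface pocket.
#' @param jitter uniform lattice jitter amplitude per coordinate (default
#'   0.25 A; keeps the Delaunay triangulation non-degenerate).
#' @param seed integer; fixes the output exactly.
#' @return a `shell_spec` list.
#' @export
shell_spec <- function(inner_radius = 6, shell_thickness = 6,
                       atom_spacing = 1.6, tubes = list(),
                       surface_cleft = NULL, jitter = 0.25, seed = 1) {
  stopifnot(inner_radius > 0, shell_thickness > 0, atom_spacing > 0)
  for (tb in tubes) {
    stopifnot(length(tb$direction) == 3, tb$bottleneck > 0)
    if (2 * tb$bottleneck > inner_radius + shell_thickness)
      stop_enzport("enzport_spec_error",
                   "tube bottleneck too wide for the shell")
  }
  structure(list(inner_radius = inner_radius,
                 shell_thickness = shell_thickness,
                 atom_spacing = atom_spacing, tubes = tubes,
                 surface_cleft = surface_cleft, jitter = jitter,
                 seed = seed), class = "shell_spec")
}

#' Generate a synthetic shell protein with known tunnel ground truth
#'
#' @param spec a [shell_spec()].
#' @return list with `structure` (an `enz_structure` centered at the
#'   origin) and `ground_truth`: per tube, its axis, bottleneck radius and
#'   length (cavity center to outer surface).
#' @export
make_shell_protein <- function(spec) {
  stopifnot(inherits(spec, "shell_spec"))
  outer <- spec$inner_radius + spec$shell_thickness
  g <- seq(-outer - spec$atom_spacing, outer + spec$atom_spacing,
           by = spec$atom_spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- with_seed(spec$seed,
                   pts + matrix(runif(length(pts), -spec$jitter, spec$jitter),
                                nrow(pts), 3))
  rad <- sqrt(rowSums(pts^2))
  keep <- rad >= spec$inner_radius & rad <= outer
  pts <- pts[keep, , drop = FALSE]
  # carve tubes on the jittered positions (so the prescribed bottleneck is a
  # hard lower bound on the remaining clearance), then line each tube with
  # rings of wall atoms exactly at the carve radius so the realized
  # bottleneck equals the prescribed one rather than the looser value the
  # discrete lattice happens to leave
  for (ti in seq_along(spec$tubes)) {
    tb <- spec$tubes[[ti]]
    u <- tb$direction / sqrt(sum(tb$direction^2))
    wall <- tb$bottleneck + 1.7
    axial <- as.numeric(pts %*% u)
    radial <- sqrt(pmax(0, rowSums(pts^2) - axial^2))
    cut <- axial > 0 & radial < wall
    pts <- pts[!cut, , drop = FALSE]
    ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    # rings sit 0.02 A inside the carve radius: the realized bottleneck is
    # then bounded above by the prescription (a probe of exactly the
    # prescribed radius does not fit) and below by prescription - 0.02
    ring_r <- wall - 0.02
    ring_ax <- seq(spec$inner_radius, outer, by = 1.0)
    n_ring <- max(8L, ceiling(2 * pi * ring_r / 1.2))
    phase <- with_seed(spec$seed + 100L + ti,
                       runif(length(ring_ax), 0, 2 * pi / n_ring))
    rings <- do.call(rbind, lapply(seq_along(ring_ax), function(i) {
      th <- phase[i] + 2 * pi * seq_len(n_ring) / n_ring
      outer(rep(1, n_ring), ring_ax[i] * u) +
        ring_r * (cos(th) %o% e1 + sin(th) %o% e2)
    }))
    pts <- rbind(pts, rings)
  }
  if (!is.null(spec$surface_cleft)) {
    u <- spec$surface_cleft$direction /
      sqrt(sum(spec$surface_cleft$direction^2))
    anchor <- u * outer
    d <- sqrt(rowSums((pts - matrix(anchor, nrow(pts), 3, byrow = TRUE))^2))
    pts <- pts[d > spec$surface_cleft$depth, , drop = FALSE]
  }
  n <- nrow(pts)
  atoms <- data.frame(
    serial = seq_len(n), name = "C", element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    vdw_radius = 1.7, chain_id = "A", residue_number = seq_len(n),
    residue_name = "SHL", is_hetero = FALSE, occupancy = 1,
    b_factor = 0, alt = "", model = 1L
  )
  gt <- lapply(spec$tubes, function(tb) {
    u <- tb$direction / sqrt(sum(tb$direction^2))
    list(axis = u, bottleneck_radius = tb$bottleneck,
         length = outer) # cavity center to outer surface
  })
  list(structure = new_structure(atoms, title = "synthetic shell"),
       ground_truth = gt)
}

#' Place a rigid synthetic ligand
#'
#' A compact random cluster of heavy atoms (pseudo-carbons) centered at the
#' requested location.
#'
#' @param structure an `enz_structure` (used for the clearance check and,
#'   for `"cavity_center"`/`"surface"`, to locate the target).
#' @param location `"cavity_center"` (centroid of the structure, i.e. the
#'   cavity of a shell), `"surface"` (a point 5 A outside the maximal atom
#'   radius along +x), or a numeric 3-vector.
#' @param n_atoms number of heavy atoms (default 8).
#' @param spread cluster radius in angstroms (default 1.2).
#' @param seed integer seed.
#' @param min_clearance minimum allowed distance from any ligand atom to
#'   any receptor atom center (default 2.4 A); violation raises a
#'   placement error.
#' @return an `enz_ligand` with het code `LIG`.
#' @export
place_ligand <- function(structure, location = "cavity_center", n_atoms = 8,
                         spread = 1.2, seed = 1, min_clearance = 2.4) {
  pts <- .coords(structure)
  center <- if (is.numeric(location)) {
    stopifnot(length(location) == 3)
    location
  } else switch(location,
                cavity_center = colMeans(pts),
                surface = c(max(sqrt(rowSums(pts^2))) + 5, 0, 0),
                stop_enzport("enzport_config_error",
                             paste0("unknown ligand location: ", location)))
  offs <- with_seed(seed, matrix(runif(3 * n_atoms, -spread, spread),
                                 n_atoms, 3))
  xyz <- sweep(offs, 2, center, "+")
  nn <- RANN::nn2(pts, xyz, k = 1)
  if (min(nn$nn.dists) < min_clearance)
    stop_enzport("enzport_placement_error",
                 "no clearance for the ligand at the requested location")
  atoms <- data.frame(
    serial = seq_len(n_atoms) + 90000L, name = "C", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    vdw_radius = 1.7, chain_id = "L", residue_number = 900L,
    residue_name = "LIG", is_hetero = TRUE, occupancy = 1,
    b_factor = 0, alt = "", model = 1L
  )
  new_ligand_instance("LIG", atoms)
}

#' Specification of a class-conditional Gaussian feature dataset
#'
#' @param n_per_class rows per class.
#' @param class_means 3 x p matrix of class means (rows: buried,
#'   borderline, surface).
#' @param class_sds 3 x p matrix of positive standard deviations.
#' @param feature_names column names (default the 20-feature schema when
#'   p = 20).
#' @param seed integer seed.
#' @return a `feature_gen_spec` list.
#' @export
feature_gen_spec <- function(n_per_class, class_means, class_sds,
                             feature_names = NULL, seed = 1) {
  class_means <- as.matrix(class_means)
  class_sds <- as.matrix(class_sds)
  stopifnot(nrow(class_means) == 3, all(dim(class_means) == dim(class_sds)),
            all(class_sds > 0), n_per_class >= 1)
  p <- ncol(class_means)
  feature_names <- feature_names %||%
    (if (p == 20) pocket_feature_names() else paste0("f", seq_len(p)))
  structure(list(n_per_class = as.integer(n_per_class),
                 class_means = class_means, class_sds = class_sds,
                 feature_names = feature_names, seed = seed),
            class = "feature_gen_spec")
}

#' Default class-conditional feature specification
#'
#' Three classes differing along descriptors that plausibly separate buried
#' from surface pockets (exposed ratio, solvent access, SASA, volume); the
#' `separation` multiplier scales the between-class mean differences
#' (0 = identical classes).
#'
#' @param n_per_class rows per class (default 67, roughly a 200-row
#'   balanced training set).
#' @param separation effect-size multiplier (default 1).
#' @param seed integer seed.
#' @return a `feature_gen_spec`.
#' @export
default_feature_spec <- function(n_per_class = 67, separation = 1, seed = 1) {
  base <- c(
    fpocket_score = 0.4, druggability_score = 0.3, n_alpha_spheres = 80,
    total_sasa = 250, polar_sasa = 100, apolar_sasa = 150, volume = 600,
    mean_local_hydrophobic_density = 25, mean_alpha_sphere_radius = 4,
    mean_alpha_sphere_solvent_access = 0.45, apolar_sphere_proportion = 0.5,
    hydrophobicity_score = 0, volume_score = 130, polarity_score = 0.45,
    charge_score = 0, proportion_polar_atoms = 0.35,
    alpha_sphere_density = 6, com_max_distance = 9, flexibility = 0.4,
    exposed_ratio = 0.45
  )
  shift <- numeric(20); names(shift) <- names(base)
  shift[c("exposed_ratio", "mean_alpha_sphere_solvent_access")] <- 0.18
  shift[c("total_sasa", "polar_sasa")] <- c(80, 35)
  shift[c("volume", "n_alpha_spheres")] <- c(-120, -15)
  shift["flexibility"] <- 0.08
  means <- rbind(buried = base - separation * shift,
                 borderline = base,
                 surface = base + separation * shift)
  sds <- matrix(rep(pmax(abs(base) * 0.25, c(
    0.08, 0.08, 12, 40, 20, 25, 90, 6, 0.4, 0.09, 0.1, 0.8, 12, 0.1, 0.3,
    0.08, 1, 1.5, 0.09, 0.09)), each = 3), nrow = 3)
  feature_gen_spec(n_per_class, means, sds, names(base), seed)
}

#' Generate a labelled Gaussian feature dataset
#'
#' Features are drawn from diagonal-covariance Gaussians per class and
#' clipped to the descriptor invariant ranges (proportions to [0,1],
#' counts/areas/volumes to non-negative). The Bayes-optimal accuracy of the
#' generating mixture (computed by applying the exact Bayes rule to a large
#' fresh sample from the unclipped model) is attached as attribute
#' `bayes_accuracy`.
#'
#' @param spec a [feature_gen_spec()].
#' @param bayes_n Monte Carlo sample size for the Bayes-accuracy estimate
#'   (default 30000).
#' @return an `enz_dataset` with balanced classes.
#' @export
make_feature_dataset <- function(spec, bayes_n = 30000) {
  stopifnot(inherits(spec, "feature_gen_spec"))
  p <- ncol(spec$class_means)
  lev <- .CLASS_LEVELS
  draw <- function(n_per_class) {
    do.call(rbind, lapply(1:3, function(ci) {
      matrix(rnorm(n_per_class * p,
                   mean = rep(spec$class_means[ci, ], each = n_per_class),
                   sd = rep(spec$class_sds[ci, ], each = n_per_class)),
             n_per_class, p)
    }))
  }
  x <- with_seed(spec$seed, draw(spec$n_per_class))
  colnames(x) <- spec$feature_names
  # clip to invariant ranges
  unitish <- grepl("ratio|proportion|score$|access|flexibility",
                   spec$feature_names) &
    !grepl("hydrophobicity|charge|volume_score", spec$feature_names)
  x[, unitish] <- pmin(pmax(x[, unitish], 0), 1)
  nonneg <- grepl("sasa|volume|spheres|radius|density|distance",
                  spec$feature_names)
  x[, nonneg] <- pmax(x[, nonneg], 0)
  labels <- rep(lev, each = spec$n_per_class)

  # Bayes rule on the unclipped generating mixture
  bayes <- with_seed(spec$seed + 7L, {
    nb <- ceiling(bayes_n / 3)
    xs <- draw(nb)
    ys <- rep(1:3, each = nb)
    ll <- vapply(1:3, function(ci) {
      rowSums(dnorm(xs, mean = matrix(spec$class_means[ci, ], nrow(xs), p,
                                      byrow = TRUE),
                    sd = matrix(spec$class_sds[ci, ], nrow(xs), p,
                                byrow = TRUE), log = TRUE))
    }, numeric(3 * nb))
    mean(max.col(ll, ties.method = "first") == ys)
  })
  ds <- labeled_dataset(as.data.frame(x), labels)
  attr(ds, "bayes_accuracy") <- bayes
  ds
}

#' Generate a synthetic energy profile
#'
#' Piecewise-smooth profiles whose window-extracted statistics equal the
#' requested E_bound/E_max/E_surface (exactly at zero noise): flat ends
#' over the first and last 10 percent of the points, half-cosine ramps to a
#' single (or double) barrier peaking at `argmax_position`.
#'
#' @param template `"single_barrier"`, `"double_barrier"` or `"flat"`.
#' @param e_bound,e_max,e_surface energies in kcal/mol (ignored except
#'   `e_bound` for `"flat"`).
#' @param n_points number of discs (default 100).
#' @param argmax_position fractional position of the maximum in (0.1, 0.9)
#'   (default 0.5).
#' @param noise_sd Gaussian noise amplitude in kcal/mol (default 0).
#' @param length profile length in angstroms (default 20).
#' @param bottleneck_position fractional position of the minimum disc
#'   radius (default `argmax_position`).
#' @param tunnel_id,ligand_role profile metadata (default tunnel 1,
#'   product).
#' @param seed integer seed (noise only).
#' @return an `enz_profile`; the requested ground-truth values are attached
#'   as attribute `ground_truth`.
#' @export
make_profile <- function(template = c("single_barrier", "double_barrier", "flat"),
                         e_bound = -8, e_max = 4, e_surface = -2,
                         n_points = 100, argmax_position = 0.5,
                         noise_sd = 0, length = 20,
                         bottleneck_position = argmax_position,
                         tunnel_id = 1L, ligand_role = "product", seed = 1) {
  template <- match.arg(template)
  stopifnot(n_points >= 10)
  d <- seq(0, length, length.out = n_points)
  f <- seq(0, 1, length.out = n_points)
  ramp <- function(from, to, x0, x1) {
    # half-cosine from `from` at x0 to `to` at x1, evaluated on f
    w <- pmin(pmax((f - x0) / (x1 - x0), 0), 1)
    from + (to - from) * (1 - cos(pi * w)) / 2
  }
  if (template == "flat") {
    e <- rep(e_bound, n_points)
    e_max <- e_surface <- e_bound
  } else {
    stopifnot(argmax_position > 0.1, argmax_position < 0.9)
    up <- ramp(e_bound, e_max, 0.1, argmax_position)
    down <- ramp(e_max, e_surface, argmax_position, 0.9)
    e <- ifelse(f <= argmax_position, up, down)
    if (template == "double_barrier") {
      x2 <- (argmax_position + 0.9) / 2
      bump_w <- 0.05
      e <- e + (e_max - e_surface) * 0.4 *
        exp(-0.5 * ((f - x2) / bump_w)^2) * as.numeric(f > argmax_position)
      e <- pmin(e, e_max) # the prescribed maximum stays the global maximum
    }
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, rnorm(n_points, 0, noise_sd))
    # keep the flat end windows noise-free so window minima stay calibrated
    guard <- f > 0.1 & f < 0.9
    e <- e + noise * as.numeric(guard)
  }
  r <- 2.5 - 1.0 * exp(-0.5 * ((f - bottleneck_position) / 0.12)^2)
  prof <- energy_profile(data.frame(distance = d, disc_radius = r, energy = e),
                         tunnel_id = tunnel_id, ligand_role = ligand_role)
  attr(prof, "ground_truth") <- list(template = template, e_bound = e_bound,
                                     e_max = e_max, e_surface = e_surface,
                                     argmax_position = argmax_position,
                                     bottleneck_position = bottleneck_position)
  prof
}

#' Emit a complete synthetic fixture directory
#'
#' Writes a shell-protein PDB (with the ligand as HETATM records), per-tube
#' energy-profile TSVs and a ground-truth JSON so the pipeline can be
#' exercised end-to-end through its file interfaces.
#'
#' @param dir output directory (created if needed).
#' @param spec a [shell_spec()]; default: one 2 A tube along +x and one
#'   1.2 A tube along -y.
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
simulate_fixture <- function(dir, spec = NULL, seed = 1) {
  spec <- spec %||% shell_spec(
    tubes = list(list(direction = c(1, 0, 0), bottleneck = 2.0),
                 list(direction = c(0, -1, 0), bottleneck = 1.2)),
    seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shell <- make_shell_protein(spec)
  lig <- place_ligand(shell$structure, "cavity_center", seed = seed)
  combined <- new_structure(rbind(shell$structure$atoms, lig$atoms),
                            title = "synthetic shell complex")
  write_structure(combined, file.path(dir, "structure.pdb"))
  for (i in seq_along(spec$tubes)) {
    prof <- make_profile("single_barrier", tunnel_id = i,
                         seed = seed + i, noise_sd = 0.3)
    write_profile_tsv(prof, file.path(dir, sprintf("profile_tunnel%d.tsv", i)))
  }
  jsonlite::write_json(
    list(seed = seed,
         tubes = lapply(shell$ground_truth, function(g)
           list(axis = g$axis, bottleneck_radius = g$bottleneck_radius,
                length = g$length))),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
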