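#' @name energetics
#' @title Ligand-transport energy-profile analytics
#'
#' @description
#' Post-processing of per-disc energy profiles from ligand-transport
#' simulations. The key quantities per profile are the bound-state energy
#' E_bound (minimum over the pocket-end window), the surface energy
#' E_surface (minimum over the tunnel-mouth window), the global maximum
#' E_max, and the transport barrier E_a, computed as E_max - E_bound for
#' products (unbinding) and E_max - E_surface for substrates (binding).
#' Energies are kcal/mol, distances angstroms along the tunnel.
NULL

#' Construct an energy profile
#'
#' @param points data frame with numeric columns `distance` (strictly
#'   increasing, A along the tunnel from the pocket end), `disc_radius` (A)
#'   and `energy` (kcal/mol); at least 3 points.
#' @param tunnel_id integer tunnel rank the profile belongs to.
#' @param ligand_role `"substrate"` or `"product"` (optional if `direction`
#'   given).
#' @param direction `"binding"` or `"unbinding"`; derived from the role via
#'   [direction_for_role()] when missing.
#' @return an `enz_profile` (the data frame with metadata attributes).
#' @export
energy_profile <- function(points, tunnel_id = 1L, ligand_role = NULL,
                           direction = NULL) {
  stopifnot(all(c("distance", "disc_radius", "energy") %in% names(points)))
  if (nrow(points) < 3)
    stop_enzport("enzport_degenerate_profile", "profile needs at least 3 points")
  if (any(diff(points$distance) <= 0))
    stop_enzport("enzport_degenerate_profile",
                 "profile distances must be strictly increasing")
  if (any(!is.finite(points$energy)))
    stop_enzport("enzport_degenerate_profile", "profile energies must be finite")
  if (is.null(direction)) {
    if (is.null(ligand_role))
      stop_enzport("enzport_config_error", "need ligand_role or direction")
    direction <- direction_for_role(ligand_role)
  }
  structure(points[, c("distance", "disc_radius", "energy")],
            tunnel_id = as.integer(tunnel_id),
            ligand_role = ligand_role, direction = direction,
            class = c("enz_profile", "data.frame"))
}

#' Simulation direction for a ligand role
#'
#' Substrates bind (travel inward), products unbind (travel outward).
#'
#' @param role `"substrate"` or `"product"`.
#' @return `"binding"` or `"unbinding"`.
#' @export
direction_for_role <- function(role) {
  switch(as.character(role),
         substrate = "binding",
         product = "unbinding",
         stop_enzport("enzport_config_error",
                      paste0("unknown ligand role: ", role)))
}

#' Extract the key energies of a profile
#'
#' E_bound is the minimum energy over the first `bound_window` fraction of
#' points (pocket end), E_surface the minimum over the last `surface_window`
#' fraction, E_max the global maximum; the barrier is
#' E_a = E_max - E_bound for products and E_a = E_max - E_surface for
#' substrates. Window minima (rather than single endpoint values) represent
#' relaxed end states and are robust to per-disc noise. Ties in the maximum
#' resolve to the point nearest the pocket end.
#'
#' @param profile an `enz_profile`.
#' @param bound_window,surface_window end-window fractions in (0, 0.5],
#'   defaults 0.1.
#' @return an `enz_profile_stats` list: `e_bound`, `e_max`, `e_surface`,
#'   `e_a`, `argmax_distance`, `tunnel_id`, `direction`, `ligand_role`.
#' @export
profile_stats <- function(profile, bound_window = 0.1, surface_window = 0.1) {
  stopifnot(bound_window > 0, bound_window <= 0.5,
            surface_window > 0, surface_window <= 0.5)
  n <- nrow(profile)
  nb <- max(1L, floor(n * bound_window))
  ns <- max(1L, floor(n * surface_window))
  e <- profile$energy
  e_bound <- min(e[seq_len(nb)])
  e_surface <- min(e[seq.int(n - ns + 1L, n)])
  imax <- which.max(e) # first occurrence on ties: nearest the pocket end
  e_max <- e[imax]
  dir <- attr(profile, "direction")
  role <- attr(profile, "ligand_role")
  e_ref <- if (identical(role, "product") || identical(dir, "unbinding"))
    e_bound else e_surface
  structure(list(
    e_bound = e_bound, e_max = e_max, e_surface = e_surface,
    e_a = e_max - e_ref, argmax_distance = profile$distance[imax],
    tunnel_id = attr(profile, "tunnel_id"),
    direction = dir, ligand_role = role
  ), class = "enz_profile_stats")
}

#' Remove the first third of a profile
#'
#' Drops the first `floor(n/3)` points (by count, profiles being per-disc
#' sequences) to suppress clash peaks at the pocket end. Distances are
#' preserved, not re-zeroed. Not idempotent: trimming twice removes more.
#'
#' @param profile an `enz_profile` with at least 3 points.
#' @return the trimmed `enz_profile`.
#' @export
trim_first_third <- function(profile) {
  n <- nrow(profile)
  if (n < 3)
    stop_enzport("enzport_degenerate_profile", "cannot trim: fewer than 3 points")
  k <- floor(n / 3)
  out <- profile[seq.int(k + 1L, n), , drop = FALSE]
  rownames(out) <- NULL
  attributes(out)[c("tunnel_id", "ligand_role", "direction", "class")] <-
    attributes(profile)[c("tunnel_id", "ligand_role", "direction", "class")]
  out
}

#' Select the energetically best tunnel
#'
#' Each profile is trimmed by [trim_first_third()], then the tunnel with the
#' lowest post-trim maximum energy wins; ties resolve to the lower tunnel
#' id.
#'
#' @param profiles list of 1 to 3 `enz_profile` with distinct tunnel ids.
#' @return winning tunnel id (integer).
#' @export
best_tunnel <- function(profiles) {
  if (length(profiles) == 0)
    stop_enzport("enzport_config_error", "best_tunnel needs at least one profile")
  ids <- vapply(profiles, function(p) attr(p, "tunnel_id"), integer(1))
  stopifnot(!anyDuplicated(ids), length(profiles) <= 3)
  emax <- vapply(profiles, function(p) max(trim_first_third(p)$energy), numeric(1))
  ord <- order(emax, ids)
  ids[ord[1]]
}

#' Compare the energetic maximum with the geometric bottleneck
#'
#' Locates the minimum-radius disc of the profile (first on ties) and flags
#' whether the energy maximum falls at that disc or within its 1.5, 3 and
#' 5 A vicinity along the tunnel. The exact-disc flag (vicinity 0) allows
#' half a disc spacing of slack.
#'
#' @param profile an `enz_profile`.
#' @param tunnel optional `enz_tunnel` in the same arc-length frame, used
#'   only to validate the frame (profile must not extend beyond the tunnel
#'   by more than one disc spacing).
#' @return a `BottleneckMatch` list: `vicinity_flags` (named logical for
#'   0/1.5/3/5 A), `argmax_distance`, `bottleneck_distance`.
#' @export
bottleneck_match <- function(profile, tunnel = NULL) {
  d <- profile$distance
  if (!is.null(tunnel)) {
    spacing <- stats::median(diff(d))
    if (max(d) > tunnel$length + spacing)
      stop_enzport("enzport_frame_error",
                   "profile extends beyond the tunnel: mismatched frames")
  }
  imin <- which.min(profile$disc_radius)
  imax <- which.max(profile$energy)
  bd <- d[imin]; ad <- d[imax]
  gap <- abs(ad - bd)
  half <- stats::median(diff(d)) / 2
  flags <- c(`0` = gap <= half, `1.5` = gap <= 1.5, `3` = gap <= 3,
             `5` = gap <= 5)
  stopifnot(!is.unsorted(flags)) # monotone in the vicinity radius
  list(vicinity_flags = flags, argmax_distance = ad, bottleneck_distance = bd)
}

#' Energy-window filter for ligand passage
#'
#' A profile passes when E_max lies in `emax_window` and E_a in `ea_window`
#' (closed intervals). Defaults are the recommended cognate-ligand windows:
#' E_max in [-10, 5] kcal/mol and E_a in [0, 10] kcal/mol.
#'
#' @param stats an `enz_profile_stats`.
#' @param emax_window,ea_window numeric length-2 (kcal/mol), ordered.
#' @return logical.
#' @export
barrier_filter <- function(stats, emax_window = c(-10, 5),
                           ea_window = c(0, 10)) {
  stopifnot(emax_window[1] <= emax_window[2], ea_window[1] <= ea_window[2])
  if (stats$e_a < 0)
    warning("negative transport barrier: profile violates its own invariant")
  stats$e_max >= emax_window[1] && stats$e_max <= emax_window[2] &&
    stats$e_a >= ea_window[1] && stats$e_a <= ea_window[2]
}

#' Summarize a set of profile statistics
#'
#' @param stats_list list of `enz_profile_stats`.
#' @param emax_window,ea_window windows passed to the fraction computation
#'   (defaults as in [barrier_filter()]).
#' @return list: `n_by_rank` (profiles per tunnel rank),
#'   `frac_emax_in_window`, `frac_ea_in_window`, `frac_pass` (both windows),
#'   `pearson_emax_ea` (NA when fewer than 2 profiles or degenerate).
#' @export
summarize_profiles <- function(stats_list, emax_window = c(-10, 5),
                               ea_window = c(0, 10)) {
  stopifnot(length(stats_list) >= 1)
  emax <- vapply(stats_list, function(s) s$e_max, numeric(1))
  ea <- vapply(stats_list, function(s) s$e_a, numeric(1))
  rank <- vapply(stats_list, function(s)
    as.integer(s$tunnel_id %||% NA_integer_), integer(1))
  in_emax <- emax >= emax_window[1] & emax <= emax_window[2]
  in_ea <- ea >= ea_window[1] & ea <= ea_window[2]
  r <- if (length(emax) >= 2 && stats::sd(emax) > 0 && stats::sd(ea) > 0)
    stats::cor(emax, ea) else NA_real_
  list(
    n_by_rank = table(rank),
    frac_emax_in_window = mean(in_emax),
    frac_ea_in_window = mean(in_ea),
    frac_pass = mean(in_emax & in_ea),
    pearson_emax_ea = r
  )
}

#' Average profile statistics over simulation snapshots
#'
#' @param per_snapshot_stats list over snapshots; each element is a list of
#'   `enz_profile_stats` (one per tunnel present in that snapshot).
#' @return list per tunnel id: averaged `e_bound`, `e_max`, `e_surface`,
#'   `e_a`, plus `occurrence` (fraction of snapshots where the tunnel
#'   exists) and `n_snapshots`.
#' @export
average_over_snapshots <- function(per_snapshot_stats) {
  stopifnot(length(per_snapshot_stats) >= 1)
  ns <- length(per_snapshot_stats)
  flat <- unlist(per_snapshot_stats, recursive = FALSE)
  ids <- vapply(flat, function(s) s$tunnel_id, integer(1))
  out <- lapply(sort(unique(ids)), function(id) {
    sel <- flat[ids == id]
    avg <- function(f) mean(vapply(sel, function(s) s[[f]], numeric(1)))
    list(tunnel_id = id, e_bound = avg("e_bound"), e_max = avg("e_max"),
         e_surface = avg("e_surface"), e_a = avg("e_a"),
         occurrence = length(sel) / ns, n_snapshots = ns)
  })
  names(out) <- vapply(out, function(x) as.character(x$tunnel_id), character(1))
  out
}

#' Read an energy profile from TSV
#'
#' The native dialect: `#key<TAB>value` comment headers (`tunnel_id`,
#' `direction`, `ligand_role`), then three tab-separated numeric columns
#' (distance, disc radius, energy) with a header row.
#'
#' @param path TSV path.
#' @return an `enz_profile`.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "[\t:]+")[[1]]
    if (length(kv) >= 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  df <- utils::read.delim(text = lines[!grepl("^#", lines)])
  names(df) <- tolower(names(df))
  energy_profile(df,
                 tunnel_id = as.integer(meta$tunnel_id %||% 1L),
                 ligand_role = meta$ligand_role,
                 direction = meta$direction)
}

#' Write an energy profile to TSV
#'
#' @param profile an `enz_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#tunnel_id\t%d", attr(profile, "tunnel_id")), con)
  if (!is.null(attr(profile, "direction")))
    writeLines(sprintf("#direction\t%s", attr(profile, "direction")), con)
  if (!is.null(attr(profile, "ligand_role")))
    writeLines(sprintf("#ligand_role\t%s", attr(profile, "ligand_role")), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a lower-bound trajectory energy text file
#'
#' Tolerant reader for per-disc lower-bound output: whitespace-separated
#' lines whose first numeric field is the disc index and last numeric field
#' the energy (kcal/mol). Disc indices are converted to distances and radii
#' through the disc table of the corresponding tunnel
#' (see [discretize_tunnel()]).
#'
#' @param path text file path.
#' @param discs disc table from [discretize_tunnel()].
#' @param tunnel_id,ligand_role,direction profile metadata.
#' @return an `enz_profile`.
#' @export
read_caverdock_profile <- function(path, discs, tunnel_id = 1L,
                                   ligand_role = NULL, direction = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parsed <- lapply(strsplit(trimws(lines), "\\s+"), function(f) {
    v <- suppressWarnings(as.numeric(f))
    v <- v[!is.na(v)]
    if (length(v) >= 2) c(v[1], v[length(v)]) else NULL
  })
  parsed <- do.call(rbind, parsed)
  if (is.null(parsed) || nrow(parsed) < 3)
    stop_enzport("enzport_parse_error",
                 paste0("no parseable disc/energy rows in ", path))
  idx <- as.integer(parsed[, 1])
  row <- match(idx, discs$index)
  if (any(is.na(row)))
    stop_enzport("enzport_frame_error",
                 "disc indices in profile not present in the disc table")
  energy_profile(data.frame(distance = discs$distance[row],
                            disc_radius = discs$radius[row],
                            energy = parsed[, 2]),
                 tunnel_id = tunnel_id, ligand_role = ligand_role,
                 direction = direction)
}
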