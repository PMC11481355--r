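#' @name tunnelcalc
#' @title Tunnel detection, priority scoring and disc discretization
#'
#' @description
#' Tunnels are searched on the Voronoi graph of the heavy atoms: graph nodes
#' are Delaunay-tetrahedron circumcenters (Voronoi vertices), edges connect
#' adjacent tetrahedra, and each edge carries a clearance (sampled distance
#' to the nearest atom surface) and a cost, the line integral of
#' \eqn{dl / r(l)^2} along the edge. A tunnel is a lowest-cost path from the
#' start point to a convex-hull exit with clearance at least the probe
#' radius everywhere. Tunnel priority is the throughput-style score
#' \eqn{exp(-\int dl / r^2)}: a value in (0,1], close to 1 for short, wide
#' tunnels. The relevance conventions implemented here: keep the first
#' `top_n` tunnels plus any tunnel with priority above the cutoff (default
#' 0.55).
NULL

new_tunnel <- function(tunnel_id, nodes) {
  stopifnot(nrow(nodes) >= 2)
  seg <- sqrt(rowSums((nodes[-1, c("x", "y", "z")] -
                         nodes[-nrow(nodes), c("x", "y", "z")])^2))
  len <- sum(seg)
  ee <- sqrt(sum((as.numeric(nodes[nrow(nodes), c("x", "y", "z")]) -
                    as.numeric(nodes[1, c("x", "y", "z")]))^2))
  t <- structure(list(
    tunnel_id = tunnel_id, nodes = nodes, length = len,
    bottleneck_radius = min(nodes$clearance),
    curvature = if (ee > 0) len / ee else Inf,
    throughput = NA_real_, priority = NA_real_
  ), class = "enz_tunnel")
  t$throughput <- t$priority <- priority_score(t)
  t
}

#' @export
print.enz_tunnel <- function(x, ...) {
  cat(sprintf(
    "<enz_tunnel> id %d: length %.1f A, bottleneck %.2f A, curvature %.2f, priority %.3f\n",
    x$tunnel_id, x$length, x$bottleneck_radius, x$curvature, x$priority))
  invisible(x)
}

#' Tunnel priority (throughput) score
#'
#' \eqn{exp(-cost)} with cost the trapezoidal line integral of
#' \eqn{dl / r(l)^2} over the tunnel nodes. Short and wide tunnels score
#' near 1; long or narrow tunnels decay towards 0.
#'
#' @param tunnel an `enz_tunnel`.
#' @return priority in (0, 1].
#' @export
priority_score <- function(tunnel) {
  n <- tunnel$nodes
  if (nrow(n) < 2) return(1)
  seg <- sqrt(rowSums((n[-1, c("x", "y", "z")] - n[-nrow(n), c("x", "y", "z")])^2))
  invr2 <- 1 / pmax(n$clearance, 1e-3)^2
  cost <- sum(seg * 0.5 * (invr2[-length(invr2)] + invr2[-1]))
  exp(-cost)
}

#' Voronoi tunnel graph of a structure
#'
#' Lower-level access to the search graph used by [find_tunnels()]: Voronoi
#' vertices (Delaunay circumcenters) with clearances, edges between adjacent
#' tetrahedra with sampled minimum clearance and integrated cost, and
#' convex-hull exit faces.
#'
#' @param structure an `enz_structure`.
#' @param n_edge_samples clearance samples per edge (default 10).
#' @param probe_inflate probe radius used to inflate the hull exit points
#'   (default 0.9 A; exits sit at hull faces pushed out by
#'   `probe_inflate + max(vdW)`).
#' @return list with `nodes` (x, y, z, clearance), `edges` (from, to,
#'   min_clearance, cost, length) and `exits` (node, x, y, z — inflated hull
#'   exit points per boundary face).
#' @export
tunnel_graph <- function(structure, n_edge_samples = 10, probe_inflate = 0.9) {
  a <- structure$atoms
  pts <- .coords(structure)
  vdw <- a$vdw_radius
  dt <- delaunay3d_cpp(pts)
  nt <- nrow(dt$tets)
  k <- min(20L, nrow(pts))
  clearance_at <- function(q) {
    nn <- RANN::nn2(pts, q, k = k)
    apply(nn$nn.dists - matrix(vdw[nn$nn.idx], nrow = nrow(q)), 1, min)
  }
  node_cl <- clearance_at(dt$circ)
  nodes <- data.frame(x = dt$circ[, 1], y = dt$circ[, 2], z = dt$circ[, 3],
                      clearance = node_cl)

  # undirected edges from tet adjacency
  pair_from <- rep(seq_len(nt), 4)
  pair_to <- as.integer(dt$adj)
  keep <- pair_to > pair_from
  ef <- pair_from[keep]; et <- pair_to[keep]
  if (length(ef) > 0) {
    p0 <- dt$circ[ef, , drop = FALSE]
    p1 <- dt$circ[et, , drop = FALSE]
    tgrid <- seq(0, 1, length.out = n_edge_samples)
    samples <- do.call(rbind, lapply(tgrid, function(t) p0 + t * (p1 - p0)))
    scl <- matrix(clearance_at(samples), ncol = n_edge_samples)
    elen <- sqrt(rowSums((p1 - p0)^2))
    seg <- elen / (n_edge_samples - 1)
    invr2 <- 1 / pmax(scl, 1e-3)^2
    cost <- seg * rowSums(0.5 * (invr2[, -1, drop = FALSE] +
                                   invr2[, -n_edge_samples, drop = FALSE]))
    min_cl <- apply(scl, 1, min)
    # long edges (sliver circumcenters can sit far out) are resampled at
    # <= 0.5 A so a narrow crossing cannot slip between samples
    long <- which(elen > 0.5 * (n_edge_samples - 1))
    for (i in long) {
      m <- ceiling(elen[i] / 0.5) + 1L
      tg <- seq(0, 1, length.out = m)
      qs <- outer(1 - tg, p0[i, ]) + outer(tg, p1[i, ])
      cl <- clearance_at(qs)
      invl <- 1 / pmax(cl, 1e-3)^2
      cost[i] <- (elen[i] / (m - 1)) * sum(0.5 * (invl[-1] + invl[-m]))
      min_cl[i] <- min(cl)
    }
    edges <- data.frame(from = ef, to = et,
                        min_clearance = min_cl,
                        cost = cost, length = elen)
  } else {
    edges <- data.frame(from = integer(), to = integer(),
                        min_clearance = numeric(), cost = numeric(),
                        length = numeric())
  }

  # hull exit points: boundary faces pushed outward by probe + max vdW
  bt <- which(dt$adj == 0, arr.ind = TRUE)
  exits <- NULL
  if (nrow(bt) > 0) {
    inflate <- max(vdw) + probe_inflate
    acen <- colMeans(pts)
    ex <- t(vapply(seq_len(nrow(bt)), function(i) {
      tet <- bt[i, 1]; f <- bt[i, 2]
      vs <- dt$tets[tet, ]
      face <- vs[-f]
      cen <- colMeans(pts[face, , drop = FALSE])
      v1 <- pts[face[2], ] - pts[face[1], ]
      v2 <- pts[face[3], ] - pts[face[1], ]
      fn <- c(v1[2] * v2[3] - v1[3] * v2[2],
              v1[3] * v2[1] - v1[1] * v2[3],
              v1[1] * v2[2] - v1[2] * v2[1])
      # hull faces point away from the atom centroid (strictly inside the
      # hull) — robust where the tet's fourth vertex is almost coplanar
      if (sum(fn * (cen - acen)) < 0) fn <- -fn
      fnorm <- sqrt(sum(fn^2))
      # collinear face vertices give a degenerate normal; such faces take a
      # zero plane (never classifies a node as outside) and exit at the
      # face centroid
      fn <- if (fnorm > 1e-6) fn / fnorm else c(0, 0, 0)
      c(tet, cen + inflate * fn, fn, sum(fn * pts[face[1], ]))
    }, numeric(8)))
    exits <- data.frame(node = as.integer(ex[, 1]),
                        x = ex[, 2], y = ex[, 3], z = ex[, 4])
    exits$clearance <- clearance_at(as.matrix(exits[, c("x", "y", "z")]))
    # circumcenters beyond any hull-face plane lie outside the convex hull:
    # such Voronoi vertices (of sliver surface tetrahedra) are bulk solvent
    signed <- dt$circ %*% t(ex[, 5:7, drop = FALSE]) -
      matrix(ex[, 8], nt, nrow(ex), byrow = TRUE)
    nodes$outside_hull <- apply(signed, 1, max) > 1e-6
  } else {
    nodes$outside_hull <- FALSE
  }
  list(nodes = nodes, edges = edges, exits = exits,
       atoms = pts, vdw = vdw, clearance_at = clearance_at)
}

# Re-center path nodes on the medial axis: pattern search in the plane
# perpendicular to the local tangent, maximizing clearance. Moves are capped
# so nodes cannot jump into a neighbouring void; clearance never decreases.
.refine_path_nodes <- function(nodes, pts, vdw, max_shift = 1.2) {
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 3) return(nodes)
  k <- min(20L, nrow(pts))
  clearance_of <- function(q) {
    nn <- RANN::nn2(pts, q, k = k)
    apply(nn$nn.dists - matrix(vdw[nn$nn.idx], nrow = nrow(q)), 1, min)
  }
  cl <- clearance_of(xyz)
  orig <- xyz
  for (step in c(0.4, 0.2, 0.1)) {
    for (iter in 1:4) {
      tang <- rbind(xyz[2, ] - xyz[1, ],
                    (xyz[-(1:2), , drop = FALSE] - xyz[seq_len(n - 2), , drop = FALSE]) / 2,
                    xyz[n, ] - xyz[n - 1, ])
      tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-9)
      ref <- cbind(-tang[, 2], tang[, 1], rep(0, n))
      deg <- rowSums(ref^2) < 1e-12
      if (any(deg)) ref[deg, ] <- matrix(c(1, 0, 0), sum(deg), 3, byrow = TRUE)
      u1 <- ref - tang * rowSums(ref * tang)
      u1 <- u1 / pmax(sqrt(rowSums(u1^2)), 1e-9)
      u2 <- cbind(tang[, 2] * u1[, 3] - tang[, 3] * u1[, 2],
                  tang[, 3] * u1[, 1] - tang[, 1] * u1[, 3],
                  tang[, 1] * u1[, 2] - tang[, 2] * u1[, 1])
      improved <- FALSE
      for (dir in list(u1, -u1, u2, -u2)) {
        cand <- xyz + step * dir
        ccl <- clearance_of(cand)
        within <- sqrt(rowSums((cand - orig)^2)) <= max_shift
        better <- ccl > cl + 1e-6 & within
        if (any(better)) {
          xyz[better, ] <- cand[better, , drop = FALSE]
          cl[better] <- ccl[better]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
  }
  nodes$x <- xyz[, 1]; nodes$y <- xyz[, 2]; nodes$z <- xyz[, 3]
  nodes$clearance <- cl
  nodes
}

# resample a node polyline at uniform arc-length spacing, recomputing
# clearances at the interpolated points
.resample_path <- function(nodes, spacing, clearance_of) {
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  if (nrow(xyz) < 2) return(nodes)
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  at <- seq(0, L, length.out = max(2L, ceiling(L / spacing) + 1L))
  new_xyz <- cbind(stats::approx(arc, xyz[, 1], xout = at, rule = 2)$y,
                   stats::approx(arc, xyz[, 2], xout = at, rule = 2)$y,
                   stats::approx(arc, xyz[, 3], xout = at, rule = 2)$y)
  data.frame(x = new_xyz[, 1], y = new_xyz[, 2], z = new_xyz[, 3],
             clearance = clearance_of(new_xyz))
}

# mean nearest-node distance between two polyline node sets, symmetrized
.path_distance <- function(na, nb) {
  A <- as.matrix(na[, c("x", "y", "z")]); B <- as.matrix(nb[, c("x", "y", "z")])
  dab <- mean(RANN::nn2(B, A, k = 1)$nn.dists)
  dba <- mean(RANN::nn2(A, B, k = 1)$nn.dists)
  (dab + dba) / 2
}

#' Find tunnels from a start point to the protein surface
#'
#' Lowest-cost probe-constrained paths on the Voronoi graph; candidate
#' surface exits are clustered into distinct tunnels (single-linkage on mean
#' centerline distance, cutoff `cluster_cutoff`), the cheapest path per
#' cluster is kept, and tunnels are ranked by decreasing priority.
#'
#' @param structure an `enz_structure`.
#' @param start 3-vector, the tunnel start point (see [define_start_point()]).
#' @param probe_radius minimum clearance everywhere along a tunnel, in
#'   angstroms (default 0.9).
#' @param max_tunnels maximum number of tunnels returned (default 3, the
#'   screening convention).
#' @param cluster_cutoff path-clustering cutoff in angstroms (default 3.5).
#' @param snap_radius maximum distance allowed between `start` and the
#'   nearest free Voronoi vertex (default 8 A).
#' @param solvent_probe probe radius (A) of the bulk-solvent flood fill
#'   (default 2.6): the solvent region is the space reachable from outside
#'   the convex hull by a sphere of this radius, and tunnels terminate at
#'   its boundary. Channels wider than this everywhere are treated as open
#'   solvent, not tunnels.
#' @param refine_nodes re-center tunnel nodes on the medial axis by local
#'   clearance maximization (default TRUE; improves bottleneck estimates on
#'   coarse Voronoi graphs).
#' @param graph optional precomputed [tunnel_graph()].
#' @return list of `enz_tunnel`, ranked by priority (possibly empty when no
#'   probe-admissible path to the surface exists).
#' @export
find_tunnels <- function(structure, start, probe_radius = 0.9,
                         max_tunnels = 3, cluster_cutoff = 3.5,
                         snap_radius = 8, solvent_probe = 2.6,
                         refine_nodes = TRUE, graph = NULL) {
  g <- graph %||% tunnel_graph(structure, probe_inflate = probe_radius)
  nodes <- g$nodes
  nn_nodes <- nrow(nodes)
  if (is.null(g$exits)) return(list())

  # bulk solvent: flood fill from the hull boundary over wide edges (the
  # space a `solvent_probe` sphere can reach from outside). Hull-adjacent
  # nodes are always solvent seeds; reachability from the start keeps exits
  # confined to genuine openings.
  solv_edges <- g$edges[g$edges$min_clearance >= solvent_probe, , drop = FALSE]
  solvent <- rep(FALSE, nn_nodes)
  seeds <- unique(c(g$exits$node, which(nodes$outside_hull %||% FALSE)))
  solvent[seeds] <- TRUE
  if (length(seeds) > 0 && nrow(solv_edges) > 0) {
    gs <- igraph::graph_from_data_frame(
      solv_edges[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = seq_len(nn_nodes)))
    comp <- igraph::components(gs)$membership
    solvent <- solvent | comp %in% unique(comp[seeds])
  }

  free <- which(nodes$clearance > probe_radius & !solvent)
  if (length(free) == 0)
    stop_enzport("enzport_snap_failure",
                 "no free interior Voronoi vertex: start in solid or in open solvent")
  d2start <- (nodes$x[free] - start[1])^2 + (nodes$y[free] - start[2])^2 +
    (nodes$z[free] - start[3])^2
  if (min(d2start) > snap_radius^2)
    stop_enzport("enzport_snap_failure",
                 sprintf("start point further than %.1f A from free space", snap_radius))
  s <- free[which.min(d2start)]

  adm <- g$edges$min_clearance >= probe_radius
  interior_e <- adm & !solvent[g$edges$from] & !solvent[g$edges$to]
  e <- g$edges[interior_e, , drop = FALSE]
  if (nrow(e) == 0) return(list())
  gr <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, weight = e$cost),
    directed = FALSE, vertices = data.frame(name = seq_len(nn_nodes)))
  dists <- igraph::distances(gr, v = as.character(s), algorithm = "dijkstra")[1, ]
  dists <- dists[as.character(seq_len(nn_nodes))]

  # exit candidates: probe-admissible crossings from the reachable interior
  # into bulk solvent, plus direct hull-face exits of interior nodes
  cross <- g$edges[adm & xor(solvent[g$edges$from], solvent[g$edges$to]), ,
                   drop = FALSE]
  cand <- NULL
  if (nrow(cross) > 0) {
    inn <- ifelse(solvent[cross$from], cross$to, cross$from)
    outn <- ifelse(solvent[cross$from], cross$from, cross$to)
    cand <- data.frame(node = inn, x = nodes$x[outn], y = nodes$y[outn],
                       z = nodes$z[outn], clearance = nodes$clearance[outn],
                       hop_cost = cross$cost)
  }
  ex <- g$exits[!solvent[g$exits$node] & g$exits$clearance >= probe_radius &
                  nodes$clearance[g$exits$node] > probe_radius, , drop = FALSE]
  if (nrow(ex) > 0) {
    hop_len <- sqrt((ex$x - nodes$x[ex$node])^2 + (ex$y - nodes$y[ex$node])^2 +
                      (ex$z - nodes$z[ex$node])^2)
    hop_cost <- hop_len * 0.5 * (1 / pmax(nodes$clearance[ex$node], 1e-3)^2 +
                                   1 / pmax(ex$clearance, 1e-3)^2)
    cand <- rbind(cand, data.frame(node = ex$node, x = ex$x, y = ex$y,
                                   z = ex$z, clearance = ex$clearance,
                                   hop_cost = hop_cost))
  }
  if (is.null(cand) || nrow(cand) == 0) return(list())
  cand <- cand[is.finite(dists[cand$node]), , drop = FALSE]
  if (nrow(cand) == 0) return(list())
  cand$total_cost <- dists[cand$node] + cand$hop_cost
  cand <- cand[order(cand$total_cost), , drop = FALSE]
  cand <- utils::head(cand, 60L)

  k <- min(20L, nrow(g$atoms))
  clearance_of <- function(q) {
    nn <- RANN::nn2(g$atoms, q, k = k)
    apply(nn$nn.dists - matrix(g$vdw[nn$nn.idx], nrow = nrow(q)), 1, min)
  }
  paths <- lapply(seq_len(nrow(cand)), function(i) {
    vp <- igraph::shortest_paths(gr, from = as.character(s),
                                 to = as.character(cand$node[i]),
                                 algorithm = "dijkstra")$vpath[[1]]
    vid <- as.integer(igraph::as_ids(vp))
    nd <- nodes[vid, c("x", "y", "z", "clearance"), drop = FALSE]
    nd <- rbind(nd, data.frame(x = cand$x[i], y = cand$y[i], z = cand$z[i],
                               clearance = cand$clearance[i]))
    rownames(nd) <- NULL
    # clip the terminal hop at the bulk-solvent boundary (sampled at fixed
    # 0.5 A steps: the terminal Voronoi vertex of a sliver surface
    # tetrahedron can lie hundreds of angstroms outside)
    n0 <- nrow(nd)
    p0 <- as.numeric(nd[n0 - 1, c("x", "y", "z")])
    p1 <- as.numeric(nd[n0, c("x", "y", "z")])
    m <- max(20L, ceiling(sqrt(sum((p1 - p0)^2)) / 0.5))
    tt <- seq_len(m) / m
    qs <- outer(1 - tt, p0) + outer(tt, p1)
    qcl <- clearance_of(qs)
    hit <- which(qcl >= solvent_probe)
    if (length(hit) > 0) {
      nd[n0, c("x", "y", "z")] <- qs[hit[1], ]
      nd$clearance[n0] <- qcl[hit[1]]
    }
    nd
  })

  if (length(paths) > 1) {
    pd <- matrix(0, length(paths), length(paths))
    for (i in seq_along(paths)) for (j in seq_len(i - 1L)) {
      pd[i, j] <- pd[j, i] <- .path_distance(paths[[i]], paths[[j]])
    }
    cl <- stats::cutree(stats::hclust(stats::as.dist(pd), method = "single"),
                        h = cluster_cutoff)
  } else cl <- 1L

  reps <- vapply(unique(cl), function(ki) which(cl == ki)[1], integer(1))
  tunnels <- lapply(reps, function(i) {
    nd <- .resample_path(paths[[i]], 0.5, clearance_of)
    if (refine_nodes) nd <- .refine_path_nodes(nd, g$atoms, g$vdw)
    new_tunnel(NA_integer_, nd)
  })
  pr <- vapply(tunnels, function(t) t$priority, numeric(1))
  tunnels <- tunnels[order(-pr)]
  tunnels <- utils::head(tunnels, max_tunnels)
  for (i in seq_along(tunnels)) tunnels[[i]]$tunnel_id <- i
  tunnels
}

#' Define the tunnel start point inside a pocket
#'
#' Default strategy `"deepest-sphere"`: the center of the pocket alpha
#' sphere most deeply buried below the convex hull of the structure.
#' Strategy `"central-residue"`: the centroid of the pocket-lining residue
#' closest to the center of the structure (the recommendation for starting
#' tunnel searches from the deep part of the pocket).
#'
#' @param pocket an `enz_pocket`.
#' @param structure parent `enz_structure`.
#' @param strategy `"deepest-sphere"` (default) or `"central-residue"`.
#' @return 3-vector (angstroms).
#' @export
define_start_point <- function(pocket, structure,
                               strategy = c("deepest-sphere", "central-residue")) {
  strategy <- match.arg(strategy)
  a <- structure$atoms
  if (strategy == "central-residue") {
    cen <- colMeans(.coords(structure))
    lin <- pocket$lining_residues
    key <- paste(a$chain_id, a$residue_number)
    cents <- t(vapply(seq_len(nrow(lin)), function(i) {
      idx <- which(key == paste(lin$chain_id[i], lin$residue_number[i]))
      colMeans(as.matrix(a[idx, c("x", "y", "z")]))
    }, numeric(3)))
    return(as.numeric(cents[which.min(rowSums((cents - matrix(cen, nrow(cents), 3,
                                                              byrow = TRUE))^2)), ]))
  }
  # burial depth = distance to the convex hull boundary (min over hull-face
  # planes), evaluated at each alpha-sphere center
  pts <- .coords(structure)
  dt <- delaunay3d_cpp(pts)
  bt <- which(dt$adj == 0, arr.ind = TRUE)
  cen <- as.matrix(pocket$spheres[, c("x", "y", "z")])
  depth <- rep(Inf, nrow(cen))
  for (i in seq_len(nrow(bt))) {
    vs <- dt$tets[bt[i, 1], ]
    face <- vs[-bt[i, 2]]; opp <- vs[bt[i, 2]]
    p1 <- pts[face[1], ]
    v1 <- pts[face[2], ] - p1; v2 <- pts[face[3], ] - p1
    fn <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (sum(fn * (colMeans(pts[face, , drop = FALSE]) - pts[opp, ])) < 0) fn <- -fn
    fn <- fn / sqrt(sum(fn^2))
    d <- abs((cen - matrix(p1, nrow(cen), 3, byrow = TRUE)) %*% fn)
    depth <- pmin(depth, as.numeric(d))
  }
  as.numeric(cen[which.max(depth), ])
}

#' Bin a tunnel by length
#'
#' Short below 5 A, medium in the closed interval 5 to 15 A, long above
#' 15 A.
#'
#' @param tunnel an `enz_tunnel` (or a numeric length in angstroms).
#' @return one of `"short"`, `"medium"`, `"long"`.
#' @export
bin_tunnel_length <- function(tunnel) {
  len <- if (inherits(tunnel, "enz_tunnel")) tunnel$length else tunnel
  stopifnot(len >= 0)
  if (len < 5) "short" else if (len <= 15) "medium" else "long"
}

#' Select relevant tunnels
#'
#' The union of the first `top_n` ranked tunnels and every tunnel with
#' priority above `priority_cutoff`, rank order preserved.
#'
#' @param tunnels ranked list of `enz_tunnel`.
#' @param priority_cutoff priority threshold (default 0.55).
#' @param top_n always-kept head count (default 3).
#' @return sublist of `tunnels`.
#' @export
select_relevant <- function(tunnels, priority_cutoff = 0.55, top_n = 3) {
  if (length(tunnels) == 0) return(tunnels)
  keep <- seq_along(tunnels) <= top_n |
    vapply(tunnels, function(t) t$priority, numeric(1)) > priority_cutoff
  tunnels[keep]
}

#' Count common tunnels between two structures
#'
#' Greedy one-to-one matching over the top `top_n` tunnels of each set
#' (structures must already be in a common frame): two tunnels match when
#' the symmetrized mean nearest-node distance between their centerlines is
#' below `centerline_cutoff`.
#'
#' @param tunnels_a,tunnels_b ranked tunnel lists.
#' @param top_n head size considered on each side (default 5).
#' @param centerline_cutoff match cutoff in angstroms (default 3).
#' @return integer number of matched pairs.
#' @export
match_tunnel_sets <- function(tunnels_a, tunnels_b, top_n = 5,
                              centerline_cutoff = 3) {
  ta <- utils::head(tunnels_a, top_n); tb <- utils::head(tunnels_b, top_n)
  if (length(ta) == 0 || length(tb) == 0) return(0L)
  dm <- matrix(Inf, length(ta), length(tb))
  for (i in seq_along(ta)) for (j in seq_along(tb))
    dm[i, j] <- .path_distance(ta[[i]]$nodes, tb[[j]]$nodes)
  n <- 0L
  while (TRUE) {
    m <- which(dm == min(dm), arr.ind = TRUE)[1, , drop = TRUE]
    if (!is.finite(dm[m[1], m[2]]) || dm[m[1], m[2]] >= centerline_cutoff) break
    n <- n + 1L
    dm[m[1], ] <- Inf; dm[, m[2]] <- Inf
    if (all(!is.finite(dm))) break
  }
  n
}

#' Discretize a tunnel into oriented discs
#'
#' Discs are sampled uniformly along the centerline arc length at intervals
#' of at most `spacing`; each disc's normal is the local tangent (central
#' difference) and its radius the linearly interpolated clearance. The first
#' disc sits at the pocket end, the last at the surface end.
#'
#' @param tunnel an `enz_tunnel` with at least 2 nodes.
#' @param spacing maximum arc-length distance between consecutive discs
#'   (default 0.3 A).
#' @return data frame: index, cx, cy, cz, nx, ny, nz, radius, distance.
#' @export
discretize_tunnel <- function(tunnel, spacing = 0.3) {
  stopifnot(spacing > 0)
  n <- tunnel$nodes
  if (nrow(n) < 2)
    stop_enzport("enzport_degenerate_tunnel",
                 "tunnel has fewer than 2 nodes; cannot discretize")
  xyz <- as.matrix(n[, c("x", "y", "z")])
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  nd0 <- max(2L, ceiling(L / spacing) + 1L)
  # node arc positions are kept among the samples so radius extremes (the
  # bottleneck in particular) are preserved exactly
  at <- sort(unique(c(seq(0, L, length.out = nd0), arc)))
  nd <- length(at)
  interp <- function(v) stats::approx(arc, v, xout = at, rule = 2)$y
  cx <- interp(xyz[, 1]); cy <- interp(xyz[, 2]); cz <- interp(xyz[, 3])
  r <- interp(n$clearance)
  cmat <- cbind(cx, cy, cz)
  tang <- rbind(cmat[2, ] - cmat[1, ],
                (cmat[-(1:2), , drop = FALSE] -
                   cmat[seq_len(nd - 2), , drop = FALSE]) / 2,
                cmat[nd, ] - cmat[nd - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  data.frame(index = seq_len(nd), cx = cx, cy = cy, cz = cz,
             nx = tang[, 1], ny = tang[, 2], nz = tang[, 3],
             radius = r, distance = at)
}

#' Write a tunnel as a pseudo-atom PDB
#'
#' Nodes become HETATM pseudo-atoms with the clearance radius in the
#' B-factor column (the common tunnel-viewer convention).
#'
#' @param tunnel an `enz_tunnel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tunnel_pdb <- function(tunnel, path) {
  n <- tunnel$nodes
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(n[, c("x", "y", "z")]))),
    type = rep("HETATM", nrow(n)), resno = rep(tunnel$tunnel_id, nrow(n)),
    resid = rep("TUN", nrow(n)), eleno = seq_len(nrow(n)),
    elety = rep("C", nrow(n)), chain = rep("T", nrow(n)),
    o = rep(1, nrow(n)), b = n$clearance, elesy = rep("C", nrow(n))
  )
  invisible(path)
}

#' Summarize tunnels as a TSV table
#'
#' @param tunnels list of `enz_tunnel`.
#' @param path optional output TSV path.
#' @return the summary data frame (id, length, bottleneck, curvature,
#'   throughput, priority, length bin), invisibly written to `path` if given.
#' @export
tunnel_summary <- function(tunnels, path = NULL) {
  df <- do.call(rbind, lapply(tunnels, function(t) data.frame(
    tunnel_id = t$tunnel_id, length = t$length,
    bottleneck_radius = t$bottleneck_radius, curvature = t$curvature,
    throughput = t$throughput, priority = t$priority,
    length_bin = bin_tunnel_length(t))))
  if (is.null(df)) df <- data.frame(tunnel_id = integer(), length = numeric(),
                                    bottleneck_radius = numeric(),
                                    curvature = numeric(), throughput = numeric(),
                                    priority = numeric(), length_bin = character())
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  df
}
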