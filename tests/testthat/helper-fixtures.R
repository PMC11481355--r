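# Shared fixtures (computed once per test run) and independent oracles.
# Oracles are deliberately written as plain, slow R so they share no code
# path with the implementation they check.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# quick structure builder from a coordinate matrix
structure_from_points <- function(pts, vdw = 1.7, element = "C",
                                  residue_name = "SHL", chain = "A",
                                  b_factor = 0) {
  n <- nrow(pts)
  atoms <- data.frame(
    serial = seq_len(n), name = element, element = element,
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    vdw_radius = vdw, chain_id = chain, residue_number = seq_len(n),
    residue_name = residue_name, is_hetero = FALSE, occupancy = 1,
    b_factor = b_factor, alt = "", model = 1L
  )
  enzport:::new_structure(atoms)
}

ligand_from_points <- function(pts, het_code = "LIG") {
  n <- nrow(pts)
  atoms <- data.frame(
    serial = seq_len(n) + 90000L, name = "C", element = "C",
    x = pts[, 1], y = pts[, 2], z = pts[, 3],
    vdw_radius = 1.7, chain_id = "L", residue_number = 900L,
    residue_name = het_code, is_hetero = TRUE, occupancy = 1,
    b_factor = 0, alt = "", model = 1L
  )
  enzport:::new_ligand_instance(het_code, atoms)
}

# pocket with hand-set spheres/features, for selection-rule fixtures
pocket_from_spheres <- function(centers, radii, pocket_id = 0L,
                                druggability = 0.5, apolar = TRUE) {
  spheres <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        radius = radii, a1 = 1L, a2 = 1L, a3 = 1L, a4 = 1L,
                        apolar = apolar)
  p <- enzport:::new_pocket(pocket_id, spheres,
                            data.frame(chain_id = "A", residue_number = 1L))
  f <- stats::setNames(numeric(20), pocket_feature_names())
  f[["druggability_score"]] <- druggability
  p$features <- f
  p
}

tunnel_from_nodes <- function(xyz, clearance, id = 1L) {
  enzport:::new_tunnel(id, data.frame(x = xyz[, 1], y = xyz[, 2],
                                      z = xyz[, 3], clearance = clearance))
}

two_tube_spec <- function(seed = 1) {
  shell_spec(tubes = list(list(direction = c(1, 0, 0), bottleneck = 2.0),
                          list(direction = c(0, -1, 0), bottleneck = 1.2)),
             seed = seed)
}

fixture_two_tube <- function() fixture("two_tube", function() {
  shell <- make_shell_protein(two_tube_spec(seed = 1))
  graph <- tunnel_graph(shell$structure)
  tunnels <- find_tunnels(shell$structure, c(0, 0, 0), probe_radius = 0.9,
                          graph = graph)
  list(shell = shell, graph = graph, tunnels = tunnels)
})

fixture_sealed <- function() fixture("sealed", function() {
  make_shell_protein(shell_spec(seed = 2))
})

fixture_shell_pockets <- function() fixture("shell_pockets", function() {
  st <- fixture_two_tube()$shell$structure
  spheres <- suppressMessages(detect_alpha_spheres(st))
  pockets <- cluster_pockets(spheres, st)
  list(structure = st, spheres = spheres, pockets = pockets)
})

# ---------------------------------------------------------------------------
# oracles

# brute-force alpha spheres: all C(n,4) quadruples, both tangent-sphere
# roots, empty-interior check
oracle_alpha_spheres <- function(pts, vdw, r_min, r_max) {
  n <- nrow(pts)
  found <- NULL
  for (q in utils::combn(n, 4, simplify = FALSE)) {
    a <- pts[q, , drop = FALSE]
    w <- vdw[q]
    M <- 2 * (a[2:4, ] - matrix(a[1, ], 3, 3, byrow = TRUE))
    if (abs(det(M)) < 1e-9) next
    b0 <- rowSums(a[2:4, ]^2) - sum(a[1, ]^2) - (w[2:4]^2 - w[1]^2)
    b1 <- -2 * (w[2:4] - w[1])
    c0 <- solve(M, b0); c1 <- solve(M, b1)
    d <- c0 - a[1, ]
    qa <- sum(c1^2) - 1
    qb <- 2 * (sum(d * c1) - w[1])
    qc <- sum(d^2) - w[1]^2
    roots <- if (abs(qa) < 1e-12) {
      if (abs(qb) > 1e-12) -qc / qb else numeric(0)
    } else {
      disc <- qb^2 - 4 * qa * qc
      if (disc < 0) numeric(0)
      else (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)
    }
    for (r in roots) {
      if (r < r_min || r > r_max) next
      cen <- c0 + r * c1
      dist <- sqrt(rowSums((pts - matrix(cen, n, 3, byrow = TRUE))^2))
      dist[q] <- Inf
      if (all(dist >= r + vdw - 1e-6 | seq_len(n) %in% q))
        found <- rbind(found, c(cen, r))
    }
  }
  found
}

# connected components of the distance-cutoff graph by BFS
oracle_components <- function(cen, cutoff) {
  n <- nrow(cen)
  dm <- as.matrix(stats::dist(cen))
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(dm[v, ] <= cutoff & comp == 0))
    }
  }
  comp
}

# Shrake-Rupley SASA with seeded random directions (independent point set)
oracle_sasa <- function(pts, radii, probe = 1.4, n_points = 2000, seed = 99) {
  set.seed(seed)
  z <- runif(n_points, -1, 1)
  th <- runif(n_points, 0, 2 * pi)
  dirs <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  n <- nrow(pts)
  area <- numeric(n)
  for (i in seq_len(n)) {
    R <- radii[i] + probe
    q <- matrix(pts[i, ], n_points, 3, byrow = TRUE) + R * dirs
    freep <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      Rj <- radii[j] + probe
      dj2 <- rowSums((q - matrix(pts[j, ], n_points, 3, byrow = TRUE))^2)
      freep <- freep & dj2 >= Rj^2
    }
    area[i] <- 4 * pi * R^2 * mean(freep)
  }
  area
}

# Bellman-Ford single-source distances by repeated edge relaxation
oracle_shortest_costs <- function(edges, n_nodes, source) {
  d <- rep(Inf, n_nodes)
  d[source] <- 0
  ft <- c(edges$from, edges$to)
  tt <- c(edges$to, edges$from)
  ww <- c(edges$cost, edges$cost)
  repeat {
    cand <- d[ft] + ww
    dn <- d
    upd <- tapply(cand, tt, min)
    idx <- as.integer(names(upd))
    dn[idx] <- pmin(dn[idx], unname(upd))
    if (all(dn >= d - 1e-12)) break
    d <- dn
  }
  d
}

# two-sample KS statistic as an explicit ECDF sup difference
oracle_ks_stat <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(g) mean(x <= g), numeric(1))
  Fy <- vapply(grid, function(g) mean(y <= g), numeric(1))
  max(abs(Fx - Fy))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}
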