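test_that("tunnels recover the constructed tubes of the synthetic shell", {
  fx <- fixture_two_tube()
  tt <- fx$tunnels
  gt <- fx$shell$ground_truth
  expect_length(tt, 2)
  # wider tube ranked first
  expect_equal(tt[[1]]$bottleneck_radius, gt[[1]]$bottleneck_radius,
               tolerance = 0.3 / gt[[1]]$bottleneck_radius)
  expect_equal(tt[[2]]$bottleneck_radius, gt[[2]]$bottleneck_radius,
               tolerance = 0.3 / gt[[2]]$bottleneck_radius)
  for (i in 1:2)
    expect_lt(abs(tt[[i]]$length - gt[[i]]$length) / gt[[i]]$length, 0.15)
  # exits lie along the tube axes
  for (i in 1:2) {
    en <- as.numeric(tt[[i]]$nodes[nrow(tt[[i]]$nodes), c("x", "y", "z")])
    expect_gt(sum(en * gt[[i]]$axis) / sqrt(sum(en^2)), 0.95)
  }
})

test_that("the probe radius filters tunnels and sealed shells yield none", {
  fx <- fixture_two_tube()
  expect_length(find_tunnels(fx$shell$structure, c(0, 0, 0),
                             probe_radius = 2.5, graph = fx$graph), 0)
  sealed <- fixture_sealed()
  expect_length(find_tunnels(sealed$structure, c(0, 0, 0),
                             probe_radius = 0.9), 0)
})

test_that("accepted tunnels satisfy the clearance and ranking invariants", {
  tt <- fixture_two_tube()$tunnels
  for (t in tt) {
    expect_true(all(t$nodes$clearance >= 0.9))
    expect_equal(t$bottleneck_radius, min(t$nodes$clearance))
    expect_gte(t$curvature, 1)
    seg <- sqrt(rowSums((t$nodes[-1, c("x", "y", "z")] -
                           t$nodes[-nrow(t$nodes), c("x", "y", "z")])^2))
    expect_equal(t$length, sum(seg))
  }
  pr <- vapply(tt, function(t) t$priority, numeric(1))
  expect_true(all(diff(pr) <= 0))
  expect_equal(vapply(tt, function(t) t$tunnel_id, integer(1)),
               seq_along(tt))
})

test_that("path costs from the graph search match independent relaxation", {
  fx <- fixture_two_tube()
  g <- fx$graph
  probe <- 0.9
  e <- g$edges[g$edges$min_clearance >= probe, ]
  start_node <- which.min((g$nodes$x)^2 + (g$nodes$y)^2 + (g$nodes$z)^2 +
                            ifelse(g$nodes$clearance > probe, 0, Inf))
  gr <- igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, weight = e$cost),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(g$nodes))))
  d_impl <- igraph::distances(gr, v = as.character(start_node),
                              algorithm = "dijkstra")[1, ]
  d_impl <- d_impl[as.character(seq_len(nrow(g$nodes)))]
  d_oracle <- oracle_shortest_costs(e, nrow(g$nodes), start_node)
  fin <- is.finite(d_oracle)
  expect_equal(sum(fin), sum(is.finite(d_impl)))
  expect_equal(unname(d_impl[fin]), d_oracle[fin], tolerance = 1e-9)
})

test_that("priority has its closed form and refinement-oracle behaviour", {
  straight <- tunnel_from_nodes(cbind(0, 0, seq(0, 2, by = 0.5)),
                                clearance = rep(1, 5))
  expect_equal(straight$priority, exp(-2), tolerance = 1e-12)
  expect_equal(straight$throughput, straight$priority)
  # widening every node strictly increases priority
  wider <- tunnel_from_nodes(cbind(0, 0, seq(0, 2, by = 0.5)),
                             clearance = rep(1.3, 5))
  expect_gt(wider$priority, straight$priority)
  # trapezoidal integral matches a 10x-refined integration within 2%
  z <- seq(0, 10, length.out = 21)
  rfun <- function(z) 1.5 + 0.5 * sin(z / 2)
  coarse <- tunnel_from_nodes(cbind(0, 0, z), clearance = rfun(z))
  zf <- seq(0, 10, length.out = 201)
  cost_fine <- sum(diff(zf) * 0.5 * (1 / rfun(zf)[-201]^2 + 1 / rfun(zf)[-1]^2))
  expect_equal(-log(coarse$priority), cost_fine, tolerance = 0.02)
})

test_that("length bins use the 5 and 15 A boundaries", {
  expect_equal(bin_tunnel_length(4.9), "short")
  expect_equal(bin_tunnel_length(5.0), "medium")
  expect_equal(bin_tunnel_length(15.0), "medium")
  expect_equal(bin_tunnel_length(20), "long")
})

test_that("relevance selection unions the top-n with the priority cutoff", {
  mk <- function(p, id) {
    t <- tunnel_from_nodes(cbind(0, 0, c(0, -log(p))), clearance = c(1, 1),
                           id = id)
    t # priority = exp(-length) = p for unit radius
  }
  ts <- lapply(seq_along(c(0.9, 0.6, 0.4, 0.58)), function(i)
    mk(c(0.9, 0.6, 0.4, 0.58)[i], i))
  keep <- select_relevant(ts, priority_cutoff = 0.55, top_n = 3)
  expect_length(keep, 4) # rank 4 passes the cutoff
  low <- lapply(1:2, function(i) mk(c(0.3, 0.2)[i], i))
  expect_length(select_relevant(low, 0.55, 3), 2) # top-n dominates
  expect_length(select_relevant(list(), 0.55, 3), 0)
})

test_that("tunnel matching counts one-to-one centerline pairs", {
  set.seed(15)
  mk_path <- function(dir, n = 20) {
    z <- seq(0, 12, length.out = n)
    tunnel_from_nodes(outer(z, dir), clearance = rep(1.5, n))
  }
  a <- list(mk_path(c(1, 0, 0)), mk_path(c(0, 1, 0)),
            mk_path(c(0, 0, 1)), mk_path(c(1, 1, 0) / sqrt(2)))
  expect_equal(match_tunnel_sets(a, a), 4L)
  b_opp <- list(mk_path(c(-1, 0, 0)), mk_path(c(0, -1, 0)))
  expect_equal(match_tunnel_sets(a[1:2], b_opp), 0L)
  perturbed <- lapply(a, function(t) {
    t$nodes[, c("x", "y", "z")] <- t$nodes[, c("x", "y", "z")] +
      matrix(runif(3 * nrow(t$nodes), -0.5, 0.5), ncol = 3)
    t
  })
  expect_equal(match_tunnel_sets(a, perturbed, centerline_cutoff = 3), 4L)
})

test_that("disc discretization covers the centerline with oriented discs", {
  straight <- tunnel_from_nodes(cbind(0, 0, c(0, 3)),
                                clearance = c(2, 1.2))
  d <- discretize_tunnel(straight, spacing = 1)
  expect_equal(nrow(d), 4)
  expect_true(all(abs(d$cx) < 1e-9 & abs(d$cy) < 1e-9))
  expect_equal(d$nz, rep(1, 4)) # identical collinear normals
  expect_equal(min(d$radius), straight$bottleneck_radius, tolerance = 1e-6)
  expect_equal(d$distance, c(0, 1, 2, 3))
  # consecutive centers no further apart than the spacing
  dd <- discretize_tunnel(fixture_two_tube()$tunnels[[1]], spacing = 0.3)
  gaps <- sqrt(diff(dd$cx)^2 + diff(dd$cy)^2 + diff(dd$cz)^2)
  expect_true(all(gaps <= 0.3 + 1e-9))
  expect_equal(min(dd$radius),
               fixture_two_tube()$tunnels[[1]]$bottleneck_radius,
               tolerance = 1e-6)
  one_node <- list(nodes = data.frame(x = 0, y = 0, z = 0, clearance = 1))
  expect_error(discretize_tunnel(structure(one_node, class = "enz_tunnel")),
               class = "enzport_degenerate_tunnel")
})

test_that("disc normals on a helix stay within 5 degrees of analytic tangents", {
  R <- 3; c0 <- 0.8
  tpar <- seq(0, 4 * pi, length.out = 120)
  xyz <- cbind(R * cos(tpar), R * sin(tpar), c0 * tpar)
  hel <- tunnel_from_nodes(xyz, clearance = rep(1.5, length(tpar)))
  d <- discretize_tunnel(hel, spacing = 0.4)
  # analytic tangent at the nearest parameter point
  ana <- function(t) {
    v <- c(-R * sin(t), R * cos(t), c0)
    v / sqrt(sum(v^2))
  }
  angles <- vapply(seq(2, nrow(d) - 1, by = 7), function(i) {
    p <- c(d$cx[i], d$cy[i], d$cz[i])
    t0 <- p[3] / c0 # exact parameter inverse via z
    a <- ana(t0)
    n <- c(d$nx[i], d$ny[i], d$nz[i])
    acos(pmin(1, abs(sum(a * n)))) * 180 / pi
  }, numeric(1))
  expect_lt(max(angles), 5)
})

test_that("the start point sits deep in the pocket and translates with the structure", {
  fx <- fixture_shell_pockets()
  cavity <- fx$pockets[[1]]
  start <- define_start_point(cavity, fx$structure)
  expect_lt(sqrt(sum(start^2)), 2) # the cavity center is the origin
  # single-sphere pocket: that sphere's center
  sph <- cavity$spheres[which.max(cavity$spheres$radius), , drop = FALSE]
  p1 <- enzport:::new_pocket(0L, sph, cavity$lining_residues)
  s1 <- define_start_point(p1, fx$structure)
  expect_equal(s1, as.numeric(sph[1, c("x", "y", "z")]), tolerance = 1e-6)
  # translation equivariance
  shift <- c(5, -3, 2)
  st2 <- fx$structure
  st2$atoms$x <- st2$atoms$x + shift[1]
  st2$atoms$y <- st2$atoms$y + shift[2]
  st2$atoms$z <- st2$atoms$z + shift[3]
  p2 <- cavity
  p2$spheres$x <- p2$spheres$x + shift[1]
  p2$spheres$y <- p2$spheres$y + shift[2]
  p2$spheres$z <- p2$spheres$z + shift[3]
  expect_equal(define_start_point(p2, st2), start + shift, tolerance = 1e-4)
  # central-residue strategy returns a lining-residue centroid
  s3 <- define_start_point(cavity, fx$structure, strategy = "central-residue")
  expect_lt(sqrt(sum(s3^2)), fx$structure$atoms$vdw_radius[1] + 8)
})

test_that("removing atoms far from a tunnel never shrinks its bottleneck", {
  fx <- fixture_two_tube()
  st <- fx$shell$structure
  before <- fx$tunnels[[1]]$bottleneck_radius
  # delete a patch of wall on the far side (-x hemisphere, away from both tubes)
  a <- st$atoms
  drop <- a$x < -8 & abs(a$y) < 4 & abs(a$z) < 4
  st2 <- enzport:::new_structure(a[!drop, , drop = FALSE])
  tt2 <- find_tunnels(st2, c(0, 0, 0), probe_radius = 0.9)
  # the +x tube survives; find it by exit direction
  exits <- vapply(tt2, function(t)
    as.numeric(t$nodes[nrow(t$nodes), "x"]), numeric(1))
  surv <- tt2[[which.max(exits)]]
  # allow numerical noise from the re-triangulation and node refinement
  expect_gte(surv$bottleneck_radius, before - 0.05)
})

test_that("tunnel files round-trip through PDB and TSV writers", {
  tt <- fixture_two_tube()$tunnels
  f <- withr::local_tempfile(fileext = ".pdb")
  write_tunnel_pdb(tt[[1]], f)
  back <- bio3d::read.pdb(f)
  expect_equal(nrow(back$atom), nrow(tt[[1]]$nodes))
  expect_equal(back$atom$b, tt[[1]]$nodes$clearance, tolerance = 1e-2)
  g <- withr::local_tempfile(fileext = ".tsv")
  df <- tunnel_summary(tt, g)
  expect_equal(nrow(df), 2)
  expect_equal(df$length_bin, c("medium", "medium"))
  expect_equal(utils::read.delim(g)$tunnel_id, 1:2)
})
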