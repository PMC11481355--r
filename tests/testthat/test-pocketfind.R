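regular_tetrahedron <- function(edge) {
  rbind(c(0, 0, 0), c(edge, 0, 0), c(edge / 2, edge * sqrt(3) / 2, 0),
        c(edge / 2, edge * sqrt(3) / 6, edge * sqrt(2 / 3)))
}

test_that("the tangent sphere of a regular tetrahedron has its analytic radius", {
  st <- structure_from_points(regular_tetrahedron(9))
  s <- detect_alpha_spheres(st, 3, 6)
  expect_equal(nrow(s), 1)
  expect_equal(s$radius, 9 * sqrt(3 / 8) - 1.7, tolerance = 1e-4)
  expect_true(s$apolar) # four carbon contacts
  # edge 4: tangent radius ~0.75 falls below r_min
  st4 <- structure_from_points(regular_tetrahedron(4))
  expect_equal(nrow(detect_alpha_spheres(st4, 3, 6)), 0)
  # fewer than 4 atoms is degenerate
  expect_error(detect_alpha_spheres(structure_from_points(diag(3))),
               class = "enzport_degenerate_input")
})

test_that("alpha-sphere detection matches brute-force quadruple enumeration", {
  for (seed in 1:5) {
    set.seed(seed)
    pts <- matrix(runif(36, 0, 10), 12, 3)
    st <- structure_from_points(pts)
    impl <- detect_alpha_spheres(st, 1.0, 8.0)
    bf <- oracle_alpha_spheres(pts, rep(1.7, 12), 1.0, 8.0)
    n_bf <- if (is.null(bf)) 0L else nrow(bf)
    expect_equal(nrow(impl), n_bf)
    if (n_bf > 0) {
      ord_i <- order(impl$radius)
      ord_b <- order(bf[, 4])
      expect_equal(impl$radius[ord_i], bf[ord_b, 4], tolerance = 1e-4)
      expect_equal(as.matrix(impl[ord_i, c("x", "y", "z")]),
                   bf[ord_b, 1:3, drop = FALSE], tolerance = 1e-3,
                   ignore_attr = TRUE)
    }
  }
})

test_that("every detected alpha sphere has an atom-free interior", {
  fx <- fixture_shell_pockets()
  pts <- as.matrix(fx$structure$atoms[, c("x", "y", "z")])
  s <- fx$spheres
  idx <- seq(1, nrow(s), length.out = min(80, nrow(s)))
  for (i in as.integer(idx)) {
    d <- sqrt(rowSums((pts - matrix(c(s$x[i], s$y[i], s$z[i]),
                                    nrow(pts), 3, byrow = TRUE))^2))
    contacts <- c(s$a1[i], s$a2[i], s$a3[i], s$a4[i])
    d[contacts] <- Inf
    expect_gte(min(d - fx$structure$atoms$vdw_radius), s$radius[i] - 1e-4)
  }
})

test_that("sphere clustering equals connected components of the cutoff graph", {
  st <- fixture_two_tube()$shell$structure
  # two groups 20 A apart -> 2 pockets at cutoff 4
  g1 <- matrix(rnorm(30, 0, 1.5), 10, 3)
  g2 <- g1 + 20
  sph <- data.frame(rbind(g1, g2))
  names(sph) <- c("x", "y", "z")
  sph$radius <- 3.5; sph$a1 <- sph$a2 <- sph$a3 <- sph$a4 <- 1L
  sph$apolar <- TRUE
  pk <- cluster_pockets(sph, st, linkage_cutoff = 4, min_spheres = 1,
                        compute = FALSE)
  expect_length(pk, 2)
  expect_equal(vapply(pk, function(p) p$pocket_id, integer(1)), 0:1)
  # one chained cluster when everything sits within the cutoff
  chain <- cbind(seq(0, 27, by = 3), 0, 0)
  sph2 <- sph[1:10, ]; sph2[, c("x", "y", "z")] <- chain
  expect_length(cluster_pockets(sph2, st, linkage_cutoff = 4,
                                min_spheres = 1, compute = FALSE), 1)
  # random configurations against the BFS component oracle
  for (seed in 1:5) {
    set.seed(100 + seed)
    cen <- matrix(runif(90, 0, 25), 30, 3)
    sph3 <- sph[rep(1, 30), ]; sph3[, c("x", "y", "z")] <- cen
    pk3 <- cluster_pockets(sph3, st, linkage_cutoff = 5, min_spheres = 1,
                           compute = FALSE)
    comp <- oracle_components(cen, 5)
    expect_length(pk3, length(unique(comp)))
    sizes_impl <- sort(vapply(pk3, function(p) nrow(p$spheres), integer(1)))
    expect_equal(sizes_impl, sort(unname(as.integer(table(comp)))))
  }
})

test_that("pocket ids are a 0-based permutation in fpocket-score order", {
  pk <- fixture_shell_pockets()$pockets
  ids <- vapply(pk, function(p) p$pocket_id, integer(1))
  expect_equal(sort(ids), seq_along(pk) - 1L)
  scores <- vapply(pk, function(p) p$features[["fpocket_score"]], numeric(1))
  expect_equal(ids[order(-scores)], seq_along(pk) - 1L)
})

test_that("descriptor arithmetic: proportions, radii and volume", {
  st <- fixture_two_tube()$shell$structure
  sasa <- structure_sasa(st)
  sph <- data.frame(x = c(0, 1), y = 0, z = 0, radius = c(3.2, 4.8),
                    a1 = 1L, a2 = 2L, a3 = 3L, a4 = 4L,
                    apolar = c(TRUE, TRUE))
  p <- enzport:::new_pocket(0L, sph, enzport:::.pocket_lining(sph, st$atoms))
  f <- compute_features(p, st, sasa = sasa)
  expect_equal(unname(f[["mean_alpha_sphere_radius"]]), 4.0)
  expect_equal(unname(f[["apolar_sphere_proportion"]]), 1.0)
  expect_equal(unname(f[["n_alpha_spheres"]]), 2)
  expect_equal(names(f), pocket_feature_names())
  # deterministic for fixed input
  expect_identical(f, compute_features(p, st, sasa = sasa))
  # single sphere with 4 apolar contacts
  p1 <- enzport:::new_pocket(0L, sph[1, ],
                             enzport:::.pocket_lining(sph[1, ], st$atoms))
  expect_equal(unname(compute_features(p1, st, sasa = sasa)[["apolar_sphere_proportion"]]), 1)
})

test_that("grid union volume agrees with Monte Carlo sampling within 5%", {
  pk <- fixture_shell_pockets()$pockets[[1]]
  vol <- pk$features[["volume"]]
  cen <- as.matrix(pk$spheres[, c("x", "y", "z")])
  r <- pk$spheres$radius
  lo <- apply(cen - r, 2, min); hi <- apply(cen + r, 2, max)
  set.seed(7)
  n <- 4e5
  q <- cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]),
             runif(n, lo[3], hi[3]))
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(cen))) # plain per-sphere scan, no shared code
    inside <- inside | rowSums((q - matrix(cen[i, ], n, 3, byrow = TRUE))^2) <= r[i]^2
  mc <- mean(inside) * prod(hi - lo)
  expect_lt(abs(vol - mc) / mc, 0.05)
})

test_that("exposed ratio separates buried from exposed linings and matches a SASA oracle", {
  fx <- fixture_shell_pockets()
  cavity <- fx$pockets[[1]]
  expect_equal(exposed_ratio(cavity, fx$structure), 0)
  # fully exposed construction: a sparse ring of atoms, every residue free
  ring <- cbind(10 * cos(seq_len(8) * pi / 4), 10 * sin(seq_len(8) * pi / 4), 0)
  st_ring <- structure_from_points(ring)
  sph <- data.frame(x = 0, y = 0, z = 0, radius = 5,
                    a1 = 1L, a2 = 3L, a3 = 5L, a4 = 7L, apolar = TRUE)
  p_ring <- enzport:::new_pocket(0L, sph,
                                 enzport:::.pocket_lining(sph, st_ring$atoms))
  expect_equal(exposed_ratio(p_ring, st_ring), 1.0)
  # monotone: lowering the threshold never lowers the ratio
  st <- fx$structure
  sasa <- structure_sasa(st)
  some <- fx$pockets[[min(2, length(fx$pockets))]]
  ths <- c(0.05, 0.1, 0.2, 0.4)
  vals <- vapply(ths, function(th) exposed_ratio(some, st, th, sasa = sasa),
                 numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("per-residue relative SASA matches an independent implementation", {
  set.seed(31)
  pts <- matrix(runif(60, 0, 12), 20, 3)
  st <- structure_from_points(pts)
  sasa <- structure_sasa(st)
  area_o <- oracle_sasa(pts, rep(1.7, 20))
  # single-atom residues: relative SASA = context / isolated sphere area
  rel_o <- area_o / (4 * pi * (1.7 + 1.4)^2)
  # align: the residue table is keyed by chain+number, not atom order
  expect_lt(max(abs(sasa$residues$rel_sasa -
                      rel_o[sasa$residues$residue_number])), 0.05)
})

test_that("druggability is a logistic composite, monotone in hydrophobic density", {
  f0 <- stats::setNames(numeric(20), pocket_feature_names())
  f0[["hydrophobicity_score"]] <- -4.5 # normalizes to zero
  expect_equal(druggability_score(f0), 1 / (1 + exp(3)))
  vals <- vapply(seq(0, 60, by = 5), function(d) {
    f <- f0; f[["mean_local_hydrophobic_density"]] <- d
    druggability_score(f)
  }, numeric(1))
  expect_true(all(diff(vals) >= 0))
  # random feature vectors against the hand-evaluated formula
  set.seed(5)
  for (i in 1:20) {
    f <- f0
    f[["mean_local_hydrophobic_density"]] <- runif(1, 0, 80)
    f[["hydrophobicity_score"]] <- runif(1, -5, 5)
    f[["polarity_score"]] <- runif(1, 0, 1)
    nm <- function(x, lo, hi) min(1, max(0, (x - lo) / (hi - lo)))
    z <- -3 + 3.5 * nm(f[["mean_local_hydrophobic_density"]], 0, 60) +
      2.5 * nm(f[["hydrophobicity_score"]], -4.5, 4.5) -
      1 * nm(f[["polarity_score"]], 0, 1)
    expect_equal(druggability_score(f), 1 / (1 + exp(-z)), tolerance = 1e-9)
  }
})

test_that("pocket tables and alpha-sphere PDBs are written", {
  pk <- fixture_shell_pockets()$pockets
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pocket_table(pk, f)
  df <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(df), length(pk))
  expect_equal(names(df), c("pocket_id", pocket_feature_names()))
  g <- withr::local_tempfile(fileext = ".pdb")
  write_alpha_spheres_pdb(pk[[1]], g)
  reread <- bio3d::read.pdb(g)
  expect_equal(nrow(reread$atom), nrow(pk[[1]]$spheres))
})
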