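profile_from <- function(energy, radius = NULL, role = "product",
                         id = 1L, spacing = 0.5) {
  n <- length(energy)
  energy_profile(data.frame(distance = seq(0, by = spacing, length.out = n),
                            disc_radius = radius %||% rep(2, n),
                            energy = energy),
                 tunnel_id = id, ligand_role = role)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ligand roles map to transport directions", {
  expect_equal(direction_for_role("substrate"), "binding")
  expect_equal(direction_for_role("product"), "unbinding")
  expect_error(direction_for_role("inhibitor"), class = "enzport_config_error")
})

test_that("profile statistics extract the documented energies and barriers", {
  # flat profile: zero barrier
  flat <- profile_from(rep(-5, 20))
  sf <- profile_stats(flat)
  expect_equal(sf$e_a, 0)
  expect_equal(sf$e_bound, -5)
  # product: E_a = E_max - E_bound = 4 - (-8) = 12
  e <- c(-8, -8, 0, 4, 1, -2, -2, -2, -2, -2)
  sp <- profile_stats(profile_from(e, role = "product"))
  expect_equal(sp$e_bound, -8)
  expect_equal(sp$e_max, 4)
  expect_equal(sp$e_surface, -2)
  expect_equal(sp$e_a, 12)
  # substrate: E_a = E_max - E_surface = 6 - (-2) = 8
  e2 <- c(-8, -8, 0, 6, 1, -2, -2, -2, -2, -2)
  ss <- profile_stats(profile_from(e2, role = "substrate"))
  expect_equal(ss$e_a, 8)
  # barrier is never negative, argmax ties resolve to the pocket end
  expect_gte(sp$e_a, 0)
  tie <- profile_from(c(0, 3, 1, 3, 0, 0, 0, 0, 0, 0))
  expect_equal(profile_stats(tie)$argmax_distance, 0.5)
  # malformed profiles are rejected
  expect_error(energy_profile(data.frame(distance = c(0, 1), disc_radius = 2,
                                         energy = 0), ligand_role = "product"),
               class = "enzport_degenerate_profile")
  expect_error(energy_profile(data.frame(distance = c(0, 1, 1),
                                         disc_radius = 2, energy = 0),
                              ligand_role = "product"),
               class = "enzport_degenerate_profile")
})

test_that("first-third trimming removes floor(n/3) points, keeps distances", {
  p9 <- profile_from(seq_len(9))
  t9 <- trim_first_third(p9)
  expect_equal(nrow(t9), 6)
  expect_equal(t9$distance[1], p9$distance[4]) # not re-zeroed
  p10 <- profile_from(seq_len(10))
  expect_equal(nrow(trim_first_third(p10)), 7)
  # not idempotent: trimming twice removes more
  expect_lt(nrow(trim_first_third(trim_first_third(p10))), 7)
  # trimming never changes e_surface and never increases e_max (profiles
  # short enough that the surface window is the same single end point
  # before and after the trim)
  set.seed(2)
  for (i in 1:10) {
    p <- profile_from(rnorm(15))
    s0 <- profile_stats(p); s1 <- profile_stats(trim_first_third(p))
    expect_equal(s1$e_surface, s0$e_surface)
    expect_lte(s1$e_max, s0$e_max)
  }
  expect_error(trim_first_third(profile_from(1:3)[1:2, ]),
               class = "enzport_degenerate_profile")
})

test_that("the best tunnel has the lowest post-trim maximum energy", {
  mk <- function(peak, id) profile_from(c(9, 9, 0, peak, 0, 0, 0, 0, 0), id = id)
  expect_equal(best_tunnel(list(mk(3.0, 1L), mk(7.1, 2L), mk(9.4, 3L))), 1L)
  expect_equal(best_tunnel(list(mk(7.1, 2L))), 2L)
  # tie resolves to the lower tunnel id, order-invariantly
  tie <- list(mk(5, 3L), mk(5, 1L), mk(6, 2L))
  expect_equal(best_tunnel(tie), 1L)
  expect_equal(best_tunnel(rev(tie)), 1L)
  # the first-third trim protects against pocket-end clash peaks
  clash <- profile_from(c(50, 9, 0, 1, 0, 0, 0, 0, 0), id = 1L)
  calm <- profile_from(c(0, 0, 0, 2, 0, 0, 0, 0, 0), id = 2L)
  expect_equal(best_tunnel(list(clash, calm)), 1L)
  expect_error(best_tunnel(list()), class = "enzport_config_error")
})

test_that("bottleneck vicinity flags are thresholded and monotone", {
  r <- c(3, 3, 1.2, 3, 3, 3, 3, 3, 3, 3, 3)
  # argmax at the minimum-radius disc
  e <- c(0, 0, 5, 0, 0, 0, 0, 0, 0, 0, 0)
  bm <- bottleneck_match(profile_from(e, radius = r))
  expect_true(all(bm$vicinity_flags))
  # argmax 4 A away: only the 5 A flag
  e2 <- c(0, 0, 5, 0, 0, 0, 0, 0, 0, 0, 0)
  r2 <- c(3, 3, 3, 3, 3, 3, 3, 3, 3, 3, 1.2) # bottleneck at 5.0, argmax at 1.0
  bm2 <- bottleneck_match(profile_from(e2, radius = r2))
  expect_equal(unname(bm2$vicinity_flags), c(FALSE, FALSE, FALSE, TRUE))
  # random profiles against a direct scan
  set.seed(19)
  for (i in 1:10) {
    e3 <- rnorm(15); r3 <- runif(15, 1, 3)
    p <- profile_from(e3, radius = r3)
    bm3 <- bottleneck_match(p)
    gap <- abs(p$distance[which.max(e3)] - p$distance[which.min(r3)])
    expect_equal(unname(bm3$vicinity_flags),
                 c(gap <= 0.25, gap <= 1.5, gap <= 3, gap <= 5))
    expect_false(is.unsorted(bm3$vicinity_flags))
  }
  # frame mismatch: profile longer than the tunnel
  short_tunnel <- tunnel_from_nodes(cbind(0, 0, c(0, 1)), clearance = c(2, 2))
  expect_error(bottleneck_match(profile_from(rnorm(30)), short_tunnel),
               class = "enzport_frame_error")
})

test_that("barrier windows accept cognate-like profiles and reject outliers", {
  st <- list(e_max = -3, e_a = 4)
  expect_true(barrier_filter(st))
  expect_false(barrier_filter(list(e_max = 7, e_a = 4)))
  expect_false(barrier_filter(list(e_max = -3, e_a = 12)))
  expect_warning(ok <- barrier_filter(list(e_max = -3, e_a = -0.1)),
                 "invariant")
  expect_false(ok)
  # boundary values are inside the closed intervals
  expect_true(barrier_filter(list(e_max = 5, e_a = 10)))
  expect_true(barrier_filter(list(e_max = -10, e_a = 0)))
})

test_that("profile summaries compute window fractions and Pearson r", {
  mk_stats <- function(emax, ea, id = 1L)
    structure(list(e_bound = 0, e_max = emax, e_surface = 0, e_a = ea,
                   argmax_distance = 1, tunnel_id = id,
                   direction = "unbinding", ligand_role = "product"),
              class = "enz_profile_stats")
  all_in <- lapply(1:5, function(i) mk_stats(-2, 3, id = (i %% 3) + 1L))
  s <- summarize_profiles(all_in)
  expect_equal(s$frac_pass, 1)
  # affine relation: r = 1
  aff <- lapply(1:6, function(i) mk_stats(i, i - 3))
  expect_equal(summarize_profiles(aff)$pearson_emax_ea, 1.0)
  # random sets equal the textbook formula
  set.seed(4)
  emax <- rnorm(20); ea <- rnorm(20)
  rnd <- lapply(1:20, function(i) mk_stats(emax[i], ea[i]))
  expect_equal(summarize_profiles(rnd)$pearson_emax_ea,
               oracle_pearson(emax, ea), tolerance = 1e-12)
  # a single profile has no correlation
  expect_true(is.na(summarize_profiles(all_in[1])$pearson_emax_ea))
})

test_that("snapshot averaging is the per-tunnel mean with occurrence counts", {
  mk_stats <- function(emax, id)
    structure(list(e_bound = -5, e_max = emax, e_surface = -1, e_a = emax + 5,
                   argmax_distance = 1, tunnel_id = id,
                   direction = "unbinding", ligand_role = "product"),
              class = "enz_profile_stats")
  snaps <- list(list(mk_stats(2, 1L), mk_stats(5, 2L)),
                list(mk_stats(4, 1L)),
                list(mk_stats(3, 1L), mk_stats(7, 2L)))
  avg <- average_over_snapshots(snaps)
  expect_equal(avg[["1"]]$e_max, 3)
  expect_equal(avg[["1"]]$occurrence, 1)
  expect_equal(avg[["2"]]$e_max, 6)
  expect_equal(avg[["2"]]$occurrence, 2 / 3)
  # identical stats are a fixed point
  same <- list(list(mk_stats(2, 1L)), list(mk_stats(2, 1L)))
  expect_equal(average_over_snapshots(same)[["1"]]$e_max, 2)
})

test_that("profile TSVs and lower-bound text round-trip", {
  p <- make_profile("single_barrier", e_bound = -8, e_max = 4,
                    e_surface = -2, ligand_role = "product", seed = 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, f)
  back <- read_profile_tsv(f)
  expect_equal(back$energy, p$energy, tolerance = 1e-9)
  expect_equal(attr(back, "direction"), "unbinding")
  expect_equal(attr(back, "tunnel_id"), 1L)
  # lower-bound dialect: disc index + energy, converted through a disc table
  tun <- tunnel_from_nodes(cbind(0, 0, seq(0, 6, by = 0.5)),
                           clearance = rep(2, 13))
  discs <- discretize_tunnel(tun, spacing = 0.5)
  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# lower-bound energies",
               sprintf("%d %.2f", discs$index[1:10], seq(-5, 4, by = 1))), g)
  lb <- read_caverdock_profile(g, discs, tunnel_id = 2L,
                               ligand_role = "substrate")
  expect_equal(nrow(lb), 10)
  expect_equal(lb$distance, discs$distance[1:10])
  expect_equal(attr(lb, "direction"), "binding")
})
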