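small_sphere <- function(spacing, n_frames = 1)
  make_fixture("sphere", radius = 15, spacing = spacing, box = c(44, 44, 44),
               n_frames = n_frames)

test_that("cell-mode counts are conserved over bins", {
  sys <- small_sphere(3)
  p <- density_profile(sys, "all", "all", n = 4, mode = "cell")
  expect_equal(sum(p$count), nrow(sys$atoms))
  # and per-frame over a short trajectory
  sys3 <- small_sphere(3, n_frames = 3)
  p3 <- density_profile(sys3, "all", "all", n = 4, mode = "cell")
  expect_equal(sum(p3$count), 3 * nrow(sys3$atoms))
})

test_that("interior plateau recovers the constructed lattice density", {
  # lattice assemblies of known density rho = spacing^-3 across the
  # physically relevant range; all lengths scale with the spacing so each
  # assembly resolves the plateau window equally well (about 5 lattice
  # planes across it)
  for (rho in c(0.01, 0.0375, 0.1)) {
    s <- rho^(-1 / 3)
    sc <- s / 2.988
    sys <- make_fixture("sphere", radius = 29 * sc, spacing = s,
                        box = rep(80 * sc, 3))
    p <- density_profile(sys, "all", "all", n = 8, bin_width = sc,
                         mode = "atom")
    plateau <- profile_mean_density(p, -25 * sc, -10 * sc)
    expect_equal(plateau, rho, tolerance = 0.03)
  }
})

test_that("no structure atom registers outside its own hull (atom mode)", {
  sys <- small_sphere(3)
  p <- density_profile(sys, "all", "all", n = 4, mode = "atom")
  expect_equal(sum(p$count[p$r_lo >= 0]), 0)
})

test_that("undefined bins are reported as NA, never zero-filled", {
  sys <- small_sphere(3)
  p <- density_profile(sys, "all", "all", n = 4, bin_width = 1,
                       mode = "cell")
  # with 11 A cells and 1 A bins most bins hold no cell center
  expect_true(any(is.na(p$density)))
  expect_true(all(p$free_volume[!is.na(p$density)] > 0))
})

test_that("an empty target selection yields an all-zero-count profile", {
  sys <- small_sphere(3)
  p <- density_profile(sys, "all", "name NOSUCH", n = 4)
  expect_equal(sum(p$count), 0)
  expect_true(all(p$density[!is.na(p$density)] == 0))
})

test_that("a degenerate structure frame raises an error naming the frame", {
  sys <- small_sphere(3)
  sys$frames[[1]]$xyz[, 3] <- 1.0   # flatten -> coplanar structure
  expect_error(density_profile(sys, "all", "all", n = 4), "frame 0")
})

test_that("count_inside is exact for self, exterior and planted targets", {
  sys <- small_sphere(3)
  ci <- count_inside(sys, "all", "all")
  expect_equal(ci$count, nrow(sys$atoms))   # self-containment

  msh <- build_convex_hull(sys$frames[[1]]$xyz)
  bath <- make_fixture("solvent_bath", spacing = 3.2, box = c(44, 44, 44),
                       exclusion = msh)
  comb <- combine_systems(sys, bath)
  expect_equal(count_inside(comb, "resname FIX", "resname SOL")$count, 0)

  # plant k solvent atoms strictly inside and recount
  k <- 7L
  planted <- bath
  set.seed(21)
  inside_pts <- matrix(22 + runif(3 * k, -4, 4), ncol = 3)
  planted$frames[[1]]$xyz[seq_len(k), ] <- inside_pts
  comb2 <- combine_systems(sys, planted)
  expect_equal(count_inside(comb2, "resname FIX", "resname SOL")$count, k)
  # brute-force oracle over all target atoms
  oracle <- sum(oracle_signed_distance(msh, planted$frames[[1]]$xyz) <= 1e-9)
  expect_equal(oracle, k)
  # residue granularity agrees for single-atom residues
  expect_equal(count_inside(comb2, "resname FIX", "resname SOL",
                            granularity = "residue")$count, k)
})

test_that("volume series is constant for a static structure", {
  sys <- small_sphere(3, n_frames = 5)
  vs <- volume_series(sys, "all", area = TRUE)
  expect_equal(nrow(vs), 5)
  expect_equal(length(unique(vs$volume)), 1L)
  expect_equal(length(unique(vs$area)), 1L)
  # alpha at effectively infinite radius equals the hull frame by frame
  va <- volume_series(sys, "all", interface = "alpha", alpha = 1e6)
  expect_equal(va$volume, vs$volume)
})

test_that("frame parallelism does not change any result", {
  sys <- small_sphere(3, n_frames = 5)
  ref <- density_profile(sys, "all", "all", n = 4, workers = 1)
  for (w in c(2L, 4L)) {
    expect_identical(density_profile(sys, "all", "all", n = 4, workers = w),
                     ref)
  }
  expect_identical(volume_series(sys, "all", workers = 3L),
                   volume_series(sys, "all", workers = 1L))
})

test_that("the COM radial control smears aspherical interfaces", {
  cyl <- make_fixture("cylinder", radius = 12, half_height = 12, spacing = 3,
                      box = c(44, 44, 44))
  naive <- com_radial_profile(cyl, "all")
  intrinsic <- density_profile(cyl, "all", "all", n = 4, mode = "atom")
  # naive: mass appears beyond its own nominal surface; intrinsic: none
  expect_gt(sum(naive$count[naive$r_lo >= 0]), 0)
  expect_equal(sum(intrinsic$count[intrinsic$r_lo >= 0]), 0)
})
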