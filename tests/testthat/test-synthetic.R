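test_that("lattice fixtures realize the constructed number density", {
  sph <- make_fixture("sphere", radius = 29, spacing = 2.988,
                      box = c(80, 80, 80))
  expect_equal(nrow(sph$atoms), 3887L)     # frozen deterministic count
  achieved <- nrow(sph$atoms) / (4 / 3 * pi * 29^3)
  # the surface shell carries a small excess over spacing^-3 (~1.5% here)
  expect_equal(achieved, 2.988^-3, tolerance = 0.02)
  # interior counting balls recover the density up to the counting-shell
  # fluctuation of a ~3 A lattice (a few percent at these radii)
  d <- sqrt(rowSums(sweep(sph$frames[[1]]$xyz, 2, c(40, 40, 40))^2))
  for (rr in c(15, 20, 25))
    expect_equal(sum(d <= rr) / (4 / 3 * pi * rr^3), 2.988^-3,
                 tolerance = 0.04)
})

test_that("shape predicates hold for every generated point", {
  ctr <- c(40, 40, 40)
  sh <- make_fixture("hollow_shell", r_inner = 20, r_outer = 29, spacing = 3,
                     box = c(80, 80, 80))
  d <- sqrt(rowSums(sweep(sh$frames[[1]]$xyz, 2, ctr)^2))
  expect_true(all(d >= 20 & d <= 29))

  cyl <- make_fixture("cylinder", radius = 10, half_height = 14, spacing = 3,
                      box = c(40, 40, 40))
  dc <- sweep(cyl$frames[[1]]$xyz, 2, c(20, 20, 20))
  expect_true(all(dc[, 1]^2 + dc[, 2]^2 <= 100 & abs(dc[, 3]) <= 14))

  msh <- build_convex_hull(make_fixture("sphere", radius = 12, spacing = 3,
                                        box = c(40, 40, 40))$frames[[1]]$xyz)
  bath <- make_fixture("solvent_bath", spacing = 3.104, box = c(40, 40, 40),
                       exclusion = msh)
  expect_true(all(signed_distance(msh, bath$frames[[1]]$xyz) > 3.104))
})

test_that("generation is deterministic, also for random placement", {
  a <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30))
  b <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30))
  expect_identical(a$frames[[1]]$xyz, b$frames[[1]]$xyz)
  r1 <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30),
                     placement = "random", seed = 5)
  r2 <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30),
                     placement = "random", seed = 5)
  expect_identical(r1$frames[[1]]$xyz, r2$frames[[1]]$xyz)
  r3 <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30),
                     placement = "random", seed = 6)
  expect_false(identical(r1$frames[[1]]$xyz, r3$frames[[1]]$xyz))
  # random generation must not disturb the session RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(make_fixture("sphere", radius = 10, spacing = 3,
                                      box = c(30, 30, 30),
                                      placement = "random", seed = 9))
  expect_equal(runif(1), before)
})

test_that("shapes that do not fit the box are rejected", {
  expect_error(make_fixture("sphere", radius = 29, spacing = 3,
                            box = c(40, 40, 40)), "does not fit")
  expect_error(make_fixture("bent_rod", spacing = 2, arc_radius = 30,
                            tube_radius = 15, box = c(40, 40, 40)),
               "does not fit")
})

test_that("artificial wrapping splits shapes and is invertible", {
  sys <- make_fixture("sphere", radius = 10, spacing = 3, box = c(30, 30, 30))
  w0 <- wrap_artificially(sys, c(0, 0, 0))
  expect_equal(w0$frames[[1]]$xyz, sys$frames[[1]]$xyz)
  w <- wrap_artificially(sys, c(15, 0, 0))
  x <- w$frames[[1]]$xyz[, 1]
  expect_gt(sum(x < 5), 0)      # mass near both x faces
  expect_gt(sum(x > 25), 0)
  # unwrap via make_whole recovers all pairwise distances
  cl <- find_clusters(w, "all", cutoff = 3.5)
  fixed <- make_whole(w, residues = cl$clusters[[1]])
  expect_equal(as.matrix(dist(fixed$frames[[1]]$xyz)),
               as.matrix(dist(sys$frames[[1]]$xyz)), tolerance = 1e-9)
})

test_that("fixture files regenerate byte-identically", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  p1 <- write_fixtures(d1)
  p2 <- write_fixtures(d2)
  for (k in seq_along(p1)) {
    expect_identical(readLines(p1[k]), readLines(p2[k]))
  }
  back <- load_system(file.path(d1, "sphere.xyz"))
  expect_equal(nrow(back$atoms), 3887L)
})
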