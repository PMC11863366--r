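two_spheres <- function(sep = c(30, 0, 0), box = c(80, 80, 80)) {
  a <- make_fixture("sphere", radius = 8, spacing = 3, box = box)
  b <- make_fixture("sphere", radius = 8, spacing = 3, box = box)
  b$frames[[1]]$xyz <- b$frames[[1]]$xyz + rep(sep, each = nrow(b$atoms))
  combine_systems(a, b)
}

test_that("well-separated aggregates are recovered with their memberships", {
  sys <- two_spheres()
  cl <- find_clusters(sys, "all", cutoff = 3.5)
  expect_length(cl, 2)
  na <- length(cl$clusters[[1]])
  expect_equal(sort(unlist(cl$clusters)), sort(unique(sys$atoms$resid)))
  # planted membership: residues of sphere A vs sphere B
  half <- nrow(sys$atoms) / 2
  expect_true(setequal(cl$clusters[[1]], seq_len(half)) ||
              setequal(cl$clusters[[1]], half + seq_len(half)))
})

test_that("a cluster straddling the box face is found via minimum image", {
  sys <- two_spheres()
  w <- wrap_artificially(sys, c(37, 0, 0))   # splits one sphere at +x face
  cl <- find_clusters(w, "all", cutoff = 3.5)
  expect_length(cl, 2)
  # brute-force oracle: all-pairs minimum-image single linkage
  fr <- w$frames[[1]]
  lab <- oracle_components(min_image_dist(fr$xyz, fr$box), 3.5)
  expect_equal(length(unique(lab)), 2L)
  # same partition of residues
  got <- lapply(cl$clusters, sort)
  want <- lapply(split(w$atoms$resid, lab), function(r) sort(unique(r)))
  expect_true(setequal(lapply(got, paste, collapse = ","),
                       lapply(want, paste, collapse = ",")))
})

test_that("a cutoff below any spacing isolates every residue", {
  sys <- two_spheres()
  cl <- find_clusters(sys, "all", cutoff = 1.0)
  expect_length(cl, nrow(sys$atoms))
  expect_true(all(lengths(cl$clusters) == 1L))
})

test_that("clusters are ordered by size then smallest residue id", {
  a <- make_fixture("sphere", radius = 10, spacing = 3, box = c(80, 80, 80))
  b <- make_fixture("sphere", radius = 6, spacing = 3, box = c(80, 80, 80))
  b$frames[[1]]$xyz <- b$frames[[1]]$xyz + rep(c(30, 0, 0), each = nrow(b$atoms))
  sys <- combine_systems(a, b)
  cl <- find_clusters(sys, "all", cutoff = 3.5)
  expect_gt(length(cl$clusters[[1]]), length(cl$clusters[[2]]))
  expect_equal(min(cl$clusters[[1]]), 1L)
})

test_that("empty selections give an empty cluster set", {
  sys <- two_spheres()
  cl <- find_clusters(sys, "name NOSUCH")
  expect_length(cl, 0)
})

test_that("make_whole reassembles split residues and is idempotent", {
  # one 3-atom molecule straddling the +x face
  atoms <- data.frame(id = 1:3, name = c("C1", "C2", "C3"),
                      element = "C", resid = 1L, resname = "MOL",
                      stringsAsFactors = FALSE)
  xyz <- rbind(c(19.0, 10, 10), c(19.8, 10, 10), c(0.6, 10, 10))  # wrapped
  sys <- structure(list(atoms = atoms,
                        frames = list(list(xyz = xyz, box = c(20, 20, 20),
                                           index = 0L))),
                   class = "md_system")
  fixed <- make_whole(sys)
  gap <- function(s) max(dist(s$frames[[1]]$xyz))
  expect_lt(gap(fixed), gap(sys))
  expect_equal(fixed$frames[[1]]$xyz[3, 1], 20.6)
  # an already-whole frame is unchanged
  again <- make_whole(fixed)
  expect_equal(again$frames[[1]]$xyz, fixed$frames[[1]]$xyz)
})

test_that("wrapped multi-residue clusters recover their true geometry", {
  sys <- make_fixture("sphere", radius = 12, spacing = 3, box = c(40, 40, 40))
  ref <- as.matrix(dist(sys$frames[[1]]$xyz))
  w <- wrap_artificially(sys, c(20, 13, 7))
  cl <- find_clusters(w, "all", cutoff = 3.5)
  expect_length(cl, 1)
  fixed <- make_whole(w, residues = cl$clusters[[1]])
  got <- as.matrix(dist(fixed$frames[[1]]$xyz))
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("center_cluster puts the aggregate at the box center and is idempotent", {
  sys <- make_fixture("sphere", radius = 12, spacing = 3, box = c(40, 40, 40),
                      n_frames = 2)
  w <- wrap_artificially(sys, c(17, 0, 11))
  cl <- find_clusters(w, "all", cutoff = 3.5)
  cen <- center_cluster(w, cl$clusters[[1]])
  for (fr in cen$frames) {
    expect_equal(colMeans(fr$xyz), c(20, 20, 20), tolerance = 1e-6)
  }
  twice <- center_cluster(cen, cl$clusters[[1]])
  expect_equal(twice$frames[[1]]$xyz, cen$frames[[1]]$xyz, tolerance = 1e-9)
})

test_that("centering a wrapped fixture restores the unwrapped density profile", {
  sys <- make_fixture("sphere", radius = 12, spacing = 3, box = c(40, 40, 40))
  ref <- density_profile(sys, "all", "all", n = 4, bin_width = 1)
  w <- wrap_artificially(sys, c(20, 13, 0))
  cl <- find_clusters(w, "all", cutoff = 3.5)
  cen <- center_cluster(w, cl$clusters[[1]])
  got <- density_profile(cen, "all", "all", n = 4, bin_width = 1)
  expect_equal(got$count, ref$count)
  expect_equal(got$free_volume, ref$free_volume)
})

test_that("center_cluster validates its argument combinations", {
  sys <- make_fixture("sphere", radius = 8, spacing = 3, box = c(30, 30, 30))
  expect_error(center_cluster(sys, integer(0)), "at least one residue")
  expect_error(center_cluster(sys, 1L, in_memory = TRUE, out_path = "x.gro"),
               "out_path")
  expect_error(center_cluster(sys, 1L, in_memory = FALSE), "out_path")
  out <- tempfile(fileext = ".gro")
  center_cluster(sys, sort(unique(sys$atoms$resid)), in_memory = FALSE,
                 out_path = out)
  expect_true(file.exists(out))
  expect_equal(n_frames(load_system(out)), 1L)
})
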