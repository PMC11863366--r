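#' Deterministic synthetic point assemblies of known density
#'
#' Generates test systems that emulate assemblies with exactly known
#' number density and geometry: a lattice-filled sphere or cylinder, a
#' bent rod (circular-arc centerline), a hollow shell, and a solvent bath
#' filling the box outside an exclusion interface. Points are placed on a
#' cubic lattice with the requested `spacing`, so the constructed number
#' density is exactly `spacing^-3`; optional uniform-random placement (for
#' property tests) is seeded and reproducible. Structure lattices are
#' anchored at the box center (one site exactly at the center); the
#' solvent lattice is anchored at the box origin with a half-spacing
#' offset.
#'
#' Shapes and their parameters (all Angstrom, centered at the box center):
#' * `sphere`: `radius`
#' * `cylinder`: `radius` and `half_height` (axis along z)
#' * `bent_rod`: tube of radius `tube_radius` around a circular arc of
#'   radius `arc_radius` spanning `arc_angle` degrees in the xy-plane
#' * `hollow_shell`: `r_inner <= |p - c| <= r_outer`
#' * `solvent_bath`: every lattice site in the box farther than `margin`
#'   outside `exclusion` (an `interface_mesh`), or the whole box when
#'   `exclusion = NULL`
#'
#' @param shape one of `"sphere"`, `"cylinder"`, `"bent_rod"`,
#'   `"hollow_shell"`, `"solvent_bath"`.
#' @param spacing lattice spacing in Angstrom (number density
#'   `spacing^-3`).
#' @param box length-3 box edges in Angstrom.
#' @param radius,half_height,r_inner,r_outer,arc_radius,arc_angle,tube_radius
#'   shape parameters, see above.
#' @param exclusion optional `interface_mesh` carved out of a solvent bath.
#' @param margin clearance (Angstrom) between solvent sites and the
#'   exclusion interface; defaults to one lattice spacing.
#' @param placement `"lattice"` (deterministic, exact density) or
#'   `"random"` (uniform in the shape, matching expected count).
#' @param seed integer seed for random placement.
#' @param n_frames replicate the static coordinates over this many frames.
#' @param name,resname atom and residue names; each atom gets its own
#'   residue id.
#' @return an `md_system`.
#' @examples
#' sph <- make_fixture("sphere", radius = 29, spacing = 2.988,
#'                     box = c(80, 80, 80))
#' nrow(sph$atoms) / (4 / 3 * pi * 29^3)  # ~0.0375 atoms/A^3
#' @export
make_fixture <- function(shape = c("sphere", "cylinder", "bent_rod",
                                   "hollow_shell", "solvent_bath"),
                         spacing, box = c(80, 80, 80),
                         radius = 29, half_height = 29,
                         r_inner = 20, r_outer = 29,
                         arc_radius = 30, arc_angle = 120, tube_radius = 8,
                         exclusion = NULL, margin = spacing,
                         placement = c("lattice", "random"), seed = 1L,
                         n_frames = 1L, name = "P", resname = "FIX") {
  shape <- match.arg(shape)
  placement <- match.arg(placement)
  stopifnot(spacing > 0, length(box) == 3, all(box > 0))
  ctr <- box / 2
  pred <- fixture_predicate(shape, ctr, radius, half_height, r_inner,
                            r_outer, arc_radius, arc_angle, tube_radius,
                            exclusion, margin)
  if (!fixture_fits(shape, ctr, box, radius, half_height, r_outer,
                    arc_radius, arc_angle, tube_radius))
    stop_fmt("the requested %s does not fit inside the box", shape)
  pts <- if (placement == "lattice") {
    cand <- if (shape == "solvent_bath") {
      origin_lattice(box, spacing)
    } else {
      centered_lattice(box, spacing, ctr)
    }
    cand[pred(cand), , drop = FALSE]
  } else {
    random_points(pred, shape, box, spacing, seed)
  }
  if (nrow(pts) == 0) stop_fmt("fixture is empty; decrease the spacing")
  solvent <- shape == "solvent_bath"
  atoms <- atoms_frame(id = seq_len(nrow(pts)),
                       name = if (solvent) "OW" else name,
                       resid = seq_len(nrow(pts)),
                       resname = if (solvent) "SOL" else resname)
  frames <- lapply(seq_len(n_frames), function(k)
    list(xyz = pts, box = as.numeric(box), index = k - 1L))
  structure(list(atoms = atoms, frames = frames,
                 topology = sprintf("<synthetic:%s>", shape),
                 trajectory = NULL),
            class = "md_system")
}

centered_lattice <- function(box, spacing, ctr) {
  ax <- lapply(1:3, function(j) {
    k <- floor(ctr[j] / spacing)
    ctr[j] + spacing * seq.int(-k, floor((box[j] - ctr[j]) / spacing))
  })
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g[g[, 1] < box[1] & g[, 2] < box[2] & g[, 3] < box[3] &
      g[, 1] >= 0 & g[, 2] >= 0 & g[, 3] >= 0, , drop = FALSE]
}

origin_lattice <- function(box, spacing) {
  ax <- lapply(1:3, function(j)
    seq.int(0, floor((box[j] - spacing / 2) / spacing)) * spacing +
      spacing / 2)
  g <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]],
                             KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

fixture_predicate <- function(shape, ctr, radius, half_height, r_inner,
                              r_outer, arc_radius, arc_angle, tube_radius,
                              exclusion, margin) {
  switch(shape,
    sphere = function(p) {
      rowSums(sweep(p, 2, ctr)^2) <= radius^2
    },
    cylinder = function(p) {
      d <- sweep(p, 2, ctr)
      d[, 1]^2 + d[, 2]^2 <= radius^2 & abs(d[, 3]) <= half_height
    },
    hollow_shell = function(p) {
      r2 <- rowSums(sweep(p, 2, ctr)^2)
      r2 >= r_inner^2 & r2 <= r_outer^2
    },
    bent_rod = function(p) {
      arc_dist(p, ctr, arc_radius, arc_angle) <= tube_radius
    },
    solvent_bath = function(p) {
      if (is.null(exclusion)) return(rep(TRUE, nrow(p)))
      signed_distance(exclusion, p) > margin
    })
}

# distance to a circular arc of radius R in the xy-plane through ctr,
# centered on ctr and spanning +-(arc_angle/2) degrees around +x
arc_dist <- function(p, ctr, R, arc_angle) {
  d <- sweep(p, 2, ctr)
  half <- arc_angle / 2 * pi / 180
  theta <- pmin(pmax(atan2(d[, 2], d[, 1]), -half), half)
  ax <- R * cos(theta)
  ay <- R * sin(theta)
  sqrt((d[, 1] - ax)^2 + (d[, 2] - ay)^2 + d[, 3]^2)
}

fixture_fits <- function(shape, ctr, box, radius, half_height, r_outer,
                         arc_radius, arc_angle, tube_radius) {
  room <- min(ctr, box - ctr)
  switch(shape,
    sphere = radius <= room,
    cylinder = max(radius, half_height) <= room,
    hollow_shell = r_outer <= room,
    bent_rod = arc_radius + tube_radius <= room,
    solvent_bath = TRUE)
}

random_points <- function(pred, shape, box, spacing, seed) {
  # expected count = density * box volume, rejection-sampled by predicate
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_try <- ceiling(prod(box) / spacing^3)
  cand <- cbind(runif(n_try, 0, box[1]), runif(n_try, 0, box[2]),
                runif(n_try, 0, box[3]))
  cand[pred(cand), , drop = FALSE]
}

#' Translate and wrap a system across periodic boundaries
#'
#' Shifts all coordinates by a constant vector and wraps them back into
#' the primary box, deliberately splitting assemblies across box faces —
#' an adversarial input for cluster identification and recentering.
#'
#' @param system an `md_system` with an orthorhombic box.
#' @param shift length-3 translation in Angstrom.
#' @return the wrapped system.
#' @export
wrap_artificially <- function(system, shift) {
  stopifnot(length(shift) == 3)
  for (k in seq_along(system$frames)) {
    fr <- system$frames[[k]]
    x <- fr$xyz + rep(shift, each = nrow(fr$xyz))
    L <- rep(fr$box, each = nrow(fr$xyz))
    system$frames[[k]]$xyz <- x - floor(x / L) * L
  }
  system
}

#' Write the standard validation fixtures to disk
#'
#' Regenerates the deterministic sphere and cylinder assemblies (29
#' Angstrom radius / half-height, 2.988 Angstrom spacing, 80 Angstrom
#' box) as GRO and XYZ files.
#'
#' @param dir output directory (created if needed).
#' @return the written paths, invisibly.
#' @export
write_fixtures <- function(dir = "fixtures") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    sphere = make_fixture("sphere", radius = 29, spacing = 2.988),
    cylinder = make_fixture("cylinder", radius = 29, half_height = 29,
                            spacing = 2.988))
  paths <- character(0)
  for (nm in names(specs)) {
    for (ext in c("gro", "xyz")) {
      p <- file.path(dir, paste0(nm, ".", ext))
      write_trajectory(specs[[nm]], p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
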