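#' Build an interface mesh over a point cloud
#'
#' Constructs a closed triangulated interface over a set of 3D points,
#' either as the convex hull or as a three-dimensional alpha shape. Both
#' are derived from one Delaunay tetrahedralization of the points: the
#' hull is the boundary of the full tetrahedron set, while the alpha shape
#' keeps only tetrahedra whose circumscribed-sphere radius is at most
#' `alpha` ("scooping out" empty space), so it can follow concave, bent or
#' hollow assemblies and can consist of several components or enclose
#' cavities. As `alpha` grows to infinity the alpha shape coincides with
#' the convex hull.
#'
#' Lattice-like input is exactly degenerate (many cospherical point
#' groups); the triangulation therefore applies a tiny deterministic
#' coordinate joggle (default 1e-4 Angstrom) before computing predicates.
#' Volumes, areas and distances are always evaluated on the original
#' coordinates.
#'
#' @param points numeric matrix (n x 3), at least 4 non-coplanar rows, in
#'   Angstrom.
#' @param kind `"hull"` or `"alpha"`.
#' @param alpha alpha radius in Angstrom, or `"auto"` to use
#'   [optimal_alpha()]. Ignored for hulls.
#' @param joggle amplitude (Angstrom) of the deterministic degeneracy-
#'   breaking perturbation (well below the coordinate precision of MD
#'   file formats).
#' @return an `interface_mesh`: vertices (row indices of `points` on the
#'   boundary), outward-oriented triangular `facets`, the underlying
#'   tetrahedra with interior flags, and cached `volume` (Angstrom^3) and
#'   `area` (Angstrom^2).
#' @seealso [signed_distance()], [mesh_contains()], [mesh_volume()],
#'   [export_mesh()]
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' m <- build_convex_hull(cube)
#' mesh_volume(m)  # 1
#' mesh_area(m)    # 6
#' @export
build_interface <- function(points, kind = c("hull", "alpha"),
                            alpha = "auto", joggle = 1e-4) {
  kind <- match.arg(kind)
  points <- validate_points(points)
  del <- cpp_delaunay(points, joggle)
  if (kind == "hull") {
    interior <- rep(TRUE, nrow(del$tets))
    alpha_val <- Inf
  } else {
    if (identical(alpha, "auto")) {
      alpha_val <- optimal_alpha_del(points, del)
    } else {
      stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
      alpha_val <- alpha
    }
    interior <- del$radius <= alpha_val
    if (!any(interior))
      stop_fmt(paste0("alpha = %g Angstrom is too small: no tetrahedron ",
                      "qualifies; increase alpha or use alpha = \"auto\""),
               alpha_val)
  }
  finish_mesh(points, del, interior, kind, alpha_val)
}

finish_mesh <- function(points, del, interior, kind, alpha_val) {
  facets <- cpp_boundary_facets(del$tets, del$adj, interior, del$qpoints)
  structure(list(
    kind = kind, alpha = alpha_val,
    points = points, qpoints = del$qpoints,
    tets = del$tets, adj = del$adj, radius = del$radius,
    tet_volume = del$volume, interior = interior,
    facets = facets,
    vertices = sort(unique(as.integer(facets))),
    volume = sum(del$volume[interior]),
    area = sum(facet_areas(points, facets)),
    joggle = del$joggle), class = "interface_mesh")
}

validate_points <- function(points) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3) stop_fmt("points must be an n x 3 matrix")
  if (any(!is.finite(points))) stop_fmt("points contain non-finite values")
  if (nrow(points) < 4)
    stop_fmt("need at least 4 points to build an interface (got %d)",
             nrow(points))
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1)) {
    what <- if (sv[2] < 1e-9 * max(sv[1], 1)) "collinear" else "coplanar"
    stop_fmt("degenerate input: points are (nearly) %s", what)
  }
  dimnames(points) <- NULL
  points
}

facet_areas <- function(points, facets) {
  if (nrow(facets) == 0) return(numeric(0))
  a <- points[facets[, 1], , drop = FALSE]
  u <- points[facets[, 2], , drop = FALSE] - a
  v <- points[facets[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' @rdname build_interface
#' @export
build_convex_hull <- function(points, joggle = 1e-4) {
  build_interface(points, kind = "hull", joggle = joggle)
}

#' @rdname build_interface
#' @export
build_alpha_shape <- function(points, alpha = "auto", joggle = 1e-4) {
  build_interface(points, kind = "alpha", alpha = alpha, joggle = joggle)
}

#' @export
print.interface_mesh <- function(x, ...) {
  cat(sprintf(
    "<interface_mesh> kind=%s%s: %d vertices, %d facets\n",
    x$kind,
    if (x$kind == "alpha") sprintf(" (alpha=%.3g A)", x$alpha) else "",
    length(x$vertices), nrow(x$facets)))
  cat(sprintf("  volume %.4g A^3, area %.4g A^2\n", x$volume, x$area))
  invisible(x)
}

#' Optimal alpha radius for an alpha shape
#'
#' Chooses the smallest alpha, among the critical values (the tetrahedron
#' circumradii of the Delaunay triangulation), for which the alpha shape
#' contains every input point in its closure and its interior forms a
#' single connected solid component. If no critical value satisfies both
#' conditions the hull-equivalent alpha (the largest circumradius) is
#' returned with a warning.
#'
#' @inheritParams build_interface
#' @return alpha in Angstrom.
#' @export
optimal_alpha <- function(points, joggle = 1e-4) {
  points <- validate_points(points)
  optimal_alpha_del(points, cpp_delaunay(points, joggle))
}

optimal_alpha_del <- function(points, del) {
  scan <- cpp_alpha_scan(del$tets, del$adj, del$radius, nrow(points))
  # state after admitting all tetrahedra with radius <= r is the state at
  # the last scan entry of each tied radius group
  last <- rev(!duplicated(rev(scan$radius)))
  ok <- scan$covered == nrow(points) & scan$components == 1L & last
  if (!any(ok)) {
    warn_fmt(paste0("no alpha yields a single component containing all ",
                    "points; falling back to the hull-equivalent alpha"))
    return(max(scan$radius))
  }
  scan$radius[which(ok)[1]]
}

#' Signed distance from points to an interface
#'
#' The magnitude is the minimum Euclidean distance from each query point
#' to the triangulated boundary (nearest facet interior, edge or vertex);
#' the sign is negative for points in the interior of the mesh, positive
#' outside, and zero on the boundary. For hulls the interior test uses
#' half-space checks against the outward facet planes; for alpha shapes it
#' uses point location in the underlying tetrahedralization.
#'
#' @param mesh an `interface_mesh`.
#' @param points numeric matrix (q x 3) or a length-3 vector.
#' @param tol boundary tolerance in Angstrom.
#' @return numeric vector of signed distances in Angstrom.
#' @export
signed_distance <- function(mesh, points, tol = 1e-9) {
  stopifnot(inherits(mesh, "interface_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  d <- cpp_dist_to_facets(points, mesh$points, mesh$facets)
  inside <- mesh_inside(mesh, points, tol)
  ifelse(inside, -d, d)
}

# interior test (boundary inclusive up to tol)
mesh_inside <- function(mesh, points, tol = 1e-9) {
  if (mesh$kind == "hull") {
    cpp_halfspace_offset(points, mesh$qpoints, mesh$facets) <= tol
  } else {
    loc <- cpp_locate(points, mesh$qpoints, mesh$tets, mesh$adj)
    ins <- loc > 0 & mesh$interior[pmax(loc, 1L)]
    if (!all(ins)) {
      # points near the boundary may be located in an exterior tetrahedron;
      # count them as inside when they touch the boundary surface
      d <- cpp_dist_to_facets(points[!ins, , drop = FALSE],
                              mesh$points, mesh$facets)
      ins[!ins] <- d <= tol
    }
    ins
  }
}

#' Point-in-interface test
#'
#' `TRUE` when the signed distance is at most zero; points exactly on the
#' boundary (hull vertices in particular) count as inside.
#'
#' @inheritParams signed_distance
#' @return logical vector.
#' @export
mesh_contains <- function(mesh, points, tol = 1e-9) {
  stopifnot(inherits(mesh, "interface_mesh"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  mesh_inside(mesh, points, tol) |
    cpp_dist_to_facets(points, mesh$points, mesh$facets) <= tol
}

#' Interface volume and surface area
#'
#' The enclosed volume is the sum of the interior tetrahedron volumes (for
#' hulls this equals the divergence-theorem volume over the oriented
#' boundary); the area is the total area of the boundary facets.
#'
#' @param mesh an `interface_mesh`.
#' @return volume in Angstrom^3 / area in Angstrom^2.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "interface_mesh"))
  mesh$volume
}

#' @rdname mesh_volume
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "interface_mesh"))
  mesh$area
}
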